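# Synthetic structures for validation: idealized guanine rings, phosphate
# placements at chosen (R, A, azimuth), two-state conformational ensembles,
# minimal hairpin fixtures and circular dihedral samples.
#
# Fixtures are geometrically plausible, not energy-minimized: the generator
# exists to exercise the descriptor and profiling code with known ground
# truth, not to emulate a force field.

P_O_BOND <- 1.48           # idealized P-O bond length, Angstrom
OPO_ANGLE <- 109.47        # tetrahedral-ish O-P-O angle, degrees

#' Idealized guanine six-membered ring
#'
#' A planar hexagon of side 1.39 Angstrom centered at the origin in the
#' xy-plane, with atoms named N1, C2, N3, C4, C5, C6 in ring order (other
#' purines use the same idealized hexagon with renamed substituents).
#'
#' @return `6 x 3` coordinate matrix with atom-name rownames.
#' @examples
#' rf <- ring_frame(make_guanine_ring())
#' rf$centroid   # the origin
#' @export
make_guanine_ring <- function() {
  ang <- deg2rad(90 - 60 * (0:5))
  m <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  rownames(m) <- PURINE_RING6
  colnames(m) <- c("x", "y", "z")
  m
}

# von Mises sampler (Best & Fisher 1979 wrapped-Cauchy rejection scheme);
# no installed package provides one. mu in degrees; returns degrees on
# [-180, 180). kappa = 0 degenerates to the circular uniform.
rvonmises_deg <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-10) return(wrap180(stats::runif(n, -180, 180)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k > 0) {
      theta <- sign(u3[ok] - 0.5) * acos(pmax(-1, pmin(1, f[ok])))
      out[(got + 1):(got + k)] <- theta
      got <- got + k
    }
  }
  wrap180(rad2deg(out) + mu)
}

#' Place an idealized phosphate group at a chosen (R, A, azimuth)
#'
#' Positions the designated closest oxygen (`OP1`) at exactly distance `r`
#' from the ring centroid, at angle `a` from the centroid-to-C4 axis, on the
#' meridian selected by `azimuth` (0 tilts straight toward the ring normal,
#' so `a = 90, azimuth = 0` puts the oxygen on the normal). The phosphorus
#' continues outward along the same ray and the second oxygen (`OP2`) is
#' placed at an idealized P-O bond length and tetrahedral angle, strictly
#' farther from the centroid. At `jitter_sigma = 0`, [measure_anion_pi()]
#' recovers `(r, a)` to machine precision.
#'
#' @param ring A [ring_frame()].
#' @param r Target oxygen-centroid distance, Angstrom (> 0).
#' @param a Target O-centroid-C4 angle, degrees in `[0, 180]`.
#' @param azimuth Rotation about the C4 axis, degrees.
#' @param jitter_sigma Gaussian coordinate noise (Angstrom) added to the
#'   placed atoms after construction.
#' @param seed Optional seed for the jitter (RNG state is restored).
#' @return `3 x 3` coordinate matrix with rownames `P`, `OP1`, `OP2`.
#' @export
place_phosphate <- function(ring, r, a, azimuth = 0, jitter_sigma = 0,
                            seed = NULL) {
  stopifnot(inherits(ring, "ring_frame"))
  if (!is.finite(r) || r <= 0) stop("R must be positive", call. = FALSE)
  if (!is.finite(a) || a < 0 || a > 180) {
    stop("A must lie in [0, 180] degrees", call. = FALSE)
  }
  ar <- deg2rad(a)
  az <- deg2rad(azimuth)
  d <- cos(ar) * ring$e1 +
    sin(ar) * (cos(az) * ring$normal + sin(az) * ring$e2)
  op1 <- ring$centroid + r * d
  p <- op1 + P_O_BOND * d
  # perpendicular direction for the second oxygen, deterministic
  m <- ring$e1 - sum(ring$e1 * d) * d
  if (vnorm(m) < 1e-6) m <- ring$e2 - sum(ring$e2 * d) * d
  m <- unitize(m)
  th <- deg2rad(180 - OPO_ANGLE)
  d2 <- cos(th) * d + sin(th) * m
  op2 <- p + P_O_BOND * d2
  out <- rbind(P = p, OP1 = op1, OP2 = op2)
  colnames(out) <- c("x", "y", "z")
  if (jitter_sigma > 0) {
    out <- out + with_seed(seed, matrix(stats::rnorm(9, 0, jitter_sigma), 3))
  }
  out
}

#' Simulate a two-state close/far anion-pi ensemble
#'
#' Generates a multi-frame ensemble of an idealized guanine ring plus a loop
#' phosphate whose contact geometry alternates between a "close" state
#' (short O...centroid distances, tight near-perpendicular angles) and a
#' "far" state (long distances, broader angular scatter). The per-frame
#' state follows a two-state Markov chain with stationary close-state
#' occupancy `p_close`; within a state, `R` is Gaussian and `A` von Mises
#' (folded onto `[0, 180]`), realized geometrically via [place_phosphate()]
#' at a uniformly random azimuth. Ground-truth labels are returned for
#' recovery tests.
#'
#' Defaults reproduce the study conditions used throughout the validation
#' suite: close at 2.9 +/- 0.1 Angstrom, far at 4.1 +/- 0.2 Angstrom,
#' occupancy 0.6.
#'
#' @param n_frames Number of frames.
#' @param p_close Stationary close-state occupancy in `[0, 1]`.
#' @param close,far Lists with `mean_r`, `sd_r` (Angstrom), `mean_a`
#'   (degrees), `kappa_a` (von Mises concentration).
#' @param switch_prob Per-frame mobility in `(0, 1]`: the transition
#'   probabilities are `switch_prob * (1 - p_close)` (close to far) and
#'   `switch_prob * p_close` (far to close), so the stationary occupancy is
#'   `p_close` for any value; `switch_prob = 1` gives i.i.d. states and
#'   `switch_prob = 0` freezes the initial state.
#' @param seed Seed for reproducible generation (RNG state restored).
#' @return List with `structure` (a `nucleic_structure` ensemble of the ring
#'   residue and phosphate), `labels` (per-frame `"close"`/`"far"`),
#'   `series` (the ground-truth sampled `(R, A)`), and `params`.
#' @export
simulate_two_state_ensemble <- function(n_frames,
                                        p_close = 0.6,
                                        close = list(mean_r = 2.9, sd_r = 0.1,
                                                     mean_a = 90,
                                                     kappa_a = 50),
                                        far = list(mean_r = 4.1, sd_r = 0.2,
                                                   mean_a = 90, kappa_a = 4),
                                        switch_prob = 1,
                                        seed = NULL) {
  stopifnot(n_frames >= 1, p_close >= 0, p_close <= 1,
            switch_prob >= 0, switch_prob <= 1,
            close$sd_r > 0, far$sd_r > 0)
  ring_xyz <- make_guanine_ring()
  rf <- ring_frame(ring_xyz)

  gen <- function() {
    state <- character(n_frames)
    state[1] <- if (stats::runif(1) < p_close) "close" else "far"
    if (n_frames > 1) {
      q_cf <- switch_prob * (1 - p_close)
      q_fc <- switch_prob * p_close
      u <- stats::runif(n_frames - 1)
      for (f in 2:n_frames) {
        state[f] <- if (state[f - 1] == "close") {
          if (u[f - 1] < q_cf) "far" else "close"
        } else {
          if (u[f - 1] < q_fc) "close" else "far"
        }
      }
    }
    draw <- function(spec, k) {
      r <- stats::rnorm(k, spec$mean_r, spec$sd_r)
      while (any(r <= 0.5)) {           # keep geometry nondegenerate
        r[r <= 0.5] <- stats::rnorm(sum(r <= 0.5), spec$mean_r, spec$sd_r)
      }
      a <- abs(wrap180(rvonmises_deg(k, spec$mean_a, spec$kappa_a)))
      list(r = r, a = a)
    }
    r <- numeric(n_frames); a <- numeric(n_frames)
    ic <- state == "close"
    if (any(ic)) { d <- draw(close, sum(ic)); r[ic] <- d$r; a[ic] <- d$a }
    if (any(!ic)) { d <- draw(far, sum(!ic)); r[!ic] <- d$r; a[!ic] <- d$a }
    az <- stats::runif(n_frames, 0, 360)
    list(state = state, r = r, a = a, az = az)
  }
  g <- with_seed(seed, gen())

  xyz <- matrix(NA_real_, n_frames, 27)
  ring_flat <- as.vector(t(ring_xyz))
  for (f in seq_len(n_frames)) {
    ph <- place_phosphate(rf, g$r[f], g$a[f], azimuth = g$az[f])
    xyz[f, ] <- c(ring_flat, as.vector(t(ph)))
  }
  atoms <- data.frame(
    elety = c(PURINE_RING6, "P", "OP1", "OP2"),
    resid = c(rep("G", 6), rep("A", 3)),
    chain = "A",
    resno = c(rep(1L, 6), rep(3L, 3)),
    elesy = c(substr(PURINE_RING6, 1, 1), "P", "O", "O"),
    stringsAsFactors = FALSE)
  list(structure = as_nucleic_structure(atoms, xyz,
                                        source = "two-state simulation"),
       assignment = tetraloop_assignment("A", c(1L, 2L, 3L, 4L), "GNRA"),
       labels = g$state,
       series = data.frame(frame = seq_len(n_frames), R = g$r, A = g$a),
       params = list(p_close = p_close, close = close, far = far,
                     switch_prob = switch_prob, seed = seed))
}

# ---- hairpin fixture -------------------------------------------------------

# Base heavy-atom templates in the xy-plane (ring from make_guanine_ring();
# exocyclic atoms radial; the imidazole ring of purines is a regular pentagon
# fused on the C4-C5 edge).
base_template <- function(letter) {
  hex <- make_guanine_ring()
  radial <- function(atom, len) {
    hex[atom, ] + len * unitize(hex[atom, ])
  }
  rot2d <- function(v, pc, theta) {
    dv <- v - pc
    c(cos(theta) * dv[1] - sin(theta) * dv[2],
      sin(theta) * dv[1] + cos(theta) * dv[2], 0) + pc
  }
  if (letter %in% c("A", "G")) {
    mid <- (hex["C4", ] + hex["C5", ]) / 2
    pc <- mid + (1.39 / (2 * tan(pi / 5))) * unitize(mid)  # pentagon center
    s <- if (vnorm(rot2d(hex["C4", ], pc, 2 * pi / 5)) >
             vnorm(rot2d(hex["C4", ], pc, -2 * pi / 5))) 1 else -1
    n9 <- rot2d(hex["C4", ], pc, s * 2 * pi / 5)
    c8 <- rot2d(n9, pc, s * 2 * pi / 5)
    n7 <- rot2d(c8, pc, s * 2 * pi / 5)
    m <- if (letter == "G") {
      rbind(hex, N9 = n9, C8 = c8, N7 = n7,
            O6 = radial("C6", 1.23), N2 = radial("C2", 1.35))
    } else {
      rbind(hex, N9 = n9, C8 = c8, N7 = n7, N6 = radial("C6", 1.34))
    }
    attr(m, "attach") <- "N9"
  } else {
    m <- if (letter == "C") {
      rbind(hex, O2 = radial("C2", 1.24), N4 = radial("C4", 1.34))
    } else {
      rbind(hex, O2 = radial("C2", 1.24), O4 = radial("C4", 1.23))
    }
    attr(m, "attach") <- "N1"
  }
  m
}

# Plausible ribose + 5'-phosphate offsets, C1' at the origin.
SUGAR_TEMPLATE <- rbind(
  P     = c(-6.1,  0.5,  1.2),
  OP1   = c(-6.9, -0.6,  1.8),
  OP2   = c(-6.5,  1.0, -0.2),
  "O5'" = c(-4.7, -0.1,  1.0),
  "C5'" = c(-3.6,  0.7,  0.6),
  "C4'" = c(-2.4, -0.1,  0.2),
  "O4'" = c(-1.2,  0.8,  0.0),
  "C3'" = c(-2.2, -1.3, -0.8),
  "O3'" = c(-2.9, -2.5, -0.5),
  "C2'" = c(-0.7, -1.4, -0.6),
  "O2'" = c(-0.1, -2.6, -1.1),
  "C1'" = c( 0.0,  0.0,  0.0))

rot_z <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1),
                            3, 3)
rot_x <- function(t) matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)),
                            3, 3)

#' Minimal stem-loop fixture with a built-in anion-pi contact
#'
#' Builds an 8-residue hairpin (2-bp stem + 4-residue loop) with plausible
#' nucleotide geometry, then positions the loop-position-3 phosphate so its
#' closest non-bridging oxygen sits at exactly (`contact_r`, `contact_a`)
#' relative to the loop-position-1 base ring. When position 1 is G the
#' default pattern of [find_tetraloops()] locates the loop and
#' [classify_anion_pi()] calls the built contact canonical. The 5'-terminal
#' residue carries no phosphate, as in deposited structures.
#'
#' The fixture is a synthetic construction for validating geometry code; it
#' is not an experimental structure and no energetic realism is claimed.
#'
#' @param loop_sequence Four letters over A, C, G, U (default `"GAAA"`).
#' @param file Optional output PDB path; written when non-`NULL`.
#' @param contact_r,contact_a Built contact geometry (Angstrom, degrees).
#' @param contact_azimuth Meridian of the contact, degrees (0 = on the ring
#'   normal for `contact_a = 90`).
#' @return A `nucleic_structure` (invisibly when `file` is given), with the
#'   output path in `$source$path`.
#' @export
make_hairpin_fixture <- function(loop_sequence = "GAAA", file = NULL,
                                 contact_r = 3.0, contact_a = 90,
                                 contact_azimuth = 0) {
  letters4 <- strsplit(toupper(loop_sequence), "")[[1]]
  if (length(letters4) != 4 || !all(letters4 %in% c("A", "C", "G", "U"))) {
    stop("loop_sequence must be 4 letters over {A, C, G, U}", call. = FALSE)
  }
  # pyrimidine-only stem placeholders so a purine-led loop is the only
  # default-pattern match in the fixture (stem pairing is not enforced)
  seq8 <- c("C", "C", letters4, "U", "U")

  rows <- list()
  coords <- list()
  eleno <- 0L
  for (i in seq_along(seq8)) {
    phi <- deg2rad(36 * (i - 1) - 90)
    origin <- c(9 * cos(phi), 9 * sin(phi), 0.6 * i)
    rot <- rot_z(phi + pi / 2) %*% rot_x(deg2rad(15 * i))

    sugar <- SUGAR_TEMPLATE
    if (i == 1) sugar <- sugar[!rownames(sugar) %in% c("P", "OP1", "OP2"), ]
    base <- base_template(seq8[i])
    attach <- attr(base, "attach")
    # glycosidic attachment: base attach atom 1.47 A from C1'
    tgt <- sugar["C1'", ] + 1.47 * unitize(c(0.9, 0.9, -0.4))
    tilt <- rot_x(deg2rad(55)) %*% rot_z(deg2rad(-30))
    base_rot <- sweep(base, 2, base[attach, ]) %*% t(tilt)
    base_rot <- sweep(base_rot, 2, tgt, FUN = "+")

    local <- rbind(sugar, base_rot)
    placed <- local %*% t(rot)
    placed <- sweep(placed, 2, origin, FUN = "+")
    nm <- rownames(local)
    for (k in seq_along(nm)) {
      eleno <- eleno + 1L
      rows[[eleno]] <- data.frame(
        eleno = eleno, elety = nm[k], resid = seq8[i], chain = "A",
        resno = i, elesy = substr(nm[k], 1, 1), stringsAsFactors = FALSE)
      coords[[eleno]] <- placed[k, ]
    }
  }
  atoms <- do.call(rbind, rows)
  xyz <- matrix(unlist(coords), nrow = 1)

  x <- as_nucleic_structure(atoms, xyz, source = "hairpin fixture")

  # realize the loop anion-pi contact: loop pos 1 ring vs loop pos 3 phosphate
  ring_sel <- select_atoms(x, "A", 3L, PURINE_RING6)
  rf <- ring_frame(atom_xyz(x, attr(ring_sel, "indices")))
  ph <- place_phosphate(rf, contact_r, contact_a, azimuth = contact_azimuth)
  for (nm in rownames(ph)) {
    row <- which(x$atoms$chain == "A" & x$atoms$resno == 5L &
                   x$atoms$elety == nm)
    x$xyz[1, (3 * row - 2):(3 * row)] <- ph[nm, ]
  }
  # keep the ester oxygen near its phosphorus for plausibility
  o5 <- which(x$atoms$resno == 5L & x$atoms$elety == "O5'")
  c5 <- which(x$atoms$resno == 5L & x$atoms$elety == "C5'")
  pv <- ph["P", ]
  c5v <- x$xyz[1, (3 * c5 - 2):(3 * c5)]
  x$xyz[1, (3 * o5 - 2):(3 * o5)] <- pv + 1.59 * unitize(c5v - pv)

  if (!is.null(file)) {
    write_structure(x, file)
    x$source <- list(path = file, format = "pdb")
    return(invisible(x))
  }
  x
}

#' Sample dihedral angles from a known circular distribution
#'
#' Reproducible samples for entropy-recovery tests: von Mises (Best-Fisher
#' sampler), circular uniform, or a point mass.
#'
#' @param n Sample size (>= 1).
#' @param distribution `"von_mises"`, `"uniform"` or `"point_mass"`.
#' @param mu Mean direction, degrees.
#' @param kappa von Mises concentration (ignored otherwise).
#' @param seed Optional seed (RNG state restored).
#' @return A `torsion_sample` with values in degrees on `[-180, 180)`.
#' @export
sample_dihedrals <- function(n, distribution = c("von_mises", "uniform",
                                                 "point_mass"),
                             mu = 0, kappa = 1, seed = NULL) {
  distribution <- match.arg(distribution)
  stopifnot(n >= 1)
  vals <- with_seed(seed, switch(distribution,
    von_mises = rvonmises_deg(n, mu, kappa),
    uniform = wrap180(stats::runif(n, -180, 180)),
    point_mass = rep(wrap180(mu), n)))
  out <- list(chain = NA_character_, resno = NA_integer_,
              angle = distribution, values = vals)
  class(out) <- "torsion_sample"
  out
}
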