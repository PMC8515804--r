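# The anion-pi descriptor: ring reference frame, (R, A) measurement with
# ring-plane decomposition, and contact classification.
#
# R is the distance from the closest non-bridging phosphate oxygen to the
# centroid of the guanine six-membered ring; A is the angle at the centroid
# between that oxygen and the ring C4 atom. A perpendicular contact over the
# ring face gives A = 90 degrees because centroid->C4 lies in the ring plane.

#' Reference frame of a nucleobase six-membered ring
#'
#' Computes the ring centroid, the least-squares plane normal (the smallest
#' principal direction of the centered, optionally mass-weighted, ring
#' coordinates) and an in-plane reference axis pointing from the centroid
#' toward C4. The in-plane basis `(e1, e2, normal)` is right-handed with
#' `e1` the in-plane projection of the C4 axis; the normal's sign follows
#' the N1 -> C2 -> N3 circulation so it is reproducible across frames.
#'
#' @param ring_xyz Numeric `6 x 3` matrix of the ring heavy atoms with
#'   rownames `N1, C2, N3, C4, C5, C6` (any order; names are required).
#' @param weighting `"geometric"` (unweighted centroid, as used for the
#'   X-ray measurements) or `"mass"` (heavy-atom center of mass, as used for
#'   the trajectory monitor). For a guanine ring the two differ by a few
#'   hundredths of an Angstrom.
#' @param elements Optional element symbols per row; inferred from the first
#'   letter of the atom name when omitted.
#' @return An object of class `ring_frame`: `centroid`, `normal` (unit),
#'   `c4_axis` (unit, centroid to C4), `e1`, `e2`, `weighting`,
#'   `plane_rmsd` (Angstrom out-of-plane scatter).
#' @export
ring_frame <- function(ring_xyz, weighting = c("geometric", "mass"),
                       elements = NULL) {
  weighting <- match.arg(weighting)
  ring_xyz <- as.matrix(ring_xyz)
  if (nrow(ring_xyz) != 6 || ncol(ring_xyz) != 3) {
    stop("ring_xyz must be a 6 x 3 coordinate matrix", call. = FALSE)
  }
  nms <- rownames(ring_xyz)
  if (is.null(nms) || !all(PURINE_RING6 %in% nms)) {
    stop("ring_xyz needs rownames N1, C2, N3, C4, C5, C6", call. = FALSE)
  }
  ring_xyz <- ring_xyz[PURINE_RING6, , drop = FALSE]
  if (any(!is.finite(ring_xyz))) stop("non-finite ring coordinates",
                                      call. = FALSE)
  if (is.null(elements)) elements <- substr(PURINE_RING6, 1, 1)
  w <- if (weighting == "mass") element_mass(elements) else rep(1, 6)
  w <- w / sum(w)

  centroid <- unname(colSums(ring_xyz * w))
  xc <- sweep(ring_xyz, 2, centroid)
  cov <- crossprod(xc * sqrt(w))          # weighted 3x3 scatter
  eig <- eigen(cov, symmetric = TRUE)
  if (eig$values[2] < 1e-9) {
    stop("degenerate ring geometry (atoms nearly collinear)", call. = FALSE)
  }
  normal <- eig$vectors[, 3]
  # orient along the N1 -> C2 -> N3 circulation
  circ <- cross3(ring_xyz["C2", ] - ring_xyz["N1", ],
                 ring_xyz["N3", ] - ring_xyz["C2", ])
  if (sum(circ * normal) < 0) normal <- -normal

  c4_axis <- unitize(ring_xyz["C4", ] - centroid, "centroid->C4 axis")
  e1 <- unitize(c4_axis - sum(c4_axis * normal) * normal,
                "in-plane C4 projection")
  e2 <- cross3(normal, e1)                # (e1, e2, normal) right-handed

  out <- list(centroid = centroid, normal = normal, c4_axis = c4_axis,
              e1 = e1, e2 = e2, weighting = weighting,
              plane_rmsd = sqrt(max(eig$values[3], 0)))  # weighted rms out-of-plane
  class(out) <- "ring_frame"
  out
}

#' @export
print.ring_frame <- function(x, ...) {
  cat(sprintf("ring_frame (%s): centroid [%.3f %.3f %.3f], plane rmsd %.4f A\n",
              x$weighting, x$centroid[1], x$centroid[2], x$centroid[3],
              x$plane_rmsd))
  invisible(x)
}

#' Measure the anion-pi descriptor for one phosphate/ring pair
#'
#' `R` is the minimum distance from the candidate phosphate oxygens
#' (default the non-bridging `OP1`/`OP2`) to the ring centroid; the
#' minimizing oxygen defines the angle `A` (vertex at the centroid, rays to
#' the oxygen and to C4), the perpendicular height `h_perp` above the ring
#' plane and the in-plane offset `d_offset` (so `h_perp^2 + d_offset^2 =
#' R^2`). Ties in `R` are broken by lexicographic atom name.
#'
#' @param phosphate_xyz Coordinate matrix of the phosphate group with atom
#'   names as rownames (at least one of `o_names` must be present).
#' @param ring A [ring_frame()].
#' @param c4_xyz Position of the ring C4 atom (length-3). Defaults to the
#'   C4 implied by the ring frame's axis at the hexagon circumradius, so
#'   passing the true atom position is recommended and done by the
#'   higher-level drivers.
#' @param o_names Candidate oxygen names, default `c("OP1", "OP2")`; add
#'   `"O5'"`/`"O3'"` to include the bridging esters.
#' @param frame_index Frame number recorded on the measurement (1-based).
#' @return Object of class `anion_pi_measurement`: `R`, `A`, `h_perp`,
#'   `d_offset`, `o_atom`, `frame_index`.
#' @export
measure_anion_pi <- function(phosphate_xyz, ring, c4_xyz = NULL,
                             o_names = c("OP1", "OP2"), frame_index = 1L) {
  stopifnot(inherits(ring, "ring_frame"))
  phosphate_xyz <- as.matrix(phosphate_xyz)
  cand <- intersect(rownames(phosphate_xyz), o_names)
  if (length(cand) == 0) {
    stop("no candidate phosphate oxygen among: ",
         paste(o_names, collapse = ", "), call. = FALSE)
  }
  cand <- sort(cand)                       # lexicographic tie-break
  d <- vapply(cand, function(nm)
    vnorm(phosphate_xyz[nm, ] - ring$centroid), numeric(1))
  o_atom <- cand[which.min(d)]
  v <- phosphate_xyz[o_atom, ] - ring$centroid
  r <- vnorm(v)
  if (r < 1e-8) stop("oxygen coincides with the ring centroid", call. = FALSE)
  u <- if (is.null(c4_xyz)) ring$c4_axis else c4_xyz - ring$centroid
  if (vnorm(u) < 1e-8) stop("C4 coincides with the ring centroid",
                            call. = FALSE)
  a <- vec_angle(v, u)
  h <- abs(sum(v * ring$normal))
  vp <- v - sum(v * ring$normal) * ring$normal
  out <- list(R = r, A = a, h_perp = h, d_offset = vnorm(vp),
              o_atom = o_atom, frame_index = as.integer(frame_index))
  class(out) <- "anion_pi_measurement"
  out
}

#' @export
print.anion_pi_measurement <- function(x, ...) {
  cat(sprintf(
    "anion-pi: R = %.3f A, A = %.1f deg (%s; h_perp %.3f, offset %.3f)\n",
    x$R, x$A, x$o_atom, x$h_perp, x$d_offset))
  invisible(x)
}

#' Classify an anion-pi contact
#'
#' A contact is `canonical` when the oxygen sits within `r_max` of the ring
#' centroid at a near-perpendicular angle (`a_window`), matching the
#' canonical geometry of roughly 3.7 Angstrom at 90 degrees; `weak` when the
#' distance is within `r_max + weak_margin` regardless of angle; `absent`
#' otherwise.
#'
#' @param m An `anion_pi_measurement`, or a numeric vector of distances (then
#'   supply `A`).
#' @param A Angles in degrees when `m` is numeric.
#' @param r_max Canonical distance cutoff, Angstrom.
#' @param a_window Angular window (degrees) for the canonical class.
#' @param weak_margin Extra distance allowed for the `weak` class, Angstrom.
#' @return Character vector over `c("canonical", "weak", "absent")`.
#' @export
classify_anion_pi <- function(m, A = NULL, r_max = 3.7,
                              a_window = c(60, 120), weak_margin = 1.0) {
  if (inherits(m, "anion_pi_measurement")) {
    R <- m$R; A <- m$A
  } else {
    R <- as.numeric(m)
    if (is.null(A)) stop("supply angles A with numeric distances",
                         call. = FALSE)
  }
  if (length(A) == 1) A <- rep(A, length(R))
  stopifnot(length(R) == length(A), r_max > 0, weak_margin >= 0)
  out <- rep("absent", length(R))
  out[R <= r_max + weak_margin] <- "weak"
  out[R <= r_max & A >= a_window[1] & A <= a_window[2]] <- "canonical"
  out
}

#' Per-frame anion-pi descriptor series for a tetraloop
#'
#' Runs [measure_anion_pi()] over every frame of an ensemble for the
#' tetraloop's guanine ring and loop phosphate, recomputing the ring frame
#' per model.
#'
#' @param x A `nucleic_structure` (multi-model for ensembles).
#' @param assignment A `tetraloop_assignment` (see [find_tetraloops()]), or
#'   `NULL` to use the first scan hit.
#' @param frames Frame numbers (1-based); default all.
#' @param weighting Ring centroid weighting, see [ring_frame()].
#' @param o_names Candidate oxygens, see [measure_anion_pi()].
#' @param time_step Optional time per frame (ps), stored as metadata.
#' @return A `descriptor_series` data.frame with columns `frame`, `R`, `A`,
#'   `h_perp`, `d_offset`, `o_atom`.
#' @export
anion_pi_series <- function(x, assignment = NULL, frames = NULL,
                            weighting = "geometric",
                            o_names = c("OP1", "OP2"), time_step = NA_real_) {
  stopifnot(inherits(x, "nucleic_structure"))
  if (is.null(assignment)) {
    hits <- find_tetraloops(x)
    if (length(hits) == 0) stop("no tetraloop found and none supplied",
                                call. = FALSE)
    assignment <- hits[[1]]
  }
  frames <- frames %||% seq_len(x$n_frames)
  ring_sel <- select_atoms(x, assignment$chain_id, assignment$ring_residue,
                           PURINE_RING6)
  p_sel <- select_atoms(x, assignment$chain_id, assignment$phosphate_residue,
                        c("P", "OP1", "OP2"))
  ring_idx <- attr(ring_sel, "indices")
  p_idx <- attr(p_sel, "indices")

  rows <- lapply(frames, function(f) {
    rxyz <- atom_xyz(x, ring_idx, frame = f)
    rf <- ring_frame(rxyz, weighting = weighting,
                     elements = ring_sel$elesy)
    m <- measure_anion_pi(atom_xyz(x, p_idx, frame = f), rf,
                          c4_xyz = rxyz["C4", ], o_names = o_names,
                          frame_index = f)
    data.frame(frame = f, R = m$R, A = m$A, h_perp = m$h_perp,
               d_offset = m$d_offset, o_atom = m$o_atom,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "time_step") <- time_step
  attr(out, "assignment") <- assignment
  class(out) <- c("descriptor_series", "data.frame")
  out
}

#' @export
plot.descriptor_series <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$frame, x$R, type = "l", xlab = "frame",
                 ylab = "R (Angstrom)", main = "O...ring-centroid distance",
                 ...)
  graphics::plot(x$R, x$A, pch = 16, cex = 0.4, xlab = "R (Angstrom)",
                 ylab = "A (degrees)", main = "distance-angle correlation",
                 ...)
  graphics::abline(h = 90, lty = 2, col = "grey50")
  invisible(x)
}
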