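# Independent oracles and small generators used across the suite. Each
# oracle is coded from a different construction than the implementation it
# checks.

# Horn quaternion absolute-orientation superposition: returns the RMSD of
# `mob` onto `ref` after the optimal rigid fit (rotation + translation).
oracle_quaternion_rmsd <- function(ref, mob) {
  rc <- colMeans(ref); mc <- colMeans(mob)
  A <- sweep(mob, 2, mc); B <- sweep(ref, 2, rc)
  S <- t(A) %*% B
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lam) / nrow(ref)
  sqrt(max(msd, 0))
}

# Dihedral via the two plane normals, signed by the triple product --
# a different construction than the atan2 formula in the package.
oracle_dihedral <- function(p1, p2, p3, p4) {
  x3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- x3(p2 - p1, p3 - p2)
  n2 <- x3(p3 - p2, p4 - p3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(max(-1, min(1, cosang))) * 180 / pi
  if (sum(x3(n1, n2) * (p3 - p2)) < 0) ang <- -ang
  a <- (ang + 180) %% 360 - 180
  if (a >= 180) a <- -180
  a
}

# Direct (R, A, h, offset) computation: explicit min over oxygens, angle by
# arccos of the normalized dot product, plane normal from an SVD.
oracle_measure <- function(ring_xyz, o_xyz_list, c4_xyz) {
  ctr <- colMeans(ring_xyz)
  sv <- svd(sweep(ring_xyz, 2, ctr))
  nrm <- sv$v[, 3]
  d <- vapply(o_xyz_list, function(o) sqrt(sum((o - ctr)^2)), numeric(1))
  o <- o_xyz_list[[which.min(d)]]
  v <- o - ctr; u <- c4_xyz - ctr
  a <- acos(max(-1, min(1, sum(v * u) / sqrt(sum(v^2) * sum(u^2))))) * 180 / pi
  h <- abs(sum(v * nrm))
  list(R = sqrt(sum(v^2)), A = a, h_perp = h,
       d_offset = sqrt(max(sum(v^2) - h^2, 0)))
}

# Binned +1 entropy via stats::hist breaks -- independent binning path.
oracle_entropy <- function(values, bin_width = 10, pseudo = 1) {
  v <- (values + 180) %% 360 - 180
  cnt <- hist(v, breaks = seq(-180, 180, by = bin_width), plot = FALSE,
              right = FALSE)$counts
  p <- (cnt + pseudo) / (length(v) + pseudo * length(cnt))
  -sum(p * log(p))
}

random_rotation_matrix <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Apply a rigid transform to every frame of a structure.
transform_structure <- function(x, rot, trans) {
  for (f in seq_len(x$n_frames)) {
    m <- matrix(x$xyz[f, ], ncol = 3, byrow = TRUE)
    x$xyz[f, ] <- as.vector(t(m %*% t(rot) + matrix(trans, nrow(m), 3,
                                                    byrow = TRUE)))
  }
  x
}

# Minimal in-memory ensemble: `coords` is a list of N x 3 frames sharing an
# atom roster given by `elety` (one residue per atom by default).
toy_ensemble <- function(coords, elety = NULL, resno = NULL, chain = "A",
                         resid = "G") {
  n <- nrow(coords[[1]])
  elety <- elety %||% paste0("C", seq_len(n))
  resno <- resno %||% seq_len(n)
  atoms <- data.frame(elety = elety, resid = resid, chain = chain,
                      resno = resno, stringsAsFactors = FALSE)
  xyz <- do.call(rbind, lapply(coords, function(m) as.vector(t(m))))
  anionpi:::as_nucleic_structure(atoms, xyz)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

hairpin_path <- function(loop = "GAAA", ...) {
  f <- tempfile(fileext = ".pdb")
  make_hairpin_fixture(loop, file = f, ...)
  f
}
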