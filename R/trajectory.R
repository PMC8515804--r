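# Ensemble-level profiles: superposed RMSD, sliding-window statistics,
# per-residue RMSF, distance-angle distributions, snapshot selection,
# native-contact conservation and ion/water occupancy grids.

PROTEIN_BACKBONE_ATOMS <- c("N", "CA", "C", "O")

is_nucleotide_row <- function(atoms) residue_letter(atoms$resid) != "X"

# Default fit selection: RNA backbone heavy atoms; falls back to all heavy
# atoms when the structure carries no nucleotides.
default_fit_selection <- function(x) {
  a <- x$atoms
  sel <- which(!a$hydrogen & is_nucleotide_row(a) &
                 a$elety %in% BACKBONE_FIT_ATOMS)
  if (length(sel) < 3) sel <- which(!a$hydrogen)
  sel
}

xyz_cols <- function(indices) as.vector(rbind(3 * indices - 2,
                                              3 * indices - 1, 3 * indices))

#' Superpose every frame of an ensemble onto a reference frame
#'
#' Least-squares rigid-body fit (via bio3d's Kabsch-type superposition) of
#' each model onto `reference_frame`, fitting on `fit_selection` (default:
#' RNA backbone heavy atoms P, O5', C5', C4', C3', O3').
#'
#' @param x A `nucleic_structure` with at least 2 frames.
#' @param reference_frame Reference model (1-based).
#' @param fit_selection Atom row indices used for the fit.
#' @return `x` with superposed coordinates.
#' @export
superpose_ensemble <- function(x, reference_frame = 1, fit_selection = NULL) {
  stopifnot(inherits(x, "nucleic_structure"))
  fit_selection <- fit_selection %||% default_fit_selection(x)
  if (length(fit_selection) < 3) stop("need at least 3 fit atoms",
                                      call. = FALSE)
  cols <- xyz_cols(fit_selection)
  fitted <- bio3d::fit.xyz(fixed = x$xyz[reference_frame, ], mobile = x$xyz,
                           fixed.inds = cols, mobile.inds = cols)
  x$xyz <- matrix(fitted, nrow = x$n_frames)
  x
}

#' Per-frame RMSD after optimal superposition
#'
#' Each frame is rigid-body fitted onto the reference frame over the
#' selected atoms before the RMSD is taken, so rigid motions contribute
#' nothing. `rmsd_series(x, k)[k] == 0` by construction.
#'
#' @param x A `nucleic_structure` ensemble (>= 2 frames).
#' @param reference_frame Reference model (1-based).
#' @param selection Atom row indices entering both fit and RMSD; default all
#'   heavy atoms of nucleotide residues (falling back to all heavy atoms).
#' @param fit Superpose before measuring (default `TRUE`).
#' @return Numeric vector of per-frame RMSD (Angstrom).
#' @export
rmsd_series <- function(x, reference_frame = 1, selection = NULL, fit = TRUE) {
  stopifnot(inherits(x, "nucleic_structure"))
  if (x$n_frames < 2) stop("need an ensemble with >= 2 frames", call. = FALSE)
  selection <- selection %||% {
    s <- which(!x$atoms$hydrogen & is_nucleotide_row(x$atoms))
    if (length(s) >= 3) s else which(!x$atoms$hydrogen)
  }
  if (length(selection) == 0) stop("empty atom selection", call. = FALSE)
  if (length(selection) < 3 && fit) stop("need >= 3 atoms to superpose",
                                         call. = FALSE)
  cols <- xyz_cols(selection)
  ref <- x$xyz[reference_frame, cols]
  mob <- x$xyz[, cols, drop = FALSE]
  if (fit) {
    mob <- bio3d::fit.xyz(fixed = x$xyz[reference_frame, ], mobile = x$xyz,
                          fixed.inds = cols, mobile.inds = cols)[, cols,
                                                                 drop = FALSE]
  }
  d2 <- sweep(mob, 2, ref)^2
  sqrt(rowSums(d2) / length(selection))
}

#' Sliding-window mean/min/max across replicates
#'
#' Windows advance by one frame; the mean is taken over all values in the
#' window pooled across replicates, and min/max are the window extremes
#' across replicates (the summary used to display replicate RMSD traces with
#' a 500 ps window).
#'
#' @param series Numeric vector, a matrix with one replicate per row, or a
#'   list of equal-length numeric vectors.
#' @param window Window length in frames (>= 1).
#' @return data.frame with columns `start`, `end` (frame indices), `mean`,
#'   `min`, `max`; one row per window position.
#' @export
sliding_window_stats <- function(series, window) {
  if (is.list(series)) series <- do.call(rbind, series)
  if (is.null(dim(series))) series <- matrix(series, nrow = 1)
  n <- ncol(series)
  window <- as.integer(window)
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  if (window > n) stop("window (", window, ") exceeds series length (", n,
                       ")", call. = FALSE)
  starts <- seq_len(n - window + 1)
  stats_ <- vapply(starts, function(s) {
    block <- series[, s:(s + window - 1), drop = FALSE]
    c(mean(block), min(block), max(block))
  }, numeric(3))
  data.frame(start = starts, end = starts + window - 1,
             mean = stats_[1, ], min = stats_[2, ], max = stats_[3, ])
}

residue_selection_policy <- function(atoms, policy) {
  nuc <- is_nucleotide_row(atoms)
  bb <- ifelse(nuc, atoms$elety %in% SUGAR_PHOSPHATE_ATOMS,
               atoms$elety %in% PROTEIN_BACKBONE_ATOMS)
  switch(policy,
         all = !atoms$hydrogen,
         backbone = !atoms$hydrogen & bb,
         side_chain = !atoms$hydrogen & !bb)
}

#' Per-residue RMSF
#'
#' Root-mean-square fluctuation about each atom's ensemble-average position
#' after global superposition (same backbone fit as [rmsd_series()]),
#' averaged over the residue's selected atoms. For nucleotides the
#' `"side_chain"` policy selects the base heavy atoms (the nucleotide analog
#' of a protein side chain); `"backbone"` the sugar-phosphate atoms.
#'
#' @param x A `nucleic_structure` ensemble.
#' @param selection_policy `"side_chain"`, `"backbone"` or `"all"`.
#' @param fit Superpose frames onto `reference_frame` first.
#' @param reference_frame Frame used for the superposition.
#' @param fit_selection Atoms used for the fit (default RNA backbone).
#' @return data.frame with `chain`, `resno`, `resid`, `rmsf` (Angstrom) and
#'   `n_atoms`, one row per residue that has selected atoms.
#' @export
rmsf_per_residue <- function(x, selection_policy = c("side_chain", "backbone",
                                                     "all"),
                             fit = TRUE, reference_frame = 1,
                             fit_selection = NULL) {
  selection_policy <- match.arg(selection_policy)
  stopifnot(inherits(x, "nucleic_structure"))
  if (fit && x$n_frames > 1) {
    x <- superpose_ensemble(x, reference_frame, fit_selection)
  }
  keep <- which(residue_selection_policy(x$atoms, selection_policy) &
                  !x$atoms$het)
  if (length(keep) == 0) stop("selection policy matches no atoms",
                              call. = FALSE)
  cols <- xyz_cols(keep)
  xyz <- x$xyz[, cols, drop = FALSE]
  mean_xyz <- colMeans(xyz)
  dev2 <- sweep(xyz, 2, mean_xyz)^2
  # per-atom msf: sum deviations over x,y,z, mean over frames
  msf <- colMeans(dev2)
  atom_msf <- msf[seq(1, length(msf), 3)] + msf[seq(2, length(msf), 3)] +
    msf[seq(3, length(msf), 3)]
  rmsf_atom <- sqrt(atom_msf)

  a <- x$atoms[keep, , drop = FALSE]
  key <- paste(a$chain, a$resno, a$insert, sep = "|")
  first <- !duplicated(key)
  agg <- tapply(rmsf_atom, key, mean)
  n_at <- tapply(rmsf_atom, key, length)
  ord <- key[first]
  data.frame(chain = a$chain[first], resno = a$resno[first],
             resid = a$resid[first], rmsf = as.numeric(agg[ord]),
             n_atoms = as.integer(n_at[ord]), stringsAsFactors = FALSE)
}

#' Binned distance-angle distribution of a descriptor series
#'
#' Two-dimensional histogram of `(R, A)` with edges anchored at zero, the
#' location of the maximal cell (ties broken toward smaller `R`, then
#' smaller `A`) and the Pearson correlation of distance and angle -- the
#' summary in which a canonical contact shows up as a compact mode near
#' (3.0-3.7 Angstrom, 90 degrees).
#'
#' @param series A `descriptor_series` (or any data.frame with `R` and `A`).
#' @param r_bin Distance bin width, Angstrom.
#' @param a_bin Angle bin width, degrees.
#' @return Object of class `hist2d`: `r_edges`, `a_edges`, `r_mids`,
#'   `a_mids`, `counts` (distance x angle), `n_total`, `mode` (bin centers
#'   of the maximal cell), `pearson`.
#' @export
descriptor_distribution <- function(series, r_bin = 0.1, a_bin = 5) {
  R <- series$R; A <- series$A
  if (length(R) < 1) stop("empty descriptor series", call. = FALSE)
  stopifnot(r_bin > 0, a_bin > 0, all(is.finite(R)), all(is.finite(A)))

  edges <- function(v, b) {
    lo <- floor(min(v) / b) * b
    hi <- ceiling(max(v) / b) * b
    if (hi <= max(v)) hi <- hi + b
    seq(lo, hi, by = b)
  }
  r_edges <- edges(R, r_bin)
  a_edges <- edges(A, a_bin)
  ri <- pmin(floor((R - r_edges[1]) / r_bin) + 1, length(r_edges) - 1)
  ai <- pmin(floor((A - a_edges[1]) / a_bin) + 1, length(a_edges) - 1)
  counts <- matrix(0L, length(r_edges) - 1, length(a_edges) - 1)
  for (k in seq_along(ri)) counts[ri[k], ai[k]] <- counts[ri[k], ai[k]] + 1L

  mx <- which(counts == max(counts), arr.ind = TRUE)
  mx <- mx[order(mx[, 1], mx[, 2]), , drop = FALSE][1, ]  # min R, then min A
  r_mids <- r_edges[-length(r_edges)] + r_bin / 2
  a_mids <- a_edges[-length(a_edges)] + a_bin / 2
  pearson <- if (stats::sd(R) > 0 && stats::sd(A) > 0) stats::cor(R, A)
             else NA_real_

  out <- list(r_edges = r_edges, a_edges = a_edges, r_mids = r_mids,
              a_mids = a_mids, counts = counts, n_total = length(R),
              mode = c(R = r_mids[mx[1]], A = a_mids[mx[2]]),
              pearson = pearson)
  class(out) <- "hist2d"
  out
}

#' @export
print.hist2d <- function(x, ...) {
  cat(sprintf(
    "hist2d: %d observations, %d x %d bins; mode (R = %.2f A, A = %.1f deg); Pearson r = %s\n",
    x$n_total, nrow(x$counts), ncol(x$counts), x$mode["R"], x$mode["A"],
    ifelse(is.na(x$pearson), "NA", sprintf("%.3f", x$pearson))))
  invisible(x)
}

#' @export
plot.hist2d <- function(x, ...) {
  graphics::image(x$r_mids, x$a_mids, x$counts, xlab = "R (Angstrom)",
                  ylab = "A (degrees)", main = "distance-angle distribution",
                  ...)
  invisible(x)
}

#' Locate modes of the distance distribution
#'
#' Finds local maxima of the 1-D histogram of `R` (bin width `r_bin`),
#' ranked by height, keeping peaks at least `min_separation` bins apart.
#' Used to recover the close/far states of a two-state ensemble.
#'
#' @param series A `descriptor_series` or numeric vector of distances.
#' @param n_modes Maximum number of modes returned.
#' @param r_bin Bin width, Angstrom.
#' @param min_separation Minimum peak separation, bins.
#' @return Numeric vector of mode locations (bin centers), sorted ascending.
#' @export
distance_modes <- function(series, n_modes = 2, r_bin = 0.1,
                           min_separation = 3) {
  R <- if (is.data.frame(series)) series$R else as.numeric(series)
  lo <- floor(min(R) / r_bin) * r_bin
  nb <- ceiling((max(R) - lo) / r_bin) + 1
  idx <- pmin(floor((R - lo) / r_bin) + 1, nb)
  cnt <- tabulate(idx, nbins = nb)
  pad <- c(-1, cnt, -1)
  is_peak <- which(pad[2:(nb + 1)] > pad[1:nb] &
                     pad[2:(nb + 1)] >= pad[3:(nb + 2)])
  is_peak <- is_peak[order(-cnt[is_peak], is_peak)]
  chosen <- integer(0)
  for (p in is_peak) {
    if (all(abs(p - chosen) >= min_separation)) chosen <- c(chosen, p)
    if (length(chosen) == n_modes) break
  }
  sort(lo + (chosen - 0.5) * r_bin)
}

#' Select representative snapshots from a descriptor series
#'
#' `peak` returns the `n` frames whose distance `R` lies nearest the series
#' mean (structures close to the average); `low_tail`/`high_tail` return the
#' `n` smallest/largest-`R` frames (the representative extremes). Ties break
#' toward the earlier frame.
#'
#' @param series A `descriptor_series`.
#' @param n Number of frames (default 5).
#' @param mode `"peak"`, `"low_tail"` or `"high_tail"`.
#' @return Sorted frame indices (1-based).
#' @export
select_snapshots <- function(series, n = 5,
                             mode = c("peak", "low_tail", "high_tail")) {
  mode <- match.arg(mode)
  R <- series$R
  frames <- if (!is.null(series$frame)) series$frame else seq_along(R)
  if (n > length(R)) stop("n exceeds the number of frames", call. = FALSE)
  ord <- switch(mode,
                peak = order(abs(R - mean(R)), seq_along(R)),
                low_tail = order(R, seq_along(R)),
                high_tail = order(-R, seq_along(R)))
  sort(frames[ord[seq_len(n)]])
}

#' Native-contact conservation across an ensemble
#'
#' Heavy-atom pairs between two chain sets within `cutoff` in the reference
#' frame define the native contact set; each frame is scored by the fraction
#' of those pairs still within `cutoff`. The reference frame scores 1 by
#' construction.
#'
#' @param x A `nucleic_structure` ensemble.
#' @param chains_a,chains_b Chain identifiers of the two partners.
#' @param reference_frame Frame defining the native set (1-based).
#' @param cutoff Contact cutoff, Angstrom (default 4.5).
#' @return List with `fraction` (per-frame numeric), `n_pairs`, and `pairs`
#'   (data.frame of atom row indices `a`, `b`).
#' @export
native_contacts <- function(x, chains_a, chains_b, reference_frame = 1,
                            cutoff = 4.5) {
  stopifnot(inherits(x, "nucleic_structure"))
  ia <- which(x$atoms$chain %in% chains_a & !x$atoms$hydrogen)
  ib <- which(x$atoms$chain %in% chains_b & !x$atoms$hydrogen)
  if (length(ia) == 0 || length(ib) == 0) {
    stop("empty partner selection", call. = FALSE)
  }
  pa <- atom_xyz(x, ia, frame = reference_frame)
  pb <- atom_xyz(x, ib, frame = reference_frame)
  c2 <- cutoff^2
  pairs <- NULL
  for (k in seq_along(ia)) {           # row-wise scan keeps memory flat
    d2 <- rowSums(sweep(pb, 2, pa[k, ])^2)
    hit <- which(d2 <= c2)
    if (length(hit) > 0) {
      pairs <- rbind(pairs, cbind(a = ia[k], b = ib[hit]))
    }
  }
  if (is.null(pairs)) {
    stop("no native contacts within ", cutoff, " Angstrom in the reference",
         call. = FALSE)
  }
  ca <- xyz_cols(pairs[, "a"])
  cb <- xyz_cols(pairs[, "b"])
  frac <- vapply(seq_len(x$n_frames), function(f) {
    d <- matrix(x$xyz[f, ca] - x$xyz[f, cb], ncol = 3, byrow = TRUE)
    mean(rowSums(d^2) <= c2)
  }, numeric(1))
  list(fraction = frac, n_pairs = nrow(pairs),
       pairs = as.data.frame(pairs))
}

#' Ion/water occupancy grid over an ensemble
#'
#' Bins the positions of the selected atoms over every frame onto a regular
#' grid; each selected atom increments the voxel containing it. Assumes the
#' ensemble has been superposed on a fixed reference (see
#' [superpose_ensemble()]). Density is `counts / (n_frames * spacing^3)`.
#'
#' @param x A `nucleic_structure`.
#' @param selection Atom row indices to map (e.g. water oxygens, K+, Mg2+).
#' @param spacing Grid spacing, Angstrom.
#' @param origin Grid origin; default snaps to the data's bounding box.
#' @param dims Voxel counts per axis; default covers the bounding box.
#' @return Object of class `occupancy_grid`: `origin`, `spacing`, `counts`
#'   (3-D array), `density`, `n_frames`, `n_outside`.
#' @export
occupancy_grid <- function(x, selection, spacing = 1.0, origin = NULL,
                           dims = NULL) {
  stopifnot(inherits(x, "nucleic_structure"), spacing > 0)
  if (length(selection) == 0) stop("empty atom selection", call. = FALSE)
  cols <- xyz_cols(selection)
  pts <- do.call(rbind, lapply(seq_len(x$n_frames), function(f)
    matrix(x$xyz[f, cols], ncol = 3, byrow = TRUE)))
  if (is.null(origin)) origin <- floor(apply(pts, 2, min) / spacing) * spacing
  if (is.null(dims)) {
    dims <- pmax(ceiling((apply(pts, 2, max) - origin) / spacing), 1)
    dims <- as.integer(dims + (apply(pts, 2, max) >= origin + dims * spacing))
  }
  vi <- floor(sweep(pts, 2, origin) / spacing) + 1
  inside <- vi[, 1] >= 1 & vi[, 1] <= dims[1] &
    vi[, 2] >= 1 & vi[, 2] <= dims[2] &
    vi[, 3] >= 1 & vi[, 3] <= dims[3]
  counts <- array(0L, dim = dims)
  if (any(inside)) {
    flat <- vi[inside, 1] + dims[1] * (vi[inside, 2] - 1) +
      dims[1] * dims[2] * (vi[inside, 3] - 1)
    tab <- tabulate(flat, nbins = prod(dims))
    counts <- array(as.integer(tab), dim = dims)
  }
  out <- list(origin = origin, spacing = spacing, counts = counts,
              density = counts / (x$n_frames * spacing^3),
              n_frames = x$n_frames, n_outside = sum(!inside))
  class(out) <- "occupancy_grid"
  out
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat(sprintf(
    "occupancy_grid: %s voxels at %.2f A, %d frames, %d observations (%d outside)\n",
    paste(dim(x$counts), collapse = " x "), x$spacing, x$n_frames,
    sum(x$counts), x$n_outside))
  invisible(x)
}

#' Write an occupancy grid as an OpenDX volumetric map
#'
#' Emits the normalized density in the OpenDX grid dialect used by common
#' molecular viewers (z varies fastest).
#'
#' @param grid An `occupancy_grid`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_dx <- function(grid, file) {
  stopifnot(inherits(grid, "occupancy_grid"))
  d <- dim(grid$counts)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", grid$origin[1], grid$origin[2],
            grid$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", grid$spacing),
    sprintf("delta 0.000000 %.6f 0.000000", grid$spacing),
    sprintf("delta 0.000000 0.000000 %.6f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  vals <- as.numeric(aperm(grid$density, c(3, 2, 1)))  # z fastest
  n3 <- (length(vals) %/% 3) * 3
  if (n3 > 0) {
    writeLines(apply(matrix(vals[seq_len(n3)], ncol = 3, byrow = TRUE), 1,
                     function(r) paste(sprintf("%.6e", r), collapse = " ")),
               con)
  }
  if (n3 < length(vals)) {
    writeLines(paste(sprintf("%.6e", vals[(n3 + 1):length(vals)]),
                     collapse = " "), con)
  }
  writeLines('attribute "dep" string "positions"', con)
  invisible(file)
}
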