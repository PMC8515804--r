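# Nucleic-acid backbone/glycosidic torsions and the binned dimensionless
# entropy statistic with +1 pseudo-counts.

# Standard nucleic-acid dihedral definitions. Offsets give the residue the
# atom belongs to, relative to the residue being analyzed.
TORSION_DEFS <- list(
  alpha   = list(atoms = c("O3'", "P", "O5'", "C5'"), offset = c(-1, 0, 0, 0)),
  beta    = list(atoms = c("P", "O5'", "C5'", "C4'"), offset = c(0, 0, 0, 0)),
  gamma   = list(atoms = c("O5'", "C5'", "C4'", "C3'"), offset = c(0, 0, 0, 0)),
  delta   = list(atoms = c("C5'", "C4'", "C3'", "O3'"), offset = c(0, 0, 0, 0)),
  epsilon = list(atoms = c("C4'", "C3'", "O3'", "P"), offset = c(0, 0, 0, 1)),
  zeta    = list(atoms = c("C3'", "O3'", "P", "O5'"), offset = c(0, 0, 1, 1)),
  chi     = list(atoms = NULL, offset = c(0, 0, 0, 0))  # base-dependent
)

CHI_PURINE <- c("O4'", "C1'", "N9", "C4")
CHI_PYRIMIDINE <- c("O4'", "C1'", "N1", "C2")

#' Signed dihedral angle of four points
#'
#' Standard signed atan2 construction about the 2-3 bond, reported in
#' degrees on the principal range `[-180, 180)` (an ideal cis arrangement is
#' 0, trans maps to -180).
#'
#' @param p1,p2,p3,p4 Length-3 numeric positions.
#' @return Angle in degrees in `[-180, 180)`.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10) {
    stop("degenerate (collinear) dihedral atoms", call. = FALSE)
  }
  m1 <- cross3(n1, b2 / vnorm(b2))
  wrap180(rad2deg(atan2(-sum(m1 * n2), sum(n1 * n2))))
}

torsion_atom_indices <- function(x, chain, resno, names, offsets) {
  idx <- integer(4)
  for (k in 1:4) {
    rows <- which(x$atoms$chain == chain &
                    x$atoms$resno == resno + offsets[k] &
                    x$atoms$insert == "" & x$atoms$elety == names[k])
    if (length(rows) != 1) return(NULL)
    idx[k] <- rows
  }
  idx
}

#' Backbone and glycosidic dihedral series for one residue
#'
#' Extracts the standard nucleic-acid torsions (alpha, beta, gamma, delta,
#' epsilon, zeta and the glycosidic chi -- `O4'-C1'-N9-C4` for purines,
#' `O4'-C1'-N1-C2` for pyrimidines) over every frame. Angles whose defining
#' atoms are missing (chain termini, incomplete residues) are omitted with a
#' warning rather than failing.
#'
#' @param x A `nucleic_structure`.
#' @param chain Chain identifier.
#' @param residue Author residue number.
#' @param angles Subset of angle names; default all seven.
#' @param frames Frame numbers (default all).
#' @return Named list of `torsion_sample` objects (fields `chain`, `resno`,
#'   `angle`, `values` in degrees on `[-180, 180)`).
#' @export
backbone_dihedrals <- function(x, chain, residue,
                               angles = names(TORSION_DEFS), frames = NULL) {
  stopifnot(inherits(x, "nucleic_structure"))
  angles <- match.arg(angles, names(TORSION_DEFS), several.ok = TRUE)
  frames <- frames %||% seq_len(x$n_frames)
  res_rows <- x$atoms$chain == chain & x$atoms$resno == residue
  if (!any(res_rows)) stop("residue not found: ", chain, ":", residue,
                           call. = FALSE)
  letter <- residue_letter(x$atoms$resid[which(res_rows)[1]])
  out <- list()
  skipped <- character(0)
  for (ang in angles) {
    def <- TORSION_DEFS[[ang]]
    nm <- def$atoms
    if (ang == "chi") {
      nm <- if (letter %in% c("A", "G")) CHI_PURINE else CHI_PYRIMIDINE
    }
    idx <- torsion_atom_indices(x, chain, residue, nm, def$offset)
    if (is.null(idx)) {
      skipped <- c(skipped, ang)
      next
    }
    vals <- vapply(frames, function(f) {
      p <- atom_xyz(x, idx, frame = f)
      dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    }, numeric(1))
    smp <- list(chain = chain, resno = residue, angle = ang, values = vals)
    class(smp) <- "torsion_sample"
    out[[ang]] <- smp
  }
  if (length(skipped) > 0) {
    warning(sprintf("residue %s:%s: omitted %s (missing defining atoms)",
                    chain, residue, paste(skipped, collapse = ", ")),
            call. = FALSE)
  }
  out
}

#' Binned dimensionless torsional entropy
#'
#' Bins the angles into `360 / bin_width` intervals anchored at -180
#' degrees, adds a `pseudo_count` to every bin to avoid `log(0)` in empty
#' regions of dihedral space, and returns `H = -sum(p * log(p))` with
#' `p_i = (c_i + pseudo_count) / (n + pseudo_count * n_bins)`. With the
#' default 10-degree bins and natural logarithm, `H` ranges from near 0
#' (a single occupied bin at large n) to `log(36)` (uniform). The positive
#' sign convention makes an entropy *increase* read as a positive delta;
#' `signed = TRUE` returns the raw `sum(p * log(p))` (its negation).
#'
#' @param sample A `torsion_sample` or numeric vector of angles (degrees;
#'   values are wrapped onto `[-180, 180)`).
#' @param bin_width Bin width in degrees; must divide 360. Default 10.
#' @param pseudo_count Count added to every bin. Default 1.
#' @param log_base Base of the logarithm (default natural).
#' @param signed Return `sum(p log p)` (<= 0) instead of its magnitude.
#' @return Dimensionless entropy, with attribute `n` (sample size) and
#'   `n_bins`.
#' @export
binned_entropy <- function(sample, bin_width = 10, pseudo_count = 1,
                           log_base = exp(1), signed = FALSE) {
  values <- if (inherits(sample, "torsion_sample")) sample$values
            else as.numeric(sample)
  if (length(values) == 0) {
    stop("empty sample: pseudo-counts alone would report maximal entropy",
         call. = FALSE)
  }
  if (!isTRUE(all.equal(360 %% bin_width, 0)) || bin_width <= 0) {
    stop("bin_width must divide 360", call. = FALSE)
  }
  stopifnot(pseudo_count >= 0, all(is.finite(values)))
  n_bins <- as.integer(round(360 / bin_width))
  v <- wrap180(values)
  idx <- pmin(floor((v + 180) / bin_width) + 1, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  p <- (counts + pseudo_count) / (length(values) + pseudo_count * n_bins)
  h <- sum(p * log(p, base = log_base))
  out <- if (signed) h else -h
  attr(out, "n") <- length(values)
  attr(out, "n_bins") <- n_bins
  out
}

#' Entropy report over residues and torsion angles
#'
#' Applies [binned_entropy()] to every extracted torsion of the requested
#' residues, the per-residue summary used to compare wild-type and mutant
#' tetraloop flexibility.
#'
#' @param x A `nucleic_structure` ensemble.
#' @param residues data.frame with columns `chain` and `resno`.
#' @param bin_width,pseudo_count,log_base Passed to [binned_entropy()].
#' @param angles Torsion names to include (default all seven).
#' @return data.frame with `chain`, `resno`, `angle`, `n`, `H`.
#' @export
entropy_report <- function(x, residues, bin_width = 10, pseudo_count = 1,
                           log_base = exp(1), angles = names(TORSION_DEFS)) {
  rows <- list()
  for (i in seq_len(nrow(residues))) {
    tors <- backbone_dihedrals(x, residues$chain[i], residues$resno[i],
                               angles = angles)
    for (smp in tors) {
      h <- binned_entropy(smp, bin_width = bin_width,
                          pseudo_count = pseudo_count, log_base = log_base)
      rows[[length(rows) + 1]] <- data.frame(
        chain = smp$chain, resno = smp$resno, angle = smp$angle,
        n = length(smp$values), H = as.numeric(h), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) stop("no torsions could be extracted", call. = FALSE)
  do.call(rbind, rows)
}

#' Entropy difference between two reports
#'
#' Per-(residue, angle) difference `H_b - H_a`; a positive value means the
#' torsion is more disordered in `report_b` (e.g. mutant vs wild type). Keys
#' present in only one report are dropped with a warning.
#'
#' @param report_a,report_b Outputs of [entropy_report()].
#' @return data.frame with `chain`, `resno`, `angle`, `H_a`, `H_b`, `delta`.
#' @export
entropy_delta <- function(report_a, report_b) {
  key_a <- paste(report_a$chain, report_a$resno, report_a$angle, sep = "|")
  key_b <- paste(report_b$chain, report_b$resno, report_b$angle, sep = "|")
  shared <- intersect(key_a, key_b)
  if (length(shared) == 0) stop("no shared (residue, angle) keys",
                                call. = FALSE)
  only <- c(setdiff(key_a, key_b), setdiff(key_b, key_a))
  if (length(only) > 0) {
    warning("keys present in only one report: ",
            paste(only, collapse = "; "), call. = FALSE)
  }
  ia <- match(shared, key_a)
  ib <- match(shared, key_b)
  data.frame(chain = report_a$chain[ia], resno = report_a$resno[ia],
             angle = report_a$angle[ia], H_a = report_a$H[ia],
             H_b = report_b$H[ib],
             delta = report_b$H[ib] - report_a$H[ia],
             stringsAsFactors = FALSE)
}
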