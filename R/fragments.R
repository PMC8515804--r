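# Export of QM-ready model fragments: bases cut at the glycosidic bond,
# phosphates cut at the ester bonds, every severed bond capped along the
# original bond vector. Coordinates only -- no energies are computed here.

CAP_LENGTH <- list(
  hydrogen = c(N = 1.01, C = 1.09, O = 0.96),
  methyl   = c(N = 1.47, C = 1.54, O = 1.43))

cap_atom <- function(host_xyz, host_element, target_xyz, capping) {
  len <- CAP_LENGTH[[capping]][toupper(host_element)]
  if (is.na(len)) stop("no capping rule for element ", host_element,
                       call. = FALSE)
  list(element = if (capping == "hydrogen") "H" else "C",
       xyz = host_xyz + len * unitize(target_xyz - host_xyz))
}

prev_residue_atom <- function(x, chain, resno, name) {
  which(x$atoms$chain == chain & x$atoms$resno == resno - 1 &
          x$atoms$insert == "" & x$atoms$elety == name)
}

next_residue_atom <- function(x, chain, resno, name) {
  which(x$atoms$chain == chain & x$atoms$resno == resno + 1 &
          x$atoms$insert == "" & x$atoms$elety == name)
}

# Atom rows + severed-bond caps for one (chain, resno, part) request.
part_atoms <- function(x, chain, resno, part, frame, capping) {
  res <- select_atoms(x, chain, resno)
  idx_all <- attr(res, "indices")
  heavy <- idx_all[!res$hydrogen]
  names_h <- x$atoms$elety[heavy]
  xyz1 <- function(row) x$xyz[frame, (3 * row - 2):(3 * row)]
  need <- function(name, rows, bond) {
    r <- rows[x$atoms$elety[rows] == name]
    if (length(r) != 1) {
      stop("undefined cut site: cannot cap severed bond ", bond,
           " (missing ", name, ")", call. = FALSE)
    }
    r
  }
  caps <- list()
  add_cap <- function(host_row, target_row, bond) {
    cp <- cap_atom(xyz1(host_row), x$atoms$elesy[host_row], xyz1(target_row),
                   capping)
    caps[[length(caps) + 1]] <<- data.frame(
      bond = bond, host = x$atoms$elety[host_row], host_resno = resno,
      element = cp$element, x = cp$xyz[1], y = cp$xyz[2], z = cp$xyz[3],
      stringsAsFactors = FALSE)
  }

  if (part == "base") {
    keep <- heavy[!names_h %in% SUGAR_PHOSPHATE_ATOMS]
    if (length(keep) == 0) stop("residue ", chain, ":", resno,
                                " has no base atoms", call. = FALSE)
    letter <- residue_letter(x$atoms$resid[keep[1]])
    attach_name <- if (letter %in% c("A", "G")) "N9" else "N1"
    attach <- need(attach_name, keep, paste0(attach_name, "-C1'"))
    c1 <- need("C1'", heavy, paste0(attach_name, "-C1'"))
    add_cap(attach, c1, paste0(attach_name, "-C1'"))
    list(idx = keep, caps = caps)
  } else if (part == "phosphate") {
    keep <- heavy[names_h %in% c("P", "OP1", "OP2", "O5'")]
    if (!all(c("P", "OP1", "OP2", "O5'") %in% x$atoms$elety[keep])) {
      stop("residue ", chain, ":", resno,
           " lacks a complete 5'-phosphate (P, OP1, OP2, O5')",
           call. = FALSE)
    }
    o5 <- need("O5'", keep, "O5'-C5'")
    c5 <- need("C5'", heavy, "O5'-C5'")
    add_cap(o5, c5, "O5'-C5'")
    o3_prev <- prev_residue_atom(x, chain, resno, "O3'")
    if (length(o3_prev) == 1) {
      c3_prev <- prev_residue_atom(x, chain, resno, "C3'")
      if (length(c3_prev) != 1) {
        stop("undefined cut site: cannot cap severed bond O3'-C3' ",
             "(missing C3' on residue ", resno - 1, ")", call. = FALSE)
      }
      add_cap(o3_prev, c3_prev, "O3'-C3'")
      keep <- c(keep, o3_prev)
    }
    list(idx = keep, caps = caps)
  } else if (part == "full") {
    keep <- heavy
    if ("P" %in% names_h) {
      o3_prev <- prev_residue_atom(x, chain, resno, "O3'")
      if (length(o3_prev) == 1) {
        c3_prev <- prev_residue_atom(x, chain, resno, "C3'")
        if (length(c3_prev) != 1) {
          stop("undefined cut site: cannot cap severed bond O3'-C3'",
               call. = FALSE)
        }
        add_cap(o3_prev, c3_prev, "O3'-C3'")
        keep <- c(keep, o3_prev)
      }
    }
    p_next <- next_residue_atom(x, chain, resno, "P")
    if (length(p_next) == 1 && "O3'" %in% names_h) {
      o3 <- need("O3'", heavy, "O3'-P")
      add_cap(o3, p_next, "O3'-P")
    }
    list(idx = keep, caps = caps)
  } else {
    stop("unknown part: ", part, " (use base, phosphate or full)",
         call. = FALSE)
  }
}

#' Carve a capped model fragment from one frame
#'
#' Extracts the requested residue parts (`base`: base heavy atoms cut at the
#' glycosidic bond; `phosphate`: the PO4 core -- P, OP1, OP2, O5' plus the
#' preceding residue's O3' -- cut at the two ester bonds; `full`: all heavy
#' atoms plus the 5' bridging O3') and caps every severed bond along the
#' original bond vector at a standard bond length (N-H 1.01, C-H 1.09, O-H
#' 0.96 Angstrom; `methyl` places a carbon instead). Parent heavy atoms are
#' never moved; caps are the only added records, and each one is listed in
#' the manifest.
#'
#' @param x A `nucleic_structure`.
#' @param residues data.frame with columns `chain`, `resno`, `part`.
#' @param frame Frame to carve from (1-based).
#' @param capping `"hydrogen"` or `"methyl"`.
#' @return Object of class `qm_fragment`: `elements`, `xyz` (caps last),
#'   `atom_names`, `n_heavy`, `caps` (the severed-bond manifest).
#' @export
carve_fragment <- function(x, residues, frame = 1,
                           capping = c("hydrogen", "methyl")) {
  capping <- match.arg(capping)
  stopifnot(inherits(x, "nucleic_structure"), nrow(residues) >= 1)
  idx <- integer(0)
  caps <- list()
  for (i in seq_len(nrow(residues))) {
    pa <- part_atoms(x, residues$chain[i], residues$resno[i],
                     residues$part[i], frame, capping)
    idx <- c(idx, pa$idx)
    caps <- c(caps, pa$caps)
  }
  idx <- unique(idx)
  xyz <- atom_xyz(x, idx, frame = frame)
  caps_df <- if (length(caps) > 0) do.call(rbind, caps) else
    data.frame(bond = character(0), host = character(0),
               host_resno = integer(0), element = character(0),
               x = numeric(0), y = numeric(0), z = numeric(0))
  out <- list(
    elements = c(x$atoms$elesy[idx], caps_df$element),
    xyz = rbind(unname(xyz), as.matrix(caps_df[, c("x", "y", "z")])),
    atom_names = c(x$atoms$elety[idx],
                   paste0("cap:", caps_df$bond)),
    atom_rows = idx,
    n_heavy = length(idx),
    caps = caps_df,
    frame = frame,
    capping = capping)
  class(out) <- "qm_fragment"
  out
}

#' @export
print.qm_fragment <- function(x, ...) {
  cat(sprintf("qm_fragment: %d heavy atoms + %d cap(s) [%s capping]\n",
              x$n_heavy, nrow(x$caps), x$capping))
  if (nrow(x$caps) > 0) {
    cat("  severed bonds:", paste(x$caps$bond, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a fragment in XYZ format
#'
#' Standard XYZ: atom count, comment line, then `element x y z` per atom in
#' Angstrom. Round-trips through [read_xyz()].
#'
#' @param fragment A `qm_fragment` (or list with `elements` and `xyz`).
#' @param file Output path.
#' @param comment Comment line content.
#' @return `file`, invisibly.
#' @export
write_xyz <- function(fragment, file, comment = "") {
  n <- length(fragment$elements)
  lines <- c(as.character(n), comment,
             sprintf("%-2s %14.8f %14.8f %14.8f", fragment$elements,
                     fragment$xyz[, 1], fragment$xyz[, 2], fragment$xyz[, 3]))
  writeLines(lines, file)
  invisible(file)
}

#' Strict XYZ reader
#'
#' @param file Path to an XYZ file.
#' @return List with `elements`, `xyz`, `comment`.
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  if (length(lines) < 2) stop("not an XYZ file: too short", call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("not an XYZ file: first line must be the atom count",
                     call. = FALSE)
  if (length(lines) < 2 + n) stop("XYZ file truncated: expected ", n,
                                  " atom lines", call. = FALSE)
  toks <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  bad <- which(vapply(toks, length, integer(1)) < 4)
  if (length(bad) > 0) stop("malformed XYZ atom line ", bad[1] + 2,
                            call. = FALSE)
  xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  if (any(!is.finite(xyz))) stop("non-numeric coordinates in XYZ file",
                                 call. = FALSE)
  list(elements = vapply(toks, `[`, character(1), 1), xyz = xyz,
       comment = lines[2])
}

#' Export a two-fragment (dimer) model
#'
#' Carves two disjoint fragments from the same frame and writes a single
#' XYZ-style file whose comment records the per-fragment atom counts (the
#' bookkeeping needed downstream for counterpoise corrections -- no energy
#' is computed) and whose fragments are separated by a marker line. The JSON
#' manifest records atom counts, every cap, and the shortest heavy-atom
#' distance between the fragments.
#'
#' @param x A `nucleic_structure`.
#' @param spec_a,spec_b Residue-part data.frames as in [carve_fragment()].
#' @param frame Frame to carve from.
#' @param capping `"hydrogen"` or `"methyl"`.
#' @param file Optional output path for the dimer coordinates.
#' @param manifest_file Optional output path for the JSON manifest.
#' @return List with `fragment_a`, `fragment_b`, `manifest` (invisibly when
#'   `file` is given).
#' @export
export_dimer <- function(x, spec_a, spec_b, frame = 1,
                         capping = c("hydrogen", "methyl"), file = NULL,
                         manifest_file = NULL) {
  capping <- match.arg(capping)
  fa <- carve_fragment(x, spec_a, frame = frame, capping = capping)
  fb <- carve_fragment(x, spec_b, frame = frame, capping = capping)
  if (length(intersect(fa$atom_rows, fb$atom_rows)) > 0) {
    stop("overlapping fragment selections", call. = FALSE)
  }
  # shortest heavy-atom distance between the fragments
  pa <- fa$xyz[seq_len(fa$n_heavy), , drop = FALSE]
  pb <- fb$xyz[seq_len(fb$n_heavy), , drop = FALSE]
  dmin <- min(vapply(seq_len(nrow(pa)), function(k)
    min(rowSums(sweep(pb, 2, pa[k, ])^2)), numeric(1)))
  manifest <- list(
    n_atoms_a = length(fa$elements), n_atoms_b = length(fb$elements),
    n_heavy_a = fa$n_heavy, n_heavy_b = fb$n_heavy,
    capping = capping, frame = frame,
    min_interfragment_distance = sqrt(dmin),
    caps_a = fa$caps, caps_b = fb$caps)
  if (!is.null(file)) {
    n <- length(fa$elements) + length(fb$elements)
    fmt <- function(f) sprintf("%-2s %14.8f %14.8f %14.8f", f$elements,
                               f$xyz[, 1], f$xyz[, 2], f$xyz[, 3])
    writeLines(c(as.character(n),
                 sprintf("fragment_a=%d fragment_b=%d",
                         length(fa$elements), length(fb$elements)),
                 fmt(fa),
                 "# --- fragment boundary ---",
                 fmt(fb)), file)
  }
  if (!is.null(manifest_file)) {
    jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  }
  out <- list(fragment_a = fa, fragment_b = fb, manifest = manifest)
  if (!is.null(file)) invisible(out) else out
}
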