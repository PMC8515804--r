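# Structure input/output and residue/atom resolution.
#
# Parsing of PDB and mmCIF files is delegated to bio3d; this module wraps the
# parsed result in a light container with the conventions the geometry layer
# relies on: author residue numbering, altloc-A filtering, legacy phosphate
# oxygen names normalized, hydrogens flagged, identical atom roster across
# models.

# Backbone + sugar heavy-atom names (PDB v3 primes). Everything else that is
# not hydrogen counts as a base ("side chain") atom for a nucleotide.
SUGAR_PHOSPHATE_ATOMS <- c("P", "OP1", "OP2", "OP3",
                           "O5'", "C5'", "C4'", "O4'",
                           "C3'", "O3'", "C2'", "O2'", "C1'")

PURINE_RING6 <- c("N1", "C2", "N3", "C4", "C5", "C6")

BACKBONE_FIT_ATOMS <- c("P", "O5'", "C5'", "C4'", "C3'", "O3'")

NUCLEOTIDE_LETTER <- c(A = "A", C = "C", G = "G", U = "U",
                       DA = "A", DC = "C", DG = "G", DT = "T",
                       ADE = "A", CYT = "C", GUA = "G", URA = "U", URI = "U")

# Map a 3-letter (or 1-letter) residue code to a sequence letter; unknown
# residues (protein, ions, water) become "X" so they break nucleotide runs.
residue_letter <- function(resid) {
  l <- NUCLEOTIDE_LETTER[toupper(resid)]
  l[is.na(l)] <- "X"
  unname(l)
}

normalize_atom_names <- function(elety) {
  elety <- gsub("\\*", "'", elety)          # C1* -> C1' (legacy sugar names)
  elety[elety == "O1P"] <- "OP1"
  elety[elety == "O2P"] <- "OP2"
  elety[elety == "O3P"] <- "OP3"
  elety
}

#' Read a nucleic-acid structure or conformational ensemble
#'
#' Reads a (possibly multi-model) PDB or mmCIF file into a
#' `nucleic_structure`: an atom table plus an `n_frames x 3N` coordinate
#' matrix. HETATM records (ions, waters) are retained and flagged; hydrogens
#' are retained but flagged and ignored by all geometry operations. Alternate
#' locations are resolved deterministically: altloc `'A'` or blank is kept,
#' with the highest occupancy on ties. Legacy `O1P`/`O2P` names are
#' normalized to `OP1`/`OP2`. Author residue numbering is preserved.
#'
#' @param path Path to a PDB or mmCIF file.
#' @param format One of `"auto"` (by extension), `"pdb"`, `"cif"`.
#' @return An object of class `nucleic_structure` with elements `atoms`
#'   (data.frame: `eleno`, `elety`, `resid`, `chain`, `resno`, `insert`,
#'   `elesy`, `o`, `b`, `het`, `hydrogen`), `xyz` (matrix, one row per
#'   model), `n_frames`, and `source`.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' make_hairpin_fixture("GAAA", file = pdb)
#' s <- read_structure(pdb)
#' s$n_frames
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
    } else {
      bio3d::read.cif(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
    },
    error = function(e) {
      stop(sprintf("cannot parse '%s' as %s: %s", path, format,
                   conditionMessage(e)), call. = FALSE)
    })
  atoms <- parsed$atom
  if (is.null(atoms) || nrow(atoms) == 0) {
    stop("empty structure (zero atoms): ", path, call. = FALSE)
  }
  xyz <- as.matrix(parsed$xyz)
  if (nrow(xyz) < 1) stop("no coordinate models in ", path, call. = FALSE)

  atoms$elety <- normalize_atom_names(atoms$elety)
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$o[is.na(atoms$o)] <- 1

  keep <- resolve_altloc(atoms)
  atoms <- atoms[keep, , drop = FALSE]
  xyz_cols <- as.vector(rbind(3 * keep - 2, 3 * keep - 1, 3 * keep))
  xyz <- xyz[, xyz_cols, drop = FALSE]

  # atom-name uniqueness within a residue (after altloc resolution)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "|")
  if (anyDuplicated(key)) {
    warning("duplicate atom names within a residue; keeping first occurrence")
    keep2 <- !duplicated(key)
    atoms <- atoms[keep2, , drop = FALSE]
    idx <- which(keep2)
    xyz <- xyz[, as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx)),
               drop = FALSE]
  }
  if (any(!is.finite(xyz[1, ]))) {
    stop("non-finite coordinates in model 1 of ", path, call. = FALSE)
  }

  elesy <- atoms$elesy
  bad <- is.na(elesy) | elesy == ""
  elesy[bad] <- substr(gsub("[^A-Za-z].*", "", atoms$elety[bad]), 1, 1)
  atoms$elesy <- toupper(elesy)

  out <- list(
    atoms = data.frame(
      eleno = atoms$eleno, elety = atoms$elety, resid = atoms$resid,
      chain = atoms$chain, resno = atoms$resno, insert = atoms$insert,
      elesy = atoms$elesy, o = atoms$o, b = atoms$b,
      het = atoms$type == "HETATM",
      hydrogen = atoms$elesy %in% c("H", "D"),
      stringsAsFactors = FALSE),
    xyz = unname(xyz),
    n_frames = nrow(xyz),
    source = list(path = path, format = format)
  )
  class(out) <- "nucleic_structure"
  out
}

# Row indices to keep after altloc resolution: blank or 'A' preferred, then
# highest occupancy, then alphabetical altloc (deterministic).
resolve_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "|")
  pref <- ifelse(atoms$alt == "", 0L, ifelse(atoms$alt == "A", 1L, 2L))
  ord <- order(pref, -atoms$o, atoms$alt)
  sort(ord[!duplicated(key[ord])])
}

#' @export
print.nucleic_structure <- function(x, ...) {
  cat("nucleic_structure:", nrow(x$atoms), "atoms,",
      x$n_frames, if (x$n_frames == 1) "model," else "models,",
      length(unique(x$atoms$chain)), "chain(s)\n")
  cat("  source:", x$source$path, sprintf("[%s]\n", x$source$format))
  het <- sum(x$atoms$het)
  if (het > 0) cat("  HETATM records retained:", het, "\n")
  invisible(x)
}

# Build a nucleic_structure directly from an atom table and coordinates
# (used by the synthetic generator). xyz: n_frames x 3N matrix.
as_nucleic_structure <- function(atoms, xyz, source = "in-memory") {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  stopifnot(ncol(xyz) == 3 * nrow(atoms))
  need <- c("elety", "resid", "chain", "resno")
  stopifnot(all(need %in% names(atoms)))
  atoms$eleno <- atoms$eleno %||% seq_len(nrow(atoms))
  atoms$insert <- atoms$insert %||% ""
  atoms$elesy <- atoms$elesy %||% toupper(substr(atoms$elety, 1, 1))
  atoms$o <- atoms$o %||% 1
  atoms$b <- atoms$b %||% 0
  atoms$het <- atoms$het %||% FALSE
  atoms$hydrogen <- atoms$hydrogen %||% (atoms$elesy %in% c("H", "D"))
  out <- list(atoms = as.data.frame(atoms, stringsAsFactors = FALSE),
              xyz = unname(as.matrix(xyz)), n_frames = nrow(xyz),
              source = list(path = source, format = "memory"))
  class(out) <- "nucleic_structure"
  out
}

#' Write a structure (all models) to a PDB file
#'
#' Coordinates are written at standard PDB precision (3 decimals); multiple
#' frames become MODEL/ENDMDL blocks.
#'
#' @param x A `nucleic_structure`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_structure <- function(x, file) {
  stopifnot(inherits(x, "nucleic_structure"))
  a <- x$atoms
  bio3d::write.pdb(file = file, xyz = x$xyz,
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resid, eleno = a$eleno,
                   elety = a$elety, chain = a$chain, insert = a$insert,
                   o = a$o, b = ifelse(is.na(a$b), 0, a$b), elesy = a$elesy)
  invisible(file)
}

#' Select named atoms of one residue
#'
#' Resolves atoms by author chain/residue number (+ optional insertion code).
#' Requested names that are absent are reported in the `"missing"` attribute
#' and via a warning -- never silently dropped.
#'
#' @param x A `nucleic_structure`.
#' @param chain Chain identifier.
#' @param residue Author residue number.
#' @param names Character vector of atom names; `NULL` selects all atoms of
#'   the residue.
#' @param insert Insertion code (default `""`).
#' @return The matching rows of `x$atoms`, with attributes `indices` (row
#'   indices into the atom table, usable with [atom_xyz()]) and `missing`.
#' @export
select_atoms <- function(x, chain, residue, names = NULL, insert = "") {
  stopifnot(inherits(x, "nucleic_structure"))
  rows <- which(x$atoms$chain == chain & x$atoms$resno == residue &
                  x$atoms$insert == insert)
  if (length(rows) == 0) {
    stop(sprintf("residue %s:%s%s not found", chain, residue, insert),
         call. = FALSE)
  }
  missing <- character(0)
  if (!is.null(names)) {
    found <- x$atoms$elety[rows]
    missing <- setdiff(names, found)
    rows <- rows[match(intersect(names, found), found)]
    if (length(missing) > 0) {
      warning(sprintf("residue %s:%s lacks atom(s): %s", chain, residue,
                      paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  out <- x$atoms[rows, , drop = FALSE]
  attr(out, "indices") <- rows
  attr(out, "missing") <- missing
  out
}

#' Coordinates of selected atoms in one frame
#'
#' @param x A `nucleic_structure`.
#' @param indices Atom row indices (e.g. `attr(select_atoms(...), "indices")`).
#' @param frame Model number (1-based).
#' @return Numeric `length(indices) x 3` matrix with atom-name rownames.
#' @export
atom_xyz <- function(x, indices, frame = 1) {
  stopifnot(inherits(x, "nucleic_structure"))
  if (frame < 1 || frame > x$n_frames) stop("frame out of range", call. = FALSE)
  m <- matrix(x$xyz[frame, as.vector(rbind(3 * indices - 2, 3 * indices - 1,
                                           3 * indices))],
              ncol = 3, byrow = TRUE)
  rownames(m) <- x$atoms$elety[indices]
  m
}

# Ordered residue table for one chain (nucleotides and everything else, in
# file order, one row per (resno, insert)).
residue_table <- function(x, chain) {
  a <- x$atoms[x$atoms$chain == chain, , drop = FALSE]
  key <- paste(a$resno, a$insert, sep = "|")
  first <- !duplicated(key)
  data.frame(resno = a$resno[first], insert = a$insert[first],
             resid = a$resid[first], letter = residue_letter(a$resid[first]),
             stringsAsFactors = FALSE)
}

has_atoms <- function(x, chain, resno, names, insert = "") {
  rows <- x$atoms$chain == chain & x$atoms$resno == resno &
    x$atoms$insert == insert
  all(names %in% x$atoms$elety[rows])
}

#' Construct a tetraloop assignment by hand
#'
#' Explicit assignment of the four loop residues (5' to 3', author
#' numbering): position 1 carries the purine ring, position 3 the loop
#' phosphate. Used to bypass the sequence scan of [find_tetraloops()], e.g.
#' for a known loop position.
#'
#' @param chain Chain identifier.
#' @param loop_residues Four residue numbers in 5' to 3' order.
#' @param sequence Optional 4-letter loop sequence label.
#' @return A `tetraloop_assignment`.
#' @export
tetraloop_assignment <- function(chain, loop_residues, sequence = "NNNN") {
  stopifnot(length(loop_residues) == 4)
  new_tetraloop_assignment(chain, loop_residues, sequence)
}

new_tetraloop_assignment <- function(chain, loop_residues, sequence) {
  out <- list(chain_id = chain,
              loop_residues = as.integer(loop_residues),
              ring_residue = as.integer(loop_residues[1]),
              phosphate_residue = as.integer(loop_residues[3]),
              sequence = sequence)
  class(out) <- "tetraloop_assignment"
  out
}

#' @export
print.tetraloop_assignment <- function(x, ...) {
  cat(sprintf("tetraloop %s (chain %s, residues %s): ring G%d, loop phosphate on residue %d\n",
              x$sequence, x$chain_id,
              paste(x$loop_residues, collapse = "-"),
              x$ring_residue, x$phosphate_residue))
  invisible(x)
}

#' Locate GNRA-family tetraloops
#'
#' Scans each chain's nucleotide sequence for the loop pattern (default
#' `G[AUGC][AG][AG]`, i.e. GNRA read with the first base fixed to G) and
#' keeps matches whose first residue carries a complete purine six-membered
#' ring (N1, C2, N3, C4, C5, C6) and whose third residue carries a 5'
#' phosphate (P, OP1, OP2) -- the phosphate that sits between loop positions
#' 2 and 3 and faces the first G. Matches may overlap. An explicit
#' `override` (e.g. `list(chain = "B", start = 13)`) bypasses the sequence
#' scan but is still validated against the atom roster.
#'
#' @param x A `nucleic_structure`.
#' @param pattern Sequence regular expression for the four loop residues.
#' @param override `NULL`, or `list(chain =, start =)` naming the first loop
#'   residue by author numbering.
#' @return A list of `tetraloop_assignment` objects (possibly empty).
#' @export
find_tetraloops <- function(x, pattern = "G[AUGC][AG][AG]", override = NULL) {
  stopifnot(inherits(x, "nucleic_structure"))

  validate <- function(chain, rt, pos) {
    if (pos + 3 > nrow(rt)) return(NULL)
    block <- rt[pos:(pos + 3), , drop = FALSE]
    if (any(block$letter == "X")) return(NULL)
    # consecutive in sequence: author numbers increase by one (no inserts)
    if (!(all(diff(block$resno) == 1) && all(block$insert == ""))) return(NULL)
    if (!has_atoms(x, chain, block$resno[1], PURINE_RING6)) return(NULL)
    if (!has_atoms(x, chain, block$resno[3], c("P", "OP1", "OP2"))) return(NULL)
    new_tetraloop_assignment(chain, block$resno,
                             paste(block$letter, collapse = ""))
  }

  if (!is.null(override)) {
    if (inherits(override, "tetraloop_assignment")) return(list(override))
    rt <- residue_table(x, override$chain)
    pos <- which(rt$resno == override$start & rt$insert == "")
    if (length(pos) != 1) {
      stop("override residue not found: ", override$chain, ":",
           override$start, call. = FALSE)
    }
    asg <- validate(override$chain, rt, pos)
    if (is.null(asg)) {
      stop("override position fails tetraloop requirements (ring or ",
           "phosphate atoms missing, or residues not consecutive)",
           call. = FALSE)
    }
    return(list(asg))
  }

  out <- list()
  for (chain in unique(x$atoms$chain)) {
    rt <- residue_table(x, chain)
    if (nrow(rt) < 4) next
    seq_str <- paste(rt$letter, collapse = "")
    # zero-width lookahead so overlapping motifs are all reported
    m <- gregexpr(paste0("(?=", pattern, ")"), seq_str, perl = TRUE)[[1]]
    if (m[1] == -1) next
    for (pos in as.integer(m)) {
      asg <- validate(chain, rt, pos)
      if (!is.null(asg)) out[[length(out) + 1]] <- asg
    }
  }
  out
}
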