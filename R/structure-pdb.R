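## Structure module, part 1: complex container, amino-acid tables and
## PDB I/O.  Coordinates are stored internally in nm (contact cutoffs
## in the analysis are nm-valued); PDB files are Angstrom and converted
## on read/write.  No mature PDB parser ships with the installed R
## stack, so a minimal fixed-width reader/writer for standard
## single-character-chain PDB records lives here.

## Side-chain heavy atoms per standard residue type (PDB names, no
## hydrogens).  Backbone is N, CA, C, O (+ terminal OXT).  Glycine has
## no side-chain heavy atom; its CA acts as side-chain proxy in the
## contact analysis.
.SIDECHAIN_ATOMS <- list(
  ALA = c("CB"),
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(0),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2"))

.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

## Bondi van der Waals radii (nm) by element; fallback for unknown
## elements / coarse-grained pseudo-atoms is carbon.
.BONDI_NM <- c(C = 0.170, N = 0.155, O = 0.152, S = 0.180, H = 0.120,
               P = 0.180)

#' Side-chain heavy atom names of a residue type
#'
#' @param res_type Three-letter residue code (e.g. "LEU").
#' @return Character vector of PDB atom names (empty for GLY).
#' @export
sidechain_atoms <- function(res_type) {
  res_type <- toupper(res_type)
  if (!res_type %in% names(.SIDECHAIN_ATOMS))
    tf_stop("unknown_residue", "unknown residue type '%s'", res_type)
  .SIDECHAIN_ATOMS[[res_type]]
}

#' Construct a two-chain complex structure
#'
#' The container used by the structural analysis: a per-atom table with
#' chain role annotations.  Exactly two roles, `receptor` (the folded
#' template domain) and `ligand` (the disordered peptide), must be
#' present.
#'
#' @param atoms Data frame with columns `chain`, `resid` (integer
#'   residue index, unique per chain), `restype` (three-letter code),
#'   `atom` (atom name), `element`, `x`, `y`, `z` (nm).
#' @param receptor_chain,ligand_chain Chain identifiers taking the two
#'   roles.
#' @return Object of class `complex_structure` (the atom data frame
#'   with role attributes).
#' @export
complex_structure <- function(atoms, receptor_chain, ligand_chain) {
  need <- c("chain", "resid", "restype", "atom", "element", "x", "y", "z")
  stopifnot(is.data.frame(atoms), all(need %in% names(atoms)))
  if (identical(receptor_chain, ligand_chain))
    tf_stop("structure_invalid", "receptor and ligand chains must differ")
  for (ch in c(receptor_chain, ligand_chain))
    if (!ch %in% atoms$chain)
      tf_stop("missing_chain", "chain '%s' absent; available: %s", ch,
              paste(unique(atoms$chain), collapse = ", "))
  atoms <- atoms[atoms$chain %in% c(receptor_chain, ligand_chain), , drop = FALSE]
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    tf_stop("structure_invalid", "non-finite coordinates")
  ## residue indices unique per chain: (chain, resid, atom) must be unique
  key <- paste(atoms$chain, atoms$resid, atoms$atom)
  if (anyDuplicated(key))
    tf_stop("structure_invalid", "duplicate (chain, residue, atom) records")
  rownames(atoms) <- NULL
  structure(atoms,
            receptor_chain = receptor_chain,
            ligand_chain = ligand_chain,
            class = c("complex_structure", "data.frame"))
}

#' @export
print.complex_structure <- function(x, ...) {
  rc <- attr(x, "receptor_chain"); lc <- attr(x, "ligand_chain")
  nr <- length(unique(x$resid[x$chain == rc]))
  nl <- length(unique(x$resid[x$chain == lc]))
  cat(sprintf("Complex structure: receptor chain %s (%d residues), ligand chain %s (%d residues), %d heavy atoms\n",
              rc, nr, lc, nl, nrow(x)))
  invisible(x)
}

#' Residue table of a complex structure
#'
#' @param s A [complex_structure()].
#' @return Data frame with one row per residue: `chain`, `resid`,
#'   `restype`, `role`, `n_sidechain_atoms`.
#' @export
residue_table <- function(s) {
  stopifnot(inherits(s, "complex_structure"))
  rc <- attr(s, "receptor_chain")
  key <- paste(s$chain, s$resid)
  first <- !duplicated(key)
  sc <- !(s$atom %in% .BACKBONE_ATOMS)
  nsc <- tapply(sc, factor(key, levels = unique(key)), sum)
  data.frame(chain = s$chain[first], resid = s$resid[first],
             restype = s$restype[first],
             role = ifelse(s$chain[first] == rc, "receptor", "ligand"),
             n_sidechain_atoms = as.integer(nsc),
             row.names = NULL)
}

#' Read a two-chain complex from a PDB file
#'
#' Reads ATOM records of the first MODEL (NMR files carry several),
#' drops hydrogens, resolves alternate locations to the highest
#' occupancy, and converts coordinates from Angstrom to nm.
#'
#' @param path PDB file path.
#' @param receptor_chain,ligand_chain Chain identifiers (single
#'   characters) for the two roles.
#' @param model Which MODEL to keep (default 1; ignored for
#'   single-model files).
#' @return A [complex_structure()].  A residue with no heavy atoms
#'   beyond the backbone triggers no error (GLY is normal); a residue
#'   with no atoms at all cannot occur in a well-formed file.
#' @export
read_pdb <- function(path, receptor_chain, ligand_chain, model = 1L) {
  lines <- readLines(path, warn = FALSE)
  ## restrict to the requested MODEL block when present
  mstart <- grep("^MODEL", lines)
  if (length(mstart) >= 1L) {
    mnum <- suppressWarnings(as.integer(substr(lines[mstart], 11, 14)))
    pick <- which(mnum == model)
    if (length(pick) == 0L) pick <- model
    if (is.na(pick[1]) || pick[1] > length(mstart))
      tf_stop("missing_model", "MODEL %d not present", model)
    i0 <- mstart[pick[1]]
    iend <- grep("^ENDMDL", lines)
    i1 <- iend[iend > i0][1]
    if (is.na(i1)) i1 <- length(lines)
    lines <- lines[i0:i1]
  }
  at <- lines[startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")]
  if (length(at) == 0L) tf_stop("pdb_empty", "no ATOM records in '%s'", path)
  f <- function(a, b) trimws(substr(at, a, b))
  atoms <- data.frame(
    atom = f(13, 16),
    altloc = f(17, 17),
    restype = f(18, 20),
    chain = f(22, 22),
    resid = as.integer(f(23, 26)),
    x = as.numeric(f(31, 38)) / 10,
    y = as.numeric(f(39, 46)) / 10,
    z = as.numeric(f(47, 54)) / 10,
    occ = suppressWarnings(as.numeric(f(55, 60))),
    element = f(77, 78))
  atoms$occ[!is.finite(atoms$occ)] <- 1
  ## element fallback from atom name when columns 77-78 are blank
  blank <- atoms$element == ""
  atoms$element[blank] <- substr(gsub("[0-9']", "", atoms$atom[blank]), 1, 1)
  ## drop hydrogens
  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  ## resolve altlocs: keep highest occupancy (ties: first)
  key <- paste(atoms$chain, atoms$resid, atoms$atom)
  if (anyDuplicated(key)) {
    ord <- order(key, -atoms$occ)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resid, atoms$atom)), ,
                   drop = FALSE]
    ## restore file order
    atoms <- atoms[order(match(paste(atoms$chain, atoms$resid, atoms$atom),
                               unique(key))), , drop = FALSE]
  }
  atoms$altloc <- NULL
  atoms$occ <- NULL
  complex_structure(atoms, receptor_chain, ligand_chain)
}

#' Write a complex structure (or ensemble) to a PDB file
#'
#' Inverse of [read_pdb()]: nm coordinates are written in Angstrom.
#' When `coords` is a 3-dimensional array (atoms x 3 x frames) a
#' multi-MODEL file is produced.
#'
#' @param s A [complex_structure()] providing the atom records.
#' @param path Output file.
#' @param coords Optional replacement coordinates: matrix (n_atoms x 3)
#'   or array (n_atoms x 3 x n_frames), in nm.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path, coords = NULL) {
  stopifnot(inherits(s, "complex_structure"))
  if (is.null(coords)) coords <- as.matrix(s[, c("x", "y", "z")])
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  n <- nrow(s)
  stopifnot(dim(coords)[1] == n, dim(coords)[2] == 3L)
  con <- file(path, "w")
  on.exit(close(con))
  nf <- dim(coords)[3]
  for (fr in seq_len(nf)) {
    if (nf > 1L) writeLines(sprintf("MODEL     %4d", fr), con)
    xyz <- coords[, , fr] * 10   # nm -> Angstrom
    aname <- ifelse(nchar(s$atom) < 4L, sprintf(" %-3s", s$atom),
                    sprintf("%-4s", s$atom))
    writeLines(sprintf(
      "ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(n), aname, s$restype, s$chain, s$resid,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, s$element), con)
    if (nf > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
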