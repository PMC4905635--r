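# Coordinate data model and PDB-format I/O.
#
# A `structure3d` is a thin S3 wrapper around an atom table, one row per atom,
# preserving author chain ids, residue numbers and insertion codes end-to-end.
# No installed package parses PDB coordinate records, so the fixed-column
# reader/writer lives here.

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")

AA3 <- structure(names(AA1), names = unname(AA1))

#' Construct a structure from an atom table
#'
#' @param atoms data.frame with columns `chain`, `resno`, `icode`, `resname`,
#'   `name` (atom name), `element`, `x`, `y`, `z`, and optionally `occ`,
#'   `bfac`, `standard`, `het`.
#' @return object of class `structure3d`.
#' @export
structure3d <- function(atoms) {
  req <- c("chain", "resno", "icode", "resname", "name", "element", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (!nrow(atoms)) stop("empty structure: no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates")
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$bfac)) atoms$bfac <- 0
  if (is.null(atoms$het)) atoms$het <- FALSE
  atoms$standard <- atoms$resname %in% STANDARD_AA & !atoms$het
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate (chain, resno, icode, atom name): ",
         key[which(duplicated(key))[1]])
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("structure3d: %d atoms, %d residues, chains %s\n",
              nrow(a), length(unique(residue_keys(x))),
              paste(unique(a$chain), collapse = ",")))
  invisible(x)
}

#' Chains of a structure
#' @param s a `structure3d`.
#' @return character vector of chain ids in order of appearance.
#' @export
chains <- function(s) unique(s$atoms$chain)

#' Per-atom residue keys ("chain:resno:icode")
#' @keywords internal
residue_keys <- function(s, atoms = s$atoms) {
  paste(atoms$chain, atoms$resno, trimws(atoms$icode), sep = ":")
}

#' Residue-level table of a structure
#'
#' @param s a `structure3d`.
#' @param standard_only drop waters/ligands and other non-standard residues.
#' @return data.frame with one row per residue: `key`, `chain`, `resno`,
#'   `icode`, `resname`, `standard`.
#' @export
residue_table <- function(s, standard_only = FALSE) {
  a <- s$atoms
  key <- residue_keys(s)
  first <- !duplicated(key)
  out <- data.frame(key = key[first], chain = a$chain[first],
                    resno = a$resno[first], icode = a$icode[first],
                    resname = a$resname[first], standard = a$standard[first],
                    stringsAsFactors = FALSE)
  if (standard_only) out <- out[out$standard, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Atom coordinates as an n x 3 matrix
#' @param s a `structure3d`.
#' @param sel optional logical/integer row selector into the atom table.
#' @export
coords <- function(s, sel = NULL) {
  a <- s$atoms
  if (!is.null(sel)) a <- a[sel, , drop = FALSE]
  cbind(x = a$x, y = a$y, z = a$z)
}

#' Replace atom coordinates
#' @param s a `structure3d`.
#' @param xyz n x 3 coordinate matrix.
#' @param sel optional row selector (defaults to all atoms).
#' @export
set_coords <- function(s, xyz, sel = NULL) {
  if (is.null(sel)) sel <- seq_len(nrow(s$atoms))
  s$atoms$x[sel] <- xyz[, 1]
  s$atoms$y[sel] <- xyz[, 2]
  s$atoms$z[sel] <- xyz[, 3]
  s
}

#' Subset a structure to selected chains
#' @param s a `structure3d`.
#' @param keep character vector of chain ids.
#' @export
subset_chains <- function(s, keep) {
  a <- s$atoms[s$atoms$chain %in% keep, , drop = FALSE]
  if (!nrow(a)) stop("no atoms left after chain subset")
  structure3d(a)
}

# first alphabetic character; adequate for protein heavy atoms (C/N/O/S)
infer_element <- function(name) {
  toupper(substr(gsub("[^A-Za-z]", "", name), 1, 1))
}

#' Read a PDB coordinate file
#'
#' Parses ATOM/HETATM records with fixed-column semantics. Alternate locations
#' are resolved to the highest-occupancy conformer (ties: first in file);
#' waters and other non-standard residues are kept but flagged so downstream
#' energetics can skip them.
#'
#' @param path file path.
#' @param het keep HETATM records (default TRUE; they stay flagged
#'   non-standard).
#' @return a [structure3d()].
#' @export
read_pdb <- function(path, het = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  sel <- rec == "ATOM  " | (het & rec == "HETATM")
  lines <- lines[sel]
  if (!length(lines)) stop("no ATOM records in ", path)
  fx <- function(a, b) substr(lines, a, b)
  atoms <- data.frame(
    het = substr(lines, 1, 6) == "HETATM",
    name = trimws(fx(13, 16)),
    altloc = fx(17, 17),
    resname = trimws(fx(18, 20)),
    chain = fx(22, 22),
    resno = as.integer(fx(23, 26)),
    icode = fx(27, 27),
    x = as.numeric(fx(31, 38)),
    y = as.numeric(fx(39, 46)),
    z = as.numeric(fx(47, 54)),
    occ = suppressWarnings(as.numeric(fx(55, 60))),
    bfac = suppressWarnings(as.numeric(fx(61, 66))),
    element = trimws(fx(77, 78)),
    stringsAsFactors = FALSE
  )
  atoms$occ[is.na(atoms$occ)] <- 1
  atoms$bfac[is.na(atoms$bfac)] <- 0
  blank <- atoms$element == ""
  atoms$element[blank] <- infer_element(atoms$name[blank])
  # altloc: keep highest occupancy per (chain, resno, icode, atom name)
  if (any(atoms$altloc != " ")) {
    key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$name)
    ord <- order(key, -atoms$occ, seq_len(nrow(atoms)))
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$icode,
                                     atoms$name)), , drop = FALSE]
    atoms <- atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
  }
  atoms$altloc <- NULL
  structure3d(atoms)
}

#' Write a structure as a PDB file
#'
#' Emits ATOM (or HETATM) records with `%8.3f` coordinate fields, a TER record
#' after each chain, and END. Coordinates read by [read_pdb()] and left
#' unmodified survive a round-trip bit-exactly.
#'
#' @param s a `structure3d`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  a <- s$atoms
  lines <- character(0)
  serial <- 0L
  for (ch in chains(s)) {
    rows <- which(a$chain == ch)
    for (i in rows) {
      serial <- serial + 1L
      nm <- a$name[i]
      nm_fmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
      lines <- c(lines, sprintf(
        "%-6s%5d %s%s%3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        if (a$het[i]) "HETATM" else "ATOM", serial, nm_fmt, " ",
        a$resname[i], ch, a$resno[i], a$icode[i],
        a$x[i], a$y[i], a$z[i], a$occ[i], a$bfac[i], a$element[i]))
    }
    serial <- serial + 1L
    last <- rows[length(rows)]
    lines <- c(lines, sprintf("TER   %5d      %3s %s%4d%s", serial,
                              a$resname[last], ch, a$resno[last], a$icode[last]))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' One-letter sequence of a chain
#' @param s a `structure3d`.
#' @param chain chain id.
#' @return single string (non-standard residues become "X").
#' @export
chain_sequence <- function(s, chain) {
  rt <- residue_table(s)
  rt <- rt[rt$chain == chain, , drop = FALSE]
  if (!nrow(rt)) stop("chain not found: ", chain)
  letters1 <- ifelse(rt$resname %in% STANDARD_AA, AA1[rt$resname], "X")
  paste(letters1, collapse = "")
}
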