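# Side-chain construction from ideal-geometry templates and in-silico point
# mutation. One code path builds side chains for the toy-dimer generator and
# for mutagenesis.

AROMATIC_CHI2 <- c("PHE", "TYR", "TRP", "HIS")

#' Candidate chi-angle combinations for a residue type
#'
#' chi1 samples the three staggered wells; chi2 uses +/-90 degrees for
#' aromatics and staggered wells otherwise; chi3 and beyond are fixed anti
#' (180 degrees). At most 9 combinations per residue.
#'
#' @param resname 3-letter residue name.
#' @return matrix with one row per rotamer, one column per chi angle
#'   (0-column matrix for Ala/Gly/Pro).
#' @export
rotamer_chis <- function(resname) {
  tpl <- .aa_geometry[[resname]]
  if (is.null(tpl)) stop("no geometry template for ", resname)
  n <- tpl$n_chi
  if (n == 0) return(matrix(numeric(0), nrow = 1, ncol = 0))
  chi1 <- c(-60, 180, 60)
  if (n == 1) return(matrix(chi1, ncol = 1))
  chi2 <- if (resname %in% AROMATIC_CHI2) c(-90, 90) else c(-60, 180, 60)
  grid <- expand.grid(chi1 = chi1, chi2 = chi2)
  extra <- matrix(180, nrow = nrow(grid), ncol = n - 2)
  unname(as.matrix(cbind(grid, extra)))
}

#' Build side-chain heavy atoms from backbone frame and chi angles
#'
#' @param resname 3-letter residue name.
#' @param n,ca,c backbone N, CA, C coordinates (length-3 numeric).
#' @param chi numeric chi angles (degrees), length >= template `n_chi`.
#' @param cb optional fixed CB coordinates to keep (mutation retains CB).
#' @return data.frame with columns `name`, `element`, `x`, `y`, `z` (atoms
#'   beyond the backbone; empty for GLY).
#' @export
build_sidechain <- function(resname, n, ca, c, chi = NULL, cb = NULL) {
  tpl <- .aa_geometry[[resname]]
  if (is.null(tpl)) stop("no geometry template for ", resname)
  at <- tpl$atoms
  if (is.null(at))
    return(data.frame(name = character(0), element = character(0),
                      x = numeric(0), y = numeric(0), z = numeric(0)))
  if (tpl$n_chi > 0 && (is.null(chi) || length(chi) < tpl$n_chi))
    stop(resname, " needs ", tpl$n_chi, " chi angles")
  pos <- list(N = n, CA = ca, C = c)
  if (!is.null(cb)) pos$CB <- cb
  for (i in seq_len(nrow(at))) {
    nm <- at$name[i]
    if (!is.null(pos[[nm]])) next
    tor <- at$torsion[i]
    if (!is.na(at$chi[i])) tor <- tor + chi[at$chi[i]]
    pos[[nm]] <- place_atom(pos[[at$ggparent[i]]], pos[[at$gparent[i]]],
                            pos[[at$parent[i]]], at$bond[i], at$angle[i], tor)
  }
  xyz <- do.call(rbind, pos[at$name])
  data.frame(name = at$name, element = at$element,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Atom-table row indices of one residue
#' @param s a `structure3d`.
#' @param chain,resno,icode residue identifiers.
#' @return integer vector of row indices into `s$atoms`.
#' @export
residue_rows <- function(s, chain, resno, icode = "") {
  a <- s$atoms
  which(a$chain == chain & a$resno == resno & trimws(a$icode) == trimws(icode))
}

#' All candidate rotamer placements for a target residue type at a position
#'
#' Used by [mutate_residue()] and exposed so tests can audit rotamer choice.
#'
#' @inheritParams mutate_residue
#' @return list of side-chain atom data.frames (see [build_sidechain()]), one
#'   per rotamer; retains the existing CB where present.
#' @export
sidechain_rotamers <- function(s, chain, resno, new_aa, icode = "") {
  resname3 <- if (nchar(new_aa) == 1) unname(AA3[toupper(new_aa)]) else toupper(new_aa)
  rows <- residue_rows(s, chain, resno, icode)
  if (!length(rows)) stop("residue not found: ", chain, resno)
  a <- s$atoms[rows, , drop = FALSE]
  get <- function(nm) {
    i <- match(nm, a$name)
    if (is.na(i)) NULL else c(a$x[i], a$y[i], a$z[i])
  }
  bbN <- get("N"); bbCA <- get("CA"); bbC <- get("C")
  if (is.null(bbN) || is.null(bbCA) || is.null(bbC))
    stop("incomplete backbone at ", chain, resno)
  cb <- if (resname3 != "GLY") get("CB") else NULL
  chis <- rotamer_chis(resname3)
  lapply(seq_len(nrow(chis)), function(r)
    build_sidechain(resname3, bbN, bbCA, bbC, chi = chis[r, ], cb = cb))
}

count_clashes <- function(sc_xyz, env_xyz, cutoff = 2.0) {
  if (!nrow(sc_xyz) || !nrow(env_xyz)) return(0L)
  d2 <- outer(rowSums(sc_xyz^2), rowSums(env_xyz^2), "+") -
    2 * sc_xyz %*% t(env_xyz)
  sum(d2 < cutoff^2)
}

#' In-silico point mutation
#'
#' Replaces the side chain of one residue with an idealized rotamer of the new
#' residue type. Backbone atoms (N, CA, C, O, OXT) and CB are never moved; the
#' first rotamer without heavy-atom clashes (< 2 Angstrom against atoms
#' outside the mutated residue) is chosen, else the least-clashing one.
#' Mutation to Ala or Gly is a pure truncation.
#'
#' @param s a `structure3d`.
#' @param chain chain id.
#' @param resno author residue number.
#' @param new_aa target residue, 1-letter or 3-letter code.
#' @param icode insertion code (default none).
#' @param clash_cutoff heavy-atom clash distance in Angstrom.
#' @return mutated `structure3d`.
#' @export
mutate_residue <- function(s, chain, resno, new_aa, icode = "",
                           clash_cutoff = 2.0) {
  resname3 <- if (nchar(new_aa) == 1) unname(AA3[toupper(new_aa)]) else toupper(new_aa)
  if (is.na(resname3) || !(resname3 %in% STANDARD_AA))
    stop("target residue type not standard: ", new_aa)
  rows <- residue_rows(s, chain, resno, icode)
  if (!length(rows)) stop("residue not found: ", chain, ":", resno)
  old <- s$atoms$resname[rows[1]]
  if (!(old %in% STANDARD_AA))
    stop("cannot mutate non-standard residue ", old)
  if (old == resname3) return(s)

  keep_names <- c("N", "CA", "C", "O", "OXT")
  if (resname3 != "GLY") keep_names <- c(keep_names, "CB")
  keep_rows <- rows[s$atoms$name[rows] %in% keep_names]
  kept <- s$atoms[keep_rows, , drop = FALSE]
  kept$resname <- resname3

  new_sc <- NULL
  if (!(resname3 %in% c("GLY", "ALA"))) {
    cands <- sidechain_rotamers(s, chain, resno, resname3, icode)
    env_xyz <- coords(s, setdiff(seq_len(nrow(s$atoms)), rows))
    extra <- lapply(cands, function(df) {
      df[!(df$name %in% kept$name), , drop = FALSE]
    })
    nclash <- vapply(extra, function(df)
      count_clashes(as.matrix(df[, c("x", "y", "z")]), env_xyz, clash_cutoff),
      integer(1))
    best <- if (any(nclash == 0L)) which(nclash == 0L)[1] else which.min(nclash)
    new_sc <- extra[[best]]
  } else if (resname3 == "ALA" && !("CB" %in% kept$name)) {
    # GLY -> ALA gains a CB built from ideal geometry
    sc <- sidechain_rotamers(s, chain, resno, "ALA", icode)[[1]]
    new_sc <- sc[sc$name == "CB", , drop = FALSE]
  }
  if (!is.null(new_sc) && nrow(new_sc)) {
    tmplrow <- kept[rep(1, nrow(new_sc)), , drop = FALSE]
    tmplrow$name <- new_sc$name
    tmplrow$element <- new_sc$element
    tmplrow$x <- new_sc$x
    tmplrow$y <- new_sc$y
    tmplrow$z <- new_sc$z
    tmplrow$occ <- 1
    tmplrow$bfac <- 0
    kept <- rbind(kept, tmplrow)
  }
  before <- s$atoms[seq_len(nrow(s$atoms)) < rows[1], , drop = FALSE]
  after <- s$atoms[seq_len(nrow(s$atoms)) > rows[length(rows)], , drop = FALSE]
  structure3d(rbind(before, kept, after))
}
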