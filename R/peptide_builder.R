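# Ideal-geometry polypeptide construction (backbone from phi/psi, side chains
# from the rotamer templates). Backbone internal coordinates are standard
# peptide values; termini are left without OXT so every residue parameterizes
# identically (neutral termini).

BB <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
           a_n_ca_c = 111.2, a_ca_c_n = 116.6, a_c_n_ca = 121.9,
           a_ca_c_o = 120.5, omega = 180)

#' Build an ideal-geometry peptide chain
#'
#' @param sequence 1-letter amino-acid string.
#' @param phi,psi backbone dihedrals in degrees, recycled over residues
#'   (alpha-helix: -57/-47; beta-strand: -119/113).
#' @param chain chain id.
#' @param start_resno first residue number.
#' @param chis optional list (one numeric vector per residue) of fixed chi
#'   angles; residues with NULL entries get clash-aware defaults.
#' @return a [structure3d()] with one chain.
#' @export
build_peptide <- function(sequence, phi = -57, psi = -47, chain = "A",
                          start_resno = 1, chis = NULL) {
  seq1 <- strsplit(toupper(sequence), "")[[1]]
  if (!length(seq1)) stop("empty sequence")
  if (!all(seq1 %in% names(AA3))) stop("invalid amino-acid letters")
  nres <- length(seq1)
  phi <- rep_len(phi, nres)
  psi <- rep_len(psi, nres)
  resnames <- unname(AA3[seq1])

  N <- vector("list", nres); CAp <- vector("list", nres)
  Cp <- vector("list", nres); Op <- vector("list", nres)
  N[[1]] <- c(0, 0, 0)
  CAp[[1]] <- c(BB$b_n_ca, 0, 0)
  ang <- (180 - BB$a_n_ca_c) * pi / 180
  Cp[[1]] <- CAp[[1]] + BB$b_ca_c * c(cos(pi - ang), sin(pi - ang), 0)
  for (i in seq_len(nres)) {
    if (i < nres) {
      N[[i + 1]] <- place_atom(N[[i]], CAp[[i]], Cp[[i]],
                               BB$b_c_n, BB$a_ca_c_n, psi[i])
      CAp[[i + 1]] <- place_atom(CAp[[i]], Cp[[i]], N[[i + 1]],
                                 BB$b_n_ca, BB$a_c_n_ca, BB$omega)
      Cp[[i + 1]] <- place_atom(Cp[[i]], N[[i + 1]], CAp[[i + 1]],
                                BB$b_ca_c, BB$a_n_ca_c, phi[i + 1])
      Op[[i]] <- place_atom(N[[i + 1]], CAp[[i]], Cp[[i]],
                            BB$b_c_o, BB$a_ca_c_o, 180)
    } else {
      Op[[i]] <- place_atom(N[[i]], CAp[[i]], Cp[[i]],
                            BB$b_c_o, BB$a_ca_c_o, psi[i] + 180)
    }
  }

  rows <- list()
  placed <- matrix(numeric(0), 0, 3)
  for (i in seq_len(nres)) {
    bb <- data.frame(
      name = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
      x = c(N[[i]][1], CAp[[i]][1], Cp[[i]][1], Op[[i]][1]),
      y = c(N[[i]][2], CAp[[i]][2], Cp[[i]][2], Op[[i]][2]),
      z = c(N[[i]][3], CAp[[i]][3], Cp[[i]][3], Op[[i]][3]),
      stringsAsFactors = FALSE)
    fixed_chi <- if (!is.null(chis) && length(chis) >= i) chis[[i]] else NULL
    sc <- place_best_sidechain(resnames[i], N[[i]], CAp[[i]], Cp[[i]],
                               placed, fixed_chi)
    res <- rbind(bb, sc)
    res$chain <- chain
    res$resno <- start_resno + i - 1L
    res$icode <- " "
    res$resname <- resnames[i]
    rows[[i]] <- res
    placed <- rbind(placed, as.matrix(res[, c("x", "y", "z")]))
  }
  atoms <- do.call(rbind, rows)
  atoms$occ <- 1; atoms$bfac <- 0; atoms$het <- FALSE
  structure3d(atoms)
}

# choose the first clash-free rotamer against already-placed atoms
place_best_sidechain <- function(resname, n, ca, c, env_xyz, fixed_chi = NULL) {
  if (!is.null(fixed_chi)) {
    return(build_sidechain(resname, n, ca, c, chi = fixed_chi))
  }
  chis <- rotamer_chis(resname)
  best <- NULL; best_clash <- Inf
  for (r in seq_len(nrow(chis))) {
    sc <- build_sidechain(resname, n, ca, c, chi = chis[r, ])
    ncl <- count_clashes(as.matrix(sc[, c("x", "y", "z")]), env_xyz, 2.4)
    if (ncl < best_clash) { best <- sc; best_clash <- ncl }
    if (ncl == 0) break
  }
  best
}
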