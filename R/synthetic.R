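# Synthetic test bed: ideal-geometry toy dimers with engineered interface
# motifs, decoy alternative orientations, and simulated replicate matrices
# with planted differential residues. Stands in for homology-built dimer
# models that cannot be redistributed.

MOTIF_SEQ <- list(
  `salt-bridge` = c("K", "E"),
  `hydrophobic-contact` = c("L", "L"),
  `aromatic-stack` = c("F", "F")
)

#' Specification of a synthetic toy dimer
#'
#' @param length protomer length in residues.
#' @param scaffold "helix-pair" or "sheet-pair".
#' @param motifs list of motif descriptors: `list(pos = c(i, j), type =
#'   "salt-bridge" | "hydrophobic-contact" | "aromatic-stack")`; `pos` gives
#'   the residue position on protomer A and on protomer B.
#' @param separation inter-protomer axis distance in Angstrom.
#' @param background 1-letter code of non-motif residues.
#' @param seed integer seed controlling any stochastic placement choices.
#' @return list of class `toy_dimer_spec`.
#' @export
toy_dimer_spec <- function(length = 12, scaffold = c("helix-pair", "sheet-pair"),
                           motifs = list(), separation = 9.5,
                           background = "A", seed = 1) {
  scaffold <- match.arg(scaffold)
  stopifnot(length >= 4, separation > 0)
  for (m in motifs) {
    if (!m$type %in% names(MOTIF_SEQ)) stop("unknown motif type: ", m$type)
    if (any(m$pos < 1 | m$pos > length)) stop("motif position outside protomer")
  }
  structure(list(length = length, scaffold = scaffold, motifs = motifs,
                 separation = separation, background = background,
                 seed = seed), class = "toy_dimer_spec")
}

# align a chain's CA principal axis to +z, center at origin, and rotate about
# z so the mean CA->CB direction of `face_res` points along `face_dir`
orient_protomer <- function(s, face_res, face_dir = c(1, 0, 0)) {
  a <- s$atoms
  ca <- coords(s, a$name == "CA")
  ctr <- colMeans(ca)
  pc <- prcomp(ca)
  axis <- pc$rotation[, 1]
  if (axis[3] < 0) axis <- -axis
  v <- cross3(axis, c(0, 0, 1))
  xyz <- coords(s)
  xyz <- sweep(xyz, 2, ctr)
  if (vnorm(v) > 1e-9) {
    ang <- acos(max(-1, min(1, sum(axis * c(0, 0, 1))))) * 180 / pi
    R1 <- rotation_about_axis(v, ang)
    xyz <- xyz %*% t(R1)
  }
  s <- set_coords(s, xyz)
  # rotate about z so the motif side chains face `face_dir`
  a <- s$atoms
  dirs <- sapply(face_res, function(rn) {
    ca_i <- which(a$resno == rn & a$name == "CA")
    cb_i <- which(a$resno == rn & a$name == "CB")
    if (!length(cb_i)) return(c(0, 0))
    d <- c(a$x[cb_i] - a$x[ca_i], a$y[cb_i] - a$y[ca_i])
    d / max(vnorm(c(d, 0)), 1e-9)
  })
  mean_dir <- rowMeans(matrix(dirs, nrow = 2))
  cur <- atan2(mean_dir[2], mean_dir[1])
  tgt <- atan2(face_dir[2], face_dir[1])
  R2 <- rotation_about_axis(c(0, 0, 1), (tgt - cur) * 180 / pi)
  set_coords(s, coords(s) %*% t(R2))
}

motif_anchor_atoms <- function(type) {
  switch(type,
         `salt-bridge` = list(A = "NZ", B = c("OE1", "OE2")),
         `hydrophobic-contact` = list(A = c("CD1", "CD2"), B = c("CD1", "CD2")),
         `aromatic-stack` = list(A = c("CZ", "CE1", "CE2"),
                                 B = c("CZ", "CE1", "CE2")))
}

min_cross_distance <- function(s, resA, atomsA, resB, atomsB) {
  a <- s$atoms
  ia <- which(a$chain == "A" & a$resno == resA & a$name %in% atomsA)
  ib <- which(a$chain == "B" & a$resno == resB & a$name %in% atomsB)
  if (!length(ia) || !length(ib)) return(Inf)
  min(sqrt(outer(rowSums(coords(s, ia)^2), rowSums(coords(s, ib)^2), "+") -
             2 * coords(s, ia) %*% t(coords(s, ib))))
}

motif_target <- function(type) {
  if (type == "salt-bridge") 3.0 else 3.9
}

apply_sidechain <- function(dimer, rows, sc) {
  m <- match(dimer$atoms$name[rows], sc$name)
  hit <- rows[!is.na(m)]
  dimer$atoms$x[hit] <- sc$x[m[!is.na(m)]]
  dimer$atoms$y[hit] <- sc$y[m[!is.na(m)]]
  dimer$atoms$z[hit] <- sc$z[m[!is.na(m)]]
  dimer
}

# soft-sphere repulsion of a residue's side chain against its environment
soft_repulsion <- function(sc_xyz, env_xyz, r0 = 3.2) {
  if (!nrow(sc_xyz) || !nrow(env_xyz)) return(0)
  d2 <- outer(rowSums(sc_xyz^2), rowSums(env_xyz^2), "+") -
    2 * sc_xyz %*% t(env_xyz)
  d <- sqrt(pmax(d2, 0))
  sum(pmax(r0 - d, 0)^2)
}

# greedy rotamer relaxation over interface residues: minimize soft-sphere
# repulsion, with a distance restraint pulling motif anchor atoms to their
# target contact distance
relax_interface <- function(dimer, motifs, passes = 2, shell = 6.0) {
  motif_of <- list()
  for (m in motifs) {
    motif_of[[paste0("A", m$pos[1])]] <- list(type = m$type, partner = m$pos[2],
                                              side = "A")
    motif_of[[paste0("B", m$pos[2])]] <- list(type = m$type, partner = m$pos[1],
                                              side = "B")
  }
  for (pass in seq_len(passes)) {
    rt <- residue_table(dimer)
    inB <- dimer$atoms$chain == "B"
    xyzA <- coords(dimer, !inB); xyzB <- coords(dimer, inB)
    keyatoms <- residue_keys(dimer)
    for (k in seq_len(nrow(rt))) {
      rows <- which(keyatoms == rt$key[k])
      own_xyz <- coords(dimer, rows)
      cross <- if (rt$chain[k] == "A") xyzB else xyzA
      dmin <- sqrt(min(outer(rowSums(own_xyz^2), rowSums(cross^2), "+") -
                         2 * own_xyz %*% t(cross)))
      if (dmin > shell) next
      if (rt$resname[k] %in% c("ALA", "GLY", "PRO")) next
      cands <- sidechain_rotamers(dimer, rt$chain[k], rt$resno[k], rt$resname[k])
      env <- setdiff(seq_len(nrow(dimer$atoms)), rows)
      env_xyz <- coords(dimer, env)
      mm <- motif_of[[paste0(rt$chain[k], rt$resno[k])]]
      best_pen <- Inf; best_sc <- NULL
      for (sc in cands) {
        scx <- as.matrix(sc[!(sc$name %in% c("N", "CA", "C", "O")),
                            c("x", "y", "z"), drop = FALSE])
        pen <- soft_repulsion(scx, env_xyz)
        if (!is.null(mm)) {
          trial <- apply_sidechain(dimer, rows, sc)
          anch <- motif_anchor_atoms(mm$type)
          d <- if (mm$side == "A")
            min_cross_distance(trial, rt$resno[k], anch$A, mm$partner, anch$B)
          else
            min_cross_distance(trial, mm$partner, anch$A, rt$resno[k], anch$B)
          pen <- pen + 2 * abs(d - motif_target(mm$type))
        }
        if (pen < best_pen) { best_pen <- pen; best_sc <- sc }
      }
      if (!is.null(best_sc)) dimer <- apply_sidechain(dimer, rows, best_sc)
    }
  }
  dimer
}

#' Build a synthetic two-chain toy dimer
#'
#' Two ideal-geometry protomers (alpha-helix phi/psi -57/-47 or beta-strand
#' -119/113) whose sequences realize the requested interface motifs
#' (Lys/Glu salt bridges, Leu/Leu hydrophobic contacts, Phe/Phe aromatic
#' pairs), oriented so the motif side chains face each other across the
#' requested axis separation; motif rotamers are optimized jointly to form
#' the contact without steric clashes. Deterministic for a fixed spec.
#'
#' @param spec a [toy_dimer_spec()].
#' @param max_motif_distance error if a motif's closest contact exceeds this
#'   distance (Angstrom) after refinement.
#' @return a two-chain [structure3d()] (chains "A" and "B").
#' @export
build_toy_dimer <- function(spec, max_motif_distance = 6.0) {
  stopifnot(inherits(spec, "toy_dimer_spec"))
  set.seed(spec$seed)
  phi <- if (spec$scaffold == "helix-pair") -57 else -119
  psi <- if (spec$scaffold == "helix-pair") -47 else 113
  seqA <- rep(spec$background, spec$length)
  seqB <- rep(spec$background, spec$length)
  for (m in spec$motifs) {
    seqA[m$pos[1]] <- MOTIF_SEQ[[m$type]][1]
    seqB[m$pos[2]] <- MOTIF_SEQ[[m$type]][2]
  }
  protA <- build_peptide(paste(seqA, collapse = ""), phi, psi, chain = "A")
  protB <- build_peptide(paste(seqB, collapse = ""), phi, psi, chain = "B")
  faceA <- vapply(spec$motifs, function(m) m$pos[1], numeric(1))
  faceB <- vapply(spec$motifs, function(m) m$pos[2], numeric(1))
  if (!length(faceA)) faceA <- round(spec$length / 2)
  if (!length(faceB)) faceB <- round(spec$length / 2)
  protA <- orient_protomer(protA, faceA, c(1, 0, 0))
  protB <- orient_protomer(protB, faceB, c(-1, 0, 0))
  # antiparallel pairing: flip B head-to-tail about x, then offset along +x
  xyzB <- coords(protB) %*% t(rotation_about_axis(c(1, 0, 0), 180))
  protB <- set_coords(protB, xyzB)
  protB <- orient_protomer(protB, faceB, c(-1, 0, 0))
  xyzB <- sweep(coords(protB), 2, c(spec$separation, 0, 0), "+")
  protB$atoms$x <- xyzB[, 1]; protB$atoms$y <- xyzB[, 2]; protB$atoms$z <- xyzB[, 3]
  dimer <- structure3d(rbind(protA$atoms, protB$atoms))
  # bring the first motif pair level along z, then refine motif rotamers
  if (length(spec$motifs)) {
    m1 <- spec$motifs[[1]]
    a <- dimer$atoms
    zA <- a$z[a$chain == "A" & a$resno == m1$pos[1] & a$name == "CA"]
    zB <- a$z[a$chain == "B" & a$resno == m1$pos[2] & a$name == "CA"]
    sel <- a$chain == "B"
    dimer$atoms$z[sel] <- dimer$atoms$z[sel] + (zA - zB)
  }
  dimer <- relax_interface(dimer, spec$motifs)
  for (m in spec$motifs) {
    anch <- motif_anchor_atoms(m$type)
    d <- min_cross_distance(dimer, m$pos[1], anch$A, m$pos[2], anch$B)
    if (d > max_motif_distance)
      stop(sprintf("motif %s at (%d,%d) unrealizable: closest approach %.2f A",
                   m$type, m$pos[1], m$pos[2], d))
  }
  dimer
}

#' Generate a decoy orientation of a dimer
#'
#' Rigidly moves protomer B (rotation about an axis through its centroid,
#' then translation) while protomer A and all residue indexing stay fixed, so
#' the decoy remains comparable residue-by-residue with the original.
#'
#' @param dimer a two-chain `structure3d`.
#' @param axis rotation axis (length-3).
#' @param angle rotation angle in degrees.
#' @param translation length-3 translation (Angstrom) applied after rotation.
#' @param chain the protomer to move (default the second chain).
#' @param min_separation reject decoys with inter-chain heavy-atom contacts
#'   closer than this (Angstrom).
#' @return a `structure3d` with identical atom and residue indexing.
#' @export
make_decoy <- function(dimer, axis = c(0, 0, 1), angle = 0,
                       translation = c(0, 0, 0), chain = NULL,
                       min_separation = 1.5) {
  ch <- chains(dimer)
  if (is.null(chain)) chain <- ch[2]
  if (angle == 0 && all(translation == 0)) return(dimer)
  sel <- dimer$atoms$chain == chain
  xyz <- coords(dimer, sel)
  ctr <- colMeans(xyz)
  R <- rotation_about_axis(axis, angle)
  moved <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr + translation, "+")
  out <- dimer
  out$atoms$x[sel] <- moved[, 1]
  out$atoms$y[sel] <- moved[, 2]
  out$atoms$z[sel] <- moved[, 3]
  other <- coords(out, !sel)
  d2 <- outer(rowSums(moved^2), rowSums(other^2), "+") - 2 * moved %*% t(other)
  if (min(d2) < min_separation^2)
    stop(sprintf("decoy rejected: inter-chain clash at %.2f A",
                 sqrt(max(min(d2), 0))))
  out
}

#' Specification for simulated replicate contribution matrices
#'
#' @param n_residues residues per protomer pair (shared index).
#' @param n_replicates replicate evaluations per model (>= 2).
#' @param planted data.frame with columns `residue` (index) and `model`
#'   ("A"/"B"): residues whose contribution is shifted by `-delta` in the
#'   named model.
#' @param delta planted effect size (kcal/mol).
#' @param sigma replicate noise standard deviation (kcal/mol).
#' @param baseline mean per-residue contribution (kcal/mol).
#' @param seed integer seed.
#' @return list of class `sim_spec`.
#' @export
sim_spec <- function(n_residues = 20, n_replicates = 8,
                     planted = data.frame(residue = integer(0),
                                          model = character(0)),
                     delta = 0.9, sigma = 0.3, baseline = -0.2, seed = 1) {
  stopifnot(n_residues >= 2, n_replicates >= 2, sigma > 0)
  if (nrow(planted) && any(planted$residue < 1 | planted$residue > n_residues))
    stop("planted residue outside index range")
  structure(list(n_residues = n_residues, n_replicates = n_replicates,
                 planted = planted, delta = delta, sigma = sigma,
                 baseline = baseline, seed = seed), class = "sim_spec")
}

#' Simulate replicate per-residue contribution matrices for two models
#'
#' Non-planted residues draw i.i.d. Normal(baseline, sigma^2) contributions in
#' both models; a residue planted for model M has its model-M contributions
#' shifted by `-delta` (more stabilizing). With `delta = 0` the two models are
#' exchangeable by construction (null calibration).
#'
#' @param spec a [sim_spec()].
#' @return list with `A` and `B`: matrices (n_residues x n_replicates) with
#'   rownames "r<i>", plus the spec as attribute.
#' @export
simulate_replicates <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  dims <- c(spec$n_residues, spec$n_replicates)
  rn <- paste0("r", seq_len(spec$n_residues))
  A <- matrix(stats::rnorm(prod(dims), spec$baseline, spec$sigma), dims[1],
              dims[2], dimnames = list(rn, NULL))
  B <- matrix(stats::rnorm(prod(dims), spec$baseline, spec$sigma), dims[1],
              dims[2], dimnames = list(rn, NULL))
  if (nrow(spec$planted)) {
    for (k in seq_len(nrow(spec$planted))) {
      i <- spec$planted$residue[k]
      if (spec$planted$model[k] == "A") A[i, ] <- A[i, ] - spec$delta
      else B[i, ] <- B[i, ] - spec$delta
    }
  }
  structure(list(A = A, B = B), spec = spec)
}
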