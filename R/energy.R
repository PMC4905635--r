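# Single-trajectory binding free energy (mechanics + GB + nonpolar surface
# term) with residue-pairwise decomposition. Receptor and ligand are evaluated
# at the coordinates they hold in the complex, so intramolecular mechanical
# terms cancel exactly and are never computed; intramolecular GB desolvation
# differences are routed to the diagonal self terms of the interaction matrix
# (so off-diagonal intramolecular entries are zero while the conservation
# identity sum(matrix) == delta-G still holds).

# half-convention atom tensor: off-diagonal entries = half pair energy,
# diagonal = self energy; sum of all entries = total
half_tensor <- function(pair) {
  h <- pair / 2
  diag(h) <- diag(pair)
  h
}

agg_residue <- function(mat, fkey, levels) {
  f <- factor(fkey, levels = levels)
  rowsum(t(rowsum(mat, f)), f)
}

energy_analysis <- function(dimer, partition, cfg = energy_config(),
                            params = default_atom_params(),
                            intra_gb = c("diagonal", "zero")) {
  intra_gb <- match.arg(intra_gb)
  ps <- assign_parameters(dimer, params)
  part <- check_partition(subset_chains(dimer, unique(ps$atoms$chain)), partition)
  key <- residue_keys(ps)
  rt <- residue_table(ps)
  rt$protomer <- ifelse(rt$chain %in% part$A, "A", "B")
  lv <- rt$key
  psA <- subset_chains(ps, part$A)
  psB <- subset_chains(ps, part$B)
  keyA <- residue_keys(psA); keyB <- residue_keys(psB)

  mech <- mechanical_energy(ps, cfg)
  gb_c <- gb_polar_energy(ps, cfg)
  gb_a <- gb_polar_energy(psA, cfg)
  gb_b <- gb_polar_energy(psB, cfg)
  sa_c <- sasa(ps, cfg$probe, cfg$n_points)
  sa_a <- sasa(psA, cfg$probe, cfg$n_points)
  sa_b <- sasa(psB, cfg$probe, cfg$n_points)

  ia <- which(ps$atoms$chain %in% part$A)
  ib <- which(ps$atoms$chain %in% part$B)
  nres <- length(lv)
  zero <- matrix(0, nres, nres, dimnames = list(lv, lv))

  # mechanical channels: cross-partition entries only (intramolecular terms
  # cancel bitwise in the single-trajectory difference)
  m_ele <- zero
  m_vdw <- zero
  # aggregate a rectangular A x B atom block to residues
  cross_agg <- function(block) {
    f1 <- factor(key[ia], levels = lv[rt$protomer == "A"])
    f2 <- factor(key[ib], levels = lv[rt$protomer == "B"])
    t(rowsum(t(rowsum(block, f1)), f2))
  }
  cross_ele <- cross_agg(mech$ele_pair[ia, ib, drop = FALSE] / 2)
  cross_vdw <- cross_agg(mech$lj_pair[ia, ib, drop = FALSE] / 2)
  akeys <- rownames(cross_ele); bkeys <- colnames(cross_ele)
  m_ele[akeys, bkeys] <- cross_ele
  m_ele[bkeys, akeys] <- t(cross_ele)
  m_vdw[akeys, bkeys] <- cross_vdw
  m_vdw[bkeys, akeys] <- t(cross_vdw)

  # GB channel: complex tensor minus block-diagonal separated tensors
  g_c <- agg_residue(half_tensor(gb_c$pair), key, lv)
  g_sep <- zero
  ga <- agg_residue(half_tensor(gb_a$pair), keyA, unique(keyA))
  gbb <- agg_residue(half_tensor(gb_b$pair), keyB, unique(keyB))
  g_sep[rownames(ga), colnames(ga)] <- ga
  g_sep[rownames(gbb), colnames(gbb)] <- gbb
  m_gb <- as.matrix(g_c) - g_sep
  # route intramolecular off-diagonal GB differences onto the diagonal
  same_side <- outer(rt$protomer, rt$protomer, "==")
  intra_off <- same_side & !diag(TRUE, nres)
  if (intra_gb == "diagonal") {
    moved <- rowSums(m_gb * intra_off)
    diag(m_gb) <- diag(m_gb) + moved
  }
  m_gb[intra_off] <- 0

  # nonpolar channel: per-residue buried-surface term on the diagonal
  sasa_sep <- c(sa_a$residue$sasa, sa_b$residue$sasa)
  names(sasa_sep) <- c(sa_a$residue$key, sa_b$residue$key)
  d_np <- cfg$surften * (sa_c$residue$sasa - sasa_sep[sa_c$residue$key])
  m_np <- zero
  diag(m_np) <- as.numeric(d_np[match(lv, sa_c$residue$key)])

  total_m <- m_ele + m_vdw + m_gb + m_np
  delta <- list(covalent = 0,
                ele = sum(m_ele), vdw = sum(m_vdw),
                gb = sum(m_gb), np = sum(m_np))
  delta$total <- delta$ele + delta$vdw + delta$gb + delta$np

  per_system <- function(idx, gb_total, sa_total) {
    sub_ele <- sum(mech$ele_pair[idx, idx][upper.tri(diag(length(idx)))])
    sub_lj <- sum(mech$lj_pair[idx, idx][upper.tri(diag(length(idx)))])
    list(covalent = 0, ele = sub_ele, vdw = sub_lj, gb = gb_total,
         np = cfg$surften * sa_total,
         total = sub_ele + sub_lj + gb_total + cfg$surften * sa_total)
  }
  systems <- list(
    complex = per_system(seq_len(nrow(ps$atoms)), gb_c$total, sum(sa_c$atom)),
    receptor = per_system(ia, gb_a$total, sum(sa_a$atom)),
    ligand = per_system(ib, gb_b$total, sum(sa_b$atom)))

  structure(list(residues = rt, channels = list(ele = m_ele, vdw = m_vdw,
                                                gb = m_gb, np = m_np),
                 matrix = total_m, delta = delta, systems = systems,
                 partition = part, cfg = cfg, intra_gb = intra_gb),
            class = "interaction_matrix")
}

#' Single-trajectory binding free energy (GB/SA end-point estimate)
#'
#' Evaluates the complex, the isolated receptor (protomer A) and the isolated
#' ligand (protomer B) at identical coordinates and returns the term-by-term
#' difference. The covalent difference is zero by construction.
#'
#' @param dimer two-protomer `structure3d`.
#' @param partition list of two chain-id sets (receptor first).
#' @param cfg an [energy_config()].
#' @param params atom parameter table.
#' @return object of class `energy_breakdown`: per-system term totals
#'   (`systems`), term-by-term differences (`delta`), and `dg` (kcal/mol).
#' @export
binding_free_energy <- function(dimer, partition, cfg = energy_config(),
                                params = default_atom_params()) {
  ea <- energy_analysis(dimer, partition, cfg, params)
  structure(list(systems = ea$systems, delta = ea$delta,
                 dg = ea$delta$total, partition = ea$partition, cfg = cfg),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  d <- x$delta
  cat(sprintf(
    "delta-G binding = %.3f kcal/mol (ele %.3f, vdW %.3f, GB %.3f, SA %.3f)\n",
    d$total, d$ele, d$vdw, d$gb, d$np))
  invisible(x)
}

#' Residue-pairwise decomposition of the binding free energy
#'
#' Every atom-pairwise term is aggregated to residue pairs with the pair
#' energy split half to each symmetric entry, so the conservation identity
#' `sum(matrix) == delta-G` holds to numerical precision. Off-diagonal
#' intramolecular entries are exactly zero: mechanical ones cancel in the
#' single-trajectory difference and are never computed, GB desolvation
#' differences are folded into the diagonal self terms (`intra_gb =
#' "diagonal"`). `intra_gb = "zero"` discards them instead, which breaks
#' conservation by the reported `conservation_gap`.
#'
#' @inheritParams binding_free_energy
#' @param intra_gb "diagonal" (default) or "zero".
#' @return object of class `interaction_matrix`: `residues`, per-channel
#'   matrices (`channels$ele`, `$vdw`, `$gb`, `$np`), the summed `matrix`,
#'   `delta` totals and per-system energies.
#' @export
pairwise_decomposition <- function(dimer, partition, cfg = energy_config(),
                                   params = default_atom_params(),
                                   intra_gb = c("diagonal", "zero")) {
  ea <- energy_analysis(dimer, partition, cfg, params, intra_gb)
  full_delta <- with(ea$delta, ele + vdw + np) +
    (ea$systems$complex$gb - ea$systems$receptor$gb - ea$systems$ligand$gb)
  ea$conservation_gap <- full_delta - sum(ea$matrix)
  ea
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf(
    "interaction_matrix: %d residues, delta-G = %.3f kcal/mol (intra GB: %s)\n",
    nrow(x$residues), x$delta$total, x$intra_gb))
  invisible(x)
}

#' Per-residue contributions to the binding free energy
#'
#' Row sums of the interaction matrix: each residue receives its self term
#' plus half of every pair term it participates in. The vector sums to the
#' binding free energy.
#'
#' @param m an `interaction_matrix` (or a plain numeric matrix).
#' @return named numeric vector (kcal/mol) over all residues of both
#'   protomers.
#' @export
per_residue_contribution <- function(m) {
  mat <- if (inherits(m, "interaction_matrix")) m$matrix else as.matrix(m)
  rowSums(mat)
}

#' Cross-protomer interaction energy matrix (heatmap layout)
#'
#' @param m an `interaction_matrix`.
#' @param channel "total" or one of "ele", "vdw", "gb", "np".
#' @return matrix with protomer-A residues as rows, protomer-B residues as
#'   columns; entries are full residue-pair energies (kcal/mol).
#' @export
cross_matrix <- function(m, channel = "total") {
  mat <- if (channel == "total") m$matrix else m$channels[[channel]]
  ra <- m$residues$key[m$residues$protomer == "A"]
  rb <- m$residues$key[m$residues$protomer == "B"]
  2 * mat[ra, rb, drop = FALSE]  # symmetric halves -> full pair energy
}

#' Screened-Coulomb electrostatic complementarity at the interface
#'
#' A light-weight stand-in for grid-based potential-surface comparison: the
#' Debye-screened Coulomb potential of each protomer is evaluated at the
#' partner's interface atoms; a residue whose charges sit in favorable
#' partner potential scores positive (complementary).
#'
#' @inheritParams binding_free_energy
#' @param report optional precomputed `interface_report`; computed if NULL.
#' @param neutral_band absolute score below which a residue is called neutral.
#' @return data.frame with `key`, `protomer`, `score`, `label`
#'   (complementary / neutral / anticomplementary).
#' @export
interface_complementarity <- function(dimer, partition, cfg = energy_config(),
                                      report = NULL, neutral_band = 0.05) {
  ps <- assign_parameters(dimer)
  part <- check_partition(subset_chains(dimer, unique(ps$atoms$chain)), partition)
  if (is.null(report)) report <- delta_sasa(dimer, partition,
                                            n_points = cfg$n_points)
  iface <- interface_residues(report)
  key <- residue_keys(ps)
  xyz <- coords(ps)
  q <- ps$atoms$charge
  inA <- ps$atoms$chain %in% part$A
  pot_from <- function(src_idx, at_xyz) {
    d <- sqrt(pmax(outer(rowSums(at_xyz^2), rowSums(xyz[src_idx, , drop = FALSE]^2), "+") -
                     2 * at_xyz %*% t(xyz[src_idx, , drop = FALSE]), 1e-12))
    as.numeric((exp(-cfg$kappa * d) / d) %*% q[src_idx]) * cfg$coulomb / cfg$eout
  }
  score_side <- function(side) {
    keys <- iface[[side]]
    if (!length(keys)) return(NULL)
    own <- if (side == "A") which(inA) else which(!inA)
    partner <- if (side == "A") which(!inA) else which(inA)
    sapply(keys, function(k) {
      rows <- own[key[own] == k]
      phi <- pot_from(partner, xyz[rows, , drop = FALSE])
      -sum(q[rows] * phi)
    })
  }
  res <- rbind(
    if (length(iface$A)) data.frame(key = iface$A, protomer = "A",
                                    score = score_side("A")),
    if (length(iface$B)) data.frame(key = iface$B, protomer = "B",
                                    score = score_side("B")))
  if (is.null(res)) return(data.frame(key = character(0),
                                      protomer = character(0),
                                      score = numeric(0),
                                      label = character(0)))
  res$label <- ifelse(res$score > neutral_band, "complementary",
                      ifelse(res$score < -neutral_band, "anticomplementary",
                             "neutral"))
  rownames(res) <- NULL
  res
}
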