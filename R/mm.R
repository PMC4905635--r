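# Vacuum molecular mechanics: Coulomb and 12-6 Lennard-Jones over nonbonded
# atom pairs, with intra-residue and 1-2/1-3 backbone-link exclusions and no
# distance cutoff.

# logical n x n exclusion mask: TRUE = excluded from nonbonded energy
exclusion_mask <- function(ps) {
  a <- ps$atoms
  n <- nrow(a)
  key <- residue_keys(ps)
  excl <- outer(key, key, "==")
  # across the peptide link i -> i+1: 1-2 pair C-N; 1-3 pairs CA-N, O-N,
  # C-CA (and C-CD when the next residue is proline)
  rt <- residue_table(ps)
  for (ch in unique(rt$chain)) {
    rr <- rt[rt$chain == ch, , drop = FALSE]
    if (nrow(rr) < 2) next
    for (k in seq_len(nrow(rr) - 1)) {
      # only consecutive author numbering counts as a peptide link
      if (rr$resno[k + 1] != rr$resno[k] + 1) next
      i_rows <- which(key == rr$key[k])
      j_rows <- which(key == rr$key[k + 1])
      nm_i <- a$name[i_rows]; nm_j <- a$name[j_rows]
      pairs <- rbind(c("C", "N"), c("CA", "N"), c("O", "N"), c("C", "CA"),
                     c("C", "CD"))  # C-CD only reaches PRO
      for (p in seq_len(nrow(pairs))) {
        ii <- i_rows[nm_i == pairs[p, 1]]
        jj <- j_rows[nm_j == pairs[p, 2]]
        if (length(ii) && length(jj)) {
          excl[ii, jj] <- TRUE
          excl[jj, ii] <- TRUE
        }
      }
    }
  }
  diag(excl) <- TRUE
  excl
}

#' Vacuum Coulomb and Lennard-Jones energies with atom-pairwise terms
#'
#' Pair tensors carry the full i-j interaction symmetrically (zero diagonal);
#' totals are the upper-triangle sums. Excluded pairs: same residue, and
#' 1-2/1-3 pairs across the peptide link of consecutive residues. No distance
#' cutoff. Nonbonded atoms closer than 0.5 Angstrom trigger a clash warning
#' but energies are still returned.
#'
#' @inheritParams born_radii
#' @return list with `ele_total`, `lj_total` (kcal/mol) and `ele_pair`,
#'   `lj_pair` (n x n matrices).
#' @export
mechanical_energy <- function(ps, cfg = energy_config()) {
  a <- ps$atoms
  xyz <- coords(ps)
  q <- a$charge
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  d2[d2 < 1e-12] <- 1e-12
  r <- sqrt(d2)
  excl <- exclusion_mask(ps)
  if (any(r[!excl] < 0.5))
    warning("atom clash: nonbonded pair closer than 0.5 Angstrom")
  ele <- cfg$coulomb * (q %o% q) / (cfg$ein * r)
  rmin <- outer(a$lj_rmin2, a$lj_rmin2, "+")
  epsm <- sqrt(outer(a$lj_eps, a$lj_eps))
  s6 <- (rmin / r)^6
  lj <- epsm * (s6^2 - 2 * s6)
  ele[excl] <- 0
  lj[excl] <- 0
  list(ele_total = sum(ele[upper.tri(ele)]),
       lj_total = sum(lj[upper.tri(lj)]),
       ele_pair = ele, lj_pair = lj)
}
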