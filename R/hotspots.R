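# Hot-spot prediction: (i) an empirical rule combining relative burial on
# complexation with a knowledge-based contact-potential score, and (ii)
# computational alanine scanning against the package's energy engine; plus a
# consensus ranking across the two methods.

# symmetric residue-pair contact-preference weights built from coarse classes:
# hydrophobic packing and opposite-charge pairs score high, like charges low.
contact_weight_table <- function() {
  classes <- c(ALA = "H", VAL = "H", LEU = "H", ILE = "H", MET = "H",
               PHE = "H", TRP = "H", TYR = "H", CYS = "H",
               SER = "P", THR = "P", ASN = "P", GLN = "P", HIS = "P",
               GLY = "P", PRO = "P",
               LYS = "+", ARG = "+", ASP = "-", GLU = "-")
  w <- matrix(2.0, 20, 20, dimnames = list(names(classes), names(classes)))
  for (i in names(classes)) for (j in names(classes)) {
    ci <- classes[i]; cj <- classes[j]
    w[i, j] <-
      if (ci == "H" && cj == "H") 4.0
      else if ((ci == "+" && cj == "-") || (ci == "-" && cj == "+")) 4.0
      else if (ci %in% c("+", "-") && cj == ci) 0.5
      else if (ci == "H" || cj == "H") 2.5
      else 2.0
  }
  w
}

#' Unit-weight contact table (every residue pair counts 1)
#' @export
unit_weight_table <- function() {
  matrix(1, 20, 20, dimnames = list(STANDARD_AA, STANDARD_AA))
}

#' Contact-potential score of an interface residue
#'
#' Sum, over partner-protomer residues having any heavy atom within `shell`
#' Angstrom of the residue, of a knowledge-based residue-pair weight.
#'
#' @param dimer two-protomer `structure3d`.
#' @param partition list of two chain-id sets.
#' @param residue residue key ("chain:resno:") or (chain, resno) pair.
#' @param shell shell radius in Angstrom (default 7).
#' @param weights 20 x 20 symmetric weight matrix (rownames/colnames =
#'   3-letter codes); default [contact_weight_table()].
#' @return numeric score.
#' @export
contact_potential <- function(dimer, partition, residue, shell = 7.0,
                              weights = contact_weight_table()) {
  part <- check_partition(dimer, partition)
  key <- residue_keys(dimer)
  if (length(residue) == 2)
    residue <- paste(residue[1], residue[2], "", sep = ":")
  rows <- which(key == residue)
  if (!length(rows)) stop("residue not found: ", residue)
  own_chain <- dimer$atoms$chain[rows[1]]
  own_side <- if (own_chain %in% part$A) part$A else part$B
  partner_rows <- which(!(dimer$atoms$chain %in% own_side))
  if (!length(partner_rows)) return(0)
  own_xyz <- coords(dimer, rows)
  p_xyz <- coords(dimer, partner_rows)
  d2 <- outer(rowSums(own_xyz^2), rowSums(p_xyz^2), "+") -
    2 * own_xyz %*% t(p_xyz)
  near <- apply(d2 <= shell^2, 2, any)
  near_res <- unique(key[partner_rows[near]])
  if (!length(near_res)) return(0)
  own_name <- dimer$atoms$resname[rows[1]]
  partner_names <- dimer$atoms$resname[match(near_res, key)]
  ok <- own_name %in% rownames(weights) & partner_names %in% colnames(weights)
  sum(weights[own_name, partner_names[ok]])
}

#' Empirical hot-spot calls (burial + contact-potential rule)
#'
#' A residue is an empirical hot spot when its SASA is reduced by at least
#' `burial_min` percent on complexation AND its contact-potential score is at
#' least `contact_min`. Residues with zero isolated SASA are skipped with a
#' warning (burial undefined).
#'
#' @param report `interface_report` from [delta_sasa()] /
#'   [characterize_interface()].
#' @param dimer the dimer the report was computed from.
#' @param burial_min burial threshold in percent (default 20).
#' @param contact_min contact-potential threshold (default 18).
#' @inheritParams contact_potential
#' @return data.frame: `key`, `protomer`, `resname`, `burial_pct`, `contact`,
#'   `empirical` (flag).
#' @export
empirical_hotspots <- function(report, dimer, burial_min = 20,
                               contact_min = 18, shell = 7.0,
                               weights = contact_weight_table()) {
  res <- report$residues[report$residues$interface, , drop = FALSE]
  part <- list(report$partition$A, report$partition$B)
  out <- res[, c("key", "protomer", "resname", "burial_pct")]
  undef <- is.na(out$burial_pct)
  if (any(undef)) {
    warning("skipping residues with zero isolated SASA: ",
            paste(out$key[undef], collapse = ", "))
    out <- out[!undef, , drop = FALSE]
  }
  out$contact <- vapply(out$key, function(k)
    contact_potential(dimer, part, k, shell, weights), numeric(1))
  out$empirical <- out$burial_pct >= burial_min & out$contact >= contact_min
  rownames(out) <- NULL
  out
}

#' Computational alanine scanning across the interface
#'
#' For every interface residue (Gly/Ala/Pro skipped), the side chain beyond
#' CB is truncated and the change in binding free energy is taken as minus
#' the sum of the removed atoms' intermolecular pairwise terms (electrostatic,
#' van der Waals, and GB cross terms at frozen wild-type Born radii) --
#' internally consistent with [pairwise_decomposition()], so a residue with
#' no intermolecular interactions scores exactly zero. `mode = "recompute"`
#' instead rebuilds the truncated structure and re-runs the full energy
#' model.
#'
#' @inheritParams binding_free_energy
#' @param report optional precomputed `interface_report`.
#' @param ddg_min hot-spot threshold on ddG (kcal/mol, default 1.0).
#' @param mode "frozen" (default) or "recompute".
#' @return data.frame: `key`, `protomer`, `resname`, `ddg`, `alascan` (flag).
#' @export
alanine_scan <- function(dimer, partition, cfg = energy_config(),
                         report = NULL, ddg_min = 1.0,
                         mode = c("frozen", "recompute")) {
  mode <- match.arg(mode)
  part <- check_partition(subset_chains(
    dimer, unique(dimer$atoms$chain[dimer$atoms$standard])), partition)
  if (is.null(report))
    report <- delta_sasa(dimer, partition, n_points = cfg$n_points)
  iface <- interface_residues(report)
  keys <- c(iface$A, iface$B)
  rt <- residue_table(dimer)
  keep <- rt$resname[match(keys, rt$key)] %in%
    setdiff(STANDARD_AA, c("GLY", "ALA", "PRO"))
  keys <- keys[keep]
  out <- data.frame(key = keys,
                    protomer = ifelse(keys %in% iface$A, "A", "B"),
                    resname = rt$resname[match(keys, rt$key)],
                    ddg = rep(NA_real_, length(keys)),
                    stringsAsFactors = FALSE)
  if (mode == "frozen") {
    ps <- assign_parameters(dimer)
    key_atoms <- residue_keys(ps)
    inA <- ps$atoms$chain %in% part$A
    xyz <- coords(ps)
    mech <- mechanical_energy(ps, cfg)
    gb <- gb_polar_energy(ps, cfg)
    cross <- outer(inA, inA, "!=")
    for (i in seq_len(nrow(out))) {
      rows <- which(key_atoms == out$key[i] &
                      !(ps$atoms$name %in% c("N", "CA", "C", "O", "OXT", "CB")))
      if (!length(rows)) { out$ddg[i] <- 0; next }
      sel <- matrix(FALSE, nrow(xyz), nrow(xyz))
      sel[rows, ] <- TRUE; sel[, rows] <- TRUE
      sel <- sel & cross
      out$ddg[i] <- -(sum(mech$ele_pair[sel]) + sum(mech$lj_pair[sel]) +
                        sum(gb$pair[sel])) / 2
    }
  } else {
    wt <- binding_free_energy(dimer, partition, cfg)$dg
    for (i in seq_len(nrow(out))) {
      rt_i <- rt[rt$key == out$key[i], ]
      mut <- mutate_residue(dimer, rt_i$chain, rt_i$resno, "ALA",
                            icode = trimws(rt_i$icode))
      out$ddg[i] <- binding_free_energy(mut, partition, cfg)$dg - wt
    }
  }
  out$alascan <- out$ddg >= ddg_min
  rownames(out) <- NULL
  out
}

#' Combined hot-spot report with consensus ranking
#'
#' Residues flagged by both methods rank first, then single-method residues,
#' then the rest; within a tier residues are ordered by the mean z-score of
#' (burial, contact potential, ddG), ties broken by residue number ascending.
#'
#' @inheritParams alanine_scan
#' @inheritParams empirical_hotspots
#' @return object of class `hotspot_report`: data.frame `table` with scores,
#'   flags, `consensus` tier (2/1/0) and `rank`, plus thresholds used.
#' @export
hotspot_report <- function(dimer, partition, cfg = energy_config(),
                           report = NULL, burial_min = 20, contact_min = 18,
                           ddg_min = 1.0, shell = 7.0,
                           weights = contact_weight_table()) {
  if (is.null(report))
    report <- delta_sasa(dimer, partition, n_points = cfg$n_points)
  emp <- empirical_hotspots(report, dimer, burial_min, contact_min, shell,
                            weights)
  ala <- alanine_scan(dimer, partition, cfg, report, ddg_min)
  tab <- merge(emp, ala[, c("key", "ddg", "alascan")], by = "key", all = TRUE)
  tab$empirical[is.na(tab$empirical)] <- FALSE
  tab$alascan[is.na(tab$alascan)] <- FALSE
  tab$consensus <- as.integer(tab$empirical) + as.integer(tab$alascan)
  zs <- function(x) {
    x[is.na(x)] <- 0
    if (length(x) < 2 || stats::sd(x) < 1e-12) return(rep(0, length(x)))
    (x - mean(x)) / stats::sd(x)
  }
  tab$zmean <- rowMeans(cbind(zs(tab$burial_pct), zs(tab$contact),
                              zs(tab$ddg)))
  resno <- as.integer(sub("^.*:(\\d+):.*$", "\\1", paste0(tab$key, ":")))
  ord <- order(-tab$consensus, -tab$zmean, resno)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(table = tab,
                 thresholds = list(burial = burial_min, contact = contact_min,
                                   ddg = ddg_min, shell = shell)),
            class = "hotspot_report")
}

#' @export
print.hotspot_report <- function(x, ...) {
  cat(sprintf("hotspot_report: %d interface residues, %d consensus, %d single-method\n",
              nrow(x$table), sum(x$table$consensus == 2),
              sum(x$table$consensus == 1)))
  invisible(x)
}

#' Consensus-ranked residue list
#'
#' @param hr a `hotspot_report`.
#' @return character vector of residue keys, best-supported first.
#' @export
consensus_rank <- function(hr) {
  hr$table$key
}
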