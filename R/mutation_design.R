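# Rule-based proposal of interface point mutations that discriminate between
# two alternative dimer models: candidate positions come from the
# differential-contribution signature and hot spots of the targeted model
# (plus salt-bridge partners), and each gets a category encoding the intended
# disruption chemistry.

KYTE_DOOLITTLE <- c(ALA = 1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5, CYS = 2.5,
                    GLN = -3.5, GLU = -3.5, GLY = -0.4, HIS = -3.2, ILE = 4.5,
                    LEU = 3.8, LYS = -3.9, MET = 1.9, PHE = 2.8, PRO = -1.6,
                    SER = -0.8, THR = -0.7, TRP = -0.9, TYR = -1.3, VAL = 4.2)

HYDROPHOBIC_AA <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "CYS")
SMALL_MEDIUM_AA <- c("ALA", "VAL", "LEU", "ILE", "CYS", "SER", "THR", "MET")
CHARGED_AA <- c("LYS", "ARG", "ASP", "GLU")
POLAR_AA <- c("SER", "THR", "ASN", "GLN", "TYR", "HIS")

# partner-protomer residues with any heavy atom within `radius` of the
# residue's atoms
partner_environment <- function(dimer, partition, key, radius,
                                sidechain_only = FALSE) {
  part <- check_partition(dimer, partition)
  keys <- residue_keys(dimer)
  rows <- which(keys == key)
  if (sidechain_only)
    rows <- rows[!(dimer$atoms$name[rows] %in% c("N", "CA", "C", "O", "OXT"))]
  if (!length(rows)) return(character(0))
  own_chain <- dimer$atoms$chain[which(keys == key)[1]]
  own_side <- if (own_chain %in% part$A) part$A else part$B
  prows <- which(!(dimer$atoms$chain %in% own_side))
  if (!length(prows)) return(character(0))
  d2 <- outer(rowSums(coords(dimer, rows)^2),
              rowSums(coords(dimer, prows)^2), "+") -
    2 * coords(dimer, rows) %*% t(coords(dimer, prows))
  hit <- prows[apply(d2 <= radius^2, 2, any)]
  keys[hit]
}

count_pocket_atoms <- function(dimer, partition, key, radius = 5.0) {
  env_keys <- partner_environment(dimer, partition, key, radius,
                                  sidechain_only = TRUE)
  if (!length(env_keys)) return(0L)
  keys <- residue_keys(dimer)
  rows <- which(keys == key &
                  !(dimer$atoms$name %in% c("N", "CA", "C", "O", "OXT")))
  prows <- which(keys %in% env_keys)
  d2 <- outer(rowSums(coords(dimer, rows)^2),
              rowSums(coords(dimer, prows)^2), "+") -
    2 * coords(dimer, rows) %*% t(coords(dimer, prows))
  sum(apply(d2 <= radius^2, 2, any))
}

mean_partner_hydropathy <- function(dimer, partition, key, radius = 6.0) {
  env_keys <- partner_environment(dimer, partition, key, radius)
  if (!length(env_keys)) return(NA_real_)
  keys <- residue_keys(dimer)
  rn <- dimer$atoms$resname[match(env_keys, keys)]
  mean(KYTE_DOOLITTLE[rn], na.rm = TRUE)
}

near_positive_partner <- function(dimer, partition, key, radius = 6.0) {
  env_keys <- partner_environment(dimer, partition, key, radius)
  keys <- residue_keys(dimer)
  any(dimer$atoms$resname[match(env_keys, keys)] %in% c("LYS", "ARG", "HIS"))
}

#' Propose model-discriminating interface point mutations
#'
#' Candidate positions for each targeted model are the intersection of that
#' model's differential-contribution signature with its hot spots, extended
#' by intermolecular salt-bridge partners from the contact list. Rules assign
#' one category per position:
#' \itemize{
#'   \item hydrophobic residue in a hydrophobic partner environment (mean
#'     Kyte-Doolittle hydropathy > `hydro_min` within 6 A): mutate to Arg
#'     (or Glu when a positive partner charge is nearby) --
#'     charge-into-hydrophobic;
#'   \item charged residue in an intermolecular salt bridge: mutate to Ala --
#'     salt-bridge-removal;
#'   \item small/medium hydrophobic residue in a tight pocket (>=
#'     `pocket_min` partner heavy atoms within 5 A of the side chain):
#'     mutate to Trp -- steric-insertion;
#'   \item polar residue adjacent to an intermolecular salt-bridge network:
#'     mutate to the charge complementing the nearby partner charge --
#'     interaction-reinforcement.
#' }
#' Priority is the consensus hot-spot tier plus |LOG(RP)|; the top `k`
#' proposals per model are returned, ties broken by residue number.
#'
#' @param model_a,model_b per-model analysis bundles: lists with elements
#'   `dimer` (structure), `report` (`interface_report` with contacts),
#'   `hotspots` (`hotspot_report`).
#' @param rp an `rp_result` comparing model A vs model B (shared residue
#'   indexing).
#' @param partition chain partition shared by both models.
#' @param k maximum proposals per model.
#' @param hydro_min hydrophobic-environment threshold (default 1.5).
#' @param pocket_min tight-pocket atom-count threshold (default 18).
#' @return data.frame of proposals: `model`, `chain`, `resno`, `wt`,
#'   `proposed`, `category`, `expected_effect`, `priority`, `rationale`.
#' @export
propose_mutations <- function(model_a, model_b, rp, partition, k = 8,
                              hydro_min = 1.5, pocket_min = 18) {
  sig <- rp$signature
  proposals <- list()
  for (target in c("A", "B")) {
    bundle <- if (target == "A") model_a else model_b
    dimer <- bundle$dimer
    report <- bundle$report
    hs <- bundle$hotspots$table
    iface <- unlist(interface_residues(report), use.names = FALSE)
    hot_keys <- hs$key[hs$consensus >= 1]
    cand <- intersect(sig[[target]], hot_keys)
    # extend with salt-bridge partners seen in this model's contact list
    ct <- report$contacts
    sb <- ct[ct$salt_bridge, , drop = FALSE]
    cand <- union(cand, intersect(c(sb$res_i, sb$res_j), iface))
    cand <- intersect(cand, iface)
    if (!length(cand)) {
      warning("no candidate positions for model ", target)
      next
    }
    keys <- residue_keys(dimer)
    for (key in cand) {
      rn <- dimer$atoms$resname[match(key, keys)]
      chain <- dimer$atoms$chain[match(key, keys)]
      resno <- dimer$atoms$resno[match(key, keys)]
      in_sb <- key %in% c(sb$res_i, sb$res_j)
      hyd <- mean_partner_hydropathy(dimer, partition, key)
      pocket <- count_pocket_atoms(dimer, partition, key)
      cat_ <- NULL; prop_aa <- NULL; why <- NULL
      if (rn %in% CHARGED_AA && in_sb) {
        cat_ <- "salt-bridge-removal"; prop_aa <- "ALA"
        why <- "charged residue engaged in an intermolecular salt bridge"
      } else if (rn %in% HYDROPHOBIC_AA && !is.na(hyd) && hyd > hydro_min) {
        cat_ <- "charge-into-hydrophobic"
        prop_aa <- if (near_positive_partner(dimer, partition, key)) "GLU"
                   else "ARG"
        why <- sprintf("hydrophobic residue in hydrophobic environment (KD %.2f)",
                       hyd)
      } else if (rn %in% SMALL_MEDIUM_AA && pocket >= pocket_min) {
        cat_ <- "steric-insertion"; prop_aa <- "TRP"
        why <- sprintf("tight pocket (%d partner atoms within 5 A)", pocket)
      } else if (rn %in% POLAR_AA && nrow(sb) > 0 &&
                 length(intersect(partner_environment(dimer, partition, key, 6),
                                  c(sb$res_i, sb$res_j)))) {
        cat_ <- "interaction-reinforcement"
        prop_aa <- if (near_positive_partner(dimer, partition, key)) "GLU"
                   else "LYS"
        why <- "polar residue adjacent to an intermolecular salt-bridge network"
      }
      if (is.null(cat_)) next
      logrp <- rp$table$logRP[match(key, rp$table$residue)]
      tier <- hs$consensus[match(key, hs$key)]
      if (is.na(tier)) tier <- 0L
      proposals[[length(proposals) + 1]] <- data.frame(
        model = target, chain = chain, resno = resno, wt = rn,
        proposed = prop_aa, category = cat_,
        priority = tier + abs(if (is.na(logrp)) 0 else logrp),
        rationale = why, stringsAsFactors = FALSE)
    }
  }
  if (!length(proposals))
    return(annotate_expected_effect(data.frame(
      model = character(0), chain = character(0), resno = integer(0),
      wt = character(0), proposed = character(0), category = character(0),
      priority = numeric(0), rationale = character(0),
      stringsAsFactors = FALSE)))
  out <- do.call(rbind, proposals)
  out <- out[order(out$model, -out$priority, out$resno), , drop = FALSE]
  out <- do.call(rbind, lapply(split(out, out$model), utils::head, k))
  rownames(out) <- NULL
  annotate_expected_effect(out)
}

#' Label proposals with their expected effect on dimerization
#'
#' Interaction-reinforcement proposals are expected to reinforce the targeted
#' dimer; every other category is designed to disrupt it.
#'
#' @param p proposal data.frame from [propose_mutations()].
#' @return `p` with an `expected_effect` column ("disrupting"/"reinforcing").
#' @export
annotate_expected_effect <- function(p) {
  p$expected_effect <- ifelse(p$category == "interaction-reinforcement",
                              "reinforcing", "disrupting")
  p
}
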