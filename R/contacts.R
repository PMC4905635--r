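# Typed intermolecular contact enumeration: electrostatic contacts (H-bonds
# and salt bridges between heavy atoms) and van der Waals contacts, counted
# once per residue pair and type.

POSITIVE_GROUP <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ",
                       HIS = c("ND1", "NE2"))
NEGATIVE_GROUP <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

charged_sign <- function(resname, atom) {
  if (atom == "OXT") return(-1L)
  if (!is.null(POSITIVE_GROUP[[resname]]) && atom %in% POSITIVE_GROUP[[resname]])
    return(1L)
  if (!is.null(NEGATIVE_GROUP[[resname]]) && atom %in% NEGATIVE_GROUP[[resname]])
    return(-1L)
  0L
}

#' Enumerate typed intermolecular contacts across a dimer interface
#'
#' Ele contacts are hydrogen bonds (N/O donor-acceptor heavy-atom pairs within
#' `hbond_cutoff`) or salt bridges (side-chain charged-group N/O pairs of
#' oppositely charged residues within `salt_cutoff`); every other heavy-atom
#' pair within `vdw_cutoff` is a VdW contact. Angle criteria are not applied
#' because inputs carry no hydrogens. Each residue pair is reported at most
#' once per type, with its closest qualifying atom pair.
#'
#' @param dimer two-protomer `structure3d`.
#' @param partition list of two chain-id sets.
#' @param hbond_cutoff,salt_cutoff,vdw_cutoff distance cutoffs in Angstrom.
#' @return data.frame with columns `res_i`, `res_j` (residue keys, protomer A
#'   first), `resname_i`, `resname_j`, `type` ("Ele" or "VdW"), `atom_i`,
#'   `atom_j`, `distance`, `salt_bridge` (logical).
#' @export
enumerate_contacts <- function(dimer, partition, hbond_cutoff = 3.5,
                               salt_cutoff = 4.0, vdw_cutoff = 3.9) {
  part <- check_partition(dimer, partition)
  a <- dimer$atoms
  key <- residue_keys(dimer)
  ia <- which(a$chain %in% part$A)
  ib <- which(a$chain %in% part$B)
  xa <- coords(dimer, ia); xb <- coords(dimer, ib)
  maxcut <- max(hbond_cutoff, salt_cutoff, vdw_cutoff)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  hits <- which(d2 < maxcut^2, arr.ind = TRUE)
  out <- list()
  if (nrow(hits)) {
    i <- ia[hits[, 1]]; j <- ib[hits[, 2]]
    d <- sqrt(pmax(d2[hits], 0))
    sign_i <- mapply(charged_sign, a$resname[i], a$name[i])
    sign_j <- mapply(charged_sign, a$resname[j], a$name[j])
    is_no_i <- a$element[i] %in% c("N", "O")
    is_no_j <- a$element[j] %in% c("N", "O")
    salt <- sign_i * sign_j < 0 & d <= salt_cutoff
    hbond <- is_no_i & is_no_j & d <= hbond_cutoff
    ele <- salt | hbond
    vdw <- !ele & d <= vdw_cutoff
    df <- data.frame(res_i = key[i], res_j = key[j],
                     resname_i = a$resname[i], resname_j = a$resname[j],
                     atom_i = a$name[i], atom_j = a$name[j],
                     distance = d, salt_bridge = salt,
                     type = ifelse(ele, "Ele", ifelse(vdw, "VdW", "none")),
                     stringsAsFactors = FALSE)
    df <- df[df$type != "none", , drop = FALSE]
    if (nrow(df)) {
      # one row per (residue pair, type): keep closest atom pair; a pair with
      # any salt bridge keeps the salt-bridge flag
      df <- df[order(paste(df$res_i, df$res_j, df$type), df$distance), ,
               drop = FALSE]
      grp <- paste(df$res_i, df$res_j, df$type)
      sb_any <- tapply(df$salt_bridge, grp, any)
      df_first <- df[!duplicated(paste(df$res_i, df$res_j, df$type)), , drop = FALSE]
      df_first$salt_bridge <- as.logical(sb_any[paste(df_first$res_i,
                                                      df_first$res_j,
                                                      df_first$type)])
      out <- df_first[order(df_first$res_i, df_first$res_j, df_first$type), ]
      rownames(out) <- NULL
      return(out)
    }
  }
  data.frame(res_i = character(0), res_j = character(0),
             resname_i = character(0), resname_j = character(0),
             atom_i = character(0), atom_j = character(0),
             distance = numeric(0), salt_bridge = logical(0),
             type = character(0), stringsAsFactors = FALSE)
}

#' Full interface characterization of one dimer model
#'
#' Convenience wrapper combining [delta_sasa()] and [enumerate_contacts()]
#' into one report (buried area, interface residue counts, Ele/VdW contact
#' counts per model).
#'
#' @inheritParams delta_sasa
#' @param ... passed to [enumerate_contacts()].
#' @return an `interface_report` with a `contacts` element attached.
#' @export
characterize_interface <- function(dimer, partition, threshold = 0.1,
                                   probe = 1.4, n_points = 1920, ...) {
  rep <- delta_sasa(dimer, partition, threshold, probe, n_points)
  rep$contacts <- enumerate_contacts(dimer, partition, ...)
  rep$n_ele <- sum(rep$contacts$type == "Ele")
  rep$n_vdw <- sum(rep$contacts$type == "VdW")
  rep
}
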