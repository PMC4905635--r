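# Loop grafting: splice a topologically equivalent donor loop into a chain
# break of an acceptor structure, after superposing the donor on the anchor
# CA atoms flanking the gap.

ca_coords_for <- function(s, chain, resnos) {
  a <- s$atoms
  out <- matrix(NA_real_, length(resnos), 3)
  for (i in seq_along(resnos)) {
    j <- which(a$chain == chain & a$resno == resnos[i] & a$name == "CA")
    if (length(j) != 1) stop("missing CA for residue ", chain, ":", resnos[i])
    out[i, ] <- c(a$x[j], a$y[j], a$z[j])
  }
  out
}

#' Graft a donor loop into a chain break of an acceptor structure
#'
#' The donor segment is rigid-body superposed onto the acceptor using the CA
#' atoms of `n_anchor` residues flanking each side of the gap (2 x n_anchor
#' anchors), then spliced in and renumbered to the acceptor scheme. Used to
#' fill unresolved loops with coordinates from a structurally conserved
#' homolog.
#'
#' @param acceptor `structure3d` with a chain break spanning `gap`.
#' @param donor `structure3d` providing the replacement loop.
#' @param chain acceptor chain id to repair.
#' @param gap integer vector of missing acceptor residue numbers (consecutive).
#' @param donor_chain donor chain id.
#' @param donor_range integer vector of donor residue numbers supplying the
#'   loop; must have the same length as `gap`.
#' @param n_anchor anchor residues per gap side (default 3).
#' @param max_anchor_rmsd reject the graft if the anchor-fit RMSD (Angstrom)
#'   exceeds this limit (default 2.0).
#' @return list with `structure` (repaired `structure3d`) and `anchor_rmsd`.
#' @export
graft_loop <- function(acceptor, donor, chain, gap, donor_chain, donor_range,
                       n_anchor = 3, max_anchor_rmsd = 2.0) {
  gap <- sort(as.integer(gap))
  donor_range <- sort(as.integer(donor_range))
  if (length(gap) != length(donor_range))
    stop("donor_range length (", length(donor_range),
         ") differs from gap length (", length(gap), ")")
  acc_res <- residue_table(acceptor)
  acc_res <- acc_res[acc_res$chain == chain, ]
  if (any(gap %in% acc_res$resno))
    stop("acceptor already has residues inside the gap")
  left <- seq(gap[1] - n_anchor, gap[1] - 1)
  right <- seq(gap[length(gap)] + 1, gap[length(gap)] + n_anchor)
  dleft <- seq(donor_range[1] - n_anchor, donor_range[1] - 1)
  dright <- seq(donor_range[length(donor_range)] + 1,
                donor_range[length(donor_range)] + n_anchor)
  ref <- ca_coords_for(acceptor, chain, c(left, right))
  mob <- ca_coords_for(donor, donor_chain, c(dleft, dright))
  fit <- superpose(mob, ref)
  if (fit$rmsd > max_anchor_rmsd)
    stop(sprintf("anchor-fit rmsd %.3f A exceeds limit %.3f A",
                 fit$rmsd, max_anchor_rmsd))
  da <- donor$atoms
  loop <- da[da$chain == donor_chain & da$resno %in% donor_range, , drop = FALSE]
  if (!nrow(loop)) stop("donor loop has no atoms")
  xyz <- apply_transform(cbind(loop$x, loop$y, loop$z),
                         fit$rotation, fit$translation)
  loop$x <- xyz[, 1]; loop$y <- xyz[, 2]; loop$z <- xyz[, 3]
  loop$resno <- gap[match(loop$resno, donor_range)]
  loop$chain <- chain
  loop$het <- FALSE
  aa <- acceptor$atoms
  in_chain <- aa$chain == chain
  pre <- aa[in_chain & aa$resno < gap[1], , drop = FALSE]
  post <- aa[in_chain & aa$resno > gap[length(gap)], , drop = FALSE]
  other_before <- aa[!in_chain & cumsum(in_chain) == 0, , drop = FALSE]
  other_after <- aa[!in_chain & cumsum(in_chain) > 0, , drop = FALSE]
  out <- structure3d(rbind(other_before, pre, loop, post, other_after))
  list(structure = out, anchor_rmsd = fit$rmsd)
}
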