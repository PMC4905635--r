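# Shrake-Rupley solvent accessible surface area and interface burial
# (delta-SASA on complexation).

#' Element radii used for SASA (Angstrom)
#' @export
SASA_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

# orthonormal frame for atom i from the first two other atoms of its residue
# (identity when the residue has fewer than 3 atoms)
local_frame <- function(xyz, res_rows, i) {
  others <- setdiff(res_rows, i)
  if (length(others) < 2) return(diag(3))
  v1 <- xyz[others[1], ] - xyz[i, ]
  v2 <- xyz[others[2], ] - xyz[i, ]
  n1 <- sqrt(sum(v1^2))
  if (n1 < 1e-9) return(diag(3))
  e1 <- v1 / n1
  v2 <- v2 - sum(v2 * e1) * e1
  n2 <- sqrt(sum(v2^2))
  if (n2 < 1e-9) {
    v2 <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v2 <- v2 - sum(v2 * e1) * e1
    n2 <- sqrt(sum(v2^2))
  }
  e2 <- v2 / n2
  cbind(e1, e2, cross3(e1, e2))
}

# deterministic quasi-uniform sphere lattice (golden-section spiral)
sphere_lattice <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

atom_radii <- function(s, radii = SASA_RADII, default = NA_real_) {
  r <- radii[s$atoms$element]
  if (anyNA(r)) {
    if (is.na(default))
      stop("no SASA radius for element(s): ",
           paste(unique(s$atoms$element[is.na(r)]), collapse = ", "))
    r[is.na(r)] <- default
  }
  unname(r)
}

#' Solvent accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA with a fixed deterministic sphere lattice, so results are
#' exactly reproducible for a given `n_points`.
#'
#' @param s a `structure3d`.
#' @param probe probe radius in Angstrom (water: 1.4).
#' @param n_points quadrature points per atom (>= 92; default 1920).
#' @param radii named element-radius vector (Angstrom).
#' @return list with `atom` (per-atom SASA, Angstrom^2) and `residue`
#'   (data.frame `key`, `chain`, `resno`, `resname`, `sasa`).
#' @export
sasa <- function(s, probe = 1.4, n_points = 1920, radii = SASA_RADII) {
  stopifnot(probe > 0, n_points >= 92)
  xyz <- coords(s)
  r <- atom_radii(s, radii)
  n <- nrow(xyz)
  lat0 <- sphere_lattice(n_points)
  rs <- r + probe
  out <- numeric(n)
  key <- residue_keys(s)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (rs[i] + rs)^2 & d2 > 1e-12)
    # orient the lattice from the atom's own-residue geometry: deterministic,
    # rotates with the molecule (exact rigid-motion invariance), identical
    # between complex and isolated protomer, and decorrelates quadrature
    # boundary error across atoms so residue sums converge faster
    lat <- lat0 %*% t(local_frame(xyz, which(key == key[i]), i))
    pts <- lat * rs[i]
    pts <- sweep(pts, 2, xyz[i, ], "+")
    if (length(nb)) {
      acc <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
        acc <- acc & (dj2 >= rs[j]^2)
        if (!any(acc)) break
      }
      frac <- sum(acc) / n_points
    } else frac <- 1
    out[i] <- frac * 4 * pi * rs[i]^2
  }
  res_sasa <- tapply(out, factor(key, levels = unique(key)), sum)
  rt <- residue_table(s)
  rt$sasa <- as.numeric(res_sasa[rt$key])
  list(atom = out, residue = rt[, c("key", "chain", "resno", "resname", "sasa")])
}

check_partition <- function(s, partition) {
  if (!is.list(partition) || length(partition) != 2)
    stop("partition must be a list of two chain sets")
  ch <- chains(s)
  pa <- partition[[1]]; pb <- partition[[2]]
  if (length(intersect(pa, pb)))
    stop("partition sets overlap: ", paste(intersect(pa, pb), collapse = ","))
  if (!setequal(c(pa, pb), ch))
    stop("partition does not cover chains ", paste(ch, collapse = ","))
  list(A = pa, B = pb)
}

#' Buried surface on complexation (delta-SASA) and interface residues
#'
#' Computes per-residue SASA in the complex and in each isolated protomer at
#' complex geometry; the difference is the surface buried by the partner.
#'
#' @param dimer two-protomer `structure3d`.
#' @param partition list of two chain-id sets, e.g. `list("A", "B")`.
#' @param threshold interface flag threshold on per-residue delta-SASA
#'   (Angstrom^2, default 0.1 to suppress quadrature noise).
#' @inheritParams sasa
#' @return object of class `interface_report`: list with `residues`
#'   (per-residue table: sasa_complex, sasa_isolated, dsasa, burial_pct,
#'   protomer, interface), `totals` (per-protomer buried area), `counts`
#'   (interface residues per protomer), plus the parameters used.
#' @export
delta_sasa <- function(dimer, partition, threshold = 0.1, probe = 1.4,
                       n_points = 1920, radii = SASA_RADII) {
  part <- check_partition(dimer, partition)
  full <- sasa(dimer, probe, n_points, radii)
  res <- full$residue
  names(res)[names(res) == "sasa"] <- "sasa_complex"
  res$protomer <- ifelse(res$chain %in% part$A, "A", "B")
  res$sasa_isolated <- NA_real_
  for (side in c("A", "B")) {
    sub <- subset_chains(dimer, part[[side]])
    iso <- sasa(sub, probe, n_points, radii)$residue
    idx <- match(iso$key, res$key)
    res$sasa_isolated[idx] <- iso$sasa
  }
  res$dsasa <- pmax(res$sasa_isolated - res$sasa_complex, 0)
  res$burial_pct <- ifelse(res$sasa_isolated > 1e-9,
                           100 * res$dsasa / res$sasa_isolated, NA_real_)
  res$interface <- res$dsasa > threshold
  totals <- tapply(res$dsasa, res$protomer, sum)
  counts <- tapply(res$interface, res$protomer, sum)
  structure(list(residues = res,
                 totals = as.list(totals),
                 counts = as.list(counts),
                 threshold = threshold, probe = probe, n_points = n_points,
                 partition = part),
            class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf(
    "interface_report: %d+%d interface residues; buried area A=%.1f B=%.1f A^2\n",
    x$counts$A, x$counts$B, x$totals$A, x$totals$B))
  if (!is.null(x$contacts))
    cat(sprintf("  contacts: %d Ele, %d VdW\n",
                sum(x$contacts$type == "Ele"), sum(x$contacts$type == "VdW")))
  invisible(x)
}

#' Interface residue keys per protomer
#'
#' @param report an `interface_report` from [delta_sasa()].
#' @param threshold optional override of the delta-SASA threshold (Angstrom^2).
#' @return list with character vectors `A` and `B` of residue keys.
#' @export
interface_residues <- function(report, threshold = NULL) {
  res <- report$residues
  thr <- if (is.null(threshold)) report$threshold else threshold
  flag <- res$dsasa > thr
  list(A = res$key[flag & res$protomer == "A"],
       B = res$key[flag & res$protomer == "B"])
}
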