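# End-to-end comparison of two alternative dimer models: interface
# characterization, binding free energy decomposition, replicate ensembles,
# Rank Products signatures, hot spots, and mutation proposals, bundled with
# provenance (config hash + seed).

#' Configuration for a two-model comparison run
#'
#' @param model_a,model_b the two dimer models: `structure3d` objects or PDB
#'   file paths. Both must be assembled from the same protomers (identical
#'   residue indexing).
#' @param partition list of two chain-id sets shared by both models.
#' @param cfg an [energy_config()].
#' @param n_replicates,jitter replicate-ensemble settings (see
#'   [replicate_ensemble()]).
#' @param n_perm,alpha Rank Products settings.
#' @param seed master seed; every stochastic stage derives its own seed from
#'   it (replicates A: seed + 101, replicates B: seed + 202, permutations:
#'   seed + 303).
#' @param burial_min,contact_min,ddg_min hot-spot thresholds.
#' @param k_mutations max mutation proposals per model.
#' @return list of class `run_config`.
#' @export
run_config <- function(model_a, model_b, partition = list("A", "B"),
                       cfg = energy_config(), n_replicates = 8,
                       jitter = 0.05, n_perm = 10000, alpha = 0.05, seed,
                       burial_min = 20, contact_min = 18, ddg_min = 1.0,
                       k_mutations = 8) {
  if (missing(seed)) stop("seed is mandatory")
  load_model <- function(m) if (inherits(m, "structure3d")) m else read_pdb(m)
  a <- load_model(model_a); b <- load_model(model_b)
  structure(list(model_a = a, model_b = b, partition = partition,
                 cfg = cfg, n_replicates = n_replicates, jitter = jitter,
                 n_perm = n_perm, alpha = alpha, seed = as.integer(seed),
                 burial_min = burial_min, contact_min = contact_min,
                 ddg_min = ddg_min, k_mutations = k_mutations),
            class = "run_config")
}

config_hash <- function(rc) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(list(a = rc$model_a$atoms, b = rc$model_b$atoms,
               partition = rc$partition, cfg = unclass(rc$cfg),
               n_replicates = rc$n_replicates, jitter = rc$jitter,
               n_perm = rc$n_perm, alpha = rc$alpha, seed = rc$seed),
          f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Run the full two-model comparison
#'
#' Validates that both models share residue indexing, then characterizes both
#' interfaces, decomposes both binding free energies, builds jittered
#' replicate ensembles, compares them with Rank Products, predicts hot spots,
#' proposes discriminating mutations, and summarizes which model the evidence
#' favors (lower binding free energy).
#'
#' @param rc a [run_config()].
#' @return list of class `comparison_bundle` with elements `interface_a/b`,
#'   `energy_a/b` (interaction matrices), `replicates_a/b`, `rp`,
#'   `hotspots_a/b`, `proposals`, `summary`, `config_hash`, `seed`.
#' @export
run_comparison <- function(rc) {
  stopifnot(inherits(rc, "run_config"))
  ka <- residue_table(rc$model_a)$key
  kb <- residue_table(rc$model_b)$key
  if (!identical(ka, kb))
    stop("models do not share residue indexing; offending residues: ",
         paste(union(setdiff(ka, kb), setdiff(kb, ka)), collapse = ", "))
  hash <- config_hash(rc)
  part <- rc$partition
  cfg <- rc$cfg

  iface_a <- characterize_interface(rc$model_a, part, n_points = cfg$n_points,
                                    probe = cfg$probe)
  iface_b <- characterize_interface(rc$model_b, part, n_points = cfg$n_points,
                                    probe = cfg$probe)
  en_a <- pairwise_decomposition(rc$model_a, part, cfg)
  en_b <- pairwise_decomposition(rc$model_b, part, cfg)
  rep_a <- replicate_ensemble(rc$model_a, part, cfg, n = rc$n_replicates,
                              jitter = rc$jitter, seed = rc$seed + 101L,
                              model_id = "A")
  rep_b <- replicate_ensemble(rc$model_b, part, cfg, n = rc$n_replicates,
                              jitter = rc$jitter, seed = rc$seed + 202L,
                              model_id = "B")
  rp <- rank_products(rep_a, rep_b, n_perm = rc$n_perm, alpha = rc$alpha,
                      seed = rc$seed + 303L)
  hs_a <- hotspot_report(rc$model_a, part, cfg, report = iface_a,
                         burial_min = rc$burial_min,
                         contact_min = rc$contact_min, ddg_min = rc$ddg_min)
  hs_b <- hotspot_report(rc$model_b, part, cfg, report = iface_b,
                         burial_min = rc$burial_min,
                         contact_min = rc$contact_min, ddg_min = rc$ddg_min)
  proposals <- propose_mutations(
    list(dimer = rc$model_a, report = iface_a, hotspots = hs_a),
    list(dimer = rc$model_b, report = iface_b, hotspots = hs_b),
    rp, part, k = rc$k_mutations)

  dg_a <- en_a$delta$total
  dg_b <- en_b$delta$total
  favored <- if (dg_a < dg_b) "A" else "B"
  summary <- list(
    favored_model = favored,
    dg = list(A = dg_a, B = dg_b),
    signature = rp$signature,
    consensus_hotspots = list(
      A = hs_a$table$key[hs_a$table$consensus == 2],
      B = hs_b$table$key[hs_b$table$consensus == 2]),
    interface_size = list(A = unlist(iface_a$counts),
                          B = unlist(iface_b$counts)),
    config_hash = hash, seed = rc$seed)

  structure(list(interface_a = iface_a, interface_b = iface_b,
                 energy_a = en_a, energy_b = en_b,
                 replicates_a = rep_a, replicates_b = rep_b, rp = rp,
                 hotspots_a = hs_a, hotspots_b = hs_b,
                 proposals = proposals, summary = summary,
                 config_hash = hash, seed = rc$seed),
            class = "comparison_bundle")
}

#' @export
print.comparison_bundle <- function(x, ...) {
  s <- x$summary
  cat(sprintf("comparison_bundle (seed %d, hash %s)\n", x$seed,
              substr(x$config_hash, 1, 8)))
  cat(sprintf("  delta-G: A = %.3f, B = %.3f kcal/mol -> favored model: %s\n",
              s$dg$A, s$dg$B, s$favored_model))
  cat(sprintf("  signature sizes: A = %d, B = %d; proposals: %d\n",
              length(s$signature$A), length(s$signature$B),
              nrow(x$proposals)))
  invisible(x)
}

#' Write a comparison bundle to disk
#'
#' Emits per-residue interface tables (CSV), contact lists (CSV), interaction
#' matrices (dense CSV and long TSV), replicate matrices (TSV), the Rank
#' Products table (CSV), hot-spot tables (CSV), mutation proposals (CSV), a
#' summary JSON, LOG(RP) profile and interaction-matrix heatmap figures
#' (PDF), B-factor-annotated PDBs, and a manifest of everything written.
#'
#' @param bundle a `comparison_bundle` (possibly partial).
#' @param dir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir)
  files <- character(0)
  emit <- function(obj, name, writer) {
    path <- file.path(dir, name)
    writer(obj, path)
    files <<- c(files, name)
  }
  wcsv <- function(x, p) utils::write.csv(x, p, row.names = FALSE)
  wtsv <- function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                            col.names = NA)
  for (side in c("a", "b")) {
    up <- toupper(side)
    iface <- bundle[[paste0("interface_", side)]]
    if (!is.null(iface)) {
      emit(iface$residues, paste0("interface_", side, ".csv"), wcsv)
      emit(iface$contacts, paste0("contacts_", side, ".csv"), wcsv)
    }
    en <- bundle[[paste0("energy_", side)]]
    if (!is.null(en)) {
      emit(as.data.frame(en$matrix), paste0("matrix_", side, ".csv"),
           function(x, p) utils::write.csv(x, p, row.names = TRUE))
      long <- data.frame(res_i = rep(rownames(en$matrix),
                                     ncol(en$matrix)),
                         res_j = rep(colnames(en$matrix),
                                     each = nrow(en$matrix)))
      for (ch in names(en$channels))
        long[[ch]] <- as.vector(en$channels[[ch]])
      long$total <- as.vector(en$matrix)
      emit(long, paste0("matrix_", side, "_long.tsv"),
           function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                             row.names = FALSE))
      emit(en, paste0("energy_", side, ".json"), function(x, p)
        jsonlite::write_json(x$delta, p, auto_unbox = TRUE, digits = NA))
    }
    reps <- bundle[[paste0("replicates_", side)]]
    if (!is.null(reps)) emit(reps, paste0("replicates_", side, ".tsv"), wtsv)
    hs <- bundle[[paste0("hotspots_", side)]]
    if (!is.null(hs)) emit(hs$table, paste0("hotspots_", side, ".csv"), wcsv)
  }
  if (!is.null(bundle$rp))
    emit(bundle$rp$table, "rank_products.csv", wcsv)
  if (!is.null(bundle$proposals))
    emit(bundle$proposals, "proposals.csv", wcsv)
  if (!is.null(bundle$summary))
    emit(bundle$summary, "summary.json", function(x, p)
      jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA))
  if (!is.null(bundle$rp)) {
    p <- file.path(dir, "logrp_profile.pdf")
    grDevices::pdf(p, width = 8, height = 4)
    print(plot_logrp(bundle$rp))
    grDevices::dev.off()
    files <- c(files, "logrp_profile.pdf")
  }
  if (!is.null(bundle$energy_a)) {
    p <- file.path(dir, "interaction_heatmaps.pdf")
    grDevices::pdf(p, width = 7, height = 6)
    print(plot_interaction_matrix(bundle$energy_a, "model A"))
    if (!is.null(bundle$energy_b))
      print(plot_interaction_matrix(bundle$energy_b, "model B"))
    grDevices::dev.off()
    files <- c(files, "interaction_heatmaps.pdf")
  }
  manifest <- list(files = files, config_hash = bundle$config_hash,
                   seed = bundle$seed,
                   written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(files)
}

#' Bar profile of LOG(RP) values with signature membership
#'
#' @param rp an `rp_result`.
#' @return a ggplot object.
#' @export
plot_logrp <- function(rp) {
  tab <- rp$table
  tab$residue <- factor(tab$residue, levels = tab$residue)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$residue, y = .data$logRP,
                                    fill = .data$signature)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(A = "#2166ac", B = "#b2182b",
                                          none = "grey70")) +
    ggplot2::labs(x = NULL, y = "LOG(RP)",
                  title = "Rank Products profile (negative favors model A)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Interaction energy matrix heatmap (protomer A x protomer B)
#'
#' @param m an `interaction_matrix`.
#' @param title plot title.
#' @param channel channel to plot (default "total").
#' @return a ggplot object.
#' @export
plot_interaction_matrix <- function(m, title = "interaction energy matrix",
                                    channel = "total") {
  cm <- cross_matrix(m, channel)
  df <- data.frame(res_a = rep(rownames(cm), ncol(cm)),
                   res_b = rep(colnames(cm), each = nrow(cm)),
                   value = as.vector(cm))
  df$res_a <- factor(df$res_a, levels = rownames(cm))
  df$res_b <- factor(df$res_b, levels = colnames(cm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$res_b, y = .data$res_a,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  name = "kcal/mol") +
    ggplot2::labs(x = "protomer B", y = "protomer A", title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Write per-residue contributions into the B-factor column
#'
#' @param dimer a `structure3d`.
#' @param contributions named per-residue vector (keys as in
#'   [per_residue_contribution()]).
#' @param path output PDB path.
#' @export
write_bfactor_pdb <- function(dimer, contributions, path) {
  key <- residue_keys(dimer)
  b <- contributions[key]
  b[is.na(b)] <- 0
  dimer$atoms$bfac <- pmax(pmin(as.numeric(b), 999.99), -99.99)
  write_pdb(dimer, path)
}
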