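#!/usr/bin/env Rscript
# Step 3 — SNP imputation panel for KIV2-CN.
#
# Reproduces the train/validate protocol: 2:1 split (siblings never
# straddle), candidate filtering (4 Mb window, MAF > 0.001, imputation
# quality > 0.8), sliding-window LD pruning (50/5/0.25), 10-fold
# cross-validated LASSO on the read-depth CN estimate, random-forest
# importance ranking of the selected variants, and held-out validation.

suppressPackageStartupMessages(library(kiv2cn))
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(n_samples = 2100, n_variants = 300, ancestry = "european")
sim <- simulate_cohort(cfg, seed = 1)
est <- estimate_kiv2_cn(sim$bundle$depth)
sim$bundle$phenotypes$kiv2_cn_est <- est$kiv2_cn

sp <- split_train_validate(sim$bundle, 2/3, seed = 1, pairs = sim$truth$pairs)
cand <- filter_panel_variants(sp$train$variants,
                              window = c(158532140, 162664257))
kept <- ld_prune(sp$train$genotypes[, cand$variant_id], cand)
panel <- fit_lasso_panel(sp$train$genotypes[, kept],
                         sp$train$phenotypes$kiv2_cn_est, seed = 1)
write_panel(panel, "results/03_panel.json")
print(panel)

imp <- rank_importance(panel, sp$train$genotypes,
                       sp$train$phenotypes$kiv2_cn_est, seed = 1)
write.table(format(imp, digits = 4), "results/03_panel_importance.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

val <- validate_panel(panel, sp$validate$genotypes,
                      sp$validate$phenotypes$kiv2_cn_est)
out <- data.frame(n_train = n_samples(sp$train),
                  n_validate = n_samples(sp$validate),
                  n_candidates = length(kept),
                  n_selected = panel$n_selected,
                  training_r2 = panel$training_r2,
                  validation_r = val$pearson_r,
                  validation_r2 = val$r_squared,
                  generator_tag_r2 = sim$truth$realized_tag_r2)
write.table(format(out, digits = 3), "results/03_panel_validation.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
print(out, digits = 3)
cat(sprintf("\nHeld-out r2 = %.2f against a generator tagging ceiling of %.2f:\nthe sparse panel recovers most of the SNP-accessible CN variance.\n",
            val$r_squared, sim$truth$realized_tag_r2))
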