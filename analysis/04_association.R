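#!/usr/bin/env Rscript
# Step 4 — CN-conditioned association.
#
# Runs the CN-adjusted single-variant scan in each ancestry cohort,
# iterative conditional analysis at the locus, trans-ancestry fixed-effects
# meta-analysis with heterogeneity, the 1/CN functional-form check, the
# allelic-composition check, and Haseman-Elston heritability with and
# without conditioning on CN.

suppressPackageStartupMessages(library(kiv2cn))
dir.create("results", showWarnings = FALSE)

cohorts <- lapply(c(african = "african", european = "european"), function(anc) {
  sim <- simulate_cohort(sim_config(n_samples = 2100, n_variants = 300,
                                    ancestry = anc), seed = 1)
  sim$est <- estimate_kiv2_cn(sim$bundle$depth)
  sim
})

scans <- lapply(cohorts, function(sim)
  single_variant_scan(sim$bundle, adjust_cn = TRUE, cn = sim$est$kiv2_cn,
                      mode = "lmm"))
meta <- meta_fixed_effects(lapply(scans, function(s) s[!is.na(s$p), ]))
meta <- meta[order(meta$p), ]
write.table(format(head(meta, 25), digits = 3),
            "results/04_meta_top_hits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Top trans-ancestry meta-analysis hits (CN-adjusted):\n")
print(head(meta[, c("variant_id", "beta", "se", "p", "q", "het_p")], 5),
      digits = 3)

hits <- conditional_scan(cohorts$european$bundle, p_stop = 5e-8,
                         adjust_cn = TRUE, cn = cohorts$european$est$kiv2_cn)
write.table(format(hits, digits = 3), "results/04_conditional_hits.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("\nIterative conditioning in the European cohort: %d independent hit(s)\nat p < 5e-8 (the generator plants %d modest direct-effect SNPs, most of\nwhich sit below genome-wide significance at this sample size).\n",
            nrow(hits), length(cohorts$european$truth$causal_variants)))

eu <- cohorts$european
ff <- compare_cn_functional_form(eu$bundle$phenotypes, eu$est$kiv2_cn)
ac <- allelic_composition_test(eu$bundle$phenotypes, eu$truth$allele1,
                               eu$truth$allele2)
h2_raw <- heritability_he(eu$bundle, min_variants = 50)
h2_cn <- heritability_he(eu$bundle, adjust_cn = TRUE, cn = eu$est$kiv2_cn,
                         min_variants = 50)
checks <- data.frame(
  check = c("reciprocal_cn_added_term_p", "allelic_composition_p",
            "h2_unadjusted", "h2_cn_adjusted"),
  value = c(ff$p_reciprocal, ac$p_interaction, h2_raw$h2, h2_cn$h2),
  se = c(NA, NA, h2_raw$se, h2_cn$se))
write.table(format(checks, digits = 3), "results/04_model_checks.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
print(checks, digits = 3)
cat("\nThe linear-in-CN model is not improved by a 1/CN term, total CN (not\nits allelic split) carries the association, and conditioning on CN\nremoves the CN-tagged share of SNP heritability.\n")
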