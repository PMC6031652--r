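# Shared fixtures, built in code. Small cohorts are cached per session so
# multiple test files can reuse them without re-simulating.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# Mid-size cohort with defaults: CN tagging, sibling pairs, depth.
default_cohort <- function() cached("default_cohort", {
  simulate_cohort(sim_config(n_samples = 800, n_variants = 120), seed = 42)
})

# Tiny hand-buildable bundle: explicit dosages, no simulation.
hand_bundle <- function(G, pheno_extra = list()) {
  n <- nrow(G)
  ids <- sprintf("H%02d", seq_len(n))
  rownames(G) <- ids
  m <- ncol(G)
  if (is.null(colnames(G))) colnames(G) <- sprintf("v%02d", seq_len(m))
  variants <- data.frame(variant_id = colnames(G), chrom = "6",
                         pos = seq(159e6, by = 1000, length.out = m),
                         ref = "A", alt = "G", info_score = 1,
                         stringsAsFactors = FALSE)
  st <- allele_stats(G)
  variants$maf <- st$maf; variants$mac <- st$mac
  ph <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (nm in names(pheno_extra)) ph[[nm]] <- pheno_extra[[nm]]
  cohort_bundle(G, variants, ph)
}

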