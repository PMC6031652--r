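test_that("OLS scan equals the closed-form normal-equations solution", {
  # tiny hand-set fixture, checked against an independent solve()
  G <- cbind(v1 = c(0, 1, 2, 0, 1, 2), v2 = c(2, 2, 1, 0, 0, 1))
  age <- c(40, 50, 60, 45, 55, 65)
  y <- c(0.1, 0.5, 1.2, -0.3, 0.2, 0.9)
  b <- hand_bundle(G, pheno_extra = list(lp_a_norm = y, age = age))
  res <- single_variant_scan(b, adjust_cn = FALSE, covariates = "age",
                             maf_min = 0, mode = "ols")
  for (j in 1:2) {
    oracle <- brute_ols(y, G[, j], cbind(age))
    expect_equal(res$beta[j], oracle$beta, tolerance = 1e-8)
    expect_equal(res$se[j], oracle$se, tolerance = 1e-8)
    expect_equal(res$p[j], oracle$p, tolerance = 1e-8)
  }

  # random fixture: relative agreement to 1e-8 across many variants
  set.seed(4)
  n <- 80
  G2 <- sapply(1:10, function(i) rbinom(n, 2, runif(1, 0.1, 0.5)))
  colnames(G2) <- paste0("w", 1:10)
  age2 <- rnorm(n, 50, 8); sex2 <- rbinom(n, 1, 0.5)
  y2 <- rnorm(n)
  b2 <- hand_bundle(G2, pheno_extra = list(lp_a_norm = y2, age = age2,
                                           sex = sex2))
  res2 <- single_variant_scan(b2, adjust_cn = FALSE,
                              covariates = c("age", "sex"), maf_min = 0)
  for (j in 1:10) {
    oracle <- brute_ols(y2, G2[, j], cbind(age2, sex2))
    expect_equal(res2$beta[j], oracle$beta, tolerance = 1e-8)
    expect_equal(res2$se[j], oracle$se, tolerance = 1e-8)
  }
})

test_that("CN adjustment nulls out a purely CN-mediated SNP", {
  cfg <- sim_config(n_samples = 1500, n_variants = 80, tag_r2 = 0.6,
                    beta_cn = -0.1, n_causal_snps = 0, sibling_fraction = 0)
  sim <- simulate_cohort(cfg, seed = 17)
  # strongest CN-tagging SNP: affects the phenotype only through CN
  tags <- sim$truth$tag_variants
  cn <- sim$truth$diploid_cn
  r2tag <- sapply(tags, function(v) cor(sim$bundle$genotypes[, v], cn)^2)
  top <- names(which.max(r2tag))
  marg <- single_variant_scan(sim$bundle, adjust_cn = FALSE)
  adj <- single_variant_scan(sim$bundle, adjust_cn = TRUE, cn = cn)
  p_marg <- marg$p[marg$variant_id == top]
  p_adj <- adj$p[adj$variant_id == top]
  expect_lt(p_marg, 1e-4)
  expect_gt(p_adj, 0.01)
})

test_that("LMM mode matches OLS under identity kinship and runs with family structure", {
  set.seed(6)
  n <- 120
  G <- sapply(1:8, function(i) rbinom(n, 2, 0.3))
  colnames(G) <- paste0("v", 1:8)
  y <- 0.4 * G[, 2] + rnorm(n)
  b <- hand_bundle(G, pheno_extra = list(lp_a_norm = y, age = rnorm(n, 50, 5)))
  b$kinship <- diag(n)
  dimnames(b$kinship) <- list(rownames(G), rownames(G))
  ols <- single_variant_scan(b, adjust_cn = FALSE, covariates = "age",
                             maf_min = 0, mode = "ols")
  lmm <- single_variant_scan(b, adjust_cn = FALSE, covariates = "age",
                             maf_min = 0, mode = "lmm")
  expect_equal(lmm$beta, ols$beta, tolerance = 1e-4)
  expect_equal(lmm$se, ols$se, tolerance = 0.05)

  sim <- default_cohort()
  lm2 <- single_variant_scan(sim$bundle, adjust_cn = TRUE, mode = "lmm",
                             maf_min = 0.01)
  expect_true(all(is.finite(lm2$p[!is.na(lm2$p)])))
  expect_true(all(lm2$p[!is.na(lm2$p)] > 0 & lm2$p[!is.na(lm2$p)] <= 1))
})

test_that("conditional scan isolates independent signals", {
  set.seed(30)
  n <- 900
  g_a <- rbinom(n, 2, 0.4)          # causal
  g_b <- g_a                        # perfect proxy
  g_b[sample(n, 20)] <- rbinom(20, 2, 0.4)  # near-perfect proxy
  g_c <- rbinom(n, 2, 0.3)          # unlinked causal
  g_d <- rbinom(n, 2, 0.3)          # null
  G <- cbind(a = g_a, b = g_b, c = g_c, d = g_d)
  y <- 0.5 * g_a + 0.4 * g_c + rnorm(n)
  b <- hand_bundle(G, pheno_extra = list(lp_a_norm = y, age = rnorm(n, 50, 5)))
  hits <- conditional_scan(b, p_stop = 5e-8, adjust_cn = FALSE,
                           covariates = "age")
  expect_equal(nrow(hits), 2)
  expect_setequal(hits$variant_id, c("a", "c"))
  expect_equal(hits$variant_id[1], "a")  # larger effect first

  # nothing significant -> empty hit list
  b_null <- hand_bundle(G, pheno_extra = list(lp_a_norm = rnorm(n),
                                              age = rnorm(n, 50, 5)))
  hits0 <- conditional_scan(b_null, p_stop = 5e-8, adjust_cn = FALSE,
                            covariates = "age")
  expect_equal(nrow(hits0), 0)
})

test_that("fixed-effects meta-analysis matches closed forms and a brute-force oracle", {
  t1 <- data.frame(variant_id = "v1", beta = 0.5, se = 0.1, n = 100)
  t2 <- data.frame(variant_id = "v1", beta = 0.5, se = 0.1, n = 150)
  m <- meta_fixed_effects(list(a = t1, b = t2))
  expect_equal(m$beta, 0.5)
  expect_equal(m$se, 0.1 / sqrt(2))
  expect_equal(m$q, 0)
  expect_equal(m$het_p, 1)

  # symmetric opposite effects pool to zero
  t2b <- transform(t2, beta = -0.5)
  m2 <- meta_fixed_effects(list(a = t1, b = t2b))
  expect_equal(m2$beta, 0)
  expect_gt(m2$q, 0)

  # 3-cohort brute force: explicit weighted arithmetic
  set.seed(8)
  betas <- c(0.3, 0.45, 0.2); ses <- c(0.12, 0.2, 0.08)
  tabs <- lapply(1:3, function(i)
    data.frame(variant_id = "x", beta = betas[i], se = ses[i], n = 50))
  names(tabs) <- c("c1", "c2", "c3")
  m3 <- meta_fixed_effects(tabs)
  w <- 1 / ses^2
  expect_equal(m3$beta, sum(w * betas) / sum(w), tolerance = 1e-12)
  expect_equal(m3$se, sqrt(1 / sum(w)), tolerance = 1e-12)
  expect_equal(m3$q, sum(w * (betas - m3$beta)^2), tolerance = 1e-12)
  expect_equal(m3$het_p, pchisq(m3$q, 2, lower.tail = FALSE), tolerance = 1e-12)
  # pooled estimate bounded by cohort extremes; pooled variance smaller
  expect_gte(m3$beta, min(betas)); expect_lte(m3$beta, max(betas))
  expect_lt(m3$se, min(ses))
  # single-cohort variants flagged, non-positive SE rejected
  t_extra <- data.frame(variant_id = c("x", "solo"), beta = c(0.1, 1),
                        se = c(0.1, 0.2), n = 10)
  m4 <- meta_fixed_effects(list(c1 = tabs[[1]], c2 = t_extra))
  expect_equal(m4$flag[m4$variant_id == "solo"], "single_cohort")
  t_bad <- data.frame(variant_id = "x", beta = 1, se = 0, n = 5)
  expect_warning(meta_fixed_effects(list(a = t1, b = t_bad)), "non-positive")
})

test_that("reciprocal-CN term is detected only when the generator is reciprocal", {
  set.seed(40)
  n <- 2000
  cn <- rnorm(n, 43, 6)
  ph <- data.frame(sample_id = as.character(1:n), age = rnorm(n, 50, 8),
                   sex = rbinom(n, 1, 0.5))
  # linear generator: added reciprocal term should be null
  ps <- vapply(1:30, function(s) {
    set.seed(s)
    phx <- ph
    phx$lp_a_norm <- -0.07 * cn + rnorm(n)
    compare_cn_functional_form(phx, cn)$p_reciprocal
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  # reciprocal generator: power
  ph$lp_a_norm <- 200 / cn + rnorm(n, 0, 0.2)
  expect_lt(compare_cn_functional_form(ph, cn)$p_reciprocal, 1e-4)
  # CN <= 0 samples excluded with a message
  cn2 <- cn; cn2[1:5] <- -1
  expect_message(out <- compare_cn_functional_form(ph, cn2), "excluding 5")
  expect_equal(out$n_excluded, 5)
  expect_error(compare_cn_functional_form(ph, rep(40, n)), "constant")
})

test_that("allelic composition test is null when only total CN matters", {
  set.seed(41)
  n <- 1500
  a1 <- rnorm(n, 20, 4); a2 <- rnorm(n, 20, 4)
  ph <- data.frame(sample_id = as.character(1:n), age = rnorm(n, 50, 8),
                   sex = rbinom(n, 1, 0.5))
  ps <- vapply(1:25, function(s) {
    set.seed(200 + s)
    phx <- ph
    phx$lp_a_norm <- -0.07 * (a1 + a2) + rnorm(n)
    allelic_composition_test(phx, a1, a2)$p_interaction
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)

  # composition-specific CN slope: detected
  equal <- abs(a1 - a2) < 2
  ph$lp_a_norm <- -0.07 * (a1 + a2) * (1 + 0.5 * equal) + rnorm(n, 0, 0.3)
  expect_lt(allelic_composition_test(ph, a1, a2)$p_interaction, 0.01)
  # empty group errors cleanly
  expect_error(allelic_composition_test(ph, a1, a2, tolerance = 0),
               "group sizes")
})

test_that("Haseman-Elston recovers planted heritability and the null", {
  # genotypes without LD so the pre-GRM pruning step keeps the causal set
  set.seed(50)
  G <- sapply(1:250, function(i) rbinom(700, 2, runif(1, 0.1, 0.5)))
  colnames(G) <- paste0("v", 1:250)
  rownames(G) <- paste0("s", 1:700)
  ids <- rownames(G)
  v <- data.frame(variant_id = colnames(G), chrom = "6",
                  pos = seq_len(ncol(G)), maf = allele_stats(G)$maf)
  mk <- function(y) cohort_bundle(G, v, data.frame(sample_id = ids,
                                                   lp_a_norm = y))
  # null: h2 estimate near zero
  set.seed(51)
  h0 <- heritability_he(mk(rnorm(length(ids))), min_variants = 50)
  expect_lt(h0$h2, 0.1)
  # h2 = 0.75: recovered within 0.1 (mean over seeds)
  h_est <- vapply(1:6, function(s) {
    y <- simulate_polygenic_phenotype(G, 0.75, seed = s)
    heritability_he(mk(y), min_variants = 50)$h2
  }, numeric(1))
  expect_lt(abs(mean(h_est) - 0.75), 0.1)
  expect_true(all(h_est >= 0 & h_est <= 1))
  expect_gt(h0$se, 0)
  expect_error(heritability_he(mk(rnorm(length(ids))), min_variants = 1e5),
               "variants")
})

test_that("conditioning on CN removes the CN-mediated share of heritability", {
  cfg <- sim_config(n_samples = 700, n_variants = 150, tag_r2 = 0.6,
                    beta_cn = -0.15, n_causal_snps = 0, resid_sd = 0.6,
                    sibling_fraction = 0)
  sim <- simulate_cohort(cfg, seed = 52)
  h_raw <- heritability_he(sim$bundle, min_variants = 50)
  h_adj <- heritability_he(sim$bundle, adjust_cn = TRUE,
                           cn = sim$truth$diploid_cn, min_variants = 50)
  expect_gt(h_raw$h2, h_adj$h2)
  expect_lt(h_adj$h2, 0.15)
})
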