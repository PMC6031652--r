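test_that("train/validate split honors the published 2:1 protocol and keeps siblings together", {
  sim <- default_cohort()
  sp <- split_train_validate(sim$bundle, 2/3, seed = 5, pairs = sim$truth$pairs)
  n <- n_samples(sim$bundle)
  expect_equal(n_samples(sp$train) + n_samples(sp$validate), n)
  expect_lt(abs(n_samples(sp$train) - round(2/3 * n)), 2)
  expect_length(intersect(rownames(sp$train$genotypes),
                          rownames(sp$validate$genotypes)), 0)
  # no sibling pair straddles the split
  ids <- rownames(sim$bundle$genotypes)
  for (r in seq_len(nrow(sim$truth$pairs))) {
    a <- ids[sim$truth$pairs[r, 1]]; b <- ids[sim$truth$pairs[r, 2]]
    expect_equal(a %in% rownames(sp$train$genotypes),
                 b %in% rownames(sp$train$genotypes))
  }
  # same seed reproduces the split exactly
  sp2 <- split_train_validate(sim$bundle, 2/3, seed = 5, pairs = sim$truth$pairs)
  expect_identical(rownames(sp$train$genotypes), rownames(sp2$train$genotypes))
  expect_error(split_train_validate(sim$bundle, 1.2), "fraction")

  # the published cohort size splits 1477 / 738
  sim_big <- simulate_cohort(sim_config(n_samples = 2215, n_variants = 12,
                                        sibling_fraction = 0), seed = 1)
  spb <- split_train_validate(sim_big$bundle, 2/3, seed = 1)
  expect_equal(n_samples(spb$train), 1477)
  expect_equal(n_samples(spb$validate), 738)
})

test_that("candidate filtering applies window, MAF and imputation-quality bounds", {
  v <- data.frame(variant_id = paste0("v", 1:6), chrom = "6",
                  pos = c(1e6, 159e6, 159e6, 159e6, 159e6, 159e6),
                  maf = c(0.3, 0.0009, 0.0011, 0.3, 0.3, 0.3),
                  info_score = c(1, 1, 1, 0.79, 0.81, 1))
  out <- filter_panel_variants(v, window = c(158e6, 163e6))
  expect_setequal(out$variant_id, c("v3", "v5", "v6"))  # v1 window, v2 maf, v4 info
  expect_error(filter_panel_variants(v, window = c(1, 2)), "no variants pass")
})

test_that("LD pruning matches a brute-force oracle and handles edge cases", {
  sim <- default_cohort()
  G <- sim$bundle$genotypes[, 1:20]
  kept <- ld_prune(G, sim$bundle$variants[1:20, ], window_variants = 8,
                   step = 2, r2_max = 0.25)
  expect_identical(kept, brute_prune(G, window = 8, step = 2, r2_max = 0.25))
  # deterministic and order-stable
  expect_identical(kept, ld_prune(G, sim$bundle$variants[1:20, ],
                                  window_variants = 8, step = 2))
  expect_identical(kept, intersect(colnames(G), kept))

  # duplicates collapse to one; independent variants all survive
  set.seed(3)
  g1 <- rbinom(200, 2, 0.3)
  G2 <- cbind(a = g1, b = g1, c = rbinom(200, 2, 0.3), d = rbinom(200, 2, 0.4))
  v2 <- data.frame(variant_id = colnames(G2), maf = c(0.3, 0.3, 0.3, 0.4))
  expect_identical(ld_prune(G2, v2), c("a", "c", "d"))
  Gi <- sapply(1:5, function(i) rbinom(500, 2, 0.3))
  colnames(Gi) <- paste0("i", 1:5)
  expect_length(ld_prune(Gi, data.frame(variant_id = colnames(Gi),
                                        maf = rep(0.3, 5))), 5)
  # maf tie-break drops the rarer member instead of the later one
  v2b <- data.frame(variant_id = colnames(G2), maf = c(0.1, 0.3, 0.3, 0.4))
  expect_identical(ld_prune(G2, v2b, tie_break = "maf"), c("b", "c", "d"))
})

test_that("LASSO selects a planted predictor and controls false selection on noise", {
  set.seed(10)
  n <- 500
  X <- sapply(1:25, function(i) rbinom(n, 2, 0.3))
  colnames(X) <- paste0("v", 1:25)
  rownames(X) <- paste0("s", 1:n)
  y <- 3 * X[, "v7"] + rnorm(n, 0, 1)
  panel <- fit_lasso_panel(X, y, seed = 1)
  expect_true("v7" %in% panel$variants)
  expect_gt(panel$coefficients["v7"], 1)
  expect_gt(panel$training_r2, 0.5)

  # pure-noise response: selection stays near-empty across seeds
  set.seed(11)
  Xn <- sapply(1:25, function(i) rbinom(1000, 2, 0.3))
  colnames(Xn) <- paste0("v", 1:25)
  rownames(Xn) <- paste0("s", 1:1000)
  n_sel <- vapply(1:20, function(s) {
    set.seed(100 + s)
    fit_lasso_panel(Xn, rnorm(1000), seed = s)$n_selected
  }, numeric(1))
  expect_lte(mean(n_sel), 2)
  expect_lte(median(n_sel), 2)
  expect_error(fit_lasso_panel(X[1:5, ], y[1:5], k_folds = 10), "exceed")
})

test_that("panel application is exact linear scoring with guards for absent variants", {
  panel <- structure(list(
    variants = c("v1", "v2", "v3"),
    coefficients = c(v1 = 0.5, v2 = -1, v3 = 2),
    intercept = 40, lambda = 0.1, n_selected = 3L,
    training_r2 = NA_real_, candidates = c("v1", "v2", "v3")),
    class = "cn_panel")
  G <- rbind(s1 = c(v1 = 2, v2 = 0, v3 = 1),
             s2 = c(v1 = 0, v2 = 2, v3 = 0))
  expect_equal(unname(apply_panel(panel, G)),
               c(40 + 1 + 2, 40 - 2))  # hand arithmetic
  # empty panel -> constant intercept
  empty <- structure(list(variants = character(0), coefficients = numeric(0),
                          intercept = 41.2, n_selected = 0L),
                     class = "cn_panel")
  expect_equal(unname(apply_panel(empty, G)), c(41.2, 41.2))
  # >20% of panel variants absent -> error
  expect_error(apply_panel(panel, G[, c("v1", "v2"), drop = FALSE]), "absent")
  # missing dosages are mean-substituted with a message
  G2 <- G; G2["s1", "v1"] <- NA
  expect_message(apply_panel(panel, G2), "mean-substituted")
})

test_that("panel serialization round-trips through JSON", {
  sim <- default_cohort()
  est <- estimate_kiv2_cn(sim$bundle$depth)
  panel <- fit_lasso_panel(sim$bundle$genotypes, est$kiv2_cn, seed = 2)
  p <- withr::local_tempfile(fileext = ".json")
  write_panel(panel, p)
  back <- read_panel(p)
  expect_equal(back$coefficients, panel$coefficients, tolerance = 1e-12)
  expect_equal(apply_panel(back, sim$bundle$genotypes),
               apply_panel(panel, sim$bundle$genotypes), tolerance = 1e-10)
})

test_that("random-forest importance ranks a dominant predictor first and normalizes", {
  set.seed(12)
  n <- 600
  X <- sapply(1:8, function(i) rbinom(n, 2, 0.4))
  colnames(X) <- paste0("v", 1:8)
  rownames(X) <- paste0("s", 1:n)
  firsts <- vapply(1:5, function(s) {
    set.seed(s)
    y <- 2 * X[, "v3"] + 0.3 * X[, "v5"] + rnorm(n, 0, 1)
    panel <- fit_lasso_panel(X, y, seed = s)
    imp <- rank_importance(panel, X, y, n_trees = 300, seed = s)
    expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
    imp$variant_id[1]
  }, character(1))
  expect_gte(sum(firsts == "v3"), 4)
  # single-variant panel: importance trivially 1
  single <- structure(list(variants = "v3", coefficients = c(v3 = 1),
                           intercept = 0, n_selected = 1L),
                      class = "cn_panel")
  expect_equal(rank_importance(single, X, rnorm(n))$importance, 1)
})

test_that("validation r2 tracks the generator tagging ceiling and respects no-leakage", {
  # perfect tagging: CN deterministically linear in panel SNPs -> r = 1
  set.seed(20)
  n <- 400
  X <- sapply(1:10, function(i) rbinom(n, 2, 0.4))
  colnames(X) <- paste0("v", 1:10); rownames(X) <- paste0("s", 1:n)
  cn <- 30 + X %*% rnorm(10)
  panel <- fit_lasso_panel(X[1:300, ], cn[1:300], seed = 1)
  v <- validate_panel(panel, X[301:400, ], cn[301:400])
  expect_gt(v$pearson_r, 0.99)

  # zero tagging: panel carries no information
  cfg0 <- sim_config(n_samples = 700, n_variants = 60, tag_r2 = 0,
                     sibling_fraction = 0)
  sim0 <- simulate_cohort(cfg0, seed = 6)
  est0 <- estimate_kiv2_cn(sim0$bundle$depth)
  sp0 <- split_train_validate(sim0$bundle, 2/3, seed = 1)
  pan0 <- fit_lasso_panel(sp0$train$genotypes,
                          est0$kiv2_cn[match(rownames(sp0$train$genotypes),
                                             est0$sample_id)], seed = 1)
  v0 <- validate_panel(pan0, sp0$validate$genotypes,
                       est0$kiv2_cn[match(rownames(sp0$validate$genotypes),
                                          est0$sample_id)])
  if (!is.na(v0$r_squared)) expect_lt(v0$r_squared, 0.05)

  # information ceiling and no-leakage on the default cohort
  sim <- default_cohort()
  est <- estimate_kiv2_cn(sim$bundle$depth)
  sim$bundle$phenotypes$kiv2_cn_est <- est$kiv2_cn
  sp <- split_train_validate(sim$bundle, 2/3, seed = 2, pairs = sim$truth$pairs)
  pan <- fit_lasso_panel(sp$train$genotypes,
                         sp$train$phenotypes$kiv2_cn_est, seed = 2)
  v1 <- validate_panel(pan, sp$validate$genotypes,
                       sp$validate$phenotypes$kiv2_cn_est)
  expect_lt(v1$r_squared, sim$truth$realized_tag_r2 + 0.08)
  # transforming validation phenotypes before training changes nothing:
  # training never touches them
  sp_mut <- sp
  sp_mut$validate$phenotypes$lp_a_norm <- sp_mut$validate$phenotypes$lp_a_norm * 100
  pan2 <- fit_lasso_panel(sp_mut$train$genotypes,
                          sp_mut$train$phenotypes$kiv2_cn_est, seed = 2)
  expect_identical(pan$coefficients, pan2$coefficients)
})
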