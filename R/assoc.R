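## CN-conditioned single-variant association, iterative conditional
## analysis, fixed-effects meta-analysis with heterogeneity, functional-form
## and allelic-composition checks, and Haseman-Elston heritability.

# Build the covariate design matrix (with intercept) from a phenotype table.
covariate_matrix <- function(phenotypes, covariates) {
  miss <- setdiff(covariates, names(phenotypes))
  if (length(miss)) stop("missing covariate column(s): ",
                         paste(miss, collapse = ", "))
  C <- cbind(intercept = 1)
  if (length(covariates))
    C <- cbind(1, as.matrix(phenotypes[, covariates, drop = FALSE]))
  colnames(C)[1] <- "intercept"
  storage.mode(C) <- "double"
  C
}

# Exact per-variant OLS via Frisch-Waugh residualization: returns beta, se,
# p for each column of G regressed on y given covariates C.
ols_scan <- function(y, G, C) {
  qrC <- qr(C)
  y_r <- stats::resid(stats::lm.fit(C, y))
  n <- length(y); p <- qrC$rank
  df <- n - p - 1L
  beta <- se <- pval <- rep(NA_real_, ncol(G))
  for (j in seq_len(ncol(G))) {
    g <- G[, j]
    if (anyNA(g)) {
      mu <- mean(g, na.rm = TRUE)
      g[is.na(g)] <- mu
    }
    g_r <- stats::resid(stats::lm.fit(C, g))
    gg <- sum(g_r^2)
    if (gg < 1e-10) next  # collinear with covariates
    b <- sum(g_r * y_r) / gg
    rss <- sum(y_r^2) - b^2 * gg
    s2 <- rss / df
    beta[j] <- b
    se[j] <- sqrt(s2 / gg)
    pval[j] <- 2 * stats::pt(abs(b) / se[j], df, lower.tail = FALSE)
  }
  list(beta = beta, se = se, p = pval, n = n)
}

# Profile the kinship variance ratio under the null model, return rotated
# quantities for per-variant generalized least squares.
lmm_null <- function(y, C, kinship) {
  eig <- eigen(kinship, symmetric = TRUE)
  U <- eig$vectors; lam <- pmax(eig$values, 0)
  ys <- crossprod(U, y)
  Cs <- crossprod(U, C)
  n <- length(y)
  negll <- function(log_delta) {
    delta <- exp(log_delta)
    w <- 1 / (delta * lam + 1)
    fit <- stats::lm.wfit(Cs, ys, w)
    s2 <- sum(w * fit$residuals^2) / n
    0.5 * (n * log(s2) + sum(log(delta * lam + 1)))
  }
  opt <- stats::optimize(negll, c(-10, 10))
  delta <- exp(opt$minimum)
  list(U = U, lambda = lam, delta = delta, w = 1 / (delta * lam + 1),
       ys = ys, Cs = Cs)
}

#' Single-variant association scan
#'
#' Per variant, the effect of allele dosage on the (rank-normalized)
#' phenotype adjusted for covariates and, when `adjust_cn`, for diploid
#' KIV2-CN. `mode = "ols"` is exact fixed-effects least squares (use PCs in
#' `covariates` for structure); `mode = "lmm"` rotates by the kinship
#' eigendecomposition with one variance ratio profiled under the null, then
#' runs per-variant weighted least squares. P-values are two-sided Wald.
#'
#' Missing dosages are mean-imputed inside the fit; variants below the MAF
#' filter or collinear with the covariates are returned with NA statistics.
#'
#' @param bundle A `cohort_bundle` (kinship required for `mode = "lmm"`).
#' @param phenotype Column name of the rank-normalized phenotype.
#' @param adjust_cn Include `cn` as a covariate.
#' @param cn Numeric vector of diploid CN (defaults to the bundle's
#'   `kiv2_cn_true` column if present; pass the estimate in real use).
#' @param covariates Phenotype-table columns used as covariates.
#' @param maf_min Exclusive MAF floor (default 0.001).
#' @param mode `"ols"` or `"lmm"`.
#' @param extra_covariates Optional matrix of additional per-sample
#'   covariates (e.g. conditioning dosages).
#' @return A result table: `variant_id`, `chrom`, `pos`, `maf`, `beta`,
#'   `se`, `p`, `n`, `analysis`.
#' @export
single_variant_scan <- function(bundle, phenotype = "lp_a_norm",
                                adjust_cn = TRUE, cn = NULL,
                                covariates = c("age", "sex"),
                                maf_min = 0.001, mode = c("ols", "lmm"),
                                extra_covariates = NULL) {
  mode <- match.arg(mode)
  y <- bundle$phenotypes[[phenotype]]
  if (is.null(y)) stop("phenotype column not found: ", phenotype)
  C <- covariate_matrix(bundle$phenotypes, covariates)
  if (adjust_cn) {
    if (is.null(cn)) cn <- bundle$phenotypes$kiv2_cn_true
    if (is.null(cn)) stop("adjust_cn = TRUE but no CN supplied")
    C <- cbind(C, cn = cn)
  }
  if (!is.null(extra_covariates)) C <- cbind(C, extra_covariates)
  cc <- stats::complete.cases(C) & !is.na(y)
  C <- C[cc, , drop = FALSE]; y <- y[cc]
  G <- bundle$genotypes[cc, , drop = FALSE]
  st <- allele_stats(G)
  pass <- !is.na(st$maf) & st$maf > maf_min
  res <- data.frame(variant_id = bundle$variants$variant_id,
                    chrom = bundle$variants$chrom, pos = bundle$variants$pos,
                    maf = st$maf, beta = NA_real_, se = NA_real_,
                    p = NA_real_, n = length(y),
                    analysis = if (adjust_cn) "cn_adjusted" else "marginal",
                    stringsAsFactors = FALSE)
  if (!any(pass)) return(res)
  Gp <- G[, pass, drop = FALSE]
  if (mode == "ols") {
    sc <- ols_scan(y, Gp, C)
  } else {
    if (is.null(bundle$kinship)) stop("lmm mode needs a kinship matrix")
    K <- bundle$kinship[which(cc), which(cc), drop = FALSE]
    nl <- lmm_null(y, C, K)
    m <- ncol(Gp)
    beta <- se <- pval <- rep(NA_real_, m)
    for (j in seq_len(m)) {
      g <- Gp[, j]
      if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
      gs <- crossprod(nl$U, g)
      X <- cbind(nl$Cs, gs)
      fit <- stats::lm.wfit(X, nl$ys, nl$w)
      if (fit$rank < ncol(X)) next
      dfres <- length(y) - ncol(X)
      s2 <- sum(nl$w * fit$residuals^2) / dfres
      XtWX_inv <- chol2inv(chol(crossprod(X * sqrt(nl$w))))
      b <- fit$coefficients[ncol(X)]
      s <- sqrt(s2 * XtWX_inv[ncol(X), ncol(X)])
      beta[j] <- b; se[j] <- s
      pval[j] <- 2 * stats::pt(abs(b / s), dfres, lower.tail = FALSE)
    }
    sc <- list(beta = beta, se = se, p = pval, n = length(y))
  }
  res$beta[pass] <- sc$beta; res$se[pass] <- sc$se; res$p[pass] <- sc$p
  res
}

#' Iterative conditional association at a locus
#'
#' Repeatedly takes the most significant remaining variant (ties broken by
#' lower position), adds its dosage as a covariate, and rescans, until the
#' minimum p-value exceeds `p_stop`. Returns the ordered independent-hit
#' list.
#'
#' @param bundle A `cohort_bundle`.
#' @param p_stop Stopping threshold (default 5e-8, genome-wide).
#' @param max_iter Safety bound on rounds (default 50; exceeding errors).
#' @param ... Passed to [single_variant_scan()].
#' @return Data frame of independent hits in selection order (possibly
#'   0-row), columns as the scan plus `round`.
#' @export
conditional_scan <- function(bundle, p_stop = 5e-8, max_iter = 50, ...) {
  hits <- NULL
  extra <- NULL
  for (it in seq_len(max_iter + 1)) {
    if (it > max_iter) stop("conditional scan failed to converge in ",
                            max_iter, " iterations")
    res <- single_variant_scan(bundle, extra_covariates = extra, ...)
    res <- res[!is.na(res$p) & !(res$variant_id %in% hits$variant_id), ]
    if (nrow(res) == 0 || min(res$p) > p_stop) break
    top <- res[order(res$p, res$pos), ][1, ]
    top$round <- it
    hits <- rbind(hits, top)
    g <- bundle$genotypes[, top$variant_id]
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    extra <- cbind(extra, g)
    colnames(extra)[ncol(extra)] <- top$variant_id
  }
  if (is.null(hits))
    hits <- data.frame(variant_id = character(0), chrom = character(0),
                       pos = integer(0), maf = numeric(0), beta = numeric(0),
                       se = numeric(0), p = numeric(0), n = integer(0),
                       analysis = character(0), round = integer(0))
  hits
}

#' Inverse-variance fixed-effects meta-analysis with heterogeneity
#'
#' Pools per-cohort effects with weights `1/se^2`; reports Cochran's Q and
#' its chi-square heterogeneity p (k - 1 df). Variants present in fewer than
#' two cohorts are passed through with `flag = "single_cohort"` (their
#' pooled values equal the single cohort's). Rows with non-positive SE are
#' rejected.
#'
#' @param tables Named list of per-cohort result tables (`variant_id`,
#'   `beta`, `se`, `n`).
#' @return Meta table: `variant_id`, `n_cohorts`, `beta`, `se`, `p`, `q`,
#'   `het_p`, `n`, `flag`.
#' @export
meta_fixed_effects <- function(tables) {
  stopifnot(length(tables) >= 2)
  all_rows <- do.call(rbind, lapply(names(tables), function(nm) {
    t <- tables[[nm]][, c("variant_id", "beta", "se", "n")]
    t$cohort <- nm
    t
  }))
  all_rows <- all_rows[!is.na(all_rows$beta), ]
  bad <- !is.na(all_rows$se) & all_rows$se <= 0
  if (any(bad)) {
    warning(sprintf("rejecting %d row(s) with non-positive SE", sum(bad)))
    all_rows <- all_rows[!bad, ]
  }
  out <- lapply(split(all_rows, all_rows$variant_id), function(d) {
    k <- nrow(d)
    w <- 1 / d$se^2
    b <- sum(w * d$beta) / sum(w)
    se <- sqrt(1 / sum(w))
    q <- sum(w * (d$beta - b)^2)
    het_p <- if (k >= 2) stats::pchisq(q, k - 1, lower.tail = FALSE) else NA_real_
    data.frame(variant_id = d$variant_id[1], n_cohorts = k, beta = b,
               se = se, p = 2 * stats::pnorm(abs(b / se), lower.tail = FALSE),
               q = q, het_p = het_p, n = sum(d$n),
               flag = if (k < 2) "single_cohort" else "",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Test the functional form of the CN-phenotype relationship
#'
#' Nested-model comparison of `phenotype ~ CN + covariates` against the same
#' model plus `1/CN`; returns the partial-F p-value of the reciprocal term.
#' Samples with CN <= 0 are excluded (count reported) since the reciprocal
#' is undefined there.
#'
#' @param phenotypes Phenotype table.
#' @param cn Diploid CN vector aligned to the table.
#' @param phenotype Response column (rank-normalized).
#' @param covariates Covariate columns.
#' @return List `p_reciprocal`, `n_used`, `n_excluded`.
#' @export
compare_cn_functional_form <- function(phenotypes, cn,
                                       phenotype = "lp_a_norm",
                                       covariates = c("age", "sex")) {
  if (stats::sd(cn, na.rm = TRUE) == 0) stop("CN is constant")
  ok <- !is.na(cn) & cn > 0 & !is.na(phenotypes[[phenotype]])
  n_exc <- sum(!ok)
  if (n_exc) message(sprintf("excluding %d sample(s) with CN <= 0 or missing", n_exc))
  y <- phenotypes[[phenotype]][ok]
  C <- covariate_matrix(phenotypes[ok, , drop = FALSE], covariates)
  d <- data.frame(y = y, cn = cn[ok], C[, -1, drop = FALSE])
  f0 <- stats::lm(y ~ ., data = d)
  d$inv_cn <- 1 / d$cn
  f1 <- stats::lm(y ~ ., data = d)
  p <- stats::anova(f0, f1)[2, "Pr(>F)"]
  list(p_reciprocal = p, n_used = sum(ok), n_excluded = n_exc)
}

#' Test whether allelic composition modifies the CN-phenotype slope
#'
#' Splits samples into an equal-allele group (|allele1 - allele2| below
#' `tolerance`) versus the rest and tests a group-by-CN interaction; a null
#' interaction means only the diploid sum matters, not how it is split
#' across haplotypes.
#'
#' @param phenotypes Phenotype table.
#' @param allele1,allele2 Allelic CN vectors (simulation truth, or supply a
#'   homozygosity indicator via `group`).
#' @param group Optional logical vector overriding the allele comparison.
#' @param tolerance Allele-difference threshold defining "equal".
#' @param phenotype,covariates As in [compare_cn_functional_form()].
#' @param min_group Minimum samples per group (default 10).
#' @return List `p_interaction`, `n_equal`, `n_other`.
#' @export
allelic_composition_test <- function(phenotypes, allele1, allele2,
                                     group = NULL, tolerance = 2,
                                     phenotype = "lp_a_norm",
                                     covariates = c("age", "sex"),
                                     min_group = 10) {
  if (is.null(group)) group <- abs(allele1 - allele2) < tolerance
  if (sum(group) < min_group || sum(!group) < min_group)
    stop(sprintf("group sizes %d / %d below minimum %d",
                 sum(group), sum(!group), min_group))
  cn <- allele1 + allele2
  y <- phenotypes[[phenotype]]
  C <- covariate_matrix(phenotypes, covariates)
  d <- data.frame(y = y, cn = cn, grp = as.numeric(group),
                  C[, -1, drop = FALSE])
  fit <- stats::lm(y ~ . + cn:grp, data = d)
  sm <- summary(fit)$coefficients
  list(p_interaction = sm["cn:grp", "Pr(>|t|)"],
       n_equal = sum(group), n_other = sum(!group))
}

#' Genomic relationship matrix from standardized dosages
#'
#' @param genotypes Dosage matrix.
#' @param exclude_window Optional `c(chrom, start, end)`-style window (list
#'   with `chrom`, `start`, `end`) whose variants are excluded; pass the
#'   repeat locus to build a locus-free GRM.
#' @param variants Variant table (needed when excluding a window).
#' @return Samples x samples GRM (`Z Z' / m`).
#' @export
make_grm <- function(genotypes, exclude_window = NULL, variants = NULL) {
  if (!is.null(exclude_window)) {
    stopifnot(!is.null(variants))
    drop <- variants$chrom == exclude_window$chrom &
      variants$pos >= exclude_window$start &
      variants$pos <= exclude_window$end
    genotypes <- genotypes[, !drop, drop = FALSE]
  }
  Z <- standardize_dosages(genotypes)
  tcrossprod(Z) / ncol(Z)
}

#' Haseman-Elston heritability with jackknife SE
#'
#' Regresses centered-phenotype cross-products of all sample pairs on their
#' off-diagonal GRM entries; the slope estimates narrow-sense h2 (clipped to
#' \[0, 1\]). SE comes from a delete-one-block jackknife over samples.
#' Variants are filtered (MAF, missingness) and LD-pruned (50/5/0.9 window
#' semantics) before the GRM; optionally the phenotype is residualized on CN
#' first.
#'
#' @param bundle A `cohort_bundle`.
#' @param phenotype Response column (rank-normalized).
#' @param maf_min,miss_max Variant filters (defaults 0.001 and 0.01).
#' @param prune_r2 LD-prune ceiling (default 0.9).
#' @param adjust_cn Residualize the phenotype on CN before estimation.
#' @param cn CN vector when `adjust_cn`.
#' @param min_variants Floor on post-filter variants (default 100).
#' @param n_blocks Jackknife blocks (default 20).
#' @param grm Optional precomputed GRM (skips filtering/pruning).
#' @return List `h2`, `se`, `n_variants`, `n_samples`.
#' @export
heritability_he <- function(bundle, phenotype = "lp_a_norm",
                            maf_min = 0.001, miss_max = 0.01,
                            prune_r2 = 0.9, adjust_cn = FALSE, cn = NULL,
                            min_variants = 100, n_blocks = 20, grm = NULL) {
  y <- bundle$phenotypes[[phenotype]]
  if (adjust_cn) {
    if (is.null(cn)) cn <- bundle$phenotypes$kiv2_cn_true
    y <- stats::resid(stats::lm(y ~ cn))
  }
  y <- (y - mean(y)) / stats::sd(y)
  if (is.null(grm)) {
    st <- allele_stats(bundle$genotypes)
    miss <- 1 - st$n_called / nrow(bundle$genotypes)
    keep <- !is.na(st$maf) & st$maf > maf_min & miss < miss_max
    G <- bundle$genotypes[, keep, drop = FALSE]
    kept <- ld_prune(G, bundle$variants[keep, , drop = FALSE],
                     window_variants = 50, step = 5, r2_max = prune_r2)
    if (length(kept) < min_variants)
      stop(sprintf("only %d variants after filtering (< %d)",
                   length(kept), min_variants))
    grm <- make_grm(G[, kept, drop = FALSE])
    n_var <- length(kept)
  } else n_var <- NA_integer_
  n <- length(y)
  ut <- upper.tri(grm)
  a <- grm[ut]
  pr <- tcrossprod(y)[ut]
  slope <- function(a, p) {
    ac <- a - mean(a)
    sum(ac * p) / sum(ac^2)
  }
  h2 <- min(max(slope(a, pr), 0), 1)
  # block jackknife over samples
  blocks <- split(seq_len(n), rep_len(seq_len(n_blocks), n))
  row_i <- row(grm)[ut]; col_i <- col(grm)[ut]
  est <- vapply(blocks, function(b) {
    keep <- !(row_i %in% b) & !(col_i %in% b)
    min(max(slope(a[keep], pr[keep]), 0), 1)
  }, numeric(1))
  B <- length(blocks)
  se <- sqrt((B - 1) / B * sum((est - mean(est))^2))
  list(h2 = h2, se = se, n_variants = n_var, n_samples = n)
}
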