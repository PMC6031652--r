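## Variant-by-KIV2-CN interaction scan, LD-clump multiplicity control,
## meta-analysis of interaction terms, and sensitivity checks on top hits.

#' Variant-by-CN interaction scan
#'
#' Per variant with minor allele count strictly above `mac_min`, fits
#' `phenotype ~ CN + dosage + CN:dosage + covariates` by OLS (the
#' interaction model is fixed-effects; no kinship term) and reports the
#' Wald statistics of the interaction term, in SD per allele per copy.
#'
#' @param bundle A `cohort_bundle`.
#' @param phenotype Rank-normalized response column.
#' @param cn Diploid CN vector (estimated CN in real use; defaults to the
#'   bundle's `kiv2_cn_true`).
#' @param window Optional `c(start, end)` restricting scanned positions.
#' @param mac_min Exclusive minor-allele-count floor (default 20).
#' @param covariates Covariate columns.
#' @return Interaction table: `variant_id`, `pos`, `mac`,
#'   `beta_main`, `beta_cn`, `beta_interaction`, `se_interaction`,
#'   `p_interaction`, plus `beta`, `se`, `p` aliases of the interaction
#'   columns so clumping and meta operate on it directly.
#' @export
interaction_scan <- function(bundle, phenotype = "lp_a_norm", cn = NULL,
                             window = NULL, mac_min = 20,
                             covariates = c("age", "sex")) {
  if (is.null(cn)) cn <- bundle$phenotypes$kiv2_cn_true
  if (is.null(cn)) stop("no CN supplied")
  y <- bundle$phenotypes[[phenotype]]
  if (is.null(y)) stop("phenotype column not found: ", phenotype)
  C <- covariate_matrix(bundle$phenotypes, covariates)
  st <- allele_stats(bundle$genotypes)
  in_win <- if (is.null(window)) rep(TRUE, nrow(bundle$variants)) else
    bundle$variants$pos >= window[1] & bundle$variants$pos <= window[2]
  pass <- in_win & !is.na(st$mac) & st$mac > mac_min
  cnc <- cn - mean(cn, na.rm = TRUE)  # centered: main effects interpretable
  rows <- lapply(which(pass), function(j) {
    g <- bundle$genotypes[, j]
    if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
    X <- cbind(C, cn = cnc, g = g, gxcn = g * cnc)
    fit <- stats::lm.fit(X, y)
    if (fit$rank < ncol(X)) return(NULL)  # rank-deficient: skip
    dfres <- length(y) - ncol(X)
    s2 <- sum(fit$residuals^2) / dfres
    XtX_inv <- chol2inv(chol(crossprod(X)))
    b <- fit$coefficients
    se_int <- sqrt(s2 * XtX_inv[ncol(X), ncol(X)])
    p_int <- 2 * stats::pt(abs(b["gxcn"] / se_int), dfres, lower.tail = FALSE)
    data.frame(variant_id = bundle$variants$variant_id[j],
               chrom = bundle$variants$chrom[j],
               pos = bundle$variants$pos[j], mac = st$mac[j],
               maf = st$maf[j],
               beta_main = unname(b["g"]), beta_cn = unname(b["cn"]),
               beta_interaction = unname(b["gxcn"]),
               se_interaction = se_int, p_interaction = unname(p_int),
               n = length(y), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(variant_id = character(0), chrom = character(0),
                      pos = integer(0), mac = integer(0), maf = numeric(0),
                      beta_main = numeric(0), beta_cn = numeric(0),
                      beta_interaction = numeric(0),
                      se_interaction = numeric(0),
                      p_interaction = numeric(0), n = integer(0))
  out$beta <- out$beta_interaction
  out$se <- out$se_interaction
  out$p <- out$p_interaction
  out$analysis <- "interaction"
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping of association results
#'
#' Repeatedly takes the best remaining p-value at or below `p1` as an index
#' variant, then assigns every unassigned variant with p <= `p2`, within
#' `kb` kilobases of the index and with dosage r-squared above `r2`, to its
#' clump. Every variant passing `p1` ends in exactly one clump.
#'
#' @param results Result table with `variant_id`, `pos`, `p`.
#' @param genotypes Dosage matrix covering the result variants.
#' @param kb Distance window in kb (default 500).
#' @param p1 Index-variant p ceiling (default 1 = everything clumps).
#' @param p2 Member p ceiling (default 1).
#' @param r2 Exclusive r-squared floor for clump membership (default 0.25).
#' @return Data frame `variant_id`, `pos`, `p`, `clump_index` (the index
#'   variant id), `is_index`.
#' @export
clump_results <- function(results, genotypes, kb = 500, p1 = 1, p2 = 1,
                          r2 = 0.25) {
  res <- results[!is.na(results$p), c("variant_id", "pos", "p")]
  stopifnot(all(res$variant_id %in% colnames(genotypes)))
  res <- res[order(res$p, res$pos), ]
  assigned <- stats::setNames(rep(NA_character_, nrow(res)), res$variant_id)
  for (i in seq_len(nrow(res))) {
    vid <- res$variant_id[i]
    if (!is.na(assigned[vid]) || res$p[i] > p1) next
    assigned[vid] <- vid
    near <- which(is.na(assigned) &
                    abs(res$pos - res$pos[i]) <= kb * 1000 &
                    res$p <= p2)
    for (j in near) {
      if (dosage_r2(genotypes[, vid], genotypes[, res$variant_id[j]]) > r2)
        assigned[res$variant_id[j]] <- vid
    }
  }
  data.frame(variant_id = res$variant_id, pos = res$pos, p = res$p,
             clump_index = unname(assigned[res$variant_id]),
             is_index = res$variant_id == assigned[res$variant_id] &
               !is.na(assigned[res$variant_id]),
             stringsAsFactors = FALSE)
}

#' Bonferroni significance threshold from a clump count
#'
#' `alpha / n_clumps`: the number of LD-independent clumps is the effective
#' number of tests. With the published clump counts this reproduces the
#' cohort thresholds (1373 clumps -> 3.64e-5; 566 -> 8.83e-5).
#'
#' @param n_clumps Number of clumps (>= 1).
#' @param alpha Family-wise error rate (default 0.05).
#' @return The per-test p threshold.
#' @export
bonferroni_threshold <- function(n_clumps, alpha = 0.05) {
  if (n_clumps < 1) stop("n_clumps must be >= 1")
  alpha / n_clumps
}

#' Meta-analyze per-cohort interaction results
#'
#' Inverse-variance fixed-effects pooling of the interaction coefficients
#' (delegates to [meta_fixed_effects()] on the interaction columns).
#'
#' @param tables Named list of interaction tables from [interaction_scan()].
#' @return Meta table as [meta_fixed_effects()].
#' @export
interaction_meta <- function(tables) {
  meta_fixed_effects(lapply(tables, function(t) {
    data.frame(variant_id = t$variant_id, beta = t$beta_interaction,
               se = t$se_interaction, n = t$n, stringsAsFactors = FALSE)
  }))
}

#' Sensitivity checks on top modifier hits
#'
#' Per hit: (a) the dosage is not a CN proxy — squared Pearson correlation
#' with CN below 0.1; (b) the variant is individually associated with the
#' phenotype (marginal p < 0.05); (c) the interaction survives conditioning
#' on the supplied independent main-effect hits (re-estimated interaction p
#' reported with its pass flag at `alpha_c`).
#'
#' @param hits Character vector of variant ids to check.
#' @param bundle A `cohort_bundle`.
#' @param independent_hits Character vector of main-effect hit ids to
#'   condition on (from [conditional_scan()]).
#' @param phenotype,cn,covariates As in [interaction_scan()].
#' @param alpha_c Significance level for check (c) (default 0.05).
#' @return Data frame per hit: `r2_with_cn`, `pass_not_cn_proxy`,
#'   `marginal_p`, `pass_marginal`, `conditional_interaction_p`,
#'   `pass_conditional`.
#' @export
sensitivity_checks <- function(hits, bundle, independent_hits = character(0),
                               phenotype = "lp_a_norm", cn = NULL,
                               covariates = c("age", "sex"),
                               alpha_c = 0.05) {
  if (length(hits) == 0) stop("empty hit list")
  if (is.null(cn)) cn <- bundle$phenotypes$kiv2_cn_true
  if (is.null(cn)) stop("no CN supplied")
  y <- bundle$phenotypes[[phenotype]]
  C <- covariate_matrix(bundle$phenotypes, covariates)
  cond <- NULL
  for (v in setdiff(independent_hits, hits)) {
    g <- bundle$genotypes[, v]
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    cond <- cbind(cond, g)
  }
  cnc <- cn - mean(cn)
  out <- lapply(hits, function(v) {
    g <- bundle$genotypes[, v]
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    r2cn <- dosage_r2(g, cn)
    # marginal association (no CN adjustment)
    Xm <- cbind(C, g = g)
    fitm <- stats::lm.fit(Xm, y)
    dfm <- length(y) - ncol(Xm)
    s2m <- sum(fitm$residuals^2) / dfm
    vm <- s2m * chol2inv(chol(crossprod(Xm)))[ncol(Xm), ncol(Xm)]
    p_marg <- 2 * stats::pt(abs(fitm$coefficients["g"] / sqrt(vm)), dfm,
                            lower.tail = FALSE)
    # interaction conditioned on independent main-effect hits
    Xc <- cbind(C, cond, cn = cnc, g = g, gxcn = g * cnc)
    fitc <- stats::lm.fit(Xc, y)
    dfc <- length(y) - fitc$rank
    s2c <- sum(fitc$residuals^2) / dfc
    ok <- !is.na(fitc$coefficients)
    vi <- s2c * chol2inv(chol(crossprod(Xc[, ok, drop = FALSE])))
    k <- sum(ok)
    p_cond <- 2 * stats::pt(abs(fitc$coefficients["gxcn"] / sqrt(vi[k, k])),
                            dfc, lower.tail = FALSE)
    data.frame(variant_id = v, r2_with_cn = r2cn,
               pass_not_cn_proxy = r2cn < 0.1,
               marginal_p = unname(p_marg),
               pass_marginal = unname(p_marg) < 0.05,
               conditional_interaction_p = unname(p_cond),
               pass_conditional = unname(p_cond) < alpha_c,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
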