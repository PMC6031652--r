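## Read-depth KIV2-CN estimation: copy-ratio transform plus IBD2-sibling
## precision assessment.

#' Diploid copy ratio from depth summaries
#'
#' `rho = 2 * mean(repeat-interval depth) / mean(control depth)`, with the
#' control mean pooled across control intervals weighted by interval length.
#' A reference-structured diploid sample has rho = 2.
#'
#' @param depth Depth-summary data frame (`sample_id`, `interval`,
#'   `mean_depth`).
#' @param model A [repeat_model()].
#' @return Data frame `sample_id`, `rho`.
#' @export
estimate_copy_ratio <- function(depth, model = repeat_model()) {
  rep_key <- sprintf("%s:%d-%d", model$chrom, model$start, model$end)
  ctl_keys <- sprintf("%s:%d-%d", model$control_intervals$chrom,
                      model$control_intervals$start,
                      model$control_intervals$end)
  rep_d <- depth[depth$interval == rep_key, ]
  ctl_d <- depth[depth$interval %in% ctl_keys, ]
  if (nrow(rep_d) == 0) stop("no depth rows for the repeat interval ", rep_key)
  if (nrow(ctl_d) == 0) stop("no depth rows for any control interval")
  len <- parse_interval(ctl_d$interval)$length
  ctl_mean <- vapply(split(seq_len(nrow(ctl_d)), ctl_d$sample_id), function(i)
    stats::weighted.mean(ctl_d$mean_depth[i], len[i]), numeric(1))
  ids <- rep_d$sample_id
  missing_ctl <- setdiff(ids, names(ctl_mean))
  if (length(missing_ctl)) stop("control depth absent for sample(s): ",
                                paste(utils::head(missing_ctl, 3), collapse = ", "))
  cm <- ctl_mean[ids]
  if (any(cm <= 0)) stop("control mean depth must be positive")
  data.frame(sample_id = ids, rho = 2 * rep_d$mean_depth / cm,
             stringsAsFactors = FALSE)
}

#' KIV2 domain count from a copy ratio
#'
#' Applies the affine transform `kiv2_cn = rho * scale_A - offset_B`
#' (defaults 6.354 and 0.708, calibrated so the diploid reference layout at
#' rho = 2 yields 12 domains). Strictly increasing in rho. Negative results
#' are retained and flagged — clamping would hide estimator pathology from
#' downstream diagnostics.
#'
#' @param copy_ratio Data frame from [estimate_copy_ratio()], or a numeric
#'   vector of ratios.
#' @param model A [repeat_model()] carrying the constants.
#' @return Data frame `sample_id`, `kiv2_cn`, `qc_flag` ("" or "negative_cn").
#' @export
kiv2_cn_from_ratio <- function(copy_ratio, model = repeat_model()) {
  if (is.numeric(copy_ratio))
    copy_ratio <- data.frame(sample_id = as.character(seq_along(copy_ratio)),
                             rho = copy_ratio)
  if (any(!is.finite(copy_ratio$rho))) stop("non-finite copy ratio")
  cn <- copy_ratio$rho * model$scale_A - model$offset_B
  data.frame(sample_id = copy_ratio$sample_id, kiv2_cn = cn,
             qc_flag = ifelse(cn < 0, "negative_cn", ""),
             stringsAsFactors = FALSE)
}

#' Estimate diploid KIV2-CN from depth summaries (convenience wrapper)
#' @inheritParams estimate_copy_ratio
#' @return Data frame `sample_id`, `kiv2_cn`, `qc_flag`.
#' @export
estimate_kiv2_cn <- function(depth, model = repeat_model()) {
  kiv2_cn_from_ratio(estimate_copy_ratio(depth, model), model)
}

#' Classify candidate sample pairs as IBD2 from locus-window genotypes
#'
#' A pair is IBD2 when its genotype discordance over non-missing shared
#' variants in the window is strictly below 1%. Dosages are rounded to hard
#' calls before comparison. Pairs with fewer comparable variants than
#' `min_variants` are excluded (reported in the result).
#'
#' @param genotypes Dosage matrix restricted to the locus window
#'   (conventionally 0.5 Mb either side of the gene).
#' @param pairs Two-column matrix of sample ids or indices (candidate pairs).
#' @param max_discordance Strict upper bound for IBD2 (default 0.01).
#' @param min_variants Minimum comparable variants per pair (default 50).
#' @return Data frame per pair: ids, `n_compared`, `discordance`, `ibd2`,
#'   `excluded`.
#' @export
classify_ibd2 <- function(genotypes, pairs, max_discordance = 0.01,
                          min_variants = 50) {
  if (is.numeric(pairs)) {
    pairs <- matrix(rownames(genotypes)[pairs], ncol = 2)
  }
  res <- lapply(seq_len(nrow(pairs)), function(r) {
    g1 <- round(genotypes[pairs[r, 1], ])
    g2 <- round(genotypes[pairs[r, 2], ])
    ok <- !is.na(g1) & !is.na(g2)
    n <- sum(ok)
    disc <- if (n > 0) mean(g1[ok] != g2[ok]) else NA_real_
    data.frame(sample1 = pairs[r, 1], sample2 = pairs[r, 2],
               n_compared = n, discordance = disc,
               excluded = n < min_variants,
               ibd2 = !is.na(disc) & n >= min_variants & disc < max_discordance,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  n_exc <- sum(out$excluded)
  if (n_exc) message(sprintf("classify_ibd2: %d pair(s) excluded (<%d comparable variants)",
                             n_exc, min_variants))
  out
}

#' Estimator precision from IBD2 sibling pairs
#'
#' IBD2 siblings share their true CN, so the squared correlation of the two
#' pair-member estimate vectors bounds estimator noise. Pair member order is
#' randomized (seeded) to avoid ordering artifacts; the regression slope of
#' member 2 on member 1 is reported alongside.
#'
#' @param cn_estimates Data frame `sample_id`, `kiv2_cn`.
#' @param ibd2_pairs Two-column matrix of sample ids (IBD2 pairs only).
#' @param seed Seed for the order randomization.
#' @return List `r_squared`, `n_pairs`, `slope`.
#' @export
sibling_precision <- function(cn_estimates, ibd2_pairs, seed = 1) {
  if (nrow(ibd2_pairs) < 3) stop("need at least 3 IBD2 pairs")
  set.seed(seed)
  cn <- stats::setNames(cn_estimates$kiv2_cn, cn_estimates$sample_id)
  flip <- stats::runif(nrow(ibd2_pairs)) < 0.5
  a <- ifelse(flip, ibd2_pairs[, 2], ibd2_pairs[, 1])
  b <- ifelse(flip, ibd2_pairs[, 1], ibd2_pairs[, 2])
  x <- cn[a]; y <- cn[b]
  list(r_squared = stats::cor(x, y)^2,
       n_pairs = nrow(ibd2_pairs),
       slope = unname(stats::coef(stats::lm(y ~ x))[2]))
}
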