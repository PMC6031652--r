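## Sparse SNP panel imputing KIV2-CN from genotypes: train / validate
## protocol with LD pruning, cross-validated LASSO selection, random-forest
## importance ranking, and application to new cohorts.

#' Split a cohort into disjoint training and validation bundles
#'
#' The split is exhaustive, honors `fraction` to within one sample, and
#' never separates sibling pairs (a pair straddling the split would leak the
#' shared locus haplotypes from training into validation).
#'
#' @param bundle A `cohort_bundle`.
#' @param fraction Training fraction (default 2/3, the published protocol).
#' @param seed Integer seed.
#' @param pairs Optional two-column matrix of sibling sample indices or ids
#'   kept on the same side.
#' @return List `train`, `validate` (both `cohort_bundle`s).
#' @export
split_train_validate <- function(bundle, fraction = 2/3, seed = 1,
                                 pairs = NULL) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n <- n_samples(bundle)
  if (n < 30) stop("need at least 30 samples to split")
  ids <- rownames(bundle$genotypes)
  if (!is.null(pairs) && nrow(pairs)) {
    if (is.numeric(pairs)) pairs <- matrix(ids[pairs], ncol = 2)
  } else pairs <- matrix(character(0), ncol = 2)
  # units = sibling pairs plus singletons; sample units until the training
  # side reaches its quota
  paired <- unique(as.vector(pairs))
  singles <- setdiff(ids, paired)
  units <- c(lapply(seq_len(nrow(pairs)), function(r) pairs[r, ]),
             as.list(singles))
  set.seed(seed)
  units <- units[sample(length(units))]
  target <- round(fraction * n)
  train_ids <- character(0)
  for (u in units) {
    if (length(train_ids) >= target) break
    train_ids <- c(train_ids, u)
  }
  val_ids <- setdiff(ids, train_ids)
  list(train = subset_samples(bundle, train_ids),
       validate = subset_samples(bundle, val_ids))
}

#' Filter candidate panel variants by window, MAF and imputation quality
#'
#' @param variants Variant table with `pos`, `maf`, `info_score`.
#' @param window Length-2 vector (bp, 1-based inclusive).
#' @param maf_min Exclusive lower MAF bound (default 0.001).
#' @param info_min Exclusive lower imputation-quality bound (default 0.8).
#' @return The retained rows; errors with per-filter counts if empty.
#' @export
filter_panel_variants <- function(variants, window, maf_min = 0.001,
                                  info_min = 0.8) {
  stopifnot(length(window) == 2)
  in_win <- variants$pos >= window[1] & variants$pos <= window[2]
  info <- if ("info_score" %in% names(variants)) variants$info_score else 1
  pass_maf <- variants$maf > maf_min
  pass_info <- info > info_min
  keep <- in_win & pass_maf & pass_info
  if (!any(keep))
    stop(sprintf("no variants pass: window %d, maf %d, info %d of %d",
                 sum(in_win), sum(pass_maf), sum(pass_info), nrow(variants)))
  variants[keep, , drop = FALSE]
}

# r^2 between two dosage vectors on complete cases
dosage_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2 || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) return(0)
  stats::cor(a[ok], b[ok])^2
}

#' Greedy sliding-window LD pruning
#'
#' Within each `window_variants`-wide window (advancing by `step`), while any
#' retained pair has r-squared above `r2_max`, one member is dropped: the
#' later variant in position order by default, or the lower-MAF variant with
#' `tie_break = "maf"`. Output preserves input order and is deterministic.
#'
#' @param genotypes Dosage matrix (columns ordered by position).
#' @param variants Matching variant table (`pos`, `maf`).
#' @param window_variants,step,r2_max Window size in variants, step, and the
#'   pairwise r-squared ceiling (defaults 50, 5, 0.25).
#' @param tie_break `"position"` (drop later) or `"maf"` (drop rarer).
#' @return Character vector of retained variant ids, input order.
#' @export
ld_prune <- function(genotypes, variants, window_variants = 50, step = 5,
                     r2_max = 0.25, tie_break = c("position", "maf")) {
  tie_break <- match.arg(tie_break)
  m <- ncol(genotypes)
  if (m < 2) return(colnames(genotypes))
  G <- genotypes
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  R2 <- suppressWarnings(stats::cor(G))^2  # NA for zero-variance columns
  R2[is.na(R2)] <- 0
  keep <- rep(TRUE, m)
  start <- 1L
  repeat {
    end <- min(start + window_variants - 1L, m)
    idx <- which(keep[start:end]) + start - 1L
    if (length(idx) >= 2) {
      repeat {
        dropped <- FALSE
        for (a in seq_along(idx)) {
          if (dropped) break
          for (b in seq_along(idx)) {
            if (b <= a) next
            i <- idx[a]; j <- idx[b]
            if (R2[i, j] > r2_max) {
              drop <- if (tie_break == "position") j
                      else if (variants$maf[i] < variants$maf[j]) i else j
              keep[drop] <- FALSE
              idx <- setdiff(idx, drop)
              dropped <- TRUE
              break
            }
          }
        }
        if (!dropped || length(idx) < 2) break
      }
    }
    if (end >= m) break
    start <- start + step
  }
  colnames(genotypes)[keep]
}

#' Fit the sparse CN-imputation panel by cross-validated LASSO
#'
#' Predictors are standardized; lambda is chosen to minimize 10-fold
#' cross-validated MSE over a 100-point log-spaced path spanning four
#' decades below the all-zero lambda; the panel is refit at that lambda on
#' the full training set. The response is the read-depth CN estimate (pass
#' truth only in oracle tests).
#'
#' @param genotypes Training dosage matrix restricted to candidate variants.
#' @param response Numeric response (estimated diploid CN), length = rows.
#' @param k_folds Cross-validation folds (default 10).
#' @param seed Seed for fold assignment.
#' @return Object of class `cn_panel`: `variants`, `coefficients` (nonzero),
#'   `intercept`, `lambda`, `n_selected`, `training_r2`, `candidates`.
#' @export
fit_lasso_panel <- function(genotypes, response, k_folds = 10, seed = 1) {
  stopifnot(nrow(genotypes) == length(response))
  if (nrow(genotypes) <= k_folds) stop("training n must exceed k_folds")
  sds <- apply(genotypes, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d zero-variance variant(s)", sum(sds == 0)))
    genotypes <- genotypes[, sds > 0, drop = FALSE]
  }
  X <- genotypes
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  n <- nrow(X)
  Xs <- scale(X)
  lambda_max <- max(abs(crossprod(Xs, response - mean(response)))) / n
  lambdas <- 10^seq(log10(lambda_max), log10(lambda_max) - 4, length.out = 100)
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(k_folds), n))
  cv <- glmnet::cv.glmnet(X, response, alpha = 1, lambda = lambdas,
                          foldid = foldid, standardize = TRUE)
  fit <- glmnet::glmnet(X, response, alpha = 1, lambda = lambdas,
                        standardize = TRUE)
  cf <- as.vector(stats::coef(fit, s = cv$lambda.min))
  names(cf) <- c("(Intercept)", colnames(X))
  nz <- cf[-1][cf[-1] != 0]
  pred <- cf[1] + as.vector(X %*% cf[-1])
  structure(list(variants = names(nz), coefficients = nz,
                 intercept = unname(cf[1]), lambda = cv$lambda.min,
                 n_selected = length(nz),
                 training_r2 = if (stats::sd(pred) > 0)
                   stats::cor(pred, response)^2 else NA_real_,
                 candidates = colnames(X), seed = seed),
            class = "cn_panel")
}

#' @export
print.cn_panel <- function(x, ...) {
  cat(sprintf("<cn_panel> %d selected / %d candidate variants; lambda = %.4g; training r2 = %.3f\n",
              x$n_selected, length(x$candidates), x$lambda, x$training_r2))
  invisible(x)
}

#' Serialize / load a CN panel as JSON
#' @param panel A `cn_panel`.
#' @param path JSON file path.
#' @export
write_panel <- function(panel, path) {
  jsonlite::write_json(unclass(panel), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$coefficients <- stats::setNames(as.numeric(p$coefficients), p$variants)
  structure(p, class = "cn_panel")
}

#' Rank panel variants by ensemble-regression importance
#'
#' Fits a random-forest regression of the response on the selected panel
#' variants and returns impurity importances normalized to sum 1,
#' descending.
#'
#' @param panel A `cn_panel`.
#' @param genotypes Training dosage matrix.
#' @param response Training response.
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed.
#' @return Data frame `variant_id`, `importance`, sorted descending.
#' @export
rank_importance <- function(panel, genotypes, response, n_trees = 500,
                            seed = 1) {
  if (panel$n_selected == 0) stop("panel is empty")
  X <- genotypes[, panel$variants, drop = FALSE]
  if (panel$n_selected == 1)
    return(data.frame(variant_id = panel$variants, importance = 1,
                      stringsAsFactors = FALSE))
  df <- data.frame(y = response, X, check.names = FALSE)
  rf <- ranger::ranger(dependent.variable.name = "y", data = df,
                       num.trees = n_trees, importance = "impurity",
                       seed = seed)
  imp <- rf$variable.importance
  imp <- pmax(imp, 0)
  imp <- imp / sum(imp)
  data.frame(variant_id = names(sort(imp, decreasing = TRUE)),
             importance = unname(sort(imp, decreasing = TRUE)),
             stringsAsFactors = FALSE)
}

#' Impute CN by applying a panel to genotypes
#'
#' Linear score `intercept + sum(coef * dosage)`. Missing dosages are
#' mean-substituted (column mean, reported); more than 20% of panel variants
#' absent from the matrix is an error.
#'
#' @param panel A `cn_panel`.
#' @param genotypes Dosage matrix covering (most of) the panel variants.
#' @return Named numeric vector of imputed CN per sample.
#' @export
apply_panel <- function(panel, genotypes) {
  if (panel$n_selected == 0)
    return(stats::setNames(rep(panel$intercept, nrow(genotypes)),
                           rownames(genotypes)))
  present <- panel$variants %in% colnames(genotypes)
  if (mean(present) < 0.8)
    stop(sprintf("%d of %d panel variants absent from genotypes",
                 sum(!present), length(present)))
  if (any(!present))
    message(sprintf("apply_panel: %d absent variant(s) contribute their training coefficient x 0",
                    sum(!present)))
  X <- genotypes[, panel$variants[present], drop = FALSE]
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
    message(sprintf("apply_panel: mean-substituted %d missing dosage(s)", nrow(idx)))
  }
  stats::setNames(panel$intercept +
                    as.vector(X %*% panel$coefficients[present]),
                  rownames(genotypes))
}

#' Validate a panel on a held-out cohort
#'
#' @param panel A `cn_panel` trained on samples disjoint from `genotypes`.
#' @param genotypes Validation dosage matrix.
#' @param cn_estimated Validation read-depth CN estimates (same order).
#' @return List `pearson_r`, `r_squared`, `n`; r is NA with a message when
#'   predictions are constant.
#' @export
validate_panel <- function(panel, genotypes, cn_estimated) {
  pred <- apply_panel(panel, genotypes)
  stopifnot(length(pred) == length(cn_estimated))
  if (stats::sd(pred) == 0) {
    message("validate_panel: constant predictions; correlation undefined")
    return(list(pearson_r = NA_real_, r_squared = NA_real_, n = length(pred)))
  }
  r <- stats::cor(pred, cn_estimated)
  list(pearson_r = r, r_squared = r^2, n = length(pred))
}
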