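## Mendelian-randomization instruments: CN-adjusted genetic risk score,
## KIV2-CN score, and their combination, each calibrated so one instrument
## unit equals one phenotype SD, plus Cox and linear outcome models.

new_instrument <- function(type, raw, variants = character(0),
                           weights = numeric(0)) {
  structure(list(type = type, variants = variants, weights = weights,
                 raw_score = raw, norm_score = NULL, final_score = NULL,
                 scale_factor = NA_real_, calibration_cohort = NA_character_,
                 variance_explained = NA_real_),
            class = "instrument")
}

#' @export
print.instrument <- function(x, ...) {
  cat(sprintf("<instrument:%s> %d variant(s); scale factor %s; calibrated on %s\n",
              x$type, length(x$variants),
              if (is.na(x$scale_factor)) "unset" else sprintf("%.3f", x$scale_factor),
              x$calibration_cohort))
  invisible(x)
}

#' Build a CN-adjusted genetic risk score instrument
#'
#' Clumps a CN-adjusted association scan (index p-value ceiling `p1` within
#' `kb`/`r2` windows) over the locus window and scores each sample as
#' `sum(index beta x dosage)`. Missing dosages are substituted by twice the
#' allele frequency (the dosage mean) and reported.
#'
#' @param results CN-adjusted result table (from [single_variant_scan()]
#'   with `adjust_cn = TRUE`).
#' @param genotypes Dosage matrix.
#' @param window Optional `c(start, end)` restricting candidate positions.
#' @param p1 Sub-threshold significance ceiling (default 1e-4).
#' @param kb,r2 Clumping parameters (defaults 500 kb, 0.25).
#' @return An uncalibrated `instrument` of type `"GRS"`.
#' @export
build_grs <- function(results, genotypes, window = NULL, p1 = 1e-4,
                      kb = 500, r2 = 0.25) {
  res <- results[!is.na(results$p), ]
  if (!is.null(window))
    res <- res[res$pos >= window[1] & res$pos <= window[2], ]
  if (!any(res$p <= p1))
    stop(sprintf("no variants pass p <= %g; cannot build a GRS", p1))
  cl <- clump_results(res, genotypes, kb = kb, p1 = p1, p2 = 1, r2 = r2)
  index <- cl$variant_id[cl$is_index]
  w <- res$beta[match(index, res$variant_id)]
  X <- genotypes[, index, drop = FALSE]
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)  # = 2 x allele frequency
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
    message(sprintf("build_grs: mean-substituted %d missing dosage(s)", nrow(idx)))
  }
  raw <- stats::setNames(as.vector(X %*% w), rownames(genotypes))
  new_instrument("GRS", raw, variants = index, weights = w)
}

#' Build the KIV2-CN score instrument
#'
#' The raw score is the (estimated or imputed) diploid CN itself;
#' orientation is handled at calibration, where the inverse CN-phenotype
#' relation yields a negative scale factor so the final instrument is
#' positively associated with the phenotype.
#'
#' @param cn Named numeric vector of diploid CN per sample (NA = missing).
#' @param max_missing Maximum tolerated missing fraction (default 0.1).
#' @return An uncalibrated `instrument` of type `"KIV2CN"`.
#' @export
build_cn_score <- function(cn, max_missing = 0.1) {
  if (mean(is.na(cn)) > max_missing)
    stop(sprintf("CN missing for %.0f%% of samples (> %.0f%%)",
                 100 * mean(is.na(cn)), 100 * max_missing))
  new_instrument("KIV2CN", cn)
}

#' Calibrate an instrument so one unit equals one phenotype SD
#'
#' The raw score is inverse-rank normalized; the scale factor is the OLS
#' slope of the rank-normalized calibration phenotype on the normalized
#' score; the final instrument is `scale_factor x normalized score`. By
#' construction, re-fitting the phenotype on the final instrument in the
#' calibration cohort returns slope 1.
#'
#' @param instrument An `instrument`.
#' @param pheno_norm Rank-normalized calibration phenotype, aligned to the
#'   score.
#' @param cohort Label recorded as the calibration cohort.
#' @param min_slope Below this absolute slope the instrument is declared
#'   uninformative and an error is raised (default 0.01).
#' @return The calibrated `instrument`.
#' @export
normalize_instrument <- function(instrument, pheno_norm, cohort = "calibration",
                                 min_slope = 0.01) {
  raw <- instrument$raw_score
  stopifnot(length(raw) == length(pheno_norm))
  if (stats::sd(raw, na.rm = TRUE) == 0) stop("constant score; cannot normalize")
  z <- inverse_rank_normalize(raw)
  slope <- unname(stats::coef(stats::lm(pheno_norm ~ z))[2])
  if (!is.finite(slope) || abs(slope) < min_slope)
    stop(sprintf("uninformative instrument: |slope| = %.4f < %.2f",
                 abs(slope), min_slope))
  instrument$norm_score <- z
  instrument$scale_factor <- slope
  instrument$final_score <- slope * z
  instrument$calibration_cohort <- cohort
  instrument$variance_explained <- stats::cor(instrument$final_score,
                                              pheno_norm)^2
  instrument
}

#' Combine a GRS and a KIV2-CN instrument
#'
#' Sums the two calibrated final scores and re-calibrates the sum on the
#' same cohort, yielding a `COMBINED` instrument on the 1-unit-per-SD scale.
#'
#' @param grs,cn_score Calibrated `instrument`s over identical samples.
#' @param pheno_norm Rank-normalized calibration phenotype.
#' @param cohort Calibration-cohort label.
#' @return A calibrated `instrument` of type `"COMBINED"`.
#' @export
combine_scores <- function(grs, cn_score, pheno_norm, cohort = "calibration") {
  if (length(grs$final_score) != length(cn_score$final_score) ||
      !identical(names(grs$raw_score), names(cn_score$raw_score)))
    stop("instruments cover different sample sets")
  if (is.null(grs$final_score) || is.null(cn_score$final_score))
    stop("both instruments must be calibrated first")
  comb <- new_instrument("COMBINED", grs$final_score + cn_score$final_score,
                         variants = union(grs$variants, cn_score$variants))
  names(comb$raw_score) <- names(grs$raw_score)
  normalize_instrument(comb, pheno_norm, cohort)
}

#' Serialize / load an instrument as JSON
#'
#' By default only the transferable parts are written — variants, weights,
#' scale factor, calibration metadata — since per-sample scores are
#' recomputed when the instrument is applied to a new cohort; set
#' `scores = TRUE` to include them.
#'
#' @param instrument An `instrument`.
#' @param path JSON file path.
#' @param scores Also serialize the per-sample score vectors.
#' @export
write_instrument <- function(instrument, path, scores = FALSE) {
  x <- unclass(instrument)
  if (!scores) x[c("raw_score", "norm_score", "final_score")] <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_instrument
#' @export
read_instrument <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "instrument")
}

#' Cox proportional-hazards association of an instrument with event times
#'
#' Partial-likelihood fit (Breslow tie handling) of the event table on the
#' final instrument plus covariates; reports the hazard ratio per
#' instrument unit (= per phenotype SD for a calibrated instrument) with
#' Wald CI.
#'
#' @param events Data frame `sample_id`, `time`, `status`.
#' @param instrument A calibrated `instrument` (or a named numeric score).
#' @param covariates Matrix or data frame of covariates aligned to
#'   `events` (e.g. PCs, age, sex, fasting); NULL for none.
#' @param min_events Minimum events required (default 20).
#' @return List `hr`, `ci` (length 2), `p`, `loghr`, `se`, `n`, `n_events`.
#' @export
mr_cox <- function(events, instrument, covariates = NULL, min_events = 20) {
  score <- if (inherits(instrument, "instrument")) {
    if (is.null(instrument$final_score)) stop("instrument is not calibrated")
    instrument$final_score
  } else instrument
  stopifnot(nrow(events) == length(score))
  if (sum(events$status) == 0) stop("no events")
  if (sum(events$status) < min_events)
    stop(sprintf("only %d events (< %d)", sum(events$status), min_events))
  d <- data.frame(time = events$time, status = events$status, score = score)
  if (!is.null(covariates)) d <- cbind(d, as.data.frame(covariates))
  fit <- survival::coxph(survival::Surv(time, status) ~ ., data = d,
                         ties = "breslow")
  sm <- summary(fit)
  b <- sm$coefficients["score", "coef"]
  se <- sm$coefficients["score", "se(coef)"]
  list(hr = exp(b), ci = exp(b + c(-1.96, 1.96) * se),
       p = sm$coefficients["score", "Pr(>|z|)"],
       loghr = b, se = se, n = nrow(d), n_events = sum(events$status))
}

#' Linear association of an instrument with a quantitative outcome
#'
#' @param outcome Rank-normalized quantitative outcome vector.
#' @param instrument A calibrated `instrument` (or numeric score).
#' @param covariates Optional covariate matrix/data frame.
#' @return List `beta`, `ci`, `se`, `p`, `n`.
#' @export
mr_quantitative <- function(outcome, instrument, covariates = NULL) {
  score <- if (inherits(instrument, "instrument")) instrument$final_score
           else instrument
  stopifnot(length(outcome) == length(score))
  d <- data.frame(y = outcome, score = score)
  if (!is.null(covariates)) d <- cbind(d, as.data.frame(covariates))
  fit <- stats::lm(y ~ ., data = d)
  sm <- summary(fit)$coefficients
  b <- sm["score", "Estimate"]; se <- sm["score", "Std. Error"]
  list(beta = b, ci = b + c(-1.96, 1.96) * se, se = se,
       p = sm["score", "Pr(>|t|)"], n = nrow(d))
}

#' Phenotype variance explained by an instrument
#'
#' Squared correlation of the final instrument with the rank-normalized
#' phenotype; record whether the evaluation cohort is the calibration
#' cohort (optimistic) or held out.
#'
#' @param instrument A calibrated `instrument` (or numeric score).
#' @param pheno_norm Rank-normalized phenotype.
#' @param cohort Label of the evaluation cohort.
#' @return List `r_squared`, `n`, `cohort`, `is_calibration`.
#' @export
variance_explained <- function(instrument, pheno_norm, cohort = "held_out") {
  score <- if (inherits(instrument, "instrument")) instrument$final_score
           else instrument
  ok <- !is.na(score) & !is.na(pheno_norm)
  if (sum(ok) < 30) stop("need at least 30 samples")
  list(r_squared = stats::cor(score[ok], pheno_norm[ok])^2, n = sum(ok),
       cohort = cohort,
       is_calibration = if (inherits(instrument, "instrument"))
         identical(cohort, instrument$calibration_cohort) else NA)
}
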