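#' kiv2cn: KIV2 repeat copy number estimation, imputation, and association
#'
#' Tools for working with the LPA kringle IV-2 (KIV2) tandem repeat: diploid
#' copy-number (CN) estimation from read-depth summaries, SNP-panel CN
#' imputation, CN-conditioned association and variant-by-CN modifier scans,
#' and CN-aware Mendelian-randomization instruments, together with a
#' synthetic-cohort generator carrying full truth tables.
#'
#' @keywords internal
#' @aliases kiv2cn-package
"_PACKAGE"

## ---------------------------------------------------------------------------
## Repeat locus model
## ---------------------------------------------------------------------------

#' Repeat locus geometry and copy-ratio transform constants
#'
#' Describes the KIV2 repeat interval, the diploid control intervals used to
#' normalize read depth, and the affine constants mapping the diploid copy
#' ratio to a KIV2 domain count:
#' `KIV2-CN = rho * scale_A - offset_B`, where `rho` is 2 x (repeat-interval
#' mean depth) / (control mean depth) so a reference-structured diploid sample
#' has `rho = 2` and maps to 12 domains under the defaults.
#'
#' Coordinates are 1-based inclusive, matching how genomic intervals are
#' printed; the constants are calibrated against the hg19 reference repeat
#' layout and are configuration, never recomputed.
#'
#' @param chrom Chromosome name.
#' @param start,end Repeat interval (1-based inclusive).
#' @param scale_A Multiplicative constant of the copy-ratio transform (> 0).
#' @param offset_B Subtractive constant of the transform (>= 0), removing the
#'   flanking homologous exons counted by aggregate read depth.
#' @param unit_length_range Length range of one repeat unit in bp.
#' @param control_intervals Data frame with columns `chrom`, `start`, `end`
#'   of diploid-copy regions used for depth normalization.
#' @return An object of class `repeat_model`.
#' @export
repeat_model <- function(chrom = "6",
                         start = 161032614L, end = 161067851L,
                         scale_A = 6.354, offset_B = 0.708,
                         unit_length_range = c(5534L, 5546L),
                         control_intervals = NULL) {
  stopifnot(end > start, scale_A > 0, offset_B >= 0)
  if (is.null(control_intervals)) {
    control_intervals <- data.frame(
      chrom = c("6", "6"),
      start = c(160300001L, 161600001L),
      end   = c(160400000L, 161700000L),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("chrom", "start", "end") %in% names(control_intervals)),
            all(control_intervals$end > control_intervals$start))
  structure(list(chrom = chrom, start = start, end = end,
                 scale_A = scale_A, offset_B = offset_B,
                 unit_length_range = unit_length_range,
                 control_intervals = control_intervals),
            class = "repeat_model")
}

#' @export
print.repeat_model <- function(x, ...) {
  cat(sprintf("<repeat_model> %s:%d-%d (%.0f kb), A = %.3f, B = %.3f, %d control interval(s)\n",
              x$chrom, x$start, x$end, (x$end - x$start + 1) / 1000,
              x$scale_A, x$offset_B, nrow(x$control_intervals)))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Cohort bundle
## ---------------------------------------------------------------------------

#' Bundle genotypes, variants, phenotypes and optional depth/kinship
#'
#' The unit every analysis stage consumes: a dosage matrix (samples x
#' variants, values in \[0, 2\], NA = missing), its variant table, a phenotype
#' / covariate table, and optionally per-sample depth summaries and a kinship
#' matrix. All components are aligned on sample id at construction.
#'
#' @param genotypes Numeric matrix, samples x variants, rownames = sample ids,
#'   colnames = variant ids, entries in \[0,2\] or NA.
#' @param variants Data frame with at least `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`; `maf`, `mac`, `info_score` are added by [allele_stats()] if
#'   absent.
#' @param phenotypes Data frame with a `sample_id` column.
#' @param depth Optional depth-summary data frame (see [write_depth_summary()]).
#' @param kinship Optional symmetric samples x samples matrix.
#' @return An object of class `cohort_bundle`.
#' @export
cohort_bundle <- function(genotypes, variants, phenotypes,
                          depth = NULL, kinship = NULL) {
  stopifnot(is.matrix(genotypes), !is.null(rownames(genotypes)),
            !is.null(colnames(genotypes)),
            is.data.frame(variants), "variant_id" %in% names(variants),
            is.data.frame(phenotypes), "sample_id" %in% names(phenotypes))
  if (!all(colnames(genotypes) == variants$variant_id))
    stop("genotype columns and variant table out of order")
  rng <- range(genotypes, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  common <- intersect(rownames(genotypes), phenotypes$sample_id)
  if (length(common) == 0L) stop("no samples shared between genotypes and phenotypes")
  dropped <- setdiff(union(rownames(genotypes), phenotypes$sample_id), common)
  if (length(dropped))
    message(sprintf("cohort_bundle: dropped %d sample(s) absent from one table", length(dropped)))
  genotypes <- genotypes[common, , drop = FALSE]
  phenotypes <- phenotypes[match(common, phenotypes$sample_id), , drop = FALSE]
  rownames(phenotypes) <- NULL
  if (!is.null(kinship)) {
    stopifnot(is.matrix(kinship), !is.null(rownames(kinship)))
    kinship <- kinship[common, common, drop = FALSE]
  }
  structure(list(genotypes = genotypes, variants = variants,
                 phenotypes = phenotypes, depth = depth, kinship = kinship),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("<cohort_bundle> %d samples x %d variants; depth: %s; kinship: %s\n",
              nrow(x$genotypes), ncol(x$genotypes),
              if (is.null(x$depth)) "no" else "yes",
              if (is.null(x$kinship)) "no" else "yes"))
  invisible(x)
}

#' Number of samples in a cohort bundle
#' @param bundle A `cohort_bundle`.
#' @return Integer sample count.
#' @export
n_samples <- function(bundle) nrow(bundle$genotypes)

#' Subset a cohort bundle by sample ids
#' @param bundle A `cohort_bundle`.
#' @param sample_ids Character vector of sample ids to keep.
#' @return A `cohort_bundle` restricted to `sample_ids`.
#' @export
subset_samples <- function(bundle, sample_ids) {
  stopifnot(all(sample_ids %in% rownames(bundle$genotypes)))
  cohort_bundle(bundle$genotypes[sample_ids, , drop = FALSE],
                bundle$variants,
                bundle$phenotypes[match(sample_ids, bundle$phenotypes$sample_id), ,
                                  drop = FALSE],
                depth = if (is.null(bundle$depth)) NULL else
                  bundle$depth[bundle$depth$sample_id %in% sample_ids, , drop = FALSE],
                kinship = if (is.null(bundle$kinship)) NULL else
                  bundle$kinship[sample_ids, sample_ids, drop = FALSE])
}

## ---------------------------------------------------------------------------
## Phenotype preparation
## ---------------------------------------------------------------------------

#' Rank-based inverse-normal transform, applied separately by cohort
#'
#' Within each cohort, maps values to `qnorm((rank - 0.5) / n)` using average
#' ranks for ties; the half-offset is symmetric so the output has mean 0.
#' Missing values stay missing and do not consume ranks. Output is in SD
#' units and invariant to any strictly monotone transform of the input.
#'
#' @param values Numeric vector.
#' @param cohort_labels Vector of cohort labels, recycled if length 1; each
#'   cohort is normalized independently.
#' @return Numeric vector, same length and order as `values`.
#' @export
inverse_rank_normalize <- function(values, cohort_labels = "all") {
  if (length(cohort_labels) == 1L) cohort_labels <- rep(cohort_labels, length(values))
  stopifnot(length(cohort_labels) == length(values))
  out <- rep(NA_real_, length(values))
  for (coh in unique(cohort_labels)) {
    idx <- which(cohort_labels == coh & !is.na(values))
    if (length(idx) < 2L)
      stop(sprintf("cohort '%s' has fewer than 2 non-missing values", coh))
    v <- values[idx]
    if (length(unique(v)) == 1L)
      stop(sprintf("cohort '%s' is constant; ranks undefined", coh))
    r <- rank(v, ties.method = "average")
    out[idx] <- stats::qnorm((r - 0.5) / length(v))
  }
  out
}

#' Rescale lipid measurements of statin users to pre-treatment levels
#'
#' Total cholesterol of statin users is divided by 0.8 and directly measured
#' LDL cholesterol by 0.7, undoing the average on-treatment reduction;
#' untreated samples pass through unchanged.
#'
#' @param total_chol,ldl Concentrations in mg/dL (either may be NULL).
#' @param on_statin Logical vector.
#' @return List with adjusted `total_chol` and `ldl`.
#' @export
statin_adjust <- function(total_chol = NULL, ldl = NULL, on_statin) {
  adj <- function(x, f) {
    if (is.null(x)) return(NULL)
    if (any(x < 0, na.rm = TRUE)) stop("negative concentration")
    stopifnot(length(x) == length(on_statin))
    ifelse(!is.na(on_statin) & on_statin, x / f, x)
  }
  list(total_chol = adj(total_chol, 0.8), ldl = adj(ldl, 0.7))
}

## ---------------------------------------------------------------------------
## Allele statistics
## ---------------------------------------------------------------------------

#' Per-variant minor allele frequency and count from a dosage matrix
#'
#' Missing dosages are excluded per variant. The frequency is folded to the
#' minor allele (`maf = min(af, 1 - af)`); `mac` is the rounded minor-allele
#' dosage sum over non-missing samples. All-missing variants get NA and an
#' `all_missing` flag.
#'
#' @param genotypes Samples x variants dosage matrix.
#' @return Data frame with `variant_id`, `maf`, `mac`, `n_called`,
#'   `all_missing`.
#' @export
allele_stats <- function(genotypes) {
  stopifnot(is.matrix(genotypes), ncol(genotypes) >= 1L)
  n_called <- colSums(!is.na(genotypes))
  dose_sum <- colSums(genotypes, na.rm = TRUE)
  af <- ifelse(n_called > 0, dose_sum / (2 * n_called), NA_real_)
  maf <- pmin(af, 1 - af)
  mac <- ifelse(is.na(af), NA_integer_,
                as.integer(round(ifelse(af <= 0.5, dose_sum,
                                        2 * n_called - dose_sum))))
  data.frame(variant_id = colnames(genotypes), maf = maf, mac = mac,
             n_called = as.integer(n_called), all_missing = n_called == 0L,
             stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## File I/O
## ---------------------------------------------------------------------------

fmt_num <- function(x, digits = 6) {
  formatC(x, digits = digits, format = "g")
}

#' Write a cohort bundle to disk
#'
#' Genotypes go to a VCF v4.2 with `GT:DS` fields (GT from rounded dosage, DS
#' the dosage itself), phenotypes and depth to tab-separated text, kinship to
#' a TSV matrix. Companion files share the stem of `vcf_path`.
#'
#' @param bundle A `cohort_bundle`.
#' @param vcf_path Output VCF path; `<stem>.pheno.tsv`, `<stem>.depth.tsv`,
#'   `<stem>.kinship.tsv` are written next to it as applicable.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(bundle, vcf_path) {
  v <- bundle$variants
  G <- bundle$genotypes
  info <- if ("info_score" %in% names(v)) sprintf("INFO=%s", fmt_num(v$info_score)) else "."
  gt_of <- function(d) c("0/0", "0/1", "1/1")[pmin(pmax(round(d), 0), 2) + 1]
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(G)), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(G)), function(j) {
    d <- G[, j]
    cell <- ifelse(is.na(d), "./.:.", paste0(gt_of(d), ":", fmt_num(d)))
    paste(c(v$chrom[j], v$pos[j], v$variant_id[j], v$ref[j], v$alt[j], ".",
            "PASS", info[min(j, length(info))], "GT:DS", cell), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), vcf_path)
  stem <- sub("\\.vcf$", "", vcf_path)
  pheno_path <- paste0(stem, ".pheno.tsv")
  utils::write.table(bundle$phenotypes, pheno_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths <- c(vcf = vcf_path, pheno = pheno_path)
  if (!is.null(bundle$depth)) {
    dp <- paste0(stem, ".depth.tsv")
    write_depth_summary(bundle$depth, dp)
    paths["depth"] <- dp
  }
  if (!is.null(bundle$kinship)) {
    kp <- paste0(stem, ".kinship.tsv")
    utils::write.table(bundle$kinship, kp, sep = "\t", quote = FALSE)
    paths["kinship"] <- kp
  }
  invisible(paths)
}

#' Read a cohort bundle from a VCF plus phenotype (and optional depth) files
#'
#' Dosages come from the DS format field when present, otherwise from GT
#' calls summed to 0/1/2. Samples are restricted to the intersection of the
#' VCF and phenotype tables; dropped samples are reported.
#'
#' @param vcf_path VCF v4.2 file.
#' @param pheno_path Tab-separated phenotype table with a `sample_id` column.
#' @param depth_path Optional depth-summary TSV.
#' @param kinship_path Optional kinship-matrix TSV.
#' @return A `cohort_bundle`.
#' @export
read_cohort <- function(vcf_path, pheno_path, depth_path = NULL,
                        kinship_path = NULL) {
  stopifnot(file.exists(vcf_path), file.exists(pheno_path))
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = 7, dimnames = list(NULL, colnames(fix)))
  variants <- data.frame(
    variant_id = fix[, "ID"], chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]), ref = fix[, "REF"], alt = fix[, "ALT"],
    stringsAsFactors = FALSE)
  info <- vcfR::extract.info(vcf, "INFO", as.numeric = TRUE)
  if (!all(is.na(info))) variants$info_score <- info
  fmt <- unique(vcf@gt[, "FORMAT"])
  if (any(grepl("DS", fmt))) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else if (any(grepl("GT", fmt))) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ds <- matrix(vapply(gt, function(g) {
      if (is.na(g) || g %in% c("./.", ".")) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]))
    }, numeric(1)), nrow = nrow(gt), dimnames = dimnames(gt))
  } else stop("VCF has neither DS nor GT fields")
  G <- t(ds)  # vcfR is variants x samples
  colnames(G) <- variants$variant_id
  pheno <- utils::read.delim(pheno_path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(pheno)) stop("phenotype table lacks sample_id")
  pheno$sample_id <- as.character(pheno$sample_id)
  depth <- if (!is.null(depth_path)) read_depth_summary(depth_path) else NULL
  kin <- if (!is.null(kinship_path)) {
    k <- as.matrix(utils::read.delim(kinship_path, check.names = FALSE))
    rownames(k) <- colnames(k); k
  } else NULL
  cohort_bundle(G, variants, pheno, depth = depth, kinship = kin)
}

#' Write a depth summary table
#'
#' Three-column layout: `sample_id`, `interval` (`chrom:start-end`, 1-based
#' inclusive), `mean_depth`.
#'
#' @param depth Data frame with those columns.
#' @param path Output TSV path.
#' @export
write_depth_summary <- function(depth, path) {
  stopifnot(all(c("sample_id", "interval", "mean_depth") %in% names(depth)))
  utils::write.table(depth[, c("sample_id", "interval", "mean_depth")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a depth summary table
#' @param path TSV written by [write_depth_summary()], or a bedGraph-style
#'   file with columns sample, chrom, start, end, mean_depth.
#' @return Data frame with `sample_id`, `interval`, `mean_depth`.
#' @export
read_depth_summary <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (all(c("sample_id", "interval", "mean_depth") %in% names(d)))
    return(d)
  if (ncol(d) == 5) {  # bedGraph-like with leading sample column
    names(d) <- c("sample_id", "chrom", "start", "end", "mean_depth")
    d$interval <- sprintf("%s:%d-%d", d$chrom, d$start + 1L, d$end)
    return(d[, c("sample_id", "interval", "mean_depth")])
  }
  stop("unrecognized depth summary layout in ", path)
}

#' Parse "chrom:start-end" interval strings
#' @param interval Character vector of interval strings (1-based inclusive).
#' @return Data frame with `chrom`, `start`, `end`, `length`.
#' @export
parse_interval <- function(interval) {
  m <- regmatches(interval, regexec("^([^:]+):([0-9]+)-([0-9]+)$", interval))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stop("malformed interval: ", interval[bad][1])
  chrom <- vapply(m, `[`, character(1), 2)
  start <- as.integer(vapply(m, `[`, character(1), 3))
  end <- as.integer(vapply(m, `[`, character(1), 4))
  data.frame(chrom = chrom, start = start, end = end,
             length = end - start + 1L, stringsAsFactors = FALSE)
}

#' Principal components of a genotype matrix for ancestry covariates
#'
#' Standardizes dosages (mean-imputing missing entries), drops monomorphic
#' variants, and returns the leading principal-component scores.
#'
#' @param genotypes Samples x variants dosage matrix.
#' @param k Number of components.
#' @return Matrix of scores, samples x k, columns `PC1..PCk`.
#' @export
pca_covariates <- function(genotypes, k = 5) {
  Z <- standardize_dosages(genotypes)
  k <- min(k, ncol(Z), nrow(Z) - 1L)
  sv <- svd(Z, nu = k, nv = 0)
  sc <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  dimnames(sc) <- list(rownames(genotypes), paste0("PC", seq_len(k)))
  sc
}

# Mean-impute missing, center/scale columns, drop zero-variance variants.
standardize_dosages <- function(genotypes) {
  G <- genotypes
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  s <- apply(G, 2, stats::sd)
  keep <- which(s > 0)
  scale(G[, keep, drop = FALSE])
}
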