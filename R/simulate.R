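## Synthetic-cohort generator. Every downstream stage (CN estimation,
## imputation, association, modifier scan, MR) is exercised against cohorts
## produced here, with full truth tables recorded alongside.

#' Simulation configuration
#'
#' Defaults encode the study conditions: ancestry-specific diploid KIV2-CN
#' distributions (African-ancestry mean 38.5, SD 7.4; European-ancestry mean
#' 43.7, SD 6.2), diploid CN bounded to \[12, 85\], an inverse per-copy
#' phenotype effect of -0.07 SD/CN, 30x sequencing coverage, and SNPs tagging
#' 60% of CN variance (the information ceiling of the imputation panel).
#'
#' @param n_samples Samples per cohort.
#' @param n_variants SNPs in the simulated locus window.
#' @param window Locus window (1-based, bp) variants are placed in; defaults
#'   to the ~4 Mb region around LPA used for panel training and scans.
#' @param chrom Chromosome label.
#' @param ancestry One of `"european"`, `"african"`; sets the CN distribution.
#' @param cn_mean,cn_sd Diploid CN mean/SD; default from `ancestry`.
#' @param cn_bounds Diploid CN clipped to this range.
#' @param n_backbones Size of the backbone haplotype pool (LD generator).
#' @param switch_rate Per-site probability a haplotype switches backbone
#'   (mosaic recombination; larger = faster LD decay).
#' @param mutation_rate Per-site allele flip probability on top of the
#'   backbone copy.
#' @param n_tag_snps Number of causal CN-tagging SNPs near the repeat.
#' @param tag_r2 Target fraction of diploid-CN variance explained by the
#'   tagging SNPs, in \[0, 1).
#' @param beta_cn Phenotype effect per diploid copy, SD units (negative:
#'   more copies, less Lp(a)).
#' @param n_causal_snps,snp_beta_sd Number of SNPs with direct phenotype
#'   effects (acting beyond CN) and the SD of their effect sizes.
#' @param interaction_variants,interaction_betas Optional variant indices and
#'   interaction coefficients (SD per allele per copy) for variant-by-CN
#'   modifier effects.
#' @param age_beta,sex_beta Covariate effects on the latent phenotype.
#' @param resid_sd Residual SD of the latent phenotype.
#' @param sibling_fraction Fraction of samples paired as IBD2 siblings
#'   (sharing both locus haplotypes).
#' @param coverage Mean sequencing depth (x).
#' @param depth_dispersion Negative-binomial overdispersion d of per-bin
#'   counts (variance = mu(1+d)); 0 gives Poisson.
#' @param depth_bin_bp Bin width over which depth is averaged.
#' @param event_h0 Baseline hazard (per year) of the incident-event model.
#' @param event_loghr Log hazard ratio per phenotype SD.
#' @param event_loghr_direct Log-HR per SD of the direct SNP score, a
#'   pathway bypassing the phenotype (0 = none).
#' @param censor_time Administrative censoring horizon (years).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 2000, n_variants = 400,
                       window = c(158532140L, 162664257L), chrom = "6",
                       ancestry = c("european", "african"),
                       cn_mean = NULL, cn_sd = NULL, cn_bounds = c(12, 85),
                       n_backbones = 16, switch_rate = 0.015,
                       mutation_rate = 0.01,
                       n_tag_snps = 20, tag_r2 = 0.60,
                       beta_cn = -0.07,
                       n_causal_snps = 5, snp_beta_sd = 0.15,
                       interaction_variants = integer(0),
                       interaction_betas = numeric(0),
                       age_beta = 0.003, sex_beta = 0.05,
                       resid_sd = 0.85,
                       sibling_fraction = 0.1,
                       coverage = 30, depth_dispersion = 0.3,
                       depth_bin_bp = 100,
                       event_h0 = 0.01, event_loghr = log(1.25),
                       event_loghr_direct = 0, censor_time = 10) {
  ancestry <- match.arg(ancestry)
  if (is.null(cn_mean)) cn_mean <- c(european = 43.7, african = 38.5)[[ancestry]]
  if (is.null(cn_sd))   cn_sd   <- c(european = 6.2,  african = 7.4)[[ancestry]]
  stopifnot(cn_sd > 0, resid_sd > 0, all(cn_bounds > 0),
            tag_r2 >= 0, n_variants >= 10, n_backbones >= 1,
            length(interaction_variants) == length(interaction_betas))
  if (tag_r2 >= 1) stop("tag_r2 must be < 1")
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' Write / read a simulation configuration as YAML
#' @param config A `sim_config`.
#' @param path YAML file path.
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

## ---------------------------------------------------------------------------

#' Simulate SNP haplotypes and genotypes with blockwise LD
#'
#' Haplotypes are mosaics over a small pool of backbone haplotypes: each
#' haplotype starts from a random backbone and switches to another with
#' probability `switch_rate` at each site, then per-site mutation noise is
#' added. Reuse of backbones creates LD; switching makes it decay with
#' distance. Site frequencies are spread log-uniformly over (0.001, 0.5).
#'
#' @param config A `sim_config`.
#' @param seed Integer seed.
#' @return List: `genotypes` (n x m dosage matrix), `variants` (variant
#'   table), `haplotypes` (2n x m 0/1 matrix), `backbone_at` (2n x m backbone
#'   index active at each site).
#' @export
simulate_genotypes <- function(config, seed = 1) {
  set.seed(seed)
  n <- config$n_samples; m <- config$n_variants; B <- config$n_backbones
  if (B < 1) stop("backbone pool must be non-empty")
  pos <- sort(sample(seq(config$window[1], config$window[2]), m))
  freq <- 10^stats::runif(m, log10(0.001), log10(0.5))
  backbone <- matrix(stats::rbinom(B * m, 1, rep(freq, each = B)), nrow = B)
  nh <- 2L * n
  # vectorized mosaic: cumulative switch counts index a per-haplotype
  # sequence of backbone draws
  sw <- matrix(stats::rbinom(nh * m, 1, config$switch_rate), nrow = nh)
  sw[, 1] <- 0L
  seg <- t(apply(sw, 1, cumsum)) + 1L
  max_seg <- max(seg)
  draws <- matrix(sample.int(B, nh * max_seg, replace = TRUE), nrow = nh)
  bb_at <- matrix(draws[cbind(rep(seq_len(nh), m), as.vector(seg))], nrow = nh)
  H <- matrix(backbone[cbind(as.vector(bb_at), rep(seq_len(m), each = nh))],
              nrow = nh)
  flip <- matrix(stats::rbinom(nh * m, 1, config$mutation_rate), nrow = nh)
  H <- (H + flip) %% 2L
  G <- H[seq(1, nh, 2), , drop = FALSE] + H[seq(2, nh, 2), , drop = FALSE]
  sample_ids <- sprintf("S%04d", seq_len(n))
  variant_ids <- sprintf("var%04d", seq_len(m))
  dimnames(G) <- list(sample_ids, variant_ids)
  dimnames(H) <- list(NULL, variant_ids)
  variants <- data.frame(variant_id = variant_ids, chrom = config$chrom,
                         pos = pos, ref = "A", alt = "G",
                         info_score = 1.0, stringsAsFactors = FALSE)
  st <- allele_stats(G)
  variants$maf <- st$maf; variants$mac <- st$mac
  list(genotypes = G, variants = variants, haplotypes = H, backbone_at = bb_at)
}

#' Simulate per-haplotype repeat copy-number alleles tagged by local SNPs
#'
#' A haplotype's allelic CN is a linear combination of its alleles at
#' `n_tag_snps` causal tagging SNPs (common variants sampled within ~1.5 Mb
#' of the repeat) plus Gaussian noise, with the combination scaled so the
#' tagging SNPs explain `tag_r2` of per-haplotype CN variance exactly
#' in-sample. Diploid CN — the sum of the two allelic values — is then
#' linear in the tagging-SNP dosages, the structure a linear imputation
#' panel assumes, and is clipped to `cn_bounds`.
#'
#' @param config A `sim_config`.
#' @param geno Output of [simulate_genotypes()].
#' @param seed Integer seed.
#' @return List: `allele1`, `allele2`, `diploid_cn` (length n),
#'   `tag_variants` (ids), `tag_weights`, `realized_tag_r2` (independent
#'   regression of diploid CN on tagging dosages).
#' @export
simulate_repeat_alleles <- function(config, geno, seed = 1) {
  set.seed(seed + 1L)
  if (config$tag_r2 >= 1) stop("tag_r2 must be < 1")
  H <- geno$haplotypes
  n <- config$n_samples
  var_h <- config$cn_sd^2 / 2            # per-haplotype CN variance
  mu_h <- config$cn_mean / 2
  k <- min(config$n_tag_snps, ncol(H))
  # tagging sites: common variants sampled within ~1.5 Mb of the repeat
  # (the informative SNPs of the real panel span the surrounding megabases)
  mid <- mean(c(repeat_model()$start, repeat_model()$end))
  common <- which(geno$variants$maf >= 0.05 &
                    abs(geno$variants$pos - mid) < 1.5e6)
  if (length(common) < k)
    common <- order(geno$variants$maf, decreasing = TRUE)[seq_len(k)]
  tag_idx <- sort(sample(common, k))
  w <- stats::rnorm(k)
  u <- as.vector(H[, tag_idx, drop = FALSE] %*% w)
  if (config$tag_r2 > 0 && stats::sd(u) > 0) {
    w <- w * sqrt(config$tag_r2 * var_h) / stats::sd(u)
    u <- as.vector(H[, tag_idx, drop = FALSE] %*% w)
    u <- u - mean(u)
  } else {
    w <- numeric(k); u <- rep(0, 2 * n)
  }
  e_sd <- sqrt((1 - config$tag_r2) * var_h)
  cn_hap <- mu_h + u + stats::rnorm(2 * n, 0, e_sd)
  cn_hap <- pmax(cn_hap, config$cn_bounds[1] / 4)  # keep alleles positive
  a1 <- cn_hap[seq(1, 2 * n, 2)]; a2 <- cn_hap[seq(2, 2 * n, 2)]
  dip <- pmin(pmax(a1 + a2, config$cn_bounds[1]), config$cn_bounds[2])
  # re-apportion clipping to the alleles so dip == a1 + a2 holds exactly
  adj <- dip / (a1 + a2)
  a1 <- a1 * adj; a2 <- a2 * adj
  X <- geno$genotypes[, tag_idx, drop = FALSE]
  r2 <- if (config$tag_r2 > 0) summary(stats::lm(dip ~ X))$r.squared else 0
  list(allele1 = a1, allele2 = a2, diploid_cn = dip,
       tag_variants = geno$variants$variant_id[tag_idx],
       tag_weights = w, realized_tag_r2 = r2)
}

#' Simulate per-sample depth summaries over the repeat and control intervals
#'
#' Interval mean depth is the mean of independent per-bin counts (bin width
#' `depth_bin_bp`), each negative binomial with mean mu and variance
#' mu(1 + d); d = 0 gives Poisson and `noise = FALSE` returns the exact
#' means. Control bins have mu = coverage. Repeat-interval bins have
#' mu = (coverage / 2) x (diploid_CN + offset_B) / scale_A — the exact
#' inverse of the copy-ratio estimation transform.
#'
#' @param truth List with `diploid_cn` (e.g. from [simulate_repeat_alleles()]).
#' @param model A [repeat_model()].
#' @param config A `sim_config`.
#' @param seed Integer seed.
#' @param noise If FALSE, return expected depths exactly.
#' @return Depth-summary data frame (`sample_id`, `interval`, `mean_depth`).
#' @export
simulate_depth <- function(truth, model = repeat_model(), config, seed = 1,
                           noise = TRUE) {
  set.seed(seed + 2L)
  if (config$coverage <= 0) stop("coverage must be positive")
  cn <- truth$diploid_cn
  n <- length(cn)
  ids <- if (!is.null(truth$sample_ids)) truth$sample_ids else sprintf("S%04d", seq_len(n))
  cov <- config$coverage; d <- config$depth_dispersion
  draw_mean <- function(mu, nbins) {
    if (!noise) return(mu)
    tot <- numeric(length(mu))
    for (i in seq_along(mu)) {
      tot[i] <- if (d > 0)
        sum(stats::rnbinom(nbins, mu = mu[i], size = mu[i] / d))
      else sum(stats::rpois(nbins, mu[i]))
    }
    tot / nbins
  }
  rep_len_bp <- model$end - model$start + 1L
  rep_bins <- max(1L, rep_len_bp %/% config$depth_bin_bp)
  mu_rep <- (cov / 2) * (cn + model$offset_B) / model$scale_A
  out <- data.frame(
    sample_id = ids,
    interval = sprintf("%s:%d-%d", model$chrom, model$start, model$end),
    mean_depth = draw_mean(mu_rep, rep_bins), stringsAsFactors = FALSE)
  for (ci in seq_len(nrow(model$control_intervals))) {
    cc <- model$control_intervals[ci, ]
    nb <- max(1L, (cc$end - cc$start + 1L) %/% config$depth_bin_bp)
    out <- rbind(out, data.frame(
      sample_id = ids,
      interval = sprintf("%s:%d-%d", cc$chrom, cc$start, cc$end),
      mean_depth = draw_mean(rep(cov, n), nb), stringsAsFactors = FALSE))
  }
  out
}

#' Simulate phenotypes with CN, SNP, covariate and interaction effects
#'
#' Latent phenotype (SD scale):
#' `y = beta_cn * CN + sum(beta_j g_j) + interaction terms + age/sex effects
#'  + N(0, resid_sd)`. A right-skewed positive concentration scale is stored
#' alongside as `exp(1.1 * standardized latent + 3)` (arbitrary monotone
#' back-transform; all inference uses the rank-normalized scale).
#'
#' @param truth Output of [simulate_repeat_alleles()] plus genotypes context.
#' @param geno Output of [simulate_genotypes()].
#' @param config A `sim_config`.
#' @param seed Integer seed.
#' @return List: `phenotypes` (data frame), `snp_betas`, `causal_variants`,
#'   `snp_component` (the SNP-only part of the signal), `cn_r2` (realized
#'   variance fraction explained by CN).
#' @export
simulate_phenotypes <- function(truth, geno, config, seed = 1) {
  set.seed(seed + 3L)
  if (config$resid_sd <= 0) stop("resid_sd must be positive")
  n <- config$n_samples
  G <- geno$genotypes
  cn <- truth$diploid_cn
  betas <- numeric(ncol(G))
  if (config$n_causal_snps > 0) {
    # direct-effect SNPs: common variants away from the tagging set
    cand <- setdiff(which(geno$variants$maf >= 0.05),
                    match(truth$tag_variants, geno$variants$variant_id))
    causal <- sample(cand, min(config$n_causal_snps, length(cand)))
    betas[causal] <- stats::rnorm(length(causal), 0, config$snp_beta_sd)
  } else causal <- integer(0)
  snp_comp <- as.vector(G %*% betas)
  age <- round(stats::runif(n, 30, 75))
  sex <- stats::rbinom(n, 1, 0.5)
  fasting <- stats::rbinom(n, 1, 0.7)
  on_statin <- stats::rbinom(n, 1, 0.15)
  inter <- rep(0, n)
  if (length(config$interaction_variants)) {
    for (j in seq_along(config$interaction_variants)) {
      v <- config$interaction_variants[j]
      inter <- inter + config$interaction_betas[j] * G[, v] * (cn - mean(cn))
    }
  }
  y <- config$beta_cn * cn + snp_comp + inter +
    config$age_beta * (age - mean(age)) + config$sex_beta * sex +
    stats::rnorm(n, 0, config$resid_sd)
  z <- (y - mean(y)) / stats::sd(y)
  conc <- exp(1.1 * z + 3)
  coh <- config$ancestry
  ph <- data.frame(
    sample_id = rownames(G), lp_a = conc,
    lp_a_norm = inverse_rank_normalize(conc, coh),
    age = age, sex = sex, fasting_gt10h = fasting, on_statin = on_statin,
    cohort = coh, stringsAsFactors = FALSE)
  cn_r2 <- summary(stats::lm(y ~ cn))$r.squared
  list(phenotypes = ph, snp_betas = betas, causal_variants = causal,
       snp_component = snp_comp, latent = y, cn_r2 = cn_r2)
}

#' Designate IBD2 sibling pairs sharing both locus haplotypes
#'
#' Overwrites the second member of each pair with the first member's
#' haplotypes (hence genotypes) across the simulated window and its allelic
#' CN values, making the pair identical-by-descent on both haplotypes at the
#' locus. Call before phenotypes/depth so downstream quantities inherit the
#' sharing.
#'
#' @param config A `sim_config` (`sibling_fraction` sets how many samples
#'   are paired; must yield an even count).
#' @param geno Output of [simulate_genotypes()]; modified copy returned.
#' @param truth Output of [simulate_repeat_alleles()]; modified copy returned.
#' @param seed Integer seed.
#' @return List: `geno`, `truth`, `pairs` (two-column matrix of sample
#'   indices).
#' @export
simulate_families <- function(config, geno, truth, seed = 1) {
  set.seed(seed + 4L)
  n <- config$n_samples
  n_sib <- floor(config$sibling_fraction * n)
  if (n_sib %% 2 == 1) n_sib <- n_sib - 1L
  if (n_sib < 2) return(list(geno = geno, truth = truth,
                             pairs = matrix(integer(0), ncol = 2)))
  picked <- sample(n, n_sib)
  pairs <- matrix(picked, ncol = 2, byrow = TRUE)
  H <- geno$haplotypes; G <- geno$genotypes
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    H[c(2 * j - 1, 2 * j), ] <- H[c(2 * i - 1, 2 * i), ]
    G[j, ] <- G[i, ]
    truth$allele1[j] <- truth$allele1[i]
    truth$allele2[j] <- truth$allele2[i]
    truth$diploid_cn[j] <- truth$diploid_cn[i]
  }
  geno$haplotypes <- H; geno$genotypes <- G
  st <- allele_stats(G)
  geno$variants$maf <- st$maf; geno$variants$mac <- st$mac
  list(geno = geno, truth = truth, pairs = pairs)
}

#' Inject genotyping errors into a dosage matrix
#'
#' Each genotype is independently replaced, with probability `rate`, by a
#' different value from \{0, 1, 2\} (uniform over the other two), so a
#' corrupted entry always changes.
#'
#' @param genotypes Dosage matrix (hard calls assumed).
#' @param rate Per-genotype error probability.
#' @param seed Integer seed.
#' @return Corrupted matrix.
#' @export
inject_genotype_errors <- function(genotypes, rate, seed = 1) {
  set.seed(seed)
  G <- genotypes
  hit <- which(stats::runif(length(G)) < rate & !is.na(G))
  for (i in hit) {
    G[i] <- sample(setdiff(0:2, round(G[i])), 1)
  }
  G
}

#' Simulate incident-event times from the phenotype (and optional direct path)
#'
#' Exponential event times with hazard
#' `h0 * exp(event_loghr * y_sd + event_loghr_direct * direct_sd)` and
#' administrative censoring at `censor_time`. `direct_sd` is the standardized
#' SNP component, modelling genetic effects on the outcome that bypass the
#' phenotype.
#'
#' @param pheno_norm Rank-normalized phenotype vector.
#' @param config A `sim_config`.
#' @param seed Integer seed.
#' @param direct Optional direct-pathway score (standardized internally).
#' @return Data frame `sample_id`, `time`, `status` (1 = event).
#' @export
simulate_outcomes <- function(pheno_norm, config, seed = 1, direct = NULL) {
  set.seed(seed + 5L)
  if (config$event_h0 <= 0) stop("event_h0 must be positive")
  n <- length(pheno_norm)
  lin <- config$event_loghr * pheno_norm
  if (!is.null(direct) && config$event_loghr_direct != 0) {
    d <- (direct - mean(direct)) / stats::sd(direct)
    lin <- lin + config$event_loghr_direct * d
  }
  h <- config$event_h0 * exp(lin)
  t_event <- stats::rexp(n, rate = h)
  time <- pmin(t_event, config$censor_time)
  status <- as.integer(t_event <= config$censor_time)
  ids <- names(pheno_norm)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_len(n))
  data.frame(sample_id = ids, time = time, status = status,
             stringsAsFactors = FALSE)
}

#' Simulate a polygenic phenotype with known heritability from genotypes
#'
#' `y = Z u + e` with `u ~ N(0, h2/m)` over standardized dosages `Z` and
#' residual variance `1 - h2`; used for heritability parameter-recovery.
#'
#' @param genotypes Dosage matrix.
#' @param h2 Target narrow-sense heritability in \[0, 1\].
#' @param seed Integer seed.
#' @return Numeric phenotype vector (named by sample).
#' @export
simulate_polygenic_phenotype <- function(genotypes, h2, seed = 1) {
  stopifnot(h2 >= 0, h2 <= 1)
  set.seed(seed)
  Z <- standardize_dosages(genotypes)
  m <- ncol(Z)
  u <- stats::rnorm(m, 0, sqrt(h2 / m))
  g <- as.vector(Z %*% u)
  # rescale the realized genetic component to hit h2 exactly in-sample
  if (h2 > 0 && stats::sd(g) > 0) g <- g / stats::sd(g) * sqrt(h2)
  y <- g + stats::rnorm(nrow(Z), 0, sqrt(1 - h2))
  names(y) <- rownames(genotypes)
  y
}

#' Simulate a full cohort bundle with truth tables
#'
#' Runs the generator end to end: genotypes, repeat alleles, sibling pairs,
#' depth, phenotypes, and a sibling-aware kinship matrix (identity plus 0.5
#' between pair members — IBD2 siblings at minimum share half their genome).
#'
#' @param config A `sim_config`.
#' @param seed Integer seed governing every random draw.
#' @param model A [repeat_model()] for the depth simulation.
#' @return List: `bundle` (a `cohort_bundle`), `truth` (allelic CN, betas,
#'   interaction terms, families, realized variance fractions, config).
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1,
                            model = repeat_model()) {
  geno <- simulate_genotypes(config, seed)
  alle <- simulate_repeat_alleles(config, geno, seed)
  fam <- simulate_families(config, geno, alle, seed)
  geno <- fam$geno; alle <- fam$truth
  alle$sample_ids <- rownames(geno$genotypes)
  depth <- simulate_depth(alle, model, config, seed)
  ph <- simulate_phenotypes(alle, geno, config, seed)
  ph$phenotypes$kiv2_cn_true <- alle$diploid_cn
  n <- config$n_samples
  K <- diag(n)
  if (nrow(fam$pairs)) {
    K[fam$pairs] <- 0.5
    K[fam$pairs[, c(2, 1), drop = FALSE]] <- 0.5
  }
  dimnames(K) <- list(rownames(geno$genotypes), rownames(geno$genotypes))
  bundle <- cohort_bundle(geno$genotypes, geno$variants, ph$phenotypes,
                          depth = depth, kinship = K)
  truth <- list(allele1 = alle$allele1, allele2 = alle$allele2,
                diploid_cn = alle$diploid_cn,
                tag_variants = alle$tag_variants,
                tag_weights = alle$tag_weights,
                realized_tag_r2 = alle$realized_tag_r2,
                snp_betas = ph$snp_betas,
                causal_variants = ph$causal_variants,
                snp_component = ph$snp_component,
                latent = ph$latent,
                cn_r2 = ph$cn_r2,
                interaction_variants = config$interaction_variants,
                interaction_betas = config$interaction_betas,
                pairs = fam$pairs,
                haplotypes = geno$haplotypes,
                config = config, seed = seed)
  list(bundle = bundle, truth = truth)
}

#' Write a simulated cohort (bundle + truth table + config) to a directory
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulated_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_cohort(sim$bundle, file.path(dir, "cohort.vcf"))
  truth <- data.frame(sample_id = rownames(sim$bundle$genotypes),
                      allele1 = sim$truth$allele1,
                      allele2 = sim$truth$allele2,
                      diploid_cn = sim$truth$diploid_cn)
  tp <- file.path(dir, "truth.tsv")
  utils::write.table(truth, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  cp <- file.path(dir, "sim_config.yaml")
  write_sim_config(sim$truth$config, cp)
  invisible(c(paths, truth = tp, config = cp))
}
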