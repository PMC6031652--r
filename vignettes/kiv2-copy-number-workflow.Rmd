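---
title: "Estimating, imputing, and modelling KIV2 repeat copy number"
author: "kiv2cn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating, imputing, and modelling KIV2 repeat copy number}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kiv2cn)
```

## The problem

The apolipoprotein(a) gene *LPA* contains a tandemly repeated exon pair —
the kringle IV type 2 (KIV2) domain — whose copy number varies from about
5 to more than 40 per haplotype. Total diploid copy number (KIV2-CN) is
inversely related to circulating lipoprotein(a), differs between
ancestries, and is invisible to SNP arrays. This package implements a
complete desk-scale workflow around that variant: estimating KIV2-CN from
sequencing depth, imputing it from SNPs, conditioning association scans on
it, scanning for variants that modify its phenotype slope, and using it in
Mendelian-randomization instruments. Everything is exercised on synthetic
cohorts with recorded truth, because the real cohorts behind this design
are access-controlled.

## Read-depth estimation

Aggregate read depth over the repeat interval grows linearly with the
number of repeat units, while depth over diploid control regions tracks
sample-level coverage. We define the diploid copy ratio

$$\rho = \frac{2\,\bar d_{\text{repeat}}}{\bar d_{\text{control}}},$$

with the control mean pooled across control intervals weighted by length,
so a sample with the reference repeat structure has $\rho = 2$. The domain
count is then the affine transform

$$\widehat{\text{KIV2-CN}} = \rho \times 6.354 - 0.708 .$$

The multiplier reflects the number of full repeat units represented in the
reference interval; the offset removes the flanking KIV1/KIV3 exons that
aggregate depth picks up through homology. Both are configuration
constants in `repeat_model()`, never recomputed; with the defaults the
reference-like diploid sample maps to exactly 12 domains. Two repeat
intervals circulate for this locus (a discovery interval and a slightly
narrower genotyping interval); `repeat_model()` defaults to the genotyping
interval and accepts either. Negative estimates are retained and flagged
rather than clamped, so downstream diagnostics see the raw estimator.

Precision is audited with IBD2 sibling pairs: pairs whose genotype
discordance across the locus window is strictly below 1% share both
haplotypes, hence their true CN, so the squared correlation between the
two members' estimates isolates measurement noise. Pair order is
randomized before correlating to avoid ordering artifacts.

## The synthetic cohorts

`sim_config()` encodes the study conditions as defaults:

| parameter | default | meaning |
|---|---|---|
| `cn_mean`, `cn_sd` | 38.5/7.4 (African), 43.7/6.2 (European) | diploid CN distribution per ancestry |
| `cn_bounds` | [12, 85] | observed diploid CN range |
| `beta_cn` | −0.07 | phenotype SD per diploid copy |
| `tag_r2` | 0.60 | CN variance explained by local SNPs |
| `coverage` | 30 | mean sequencing depth (×) |
| `depth_dispersion` | 0.3 | negative-binomial overdispersion of bin counts |
| `sibling_fraction` | 0.10 | samples paired as IBD2 siblings |
| `event_loghr` | log 1.25 | hazard per phenotype SD |

Genotypes are mosaics over a small pool of backbone haplotypes with
per-site switching and mutation noise — a phenomenological LD model that
yields blockwise correlation decaying with distance, without coalescent
machinery. Allelic CN is a linear combination of haplotype alleles at a
set of common tagging SNPs near the repeat, scaled so the tagging set
explains `tag_r2` of CN variance exactly in-sample, plus Gaussian noise;
the diploid value is the allele sum, clipped to `cn_bounds` (with the clip
re-apportioned so the allele identity `CN = a1 + a2` stays exact). We
chose the linear-in-SNPs construction over a backbone-mean construction
because it makes the diploid CN exactly linear in dosages — the structure
a linear imputation panel assumes — and because empirically a LASSO
recovers far less of a categorical backbone signal, which would conflate
generator idiosyncrasy with panel performance.

Depth summaries are means of per-100-bp-bin counts, each negative binomial
with variance $\mu(1+d)$ (Poisson at $d=0$); the repeat-interval bin mean
is $(\text{coverage}/2)(\text{CN} + 0.708)/6.354$ — the exact inverse of
the estimation transform, so the noise-free path is exactly invertible. We
deliberately model binned counts rather than one draw per interval: a
single draw would put ~10% noise and a visible ratio bias on the copy
ratio, which is not how interval-mean summaries behave.

Sibling pairs are created by copying one member's haplotypes and allelic
CN onto the other across the simulated window (the window *is* the locus,
so this realizes locus-IBD2); the bundled kinship matrix sets 0.5 between
members. Phenotypes sit on a latent SD scale with CN, SNP, covariate, and
optional interaction terms plus Gaussian residual; a right-skewed
concentration scale (`exp` of the standardized latent) is stored alongside
purely for realism, since all inference runs on the rank-normalized scale.
Event times are exponential with hazard
$h_0 \exp(\gamma y + \gamma_d s)$, where $s$ is an optional direct SNP
pathway bypassing the phenotype — the mechanism that makes a GRS
instrument outperform a CN instrument per phenotype SD.

What the generator does **not** emulate: genotyping error (except when
injected), imputation uncertainty (INFO is 1.0 for simulated variants),
population stratification, GC bias in depth, allelic series beyond two
ancestries, and real LD topology. Tests passing here show the estimators
are correct and calibrated under these conditions, not that real-data
performance figures transfer.

## Phenotype preparation

`inverse_rank_normalize()` maps values to
$\Phi^{-1}((r - 0.5)/n)$ within each cohort, with average ranks for ties.
The half offset is symmetric (output mean exactly 0); the tie and offset
conventions are our choice, recorded here because published pipelines
rarely state them. Statin users' total cholesterol is divided by 0.8 and
directly measured LDL by 0.7 before normalization, undoing the average
on-treatment reduction.

## Imputation panel

The protocol is: 2:1 train/validate split (sibling pairs never straddle
the split — shared locus haplotypes would leak), candidate filtering
(4 Mb window, MAF > 0.001, imputation quality > 0.8), greedy sliding-window
LD pruning (50 variants, step 5, r² ≤ 0.25), then a LASSO on the
*estimated* CN (as in production use; truth appears only in test oracles)
with lambda minimizing 10-fold cross-validated MSE over a 100-point
log-spaced path spanning four decades below the all-zero lambda. The
standardization convention and path grid are our choices; they are
recorded as such. Pruning needs a tie-break the published tooling leaves
implicit: we drop the later variant in position order by default, with a
lower-MAF alternative behind a switch. Selected variants are re-ranked by
random-forest impurity importance (normalized to sum 1) purely for
interpretation; prediction always uses the linear panel.

Held-out validation r² sits slightly below the generator's tagging r²:
pruning caps proxy information at r² 0.25 and the LASSO pays an estimation
penalty for selecting ~70 coefficients from ~270 candidates at n ≈ 1400.
The acceptance suite therefore compares the *mean* held-out r² across
seeds against the 0.60 target with a ±0.07 band.

## Association and heritability

The OLS scan residualizes phenotype and dosage on the covariates once and
solves each variant in closed form — it is exact least squares, verified
against a normal-equations oracle at 10⁻⁸ relative tolerance. The LMM mode
rotates by the kinship eigendecomposition, profiles a single variance
ratio under the null, and runs per-variant weighted least squares; with an
identity kinship it reproduces OLS. A per-variant ratio refit would be
more faithful at strong polygenicity but is unnecessary at desk scale.
Iterative conditioning adds the current top variant as a covariate until
no p-value clears 5×10⁻⁸, with ties broken by position and a 50-iteration
guard.

Meta-analysis is inverse-variance fixed effects with Cochran's Q and a
χ²(k−1) heterogeneity p. Heritability uses Haseman–Elston regression of
phenotype cross-products on off-diagonal GRM entries — closed-form and
robust at small n, where REML machinery would be heavier than the problem
warrants — with variants filtered (MAF > 0.001, missingness < 1%),
LD-pruned at r² 0.9, a delete-one-block jackknife SE over 20 sample
blocks, and the estimate clipped to [0, 1]. A region-mask hook exists for
excluding high-LD complexity regions from the GRM; with synthetic data it
defaults to empty. Kinship thinning in the reference pipelines is random
down-sampling; where thinning matters here it is deterministic by index.

## Modifier scan and multiplicity

The interaction model is fixed-effects OLS (no kinship term), with CN
centered so main effects stay interpretable, restricted to variants with
MAC strictly above 20. Multiplicity is controlled by greedy LD clumping
(500 kb, r² 0.25, p1 = p2 = 1) and a Bonferroni threshold of
0.05 / n_clumps: with the published clump counts this reproduces
3.64×10⁻⁵ (1373 clumps) and 8.83×10⁻⁵ (566 clumps) exactly. Top hits then
face three sensitivity checks: squared Pearson correlation with CN below
0.1 (not a CN proxy), marginal phenotype association at p < 0.05, and a
re-estimated interaction conditioning on the independent main-effect hits.
Interaction meta-analysis is inverse-variance weighted; the reference
tooling leaves the weighting scheme ambiguous and we record this choice.

## Instruments and Mendelian randomization

Three instruments: a GRS over clumped sub-threshold variants
(p < 10⁻⁴ within the locus window) weighted by CN-*adjusted* effect sizes;
a KIV2-CN score (the estimated or imputed CN itself); and their sum. Each
is inverse-rank normalized, and the scale factor is the OLS slope of the
rank-normalized calibration phenotype on the normalized score, so that by
construction a one-unit change in the final instrument corresponds to one
phenotype SD (the calibration identity — refit slope exactly 1 — is
asserted in tests for all three types). The published multiplicative
factors live in supplementary material we do not reproduce; this
calibration rule is our stated reconstruction of "1 unit = 1 SD". The
inverse CN–phenotype relation makes the CN score's factor negative, which
orients the final instrument positively. GRS weights are cohort-specific
(the source of weights is ambiguous in the reference design; a config
switch covers the meta-analyzed alternative). Outcome models are Cox
partial likelihood with Breslow ties (≥20 events required, Wald CI) and
OLS for quantitative outcomes, with PCs/age/sex/fasting as covariates; PCs
come from a truncated SVD of standardized dosages, which is adequate for
synthetic cohorts.

## Numerical choices and degenerate inputs

* Missing dosages: masked in allele statistics; mean-imputed inside
  regressions and score construction (twice-MAF substitution in the GRS),
  always with a message.
* Monomorphic or covariate-collinear variants: skipped with NA statistics,
  never silently dropped from the output table.
* Constant CN, empty candidate sets, all-censored event tables, sub-floor
  IBD2 pair counts, uninformative instruments (|slope| < 0.01): explicit
  errors.
* All seeds flow from a single integer per operation; the full generator
  is byte-identical under a fixed seed.

## Problem sizes

The bundled analyses and tests run cohorts of 700–2100 samples with
120–300 variants, 10–42 replicate scans for calibration checks, and 20
seeds for the directional MR property — sizes chosen so the whole suite
exercises every stage in a few minutes on one core while keeping Monte
Carlo bands comfortably inside the asserted tolerances.

## Known limitations

* Allelic (per-haplotype) CN is observable in truth tables but not
  estimable from aggregate depth — exactly the limitation of the
  read-depth design; the allelic-composition test exists to show the
  diploid sum is the operative quantity.
* The LMM profiles one variance ratio under the null; strong polygenic
  signal plus strong relatedness would call for per-variant refits.
* Haseman–Elston trades efficiency for robustness; its SE is jackknife,
  not analytic.
* The copy-ratio constants are calibrated to the hg19 reference layout;
  other builds need their own `repeat_model()`.
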