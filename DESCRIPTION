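Package: kiv2cn
Title: Kringle IV-2 Repeat Copy Number Estimation, Imputation, and Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Workflow for the LPA kringle IV-2 (KIV2) tandem-repeat copy
    number (CN): read-depth CN estimation via a calibrated copy-ratio
    transform, precision assessment with IBD2 sibling pairs, a sparse
    (LASSO) SNP panel that imputes CN from genotypes, CN-conditioned
    single-variant association with iterative conditioning and
    fixed-effects meta-analysis, variant-by-CN modifier scans with
    LD-clump multiplicity control and sensitivity checks, and CN-aware
    genetic instruments for Mendelian randomization against incident and
    quantitative outcomes. Includes a synthetic-cohort generator with
    full truth tables (SNP haplotypes in LD with a multi-allelic repeat
    allele, ancestry-specific CN distributions, depth proportional to
    copy count, inverse CN-phenotype effects, IBD2 sibling pairs, and
    event times) so every stage is testable without access-controlled
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    ranger,
    survival,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
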