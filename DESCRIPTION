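Package: rarescan
Title: Sparse Genotype Storage and Fast Residualized Association Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Storage and regression tools for population-scale sequencing
    association studies. Provides a compact binary genotype container that
    stores rare variants as sparse difflists of (sample index, genotype)
    pairs and common variants as packed 2-bit arrays, with an importer for
    PLINK 1 BED/BIM/FAM filesets. Association scans run per-variant least
    squares through a block-matrix fast path that consumes sparse records
    directly, in O(p(k+p)) arithmetic for a variant carried by k samples.
    Residualized modes fit covariates once up front: a quantitative mode
    that regresses covariate residuals on genotype with exact subtractive
    handling of missing genotypes, and a case-control mode that freezes
    covariate effects as a fixed offset in per-variant logistic fits with
    automatic Firth-penalized fallback under separation. Multi-phenotype
    scans and an SVD-based phenotype-reduction preprocessor are included,
    along with a synthetic cohort generator with a rare-variant-skewed
    site-frequency spectrum and known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
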