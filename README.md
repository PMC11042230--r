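# rarescan

Sparse genotype storage and fast residualized association scans for
population-scale sequencing studies.

Sequencing cohorts are dominated by rare variants: most genotype columns
are almost entirely zero, yet conventional pipelines store every variant as
a full length-n array and refit a full regression model per variant.
`rarescan` attacks both costs:

* **Storage** — an `.sgen` binary container that stores a rare variant as a
  *difflist* of (sample index, genotype) pairs: 5 body bytes per nonzero
  entry plus a 4-byte directory entry, versus `ceiling(n/4)` bytes for a
  packed 2-bit dense record. A singleton carrier among 400,000 samples
  costs 5 bytes instead of 100,000. Whichever encoding is smaller is chosen
  per variant, and a PLINK 1 BED/BIM/FAM importer is included.
* **Regression** — per-variant least squares through a block-matrix fast
  path. With `X = [Xc g]`, the covariate block `A = Xc'Xc`, its inverse,
  `Xc'y` and `y'y` are computed once; finishing `(X'X)^{-1}` for a variant
  with k carriers needs only `B = Xc'g`, `D = g'g` and the Schur complement
  `F = D − B'A⁻¹B` — O(p(k+p)) arithmetic per variant, consuming the
  difflist directly and never materializing a dense genotype column. From
  `b̂` and `RSS = y'y − y'Xb̂` come the standard error, t statistic and
  p-value.
* **Residualized modes** — `qt-residualize` fits covariates once and runs
  p = 2 (intercept + genotype) fits on the residuals, with exact
  subtractive handling of missing genotypes; `cc-residualize` freezes the
  covariate-only logistic linear predictor as an offset for per-variant
  intercept + genotype fits, with automatic Firth-penalized fallback under
  separation (`firth-fallback` is also available as the full per-variant
  reference).
* **Multi-phenotype** — simultaneous scans that share per-variant algebra
  across phenotypes with a common sample mask, and `pheno_svd()`, which
  reduces a correlated phenotype matrix to the minimal number of SVD
  components reaching a requested variance-explained fraction before
  scanning.
* **Simulation** — a synthetic cohort generator with a rare-skewed site
  frequency spectrum, configurable missingness, and quantitative/binary
  phenotypes with known ground truth.

## Worked example

```r
library(rarescan)

spec <- cohort_spec(n_samples = 2000, n_variants = 1000, n_causal = 3,
                    causal_beta = 0.6, causal_maf = 0.02, seed = 42)
sim <- simulate_cohort(spec, out_prefix = file.path(tempdir(), "demo"))
fs <- sgen_open(sim$prefix)
fs
#> sgen_fileset: 1000 variants x 2000 samples; 985 sparse, 15 dense

ctx <- design_context(sim$covariates)
cache <- build_cache(ctx, sim$pheno_qt)
res <- scan(fs, ctx, cache)
head(res[order(res$P), c("ID", "N", "BETA", "SE", "T_STAT", "P", "PATH")], 5)
#>         ID    N       BETA        SE    T_STAT            P   PATH
#> 956 var956 2000  0.7252095 0.1044869  6.940675 5.262626e-12 sparse
#> 298 var298 2000  0.7757553 0.1124670  6.897623 7.080522e-12 sparse
#> 634 var634 2000  0.4453990 0.1236522  3.602031 3.234919e-04 sparse
#> 4     var4 2000 -1.2145087 0.4050302 -2.998563 2.746208e-03 sparse
#> 459 var459 2000  1.5734570 0.5733801  2.744178 6.120779e-03 sparse

sim$truth
#>   variant index  maf beta
#> 1  var298   298 0.02  0.6
#> 2  var634   634 0.02  0.6
#> 3  var956   956 0.02  0.6
```

The three planted causal variants (per-copy effect 0.6 at MAF 0.02) top the
scan, each estimate within sampling error of the truth, and 985 of 1,000
rare variants took the sparse fast path. The fileset occupies 75,428 bytes
where an all-dense layout would need 504,018. The residualized mode tracks
the full model almost exactly on this cohort:

```r
rr <- qt_residualize_scan(fs, ctx, sim$pheno_qt)
ok <- res$STATUS == "OK" & rr$STATUS == "OK"
cor(-log10(res$P[ok]), -log10(rr$P[ok]))^2
#> [1] 0.9999972
```

## Command line

A thin wrapper over the same functions is installed at
`system.file("cli", "rarescan", package = "rarescan")`:

```sh
rarescan convert  --bed cohort --out cohort_sparse
rarescan simulate --spec spec.json --out sim
rarescan glm --geno sim --pheno sim_pheno.tsv --pheno-name QT \
             --covar sim_covar.tsv --qt-residualize --out assoc.tsv
```

Association output is tab-delimited with one row per variant (CHROM, POS,
ID, REF, ALT, N, BETA, SE, T_STAT/Z_STAT, P, STATUS, and for binary traits
OR and ENGINE), modeled on PLINK 2's `.glm` files.

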