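---
title: "Sparse genotype storage and fast residualized association scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse genotype storage and fast residualized association scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarescan)
```

## The problem

Whole-genome and exome sequencing cohorts now contain hundreds of thousands
of samples and upwards of a billion discovered variants, the overwhelming
majority of them rare (minor allele frequency below 1%). Two costs dominate
association analysis at that scale: storing the genotype matrix, and
refitting a regression model once per variant. Both costs are mostly wasted
on rare variants, because a rare variant's genotype column is almost
entirely zero. `rarescan` implements a storage format and a set of
regression engines that exploit that sparsity end to end: rare variants are
stored as short difflists, and the per-variant least-squares algebra
consumes those difflists directly without ever expanding them to length-n
arrays.

## The storage model

A diploid biallelic genotype is coded additively as 0, 1 or 2 copies of the
alternate allele, with 3 as a distinct missing sentinel (never conflated
with 0). An `.sgen` fileset stores each variant in whichever of two record
encodings is smaller:

* **Dense**: a packed array of n 2-bit codes, `ceiling(n/4)` bytes, sample 0
  in the lowest-order bit pair of byte 0 (the PLINK 1 bit order).
* **Sparse (difflist)**: an ordered list of (sample index, code) pairs for
  every sample whose code is nonzero — carriers and missing genotypes. Each
  entry costs 5 bytes: a 4-byte little-endian unsigned index plus a code
  byte. A singleton among 400,000 samples therefore occupies 5 body bytes
  instead of 100,000.

Each variant also contributes exactly 4 bytes to the file's record
directory: one record-type byte (values beyond dense/sparse are reserved,
e.g. for future LD-compressed or dosage records, which this package does
not implement) and a 3-byte little-endian body length. The 3-byte length
field caps a single record at 16 MiB; that bound can only bind for dense
records of more than ~67 million samples, far beyond the target scale, and
sparse records shrink long before it matters. The global header is 2 magic
bytes plus the variant and sample counts as 8-byte little-endian unsigned
integers; variant and sample metadata live in sidecar text files (`.svar`,
`.ssam`) in the BIM/FAM dialects, mirroring the PLINK ecosystem's split
between binary genotypes and text metadata.

`choose_encoding()` picks sparse exactly when `5k < ceiling(n/4)` for a
variant with `k` nonzero entries — i.e. whenever it is strictly smaller, so
total body size is never worse than all-dense. Ties go dense because the
dense decoder is simpler and there is nothing to save.

The BED importer translates PLINK 1's 2-bit patterns (where `01` is the
missing code) into the internal coding; genotypes round-trip exactly,
including missingness.

## The regression model

For a quantitative phenotype `y` (n×1) and design `X = [Xc g]` — `Xc` an
intercept plus covariates, `g` the genotype column — the per-variant least
squares solution is `b = (X'X)^{-1} X'y` with `RSS = y'y − y'Xb`; the
genotype standard error, t statistic and two-sided Student-t p-value (df =
n_used − p) follow from those two quantities.

The fast path rests on the partitioned structure of `X'X`. With
`A = Xc'Xc` and its inverse computed once per scan:

* `B = Xc'g` and `g'y` need only the k difflist entries: O(kp);
* `D = g'g` needs O(k);
* the Schur complement `F = D − B'A^{-1}B` and the 2×2 block-inverse
  identity complete `(X'X)^{-1}` in O(p²);

so one variant costs O(p(k+p)) arithmetic instead of O(np²), and the
genotype column is never materialized. `Xc'y` and `y'y` are likewise cached.
The package asserts this work-avoidance structurally: every result records
how many genotype entries were touched, and the sparse path's count equals
k, never n. Agreement with the dense reference path is enforced by
property tests to 1e-8 relative in the coefficient and standard error.

Variants with missing genotypes cannot reuse `A^{-1}` (each missingness
pattern changes `Xc'Xc`), so the scan routes them to the dense path, which
drops the missing rows for that variant only. When several phenotypes cover
exactly the same samples, the per-variant blocks `B`, `D`, `F` are shared
across phenotype columns and only `g'y` is recomputed.

## Residualized modes

**Quantitative (`qt_residualize_scan`)**: the phenotype is regressed on the
covariates once; per-variant fits then regress the residuals on intercept +
genotype only (p = 2). With p = 2 a missing genotype is cheap to handle
exactly: the precomputed totals n, Σr and Σr² are corrected by subtracting
each missing sample's contribution, keeping the whole fit O(k) while
remaining equal (to 1e-8) to a dense regression on the observed subset.
Sums are accumulated through R's extended-precision (long double) `sum()`,
which absorbs the cancellation risk of the subtractive updates at desk
scale. The residualized fit is an approximation to the full model — it
spends n−2 rather than n−p degrees of freedom and ignores finite-sample
correlation between genotype and covariates — so its p-values track but do
not exactly equal the full model's; the acceptance suite quantifies the
agreement (R² of −log10 p above 0.999 on a 2,000-sample null-covariate
cohort).

**Case-control (`cc_scan`)**: the analogous construction for a binary
trait. The covariate-only logistic model is fitted once and its linear
predictor frozen as a per-sample offset; each variant then fits only
intercept + genotype by Newton iteration with that offset. The intercept is
refitted per variant rather than frozen with the covariates — the frozen
covariate effects already absorb the phenotype scale, and refitting the
intercept lets each variant's fit recenter under genotype-driven
prevalence shifts; freezing it too would be the other defensible reading.
The reference is `firth-fallback`: a full per-variant logistic fit that
refits with the Firth penalty `l(b) + log|I(b)|/2` when the plain fit fails
to converge within 25 Newton iterations, any coefficient passes 50 in
magnitude, or a fitted probability pins to within 1e-6 of 0 or 1. The pin
threshold doubles as the separation detector: under separation the score
shrinks as probabilities saturate, so a score-based convergence test alone
would silently accept a diverging fit. All binary-trait tests are Wald
tests (penalized-Wald under Firth); a likelihood-ratio alternative was
deliberately not implemented, and this is the main place where p-values
could diverge from other GWAS tools' internals.

Newton iterations converge when the maximum absolute score drops below
1e-8 or the largest coefficient change below 1e-10, with up to 10 step
halvings on a penalized-likelihood decrease; Firth fits get a doubled
iteration budget (50) because the penalty flattens the likelihood near
separation and the last few digits arrive slowly.

## Multi-phenotype reduction

Deep-phenotype matrices are often strongly correlated, so scanning each
column separately repeats work. `pheno_svd()` drops rows with any missing
phenotype, standardizes each column to mean 0 and unit variance (so
variance-explained fractions are scale-free — the raw-scale alternative
would let a single high-variance trait dominate the component count), and
keeps the smallest d leading components whose cumulative squared singular
values reach the requested threshold. Component signs are fixed by making
each component's largest-magnitude loading positive, so output is
deterministic across LAPACK builds. `scan_reduced()` then scans the d score
columns like ordinary phenotypes — 50 duplicated phenotypes collapse to one
component and one scan. Covariate adjustment happens inside the component
scan (reduction first, residualization second); applying the SVD to
already-residualized phenotypes is the alternative ordering and would give
slightly different components when covariates differ in effect across
traits. Back-projection of component effect sizes onto the original traits
is out of scope; the loadings are written out for interpretation.

## The synthetic cohort generator

`simulate_cohort()` emulates the inputs the engines are built for, directly
in sparse form: per-variant genotypes i.i.d. binomial(2, MAF) across
samples (Hardy-Weinberg), a site-frequency spectrum that is log-uniform on
[5e-4, 0.01] for 99% of variants (matching the "rare" = MAF < 1% regime
that dominates sequencing studies) with 1% common variants uniform on
[0.05, 0.5], MCAR missingness, Gaussian covariates, quantitative traits as
covariate + genotype effects + Gaussian noise, and binary traits from a
logistic model whose intercept is bisected to the requested expected case
fraction (±0.005). Under the default spectrum more than 95% of variants
are stored sparse, so the fast path is exercised as the dominant route.

What the generator does **not** emulate — and what passing tests therefore
do not establish — includes linkage disequilibrium, population structure
and relatedness, informative (non-MCAR) missingness, dosage genotypes and
multiallelic sites. Per-variant regression correctness does not depend on
LD or structure, but genome-wide significance behavior on real data does;
the calibration results here speak to the arithmetic, not to confounding.

## Numerical choices and problem sizes

* Singularity: the sparse path flags a variant when `F ≤ 1e-12·max(D, 1)`
  (monomorphic or collinear genotype); the dense path flags failure of the
  normal-equations solve, a constant genotype, or `n_used ≤ p`.
* RSS is clamped at 0; an exactly fitting phenotype yields a zero standard
  error and p = 0 rather than NaN.
* All scans are serial and deterministic; variants are independent work
  units, so any parallel schedule would have to preserve directory order to
  honor the same contract (the CLI accepts `--threads` for interface
  compatibility without using it).
* Test problem sizes were chosen to make every statistical check
  well-powered while staying desk-sized: oracle equivalence over 1,000
  random designs up to n = 2000 and 21 predictors; subtractive-correction
  exactness over 500 random missingness patterns; fidelity cohorts of
  2,000 samples × 5,000 variants (quantitative) and × 1,500 variants
  (case-control); calibration on null cohorts of 12,000 variants per
  regression path, giving a 99% binomial CI of ±0.0056 around the nominal
  0.05.
* Binary-trait calibration cohorts use MAF ∈ [0.02, 0.2]: Wald logistic
  calibration is an asymptotic property that requires non-trivial carrier
  counts, and at a minor allele count of a few units no Wald-type test is
  uniform (saddlepoint or exact methods exist for that regime and are out
  of scope). The quantitative t-test needs no such restriction — it is
  exact under Gaussian noise for any genotype distribution — so the
  quantitative null cohorts keep the default rare spectrum.

## Known limitations

Multiallelic variants, phase, dosage and LD-based record compression are
not representable (record-type codes are reserved for them); the binary
format is a dialect, not byte-compatible with other tools' files. The
residualized modes are approximations whose agreement with the full model
degrades when covariates are correlated with genotype — they should be
validated against the full model on a subset whenever covariate-genotype
dependence is suspected. Standard errors are not robustified, and no
multiple-testing correction is applied: raw p-values are reported, as is
standard for GWAS scans.
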