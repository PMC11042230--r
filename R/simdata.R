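# Synthetic cohort generator.
#
# Emulates a sequencing-study cohort: biallelic variants drawn under
# Hardy-Weinberg equilibrium from a site-frequency spectrum heavily skewed
# to rare variants (log-uniform minor-allele frequencies, most below 1%),
# MCAR genotype missingness, Gaussian covariates, quantitative phenotypes as
# covariate + genotype effects + Gaussian noise, and binary phenotypes from
# a logistic model whose intercept is tuned by bisection to a requested case
# fraction. Genotypes are generated directly in sparse form. No linkage
# disequilibrium or population structure is simulated: per-variant
# regression correctness does not depend on either.

#' Specify a synthetic cohort
#'
#' Defaults describe a rare-variant-dominated cohort: 99% of variants with
#' minor-allele frequency log-uniform on `[5e-4, 0.01]` ("rare" = MAF < 1%)
#' and 1% common variants uniform on `[0.05, 0.5]`, no missingness, ten
#' standard-normal covariates with effects drawn once from N(0, 0.25), unit
#' noise, and no causal variants.
#'
#' @param n_samples,n_variants Cohort dimensions.
#' @param maf_range Log-uniform MAF range for the rare component.
#' @param common_frac Fraction of variants drawn from the common component.
#' @param common_maf_range Uniform MAF range for the common component.
#' @param missing_rate Per-genotype MCAR missing probability.
#' @param n_covariates Number of standard-normal covariates.
#' @param covar_sd Standard deviation of covariate effect sizes.
#' @param n_causal Number of causal variants (0 for a null cohort).
#' @param causal_beta Per-copy effect size(s) of causal variants, recycled.
#' @param causal_maf Optional fixed MAF for causal variants (otherwise drawn
#'   from the spectrum like any other variant).
#' @param noise_sd Residual standard deviation of the quantitative trait.
#' @param case_fraction Target case fraction for the binary trait in (0, 1),
#'   or `NULL` to skip the binary trait.
#' @param seed Integer seed; fully determines the cohort.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples, n_variants,
                        maf_range = c(5e-4, 0.01),
                        common_frac = 0.01,
                        common_maf_range = c(0.05, 0.5),
                        missing_rate = 0,
                        n_covariates = 10,
                        covar_sd = 0.5,
                        n_causal = 0,
                        causal_beta = 0.5,
                        causal_maf = NULL,
                        noise_sd = 1,
                        case_fraction = NULL,
                        seed = 1L) {
  rates <- c(missing_rate, common_frac)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (!is.null(case_fraction) && (case_fraction <= 0 || case_fraction >= 1)) {
    stop("case_fraction must lie strictly between 0 and 1")
  }
  if (n_causal > n_variants) stop("more causal variants than variants")
  structure(as.list(environment()), class = "cohort_spec")
}

draw_mafs <- function(spec) {
  m <- spec$n_variants
  common <- stats::runif(m) < spec$common_frac
  lo <- log(spec$maf_range[1L])
  hi <- log(spec$maf_range[2L])
  maf <- exp(stats::runif(m, lo, hi))
  maf[common] <- stats::runif(sum(common), spec$common_maf_range[1L],
                              spec$common_maf_range[2L])
  maf
}

# One variant: HWE genotype counts by multinomial, carriers placed uniformly,
# then MCAR missingness overlaid (a missing entry overrides any carrier
# value -- the genotype is unobserved).
draw_record <- function(n, maf, missing_rate) {
  p_het <- 2 * maf * (1 - maf)
  p_hom <- maf^2
  cnt <- stats::rmultinom(1L, n, c(1 - p_het - p_hom, p_het, p_hom))
  n_het <- cnt[2L]
  n_hom <- cnt[3L]
  idx <- sample.int(n, n_het + n_hom) - 1L
  val <- rep(c(1L, 2L), c(n_het, n_hom))
  if (missing_rate > 0) {
    n_miss <- stats::rbinom(1L, n, missing_rate)
    midx <- sample.int(n, n_miss) - 1L
    keep <- !(idx %in% midx)
    idx <- c(idx[keep], midx)
    val <- c(val[keep], rep(GENO_MISSING, n_miss))
  }
  o <- order(idx)
  sparse_record(n, idx[o], val[o])
}

#' Simulate a synthetic cohort with known ground truth
#'
#' Genotypes are drawn i.i.d. binomial(2, MAF) across samples per variant
#' (Hardy-Weinberg), missingness is applied uniformly at random, the
#' quantitative phenotype is `y = Xc gamma + sum_causal g beta + e` with
#' Gaussian noise (missing genotypes contribute 0 to the signal), and the
#' binary phenotype draws from `Bernoulli(plogis(b0 + eta))` with `b0`
#' bisected so the expected case fraction matches the spec within 5e-3.
#' Everything is deterministic given the spec's seed.
#'
#' @param spec A [cohort_spec].
#' @param out_prefix Optional path prefix; when given, the fileset
#'   (`.sgen/.svar/.ssam`) plus `_pheno.tsv`, `_covar.tsv` and `_truth.tsv`
#'   are written there.
#' @return List with `records` (sparse records), `maf`, `covariates`
#'   (matrix), `pheno_qt`, `pheno_cc` (or `NULL`), `truth` (data frame of
#'   causal variants), `gamma`, `spec`, `samples`, `variants`, and `prefix`
#'   when written.
#' @export
simulate_cohort <- function(spec, out_prefix = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  m <- spec$n_variants

  maf <- draw_mafs(spec)
  records <- lapply(seq_len(m), function(j) draw_record(n, maf[j], spec$missing_rate))

  Xcov <- if (spec$n_covariates > 0) {
    matrix(stats::rnorm(n * spec$n_covariates), n,
           dimnames = list(NULL, sprintf("C%d", seq_len(spec$n_covariates))))
  } else {
    matrix(0, n, 0)
  }
  gamma <- if (spec$n_covariates > 0) stats::rnorm(spec$n_covariates, 0, spec$covar_sd) else numeric(0)

  causal_idx <- if (spec$n_causal > 0) sort(sample.int(m, spec$n_causal)) else integer(0)
  beta <- rep_len(spec$causal_beta, spec$n_causal)
  if (!is.null(spec$causal_maf) && spec$n_causal > 0) {
    maf[causal_idx] <- rep_len(spec$causal_maf, spec$n_causal)
    records[causal_idx] <- lapply(causal_idx, function(j) {
      draw_record(n, maf[j], spec$missing_rate)
    })
  }

  signal <- as.numeric(Xcov %*% gamma)
  for (i in seq_along(causal_idx)) {
    r <- records[[causal_idx[i]]]
    nz <- r$value != GENO_MISSING
    signal[r$sample_index[nz] + 1L] <-
      signal[r$sample_index[nz] + 1L] + beta[i] * r$value[nz]
  }
  pheno_qt <- signal + stats::rnorm(n, 0, spec$noise_sd)

  pheno_cc <- NULL
  if (!is.null(spec$case_fraction)) {
    b0 <- tune_intercept(signal, spec$case_fraction)
    pheno_cc <- as.integer(stats::runif(n) < stats::plogis(b0 + signal))
  }

  truth <- data.frame(
    variant = sprintf("var%d", causal_idx),
    index = causal_idx,
    maf = maf[causal_idx],
    beta = beta,
    stringsAsFactors = FALSE
  )
  samples <- default_sample_meta(n)
  variants <- default_variant_meta(m)

  out <- list(records = records, maf = maf, covariates = Xcov,
              pheno_qt = pheno_qt, pheno_cc = pheno_cc, truth = truth,
              gamma = gamma, spec = spec, samples = samples,
              variants = variants, prefix = out_prefix)
  if (!is.null(out_prefix)) {
    write_sgen(records, out_prefix, variants = variants, samples = samples)
    ph <- data.frame(FID = samples$fid, IID = samples$iid, QT = pheno_qt)
    if (!is.null(pheno_cc)) ph$CC <- pheno_cc
    utils::write.table(ph, paste0(out_prefix, "_pheno.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cv <- data.frame(FID = samples$fid, IID = samples$iid, Xcov,
                     check.names = FALSE)
    utils::write.table(cv, paste0(out_prefix, "_covar.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(truth, paste0(out_prefix, "_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}

# Bisect the logistic intercept so mean(plogis(b0 + eta)) hits the target.
tune_intercept <- function(eta, target, tol = 1e-6) {
  f <- function(b0) mean(stats::plogis(b0 + eta)) - target
  lo <- -40
  hi <- 40
  if (f(lo) > 0 || f(hi) < 0) stop("case fraction unreachable for this linear predictor")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate a cohort with no genotype effects
#'
#' [simulate_cohort] with every causal effect removed -- the null model used
#' to check type-I-error calibration of each regression path.
#'
#' @inheritParams simulate_cohort
#' @return As [simulate_cohort]; the truth table is empty.
#' @export
null_cohort <- function(spec, out_prefix = NULL) {
  spec$n_causal <- 0
  spec$causal_maf <- NULL
  simulate_cohort(spec, out_prefix)
}
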