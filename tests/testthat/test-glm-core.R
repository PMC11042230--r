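# Least-squares engine: covariate cache, dense reference path, sparse
# block-inverse fast path.

test_that("covariate cache matches hand arithmetic and a dense inverse oracle", {
  ctx <- design_context(n = 3)
  cache <- build_cache(ctx, c(1, 2, 3))
  expect_equal(unname(cache$A), matrix(3))
  expect_equal(unname(cache$A_inv), matrix(1 / 3))
  expect_equal(unname(cache$Xty), matrix(6))
  expect_equal(unname(cache$yty), 14)

  set.seed(21)
  X <- matrix(rnorm(200 * 5), 200)
  ctx2 <- design_context(X)
  cache2 <- build_cache(ctx2, rnorm(200))
  expect_lt(max(abs(cache2$A_inv %*% cache2$A - diag(6))), 1e-10)
  # independent oracle: QR-based inverse
  expect_lt(max(abs(cache2$A_inv - qr.solve(crossprod(ctx2$Xc)))), 1e-10)
})

test_that("rank-deficient designs are rejected naming the offending column", {
  x <- rnorm(30)
  expect_error(design_context(cbind(a = x, b = 2 * x)), "rank-deficient.*b")
})

test_that("dense path matches the independent lm() oracle", {
  set.seed(22)
  cases <- expand.grid(n = c(60, 300), n_cov = c(0, 4), miss = c(0, 0.1))
  for (i in seq_len(nrow(cases))) {
    inst <- random_instance(cases$n[i], cases$n_cov[i], maf = 0.2, miss = cases$miss[i])
    cache <- build_cache(inst$ctx, inst$y)
    got <- dense_linreg(inst$ctx, cache, inst$g)
    want <- lm_oracle(inst$ctx, inst$g, inst$y)
    expect_equal(got$status, "OK")
    expect_equal(got$n_used, want$n_used)
    expect_rel_equal(got$beta_g, want$beta, 1e-10)
    expect_rel_equal(got$se_g, want$se, 1e-10)
    expect_rel_equal(got$rss, want$rss, 1e-10)
    expect_lt(abs(got$p_value - want$p), 1e-10)
  }
})

test_that("dense path handles exact fits and degenerate genotypes", {
  ctx <- design_context(n = 10)
  g <- c(0, 1, 2, 0, 1, 0, 0, 2, 1, 0)
  cache <- build_cache(ctx, g) # y identical to g
  res <- dense_linreg(ctx, cache, g)
  expect_equal(res$beta_g, 1, tolerance = 1e-12)
  expect_lt(res$rss, 1e-20)

  cache2 <- build_cache(ctx, rnorm(10))
  expect_equal(dense_linreg(ctx, cache2, rep(1, 10))$status, "SINGULAR")
  # too few observed rows
  g2 <- c(0, 1, NA, NA, NA, NA, NA, NA, NA, NA)
  expect_equal(dense_linreg(ctx, cache2, g2)$status, "SINGULAR")
})

test_that("block inverse reproduces the partitioned-inverse identity", {
  # block-diagonal hand case
  bi <- block_inverse(diag(2), c(0, 0), 4)
  expect_false(bi$singular)
  expect_equal(bi$F, 4)
  expect_equal(bi$TL, diag(2))
  expect_equal(bi$BR, 1 / 4)
  expect_equal(as.numeric(bi$TR), c(0, 0))

  set.seed(23)
  for (i in 1:20) {
    M <- crossprod(matrix(rnorm(16), 4)) + diag(4) * 0.5 # SPD, 3+1 partition
    A <- M[1:3, 1:3]
    B <- M[1:3, 4, drop = FALSE]
    bi <- block_inverse(solve(A), B, M[4, 4])
    full <- rbind(cbind(bi$TL, bi$TR), cbind(bi$BL, bi$BR))
    expect_lt(max(abs(full - solve(M))), 1e-10)
    expect_lt(max(abs(full %*% M - diag(4))), 1e-8)
  }

  # F = 0 exactly: D equals B'A^{-1}B
  A <- diag(2)
  B <- c(1, 2)
  expect_true(block_inverse(solve(A), B, sum(B^2))$singular)
})

test_that("sparse fast path equals the dense reference on no-missing variants", {
  set.seed(24)
  for (i in 1:60) {
    n <- sample(50:500, 1)
    n_cov <- sample(0:8, 1)
    k <- sample.int(n %/% 2, 1)
    inst <- random_instance(n, n_cov, maf = 0)
    sv <- random_record(n, k)
    g <- codes_to_numeric(densify(sv))
    y <- inst$y + 0.3 * ifelse(is.na(g), 0, g)
    cache <- build_cache(inst$ctx, y)
    ds <- dense_linreg(inst$ctx, cache, g)
    sp <- sparse_linreg(inst$ctx, cache, sv)
    expect_equal(sp$status, ds$status)
    if (ds$status == "OK") {
      expect_rel_equal(sp$beta_g, ds$beta_g, 1e-8)
      expect_rel_equal(sp$se_g, ds$se_g, 1e-8)
      expect_lt(abs(-log10(sp$p_value) - -log10(ds$p_value)), 1e-6)
      expect_rel_equal(sp$rss, ds$rss, 1e-8)
    }
  }
})

test_that("sparse path rejects or flags degenerate inputs", {
  set.seed(25)
  ctx <- design_context(matrix(rnorm(200), 100))
  y <- rnorm(100)
  cache <- build_cache(ctx, y)
  # k = 0: all-reference, F = 0
  expect_equal(sparse_linreg(ctx, cache, sparse_record(100))$status, "SINGULAR")
  # missing entries must be routed to the dense path
  svm <- sparse_record(100, c(3, 7), c(1L, GENO_MISSING))
  expect_error(sparse_linreg(ctx, cache, svm), "missing")
  # intercept-only exact fit through the sparse path
  ctx0 <- design_context(n = 100)
  sv <- random_record(100, 12)
  g <- codes_to_numeric(densify(sv))
  cache0 <- build_cache(ctx0, 2 + 5 * g)
  res <- sparse_linreg(ctx0, cache0, sv)
  expect_equal(res$beta_g, 5, tolerance = 1e-9)
})

test_that("sparse path touches exactly k genotype entries, never n", {
  set.seed(26)
  n <- 1e6 # a record far larger than anything the arithmetic should expand
  ctx <- design_context(n = n)
  y <- rnorm(n)
  cache <- build_cache(ctx, y)
  sv <- random_record(n, 5)
  res <- sparse_linreg(ctx, cache, sv)
  expect_identical(res$g_touches, 5L)
  expect_equal(res$status, "OK")
  # dense reference touches all rows
  expect_identical(dense_linreg(ctx, cache, codes_to_numeric(densify(sv)))$g_touches,
                   as.integer(n))
})

test_that("results are scale-equivariant and permutation-invariant", {
  set.seed(27)
  inst <- random_instance(150, 3, maf = 0.1)
  sv <- random_record(150, 20)
  g <- codes_to_numeric(densify(sv))
  y <- inst$y + 0.4 * g
  cache <- build_cache(inst$ctx, y)
  base <- sparse_linreg(inst$ctx, cache, sv)

  cache_c <- build_cache(inst$ctx, 7.3 * y)
  scaled <- sparse_linreg(inst$ctx, cache_c, sv)
  expect_equal(scaled$beta_g, 7.3 * base$beta_g, tolerance = 1e-10)
  expect_equal(scaled$se_g, 7.3 * base$se_g, tolerance = 1e-10)
  expect_equal(scaled$t_stat, base$t_stat, tolerance = 1e-10)
  expect_equal(scaled$p_value, base$p_value, tolerance = 1e-10)

  perm <- sample.int(150)
  ctx_p <- design_context(inst$ctx$Xc[perm, -1, drop = FALSE])
  cache_p <- build_cache(ctx_p, y[perm])
  res_p <- dense_linreg(ctx_p, cache_p, g[perm])
  ref <- dense_linreg(inst$ctx, cache, g)
  expect_equal(res_p$beta_g, ref$beta_g, tolerance = 1e-10)
  expect_equal(res_p$se_g, ref$se_g, tolerance = 1e-10)
  expect_equal(res_p$p_value, ref$p_value, tolerance = 1e-10)
})

test_that("scan routes variants and equals an all-dense scan", {
  set.seed(28)
  spec <- cohort_spec(n_samples = 400, n_variants = 120, n_causal = 4,
                      causal_beta = 1, causal_maf = 0.03,
                      missing_rate = 0.01, seed = 91)
  prefix <- file.path(withr::local_tempdir(), "sc")
  sim <- simulate_cohort(spec, prefix)
  fs <- sgen_open(prefix)
  ctx <- design_context(sim$covariates)
  cache <- build_cache(ctx, sim$pheno_qt)

  res <- scan(fs, ctx, cache)
  expect_identical(nrow(res), 120L)
  expect_identical(res$ID, fs$variants$id)
  # some variants take each path under 1% missingness
  expect_true(all(c("sparse", "dense") %in% res$PATH))

  res_dense <- scan(fs, ctx, cache, force_dense = TRUE)
  ok <- res$STATUS == "OK"
  expect_identical(res$STATUS, res_dense$STATUS)
  expect_rel_equal(res$BETA[ok], res_dense$BETA[ok], 1e-8)
  expect_rel_equal(res$SE[ok], res_dense$SE[ok], 1e-8)
  expect_lt(max(abs(-log10(res$P[ok]) + log10(res_dense$P[ok]))), 1e-6)

  # determinism across reruns
  expect_identical(res, scan(fs, ctx, cache))

  # misaligned design is a consistency error
  expect_error(scan(fs, design_context(n = 399), build_cache(design_context(n = 399), rnorm(399))),
               "align")
})
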