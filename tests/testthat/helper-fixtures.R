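# Shared fixture builders. All randomness is driven by explicit seeds so
# every test is reproducible in isolation.

# Random sparse record: k entries among n samples, optionally with missing
# codes mixed in.
random_record <- function(n, k, p_missing = 0) {
  idx <- sort(sample.int(n, k)) - 1L
  val <- sample(c(1L, 2L), k, replace = TRUE)
  if (p_missing > 0) {
    mm <- runif(k) < p_missing
    val[mm] <- GENO_MISSING
  }
  sparse_record(n, idx, val)
}

# Random genotype code matrix with controlled allele frequency and
# missingness (codes 0/1/2/3).
random_geno_matrix <- function(n, m, maf = 0.1, miss = 0) {
  g <- matrix(rbinom(n * m, 2L, maf), n, m)
  if (miss > 0) g[runif(n * m) < miss] <- GENO_MISSING
  g
}

# Random regression instance: design context with n_cov covariates, a
# phenotype with genuine covariate signal, and a genotype column.
random_instance <- function(n, n_cov, maf = 0.1, miss = 0) {
  Xcov <- if (n_cov > 0) matrix(rnorm(n * n_cov), n) else NULL
  ctx <- design_context(Xcov, n = n)
  g <- rbinom(n, 2L, maf)
  if (miss > 0) g[runif(n) < miss] <- NA
  gamma <- if (n_cov > 0) rnorm(n_cov, 0, 0.5) else numeric(0)
  y <- as.numeric(ctx$Xc[, -1L, drop = FALSE] %*% gamma) +
    0.3 * ifelse(is.na(g), 0, g) + rnorm(n)
  list(ctx = ctx, g = as.numeric(g), y = y)
}

# Independent least-squares oracle via lm(): genotype coefficient stats.
lm_oracle <- function(ctx, g, y) {
  obs <- !is.na(g)
  df <- data.frame(y = y[obs], ctx$Xc[obs, -1L, drop = FALSE], g = g[obs])
  fit <- lm(y ~ ., data = df)
  sm <- summary(fit)$coefficients
  list(beta = sm["g", 1L], se = sm["g", 2L], p = sm["g", 4L],
       rss = sum(residuals(fit)^2), n_used = sum(obs))
}

# Independent logistic oracle via glm().
glm_oracle <- function(X_noint, y, offset = NULL) {
  df <- as.data.frame(X_noint)
  fit <- glm(y ~ ., data = df, family = binomial(),
             offset = offset, control = glm.control(epsilon = 1e-12, maxit = 50))
  summary(fit)$coefficients
}

expect_rel_equal <- function(x, y, tol, info = NULL) {
  expect_lt(max(abs(x - y) / pmax(abs(y), 1e-12)), tol)
}
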