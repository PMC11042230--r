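# Residualized fast modes.
#
# qt-residualize: regress the quantitative phenotype on the covariates once,
# then run p = 2 (intercept + genotype) regressions of the residuals per
# variant. With p = 2 a missing genotype is no longer expensive: the
# precomputed totals n, sum(r) and sum(r^2) are corrected by subtracting the
# contribution of each missing entry, so the per-variant cost stays O(k) for
# a difflist of k entries. Accumulation uses R's extended-precision sums.
#
# cc-residualize: fit the covariate-only logistic (or Firth) model once,
# freeze its linear predictor as an offset, and per variant fit only
# intercept + genotype by Newton iteration. firth-fallback is the full
# per-variant logistic fit with automatic Firth-penalized refit under
# separation, serving as the slow reference the residualized mode is
# compared against.

MAX_NEWTON_ITER <- 25L
SCORE_TOL <- 1e-8
BETA_TOL <- 1e-10
MAX_HALVINGS <- 10L
DIVERGE_BETA <- 50
MU_PIN_TOL <- 1e-6

#' Residualize a quantitative phenotype against covariates
#'
#' One upfront least-squares fit of `y` on `Xc`; the residual vector and its
#' totals (`n`, `sum r`, `sum r^2`) are cached so per-variant work can start
#' from them.
#'
#' @param ctx A [design_context] (includes the intercept).
#' @param y Numeric phenotype, no missing values (filter samples first).
#' @return Object of class `resid_pheno` with fields `r`, `sum_r`, `sum_r2`,
#'   `n`, `gamma` (covariate coefficients).
#' @export
qt_residualize <- function(ctx, y) {
  stopifnot(inherits(ctx, "design_context"))
  if (length(y) != ctx$n) stop("phenotype not aligned to design rows")
  if (anyNA(y)) stop("phenotype contains missing values; filter samples first")
  gamma <- solve(crossprod(ctx$Xc), crossprod(ctx$Xc, y))
  r <- as.numeric(y - ctx$Xc %*% gamma)
  structure(
    list(r = r, sum_r = sum(r), sum_r2 = sum(r^2), n = ctx$n,
         gamma = as.numeric(gamma)),
    class = "resid_pheno"
  )
}

#' Two-predictor sparse regression with subtractive missingness correction
#'
#' Regresses the cached residuals on intercept + genotype using only the k
#' listed entries of the difflist. For every missing entry the sample's
#' contribution is subtracted from the precomputed totals (`n`, `sum r`,
#' `sum r^2`); genotype cross-products accumulate over the non-missing
#' nonzero entries. The closed-form 2x2 normal equations then give results
#' identical to a dense regression on the non-missing subset.
#'
#' @param rp A [qt_residualize] result.
#' @param sv A [sparse_record]; missing entries (code 3) are supported here.
#' @return A `regression_result` with `df = n_used - 2` and `g_touches = k`.
#' @export
sparse_p2_linreg <- function(rp, sv) {
  stopifnot(inherits(rp, "resid_pheno"), inherits(sv, "sparse_record"))
  if (sv$n_samples != rp$n) stop("sparse record not aligned to residual vector")
  is_miss <- sv$value == GENO_MISSING
  idx_miss <- sv$sample_index[is_miss] + 1L
  idx_g <- sv$sample_index[!is_miss] + 1L
  vals <- sv$value[!is_miss]

  n_used <- rp$n - length(idx_miss)
  S_r <- rp$sum_r - sum(rp$r[idx_miss])
  S_rr <- rp$sum_r2 - sum(rp$r[idx_miss]^2)
  if (n_used <= 2L) return(singular_result(n_used, g_touches = sv$k))

  Sg <- sum(vals)
  Sgg <- sum(vals^2)
  Sgr <- sum(vals * rp$r[idx_g])
  Fs <- Sgg - Sg^2 / n_used # centered genotype sum of squares
  if (Fs <= F_SINGULAR_TOL * max(Sgg, 1)) {
    return(singular_result(n_used, g_touches = sv$k))
  }
  det2 <- n_used * Sgg - Sg^2
  beta_g <- (n_used * Sgr - Sg * S_r) / det2
  beta_0 <- (S_r - Sg * beta_g) / n_used
  rss <- max(S_rr - (beta_0 * S_r + beta_g * Sgr), 0)
  sigma2 <- rss / (n_used - 2L)
  se <- sqrt(sigma2 * n_used / det2)
  reg_result(beta_g = beta_g, se_g = se, df = n_used - 2L, rss = rss,
             n_used = n_used, g_touches = sv$k)
}

#' Quantitative residualized scan
#'
#' Applies [qt_residualize] once, then [sparse_p2_linreg] per variant
#' (dense-stored records are sparsified on the fly; the arithmetic is the
#' same O(k) difflist path).
#'
#' @param fs An [sgen_open] fileset.
#' @param ctx A [design_context] aligned to the fileset samples (or to the
#'   `keep` subset).
#' @param y Numeric phenotype vector.
#' @param keep Optional logical vector over fileset samples restricting the
#'   analysis to a subset; `ctx` and `y` must already cover that subset.
#' @return Data frame as in [scan] (PATH is `"residualized"`).
#' @export
qt_residualize_scan <- function(fs, ctx, y, keep = NULL) {
  n_expect <- if (is.null(keep)) fs$n_samples else sum(keep)
  if (ctx$n != n_expect) stop("design rows do not match analysis samples")
  rp <- qt_residualize(ctx, y)
  m <- fs$n_variants
  results <- vector("list", m)
  for (j in seq_len(m)) {
    rec <- sgen_record(fs, j, "as_stored")
    if (!inherits(rec, "sparse_record")) rec <- sparsify(rec)
    if (!is.null(keep)) rec <- subset_record(rec, keep)
    results[[j]] <- sparse_p2_linreg(rp, rec)
  }
  results_to_frame(fs, results,
                   extra = data.frame(PATH = "residualized", stringsAsFactors = FALSE))
}

# ---- logistic / Firth machinery --------------------------------------------

stable_loglik <- function(y, eta) {
  sum(y * eta) - sum(pmax(eta, 0) + log1p(exp(-abs(eta))))
}

# Newton-Raphson logistic fit with optional Firth penalty and step-halving.
# Returns beta, se, convergence state and the final fitted means. The Firth
# score is U*(b) = X'(y - mu + h(1/2 - mu)) with h the hat diagonals of the
# weighted design; the penalized log-likelihood adds log|X'WX|/2.
fit_logistic <- function(X, y, offset = NULL, firth = FALSE,
                         maxit = if (firth) 2L * MAX_NEWTON_ITER else MAX_NEWTON_ITER,
                         score_tol = SCORE_TOL, beta_tol = BETA_TOL) {
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(offset)) offset <- numeric(n)
  beta <- numeric(p)

  penalized_ll <- function(beta) {
    eta <- offset + as.numeric(X %*% beta)
    ll <- stable_loglik(y, eta)
    if (firth) {
      mu <- stats::plogis(eta)
      w <- mu * (1 - mu)
      ll <- ll + 0.5 * as.numeric(determinant(crossprod(X, X * w))$modulus)
    }
    ll
  }

  converged <- FALSE
  iter <- 0L
  ll <- penalized_ll(beta)
  trace <- numeric(0)
  while (iter < maxit) {
    iter <- iter + 1L
    eta <- offset + as.numeric(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    XtWX <- crossprod(X, X * w)
    ok <- tryCatch({R <- chol(XtWX); TRUE}, error = function(e) FALSE)
    if (!ok) {
      return(list(beta = beta, se = rep(NA_real_, p), vcov = NULL, mu = mu,
                  converged = FALSE, singular = TRUE, iterations = iter,
                  loglik = ll, trace = trace))
    }
    resid_work <- y - mu
    if (firth) {
      Cinv <- chol2inv(R)
      h <- rowSums((X %*% Cinv) * X) * w
      resid_work <- resid_work + h * (0.5 - mu)
    }
    U <- crossprod(X, resid_work)
    if (max(abs(U)) < score_tol) {
      converged <- TRUE
      break
    }
    step <- backsolve(R, forwardsolve(t(R), U))
    scale <- 1
    repeat {
      cand <- beta + scale * step
      ll_new <- penalized_ll(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      scale <- scale / 2
      if (scale < 2^-MAX_HALVINGS) break
    }
    beta_new <- beta + scale * step
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    ll <- penalized_ll(beta)
    trace <- c(trace, ll)
    if (delta < beta_tol) {
      converged <- TRUE
      break
    }
  }
  eta <- offset + as.numeric(X %*% beta)
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  XtWX <- crossprod(X, X * w)
  vcov <- tryCatch(solve(XtWX), error = function(e) NULL)
  se <- if (is.null(vcov)) rep(NA_real_, p) else sqrt(diag(vcov))
  list(beta = as.numeric(beta), se = se, vcov = vcov, mu = mu,
       converged = converged, singular = FALSE, iterations = iter,
       loglik = ll, trace = trace)
}

fit_diverged <- function(fit) {
  !fit$converged || any(abs(fit$beta) > DIVERGE_BETA) ||
    any(fit$mu < MU_PIN_TOL) || any(fit$mu > 1 - MU_PIN_TOL)
}

logit_result <- function(beta_g = NA_real_, se_g = NA_real_,
                         n_used = NA_integer_, status = "OK",
                         engine = NA_character_) {
  z <- beta_g / se_g
  p <- if (is.finite(z)) 2 * stats::pnorm(-abs(z)) else NA_real_
  structure(
    list(beta_g = beta_g, se_g = se_g, z_stat = z, p_value = p,
         n_used = n_used, status = status, engine = engine),
    class = "logit_result"
  )
}

#' Fit the covariate-only logistic model for the case-control offset
#'
#' Fits `logit P(y=1) = Xc gamma` once by Newton iteration (Firth-penalized
#' when `engine = "firth"`) and freezes the linear predictor `eta = Xc
#' gamma-hat` as a per-sample offset for the variant loop.
#'
#' @param ctx A [design_context].
#' @param y Binary 0/1 phenotype; both classes must be present.
#' @param engine `"logistic"` or `"firth"`.
#' @return Object of class `offset_model` with fields `eta`, `gamma`,
#'   `converged`, `iterations`, `engine`.
#' @export
cc_fit_offset <- function(ctx, y, engine = c("logistic", "firth")) {
  engine <- match.arg(engine)
  if (length(y) != ctx$n) stop("phenotype not aligned to design rows")
  if (!all(y %in% c(0, 1))) stop("case-control phenotype must be coded 0/1")
  if (length(unique(y)) < 2L) stop("both cases and controls are required")
  fit <- fit_logistic(ctx$Xc, y, firth = (engine == "firth"))
  if (!fit$converged || (engine == "logistic" && fit_diverged(fit))) {
    stop(structure(
      class = c("rarescan_convergence_error", "error", "condition"),
      list(message = paste0("covariate-only ", engine, " fit did not converge in ",
                            fit$iterations, " iterations (final penalized loglik ",
                            signif(fit$loglik, 8), ")"),
           call = sys.call(-1), iterations = fit$iterations, trace = fit$trace)
    ))
  }
  structure(
    list(eta = as.numeric(ctx$Xc %*% fit$beta), gamma = fit$beta,
         converged = fit$converged, iterations = fit$iterations, engine = engine),
    class = "offset_model"
  )
}

#' Per-variant case-control test with frozen covariate offset
#'
#' Fits `logit P(y=1) = eta + b0 + bg g` with `eta` fixed from
#' [cc_fit_offset]; only the intercept and genotype coefficient are
#' estimated. Missing-genotype rows are dropped. With `engine = "auto"` a
#' plain logistic fit is attempted first and refit with the Firth penalty on
#' non-convergence or divergence (the firth-fallback rule).
#'
#' @param om An `offset_model`.
#' @param sv A [sparse_record] or dense genotype dosage vector.
#' @param y Binary 0/1 phenotype aligned to the offset.
#' @param engine `"auto"`, `"logistic"` or `"firth"`.
#' @return A `logit_result` (Wald test; `engine` records the fit used).
#' @export
cc_residualize_variant <- function(om, sv, y, engine = c("auto", "logistic", "firth")) {
  engine <- match.arg(engine)
  stopifnot(inherits(om, "offset_model"))
  g <- if (inherits(sv, "sparse_record")) codes_to_numeric(densify(sv)) else as.numeric(sv)
  if (length(g) != length(om$eta)) stop("genotype not aligned to offset model")
  obs <- !is.na(g)
  n_used <- sum(obs)
  gs <- g[obs]
  if (n_used <= 2L || all(gs == gs[1L])) {
    return(logit_result(n_used = n_used, status = "SINGULAR"))
  }
  X <- cbind(1, gs)
  fit2 <- function(firth) fit_logistic(X, y[obs], offset = om$eta[obs], firth = firth)
  used <- engine
  fit <- switch(engine,
    logistic = fit2(FALSE),
    firth = fit2(TRUE),
    auto = {
      f <- fit2(FALSE)
      if (fit_diverged(f)) {
        used <- "firth"
        fit2(TRUE)
      } else {
        used <- "logistic"
        f
      }
    })
  if (fit$singular || !fit$converged) {
    return(logit_result(n_used = n_used, status = "NOCONV", engine = used))
  }
  logit_result(beta_g = fit$beta[2L], se_g = fit$se[2L], n_used = n_used,
               status = "OK", engine = used)
}

#' Full-covariate per-variant logistic fit with Firth fallback
#'
#' The slow reference for binary traits: fits `logit P(y=1) = Xc gamma + bg
#' g` per variant. If the plain fit fails to converge, any coefficient
#' exceeds 50 in magnitude, or fitted probabilities pin to 0/1, the variant
#' is refit with the Firth penalty `l(b) + log|I(b)|/2`, which stays finite
#' under separation.
#'
#' @param ctx A [design_context].
#' @param sv A [sparse_record] or dense genotype dosage vector.
#' @param y Binary 0/1 phenotype.
#' @return A `logit_result` (Wald test; `engine` is `"logistic"` or
#'   `"firth"`).
#' @export
firth_fallback_variant <- function(ctx, sv, y) {
  g <- if (inherits(sv, "sparse_record")) codes_to_numeric(densify(sv)) else as.numeric(sv)
  if (length(g) != ctx$n) stop("genotype not aligned to design rows")
  obs <- !is.na(g)
  n_used <- sum(obs)
  gs <- g[obs]
  if (n_used <= ctx$p || all(gs == gs[1L])) {
    return(logit_result(n_used = n_used, status = "SINGULAR"))
  }
  X <- cbind(ctx$Xc[obs, , drop = FALSE], g = gs)
  fit <- fit_logistic(X, y[obs])
  used <- "logistic"
  if (fit$singular) return(logit_result(n_used = n_used, status = "SINGULAR"))
  if (fit_diverged(fit)) {
    used <- "firth"
    fit <- fit_logistic(X, y[obs], firth = TRUE)
  }
  if (fit$singular || !fit$converged) {
    return(logit_result(n_used = n_used, status = "NOCONV", engine = used))
  }
  pg <- ncol(X)
  logit_result(beta_g = fit$beta[pg], se_g = fit$se[pg], n_used = n_used,
               status = "OK", engine = used)
}

logit_results_to_frame <- function(fs, results, path) {
  v <- fs$variants
  data.frame(
    CHROM = v$chrom, POS = v$pos, ID = v$id, REF = v$ref, ALT = v$alt,
    N = vapply(results, function(r) as.numeric(r$n_used), 0),
    BETA = vapply(results, function(r) r$beta_g, 0),
    SE = vapply(results, function(r) r$se_g, 0),
    Z_STAT = vapply(results, function(r) r$z_stat, 0),
    P = vapply(results, function(r) r$p_value, 0),
    OR = exp(vapply(results, function(r) r$beta_g, 0)),
    ENGINE = vapply(results, function(r) as.character(r$engine), ""),
    STATUS = vapply(results, function(r) r$status, ""),
    PATH = path,
    stringsAsFactors = FALSE
  )
}

#' Case-control association scan
#'
#' Runs one logistic test per variant, either with the full covariate design
#' refit per variant (`method = "firth-fallback"`) or with covariate effects
#' frozen as an offset (`method = "cc-residualize"`). Both apply the Firth
#' fallback rule per variant.
#'
#' @param fs An [sgen_open] fileset.
#' @param ctx A [design_context] aligned to the fileset samples.
#' @param y Binary 0/1 phenotype vector.
#' @param method `"cc-residualize"` or `"firth-fallback"`.
#' @param keep Optional logical vector over fileset samples restricting the
#'   analysis to a subset; `ctx` and `y` must already cover that subset.
#' @return Data frame with columns CHROM, POS, ID, REF, ALT, N, BETA, SE,
#'   Z_STAT, P, OR, ENGINE, STATUS, PATH.
#' @export
cc_scan <- function(fs, ctx, y, method = c("cc-residualize", "firth-fallback"),
                    keep = NULL) {
  method <- match.arg(method)
  n_expect <- if (is.null(keep)) fs$n_samples else sum(keep)
  if (ctx$n != n_expect) stop("design rows do not match analysis samples")
  get_g <- function(j) {
    rec <- sgen_record(fs, j, "force_dense")
    if (!is.null(keep)) rec <- rec[keep]
    codes_to_numeric(rec)
  }
  m <- fs$n_variants
  results <- vector("list", m)
  if (method == "cc-residualize") {
    om <- cc_fit_offset(ctx, y)
    for (j in seq_len(m)) {
      results[[j]] <- cc_residualize_variant(om, get_g(j), y)
    }
  } else {
    for (j in seq_len(m)) {
      results[[j]] <- firth_fallback_variant(ctx, get_g(j), y)
    }
  }
  logit_results_to_frame(fs, results, path = method)
}
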