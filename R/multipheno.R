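# Multi-phenotype scans and SVD-based phenotype reduction.
#
# Phenotypes covering exactly the same samples share one covariate cache, so
# the per-variant sparse products (B, D, the Schur complement) are computed
# once per variant and reused across those phenotype columns. Phenotype
# matrices with many correlated columns can first be reduced by a thin SVD
# to the minimal number of components explaining a requested variance
# fraction; the component scores are then scanned like ordinary phenotypes.

# Restrict a sparse record to a sample subset, reindexing against the kept
# samples.
subset_record <- function(sv, keep) {
  stopifnot(inherits(sv, "sparse_record"), length(keep) == sv$n_samples)
  pos <- cumsum(keep)
  in_keep <- keep[sv$sample_index + 1L]
  sparse_record(sum(keep),
                pos[sv$sample_index[in_keep] + 1L] - 1L,
                sv$value[in_keep])
}

#' Scan several phenotypes simultaneously
#'
#' Phenotype columns are grouped by their missingness pattern; each group's
#' complete samples define one design subset and one covariate cache, and
#' the sparse per-variant products are shared across the group's phenotypes.
#' Results for every phenotype are identical to an independent
#' single-phenotype scan on its complete cases.
#'
#' @param fs An [sgen_open] fileset.
#' @param ctx A [design_context] over all fileset samples.
#' @param Y Numeric `n x k` phenotype matrix (`NA` = missing), columns named.
#' @param force_dense Route every variant through the dense path.
#' @return Named list of per-phenotype data frames as in [scan].
#' @export
multi_scan <- function(fs, ctx, Y, force_dense = FALSE) {
  Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("P%d", seq_len(ncol(Y)))
  if (nrow(Y) != fs$n_samples) stop("phenotype rows do not match fileset samples")
  if (ctx$n != fs$n_samples) stop("design rows do not match fileset samples")

  masks <- apply(!is.na(Y), 2L, paste, collapse = "")
  out <- vector("list", ncol(Y))
  names(out) <- colnames(Y)
  for (key in unique(masks)) {
    cols <- which(masks == key)
    keep <- !is.na(Y[, cols[1L]])
    if (!any(keep)) stop("no overlapping samples for phenotype(s): ",
                         paste(colnames(Y)[cols], collapse = ", "))
    ctx_g <- if (all(keep)) ctx else subset_context(ctx, keep)
    cache <- build_cache(ctx_g, Y[keep, cols, drop = FALSE])
    m <- fs$n_variants
    res_group <- lapply(cols, function(ci) vector("list", m))
    for (j in seq_len(m)) {
      rec <- sgen_record(fs, j, "as_stored")
      if (!inherits(rec, "sparse_record")) rec <- sparsify(rec)
      if (!all(keep)) rec <- subset_record(rec, keep)
      if (!force_dense && !any(rec$value == GENO_MISSING)) {
        rl <- sparse_linreg_multi(ctx_g, cache, rec, seq_along(cols))
      } else {
        g <- codes_to_numeric(densify(rec))
        rl <- lapply(seq_along(cols), function(ci) dense_linreg(ctx_g, cache, g, ci))
      }
      for (ci in seq_along(cols)) res_group[[ci]][[j]] <- rl[[ci]]
    }
    for (ci in seq_along(cols)) {
      out[[cols[ci]]] <- results_to_frame(fs, res_group[[ci]])
    }
  }
  out
}

#' Reduce a phenotype matrix by thin SVD
#'
#' Drops rows with any missing phenotype, standardizes each column (mean 0,
#' variance 1), takes the thin SVD, and keeps the smallest number of leading
#' components whose cumulative squared singular values reach
#' `variance_explained`. Component signs follow the convention that each
#' component's largest-magnitude loading is positive, making output
#' deterministic across runs and LAPACK builds.
#'
#' @param Y Numeric `n x k` phenotype matrix, `k >= 2`, columns named.
#' @param variance_explained Fraction in (0, 1] of variance to retain.
#' @return Object of class `reduced_phenotypes`: `scores` (complete-rows x
#'   d), `loadings` (k x d), `d`, `singular_values`,
#'   `variance_explained_cum`, `center`, `scale`, `complete_rows` (logical
#'   over the input rows).
#' @export
pheno_svd <- function(Y, variance_explained) {
  Y <- as.matrix(Y)
  if (ncol(Y) < 2L) stop("pheno_svd needs at least 2 phenotype columns")
  if (variance_explained <= 0 || variance_explained > 1) {
    stop("variance_explained must be in (0, 1]")
  }
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("P%d", seq_len(ncol(Y)))
  complete <- stats::complete.cases(Y)
  Yc <- Y[complete, , drop = FALSE]
  if (nrow(Yc) < 2L) stop("fewer than 2 complete phenotype rows")
  sds <- apply(Yc, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance phenotype column(s): ",
         paste(colnames(Yc)[sds == 0], collapse = ", "))
  }
  ctr <- colMeans(Yc)
  Ys <- scale(Yc, center = ctr, scale = sds)
  sv <- svd(Ys)
  ve <- cumsum(sv$d^2) / sum(sv$d^2)
  d <- which(ve >= variance_explained - 1e-12)[1L]
  # sign convention: largest-magnitude loading of each component positive
  for (i in seq_len(d)) {
    lead <- which.max(abs(sv$v[, i]))
    if (sv$v[lead, i] < 0) {
      sv$v[, i] <- -sv$v[, i]
      sv$u[, i] <- -sv$u[, i]
    }
  }
  scores <- sv$u[, seq_len(d), drop = FALSE] %*% diag(sv$d[seq_len(d)], d)
  colnames(scores) <- sprintf("C%d", seq_len(d))
  loadings <- sv$v[, seq_len(d), drop = FALSE]
  dimnames(loadings) <- list(colnames(Y), colnames(scores))
  structure(
    list(scores = scores, loadings = loadings, d = d,
         singular_values = sv$d, variance_explained_cum = ve,
         center = ctr, scale = sds, complete_rows = complete),
    class = "reduced_phenotypes"
  )
}

#' @export
print.reduced_phenotypes <- function(x, ...) {
  cat("reduced_phenotypes:", length(x$center), "phenotypes ->", x$d,
      sprintf("component(s), %.4f%% variance retained\n",
              100 * x$variance_explained_cum[x$d]))
  invisible(x)
}

#' Scan SVD components as phenotypes
#'
#' Runs the standard per-variant scan on the `d` component score columns of
#' a [pheno_svd] reduction, restricted to the complete phenotype rows.
#'
#' @param fs An [sgen_open] fileset.
#' @param ctx A [design_context] over all fileset samples.
#' @param rp A `reduced_phenotypes` object.
#' @param force_dense Route every variant through the dense path.
#' @return Named list (`C1` .. `Cd`) of data frames as in [scan], with the
#'   cumulative variance-explained share attached as attribute
#'   `"variance_explained"` on the list.
#' @export
scan_reduced <- function(fs, ctx, rp, force_dense = FALSE) {
  stopifnot(inherits(rp, "reduced_phenotypes"))
  keep <- rp$complete_rows
  if (length(keep) != fs$n_samples) stop("reduction rows do not match fileset samples")
  Y <- matrix(NA_real_, fs$n_samples, rp$d,
              dimnames = list(NULL, colnames(rp$scores)))
  Y[keep, ] <- rp$scores
  out <- multi_scan(fs, ctx, Y, force_dense = force_dense)
  attr(out, "variance_explained") <- rp$variance_explained_cum[seq_len(rp$d)]
  out
}
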