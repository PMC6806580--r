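#' Adjusted R-squared of a redundancy analysis
#'
#' Multivariate least squares of the (column-centered) response matrix on the
#' (column-centered) predictor matrix: `R^2` is the trace of the fitted sum
#' of squares over the total sum of squares, and the adjustment is Ezekiel's
#' `1 - (1 - R^2)(n - 1)/(n - p - 1)` with `p` the rank of the centered
#' predictors. This is the quantity variation partitioning decomposes.
#'
#' @param Y Response matrix (e.g. Hellinger-transformed community data),
#'   samples in rows.
#' @param X Predictor matrix (or `NULL`/zero-column for the intercept-only
#'   model, giving `R^2 = 0`).
#' @return List with `r2`, `adj_r2`, `n`, `p`.
#' @export
rda_adjusted_r2 <- function(Y, X) {
  Y <- as.matrix(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  ss_tot <- sum(Yc^2)
  if (is.null(X) || NCOL(X) == 0)
    return(list(r2 = 0, adj_r2 = 0, n = nrow(Y), p = 0L))
  X <- as.matrix(X)
  if (nrow(X) != nrow(Y)) stop("Y and X must have the same rows")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qrx <- qr(Xc)
  p <- qrx$rank
  if (p < ncol(Xc)) {
    culprit <- colnames(X)[qrx$pivot[-seq_len(p)]]
    stop("predictor matrix is rank deficient (rank ", p, " < ", ncol(Xc),
         " columns); collinear columns include: ",
         paste(culprit, collapse = ", "))
  }
  n <- nrow(Y)
  if (n <= p + 1) stop("need n > p + 1 (n = ", n, ", p = ", p, ")")
  fitted <- qr.fitted(qrx, Yc)
  r2 <- sum(fitted^2) / ss_tot
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  list(r2 = r2, adj_r2 = adj, n = n, p = p)
}

#' Iterative variance-inflation-factor filter
#'
#' Removes, one at a time, the predictor with the highest VIF
#' (`VIF_j = 1 / (1 - R^2_j)` from regressing column `j` on the remaining
#' columns) until every VIF is at or below the threshold. An exactly
#' collinear column has infinite VIF and is removed first. Fewer than two
#' columns are returned unchanged.
#'
#' @param X Numeric predictor matrix with column names.
#' @param threshold Maximum admissible VIF (default 20).
#' @return List with `X` (reduced matrix), `removed` (character vector in
#'   removal order), `vif` (final VIFs).
#' @export
vif_filter <- function(X, threshold = 20) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  removed <- character(0)
  repeat {
    if (ncol(X) < 2) break
    vifs <- vapply(seq_len(ncol(X)), function(j) {
      fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
      ssr <- sum(fit$residuals^2)
      sst <- sum((X[, j] - mean(X[, j]))^2)
      if (sst == 0) return(Inf)
      r2 <- 1 - ssr / sst
      if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
    names(vifs) <- colnames(X)
    if (all(vifs <= threshold)) break
    worst <- which.max(vifs)
    removed <- c(removed, colnames(X)[worst])
    X <- X[, -worst, drop = FALSE]
  }
  final <- if (ncol(X) >= 2) {
    vapply(seq_len(ncol(X)), function(j) {
      fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
      sst <- sum((X[, j] - mean(X[, j]))^2)
      r2 <- if (sst == 0) 1 else 1 - sum(fit$residuals^2) / sst
      if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  } else rep(1, ncol(X))
  names(final) <- colnames(X)
  list(X = X, removed = removed, vif = final)
}

#' Forward selection of predictors with Blanchet's double stopping rule
#'
#' Greedy forward selection for RDA: at each step the candidate giving the
#' largest gain in `R^2` is tested by permutation (rows of the response
#' permuted, conditional on the already-selected predictors) and added only
#' if its p-value is at or below `alpha` AND (beyond the first variable) the
#' cumulative adjusted `R^2` does not exceed the adjusted `R^2` of the full
#' model. A permutation test of the full ("global") model precedes
#' selection; if it is not significant the selection is empty.
#'
#' @param Y Response matrix.
#' @param X Candidate predictor matrix (named columns).
#' @param alpha Significance level (default 0.05).
#' @param permutations Number of permutations (default 999).
#' @param seed Integer seed; the selection is deterministic given it.
#' @return List with `selected` (column names in selection order),
#'   `adj_r2` (cumulative, per step), `global_p`, `global_adj_r2`.
#' @export
forward_select <- function(Y, X, alpha = 0.05, permutations = 999, seed = 1) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  seed <- as.integer(seed)
  global <- rda_adjusted_r2(Y, X)
  global_p <- .perm_p_r2(Y, X, NULL, global$r2, permutations, seed)
  if (global_p > alpha)
    return(list(selected = character(0), adj_r2 = numeric(0),
                global_p = global_p, global_adj_r2 = global$adj_r2))
  selected <- character(0)
  adj_track <- numeric(0)
  candidates <- colnames(X)
  step <- 0L
  repeat {
    if (!length(candidates)) break
    base_r2 <- if (length(selected))
      rda_adjusted_r2(Y, X[, selected, drop = FALSE])$r2 else 0
    gains <- vapply(candidates, function(cand) {
      cols <- c(selected, cand)
      tryCatch(rda_adjusted_r2(Y, X[, cols, drop = FALSE])$r2 - base_r2,
               error = function(e) -Inf)
    }, numeric(1))
    best <- names(which.max(gains))
    if (!is.finite(gains[best])) break
    step <- step + 1L
    cols <- c(selected, best)
    cand_fit <- rda_adjusted_r2(Y, X[, cols, drop = FALSE])
    p <- .perm_p_r2(Y, X[, best, drop = FALSE],
                    if (length(selected)) X[, selected, drop = FALSE] else NULL,
                    cand_fit$r2 - base_r2, permutations, seed + step)
    # Blanchet's R2a threshold guards against accumulating variables past
    # the explanatory power of the full model; the first significant
    # variable is exempt (with a significant global test, rejecting every
    # variable would be inconsistent, and a single best predictor routinely
    # edges past the noise-penalised global adjusted R2).
    if (p > alpha) break
    if (length(selected) > 0 && cand_fit$adj_r2 > global$adj_r2) break
    selected <- cols
    adj_track <- c(adj_track, cand_fit$adj_r2)
    candidates <- setdiff(candidates, best)
  }
  list(selected = selected, adj_r2 = adj_track, global_p = global_p,
       global_adj_r2 = global$adj_r2)
}

# Adjusted R^2 on the column space of X, using the numerical rank as p.
.rda_adj_r2_rank_tolerant <- function(Y, X) {
  Y <- as.matrix(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xc <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  qrx <- qr(Xc)
  p <- qrx$rank
  n <- nrow(Y)
  if (n <= p + 1) stop("need n > p + 1 (n = ", n, ", p = ", p, ")")
  r2 <- sum(qr.fitted(qrx, Yc)^2) / sum(Yc^2)
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

# Permutation p-value for the R^2 gain of adding `Xadd` on top of `Xbase`
# (NULL for the marginal test): residuals of Y on Xbase are permuted.
.perm_p_r2 <- function(Y, Xadd, Xbase, observed_gain, permutations, seed) {
  n <- nrow(Y)
  if (is.null(Xbase)) {
    Yres <- scale(Y, center = TRUE, scale = FALSE)
    base_r2 <- function(Yp) 0
    r2_of <- function(Yp) rda_adjusted_r2(Yp, Xadd)$r2
  } else {
    qb <- qr(cbind(1, Xbase))
    Yres <- qr.resid(qb, as.matrix(Y))
    Xfull <- cbind(Xbase, Xadd)
    r2_of <- function(Yp) {
      rda_adjusted_r2(Yp, Xfull)$r2 - rda_adjusted_r2(Yp, Xbase)$r2
    }
  }
  perms <- withr::with_seed(seed, {
    vapply(seq_len(permutations), function(i) {
      idx <- sample.int(n)
      r2_of(Yres[idx, , drop = FALSE])
    }, numeric(1))
  })
  (1 + sum(perms >= observed_gain - 1e-12)) / (1 + permutations)
}

#' Two-set variation partitioning by partial RDA
#'
#' Decomposes the adjusted `R^2` of the community matrix into pure
#' environmental `[a]`, shared `[b]`, pure spatial `[c]` and unexplained
#' `[d]` fractions: `a = adjR2(env+spa) - adjR2(spa)`,
#' `c = adjR2(env+spa) - adjR2(env)`, `b = adjR2(env) - a`,
#' `d = 1 - adjR2(env+spa)`. Individual fractions can be slightly negative
#' (an adjusted-R^2 artifact) and are reported as-is, flagged in the result.
#'
#' @param Y Response (Hellinger-transformed community) matrix.
#' @param X_env,X_spatial Predictor matrices. Either may be `NULL`/empty,
#'   giving a degenerate two-fraction report with a warning.
#' @return An object of class `varpart_result`: list with `fractions`
#'   (named numeric `a`, `b`, `c`, `d`), `adj_r2` of the three models,
#'   `negative_fractions` flag, `method = "rda"`.
#' @export
varpart2 <- function(Y, X_env, X_spatial) {
  empty_env <- is.null(X_env) || NCOL(X_env) == 0
  empty_spa <- is.null(X_spatial) || NCOL(X_spatial) == 0
  if (empty_env || empty_spa) {
    warning("empty predictor set; reporting degenerate two-fraction result")
    X <- if (empty_env) X_spatial else X_env
    fit <- rda_adjusted_r2(Y, X)
    fr <- c(a = if (empty_env) 0 else fit$adj_r2, b = 0,
            c = if (empty_spa) 0 else fit$adj_r2, d = 1 - fit$adj_r2)
    return(structure(list(fractions = fr,
                          adj_r2 = c(env = if (empty_env) 0 else fit$adj_r2,
                                     spatial = if (empty_spa) 0 else fit$adj_r2,
                                     both = fit$adj_r2),
                          negative_fractions = any(fr < 0),
                          method = "rda", degenerate = TRUE),
                     class = "varpart_result"))
  }
  env <- rda_adjusted_r2(Y, X_env)$adj_r2
  spa <- rda_adjusted_r2(Y, X_spatial)$adj_r2
  # The union of the two sets may be collinear even when each set alone is
  # full rank (e.g. identical sets); fit it on its column space with p = rank.
  both <- .rda_adj_r2_rank_tolerant(Y, cbind(as.matrix(X_env),
                                             as.matrix(X_spatial)))
  a <- both - spa
  c_ <- both - env
  b <- env - a
  d <- 1 - both
  fr <- c(a = a, b = b, c = c_, d = d)
  structure(list(fractions = fr,
                 adj_r2 = c(env = env, spatial = spa, both = both),
                 negative_fractions = any(fr < 0),
                 method = "rda", degenerate = FALSE),
            class = "varpart_result")
}

#' @export
print.varpart_result <- function(x, ...) {
  cat("variation partitioning (", x$method, ")\n", sep = "")
  cat(sprintf("  pure env [a] = %+.4f\n  shared   [b] = %+.4f\n",
              x$fractions["a"], x$fractions["b"]))
  cat(sprintf("  pure spa [c] = %+.4f\n  unexpl.  [d] = %+.4f\n",
              x$fractions["c"], x$fractions["d"]))
  if (isTRUE(x$negative_fractions))
    cat("  note: negative fraction(s) reported as-is (adjusted-R2 artifact)\n")
  invisible(x)
}

#' Variation partitioning from (partial) Mantel correlations
#'
#' Distance-matrix analogue of [varpart2()]: the explained fractions come
#' from squared Mantel correlations, with the joint fraction from the
#' multiple regression of the community distances on the environmental and
#' spatial distances (upper-triangle vectors). Reported alongside, never
#' mixed with, the RDA version.
#'
#' @param dm_comm,dm_env,dm_spa `dist_matrix` objects with matching labels.
#' @param method Correlation method.
#' @param permutations,seed Passed to the underlying Mantel tests.
#' @return A `varpart_result` with `method = "partial-mantel"` and element
#'   `tests` holding the plain and partial Mantel statistics.
#' @export
varpart_mantel <- function(dm_comm, dm_env, dm_spa,
                           method = c("spearman", "pearson"),
                           permutations = 999, seed = 1) {
  method <- match.arg(method)
  .check_labels(dm_comm, dm_env)
  .check_labels(dm_comm, dm_spa)
  y <- .utri(dm_comm); e <- .utri(dm_env); s <- .utri(dm_spa)
  if (method == "spearman") { y <- rank(y); e <- rank(e); s <- rank(s) }
  r2_env <- stats::cor(y, e)^2
  r2_spa <- stats::cor(y, s)^2
  both <- summary(stats::lm(y ~ e + s))$r.squared
  a <- both - r2_spa
  c_ <- both - r2_env
  b <- r2_env - a
  d <- 1 - both
  m_env <- mantel_test(dm_comm, dm_env, method = method,
                       permutations = permutations, seed = seed)
  m_spa <- mantel_test(dm_comm, dm_spa, method = method,
                       permutations = permutations, seed = seed + 1L)
  pm_env <- partial_mantel(dm_comm, dm_env, dm_spa, method = method,
                           permutations = permutations, seed = seed + 2L)
  pm_spa <- partial_mantel(dm_comm, dm_spa, dm_env, method = method,
                           permutations = permutations, seed = seed + 3L)
  fr <- c(a = a, b = b, c = c_, d = d)
  structure(list(fractions = fr,
                 adj_r2 = c(env = r2_env, spatial = r2_spa, both = both),
                 negative_fractions = any(fr < 0),
                 method = "partial-mantel",
                 tests = list(mantel_env = m_env, mantel_spatial = m_spa,
                              partial_env = pm_env, partial_spatial = pm_spa)),
            class = "varpart_result")
}
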