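#' Mantel test between two distance matrices
#'
#' Correlation of the off-diagonal (upper triangle) entries of two distance
#' matrices, with significance from simultaneous row/column permutation of
#' the second matrix ([vegan::mantel()]). The p-value is one-tailed for
#' positive association, `p = (1 + #{perm r >= observed}) / (1 + permutations)`.
#'
#' @param dm1,dm2 `dist_matrix` objects with matching labels.
#' @param method `"spearman"` (ties by average ranks) or `"pearson"`.
#' @param permutations Number of permutations (>= 99).
#' @param seed Integer seed making the permutation p-value deterministic.
#' @param two_tailed If `TRUE`, doubles the smaller tail (capped at 1).
#' @return List with `r`, `p`, `permutations`, `method`.
#' @export
mantel_test <- function(dm1, dm2, method = c("spearman", "pearson"),
                        permutations = 999, seed = 1, two_tailed = FALSE) {
  method <- match.arg(method)
  .check_labels(dm1, dm2)
  if (permutations < 99) stop("use at least 99 permutations")
  res <- withr::with_seed(as.integer(seed),
    vegan::mantel(as_dist(dm1), as_dist(dm2), method = method,
                  permutations = permutations))
  p <- res$signif
  if (two_tailed) p <- min(1, 2 * min(p, 1 - p + 1 / (permutations + 1)))
  list(r = unname(res$statistic), p = p, permutations = permutations,
       method = method)
}

#' Partial Mantel test
#'
#' Correlation between `dm1` and `dm2` after removing the linear effect of a
#' third matrix `dm3` from both, with permutation significance
#' ([vegan::mantel.partial()]). A degenerate design in which the three
#' matrices are identical is reported as `r = 0` with `p = 1` rather than an
#' error.
#'
#' @inheritParams mantel_test
#' @param dm3 Conditioning `dist_matrix`.
#' @return List with `r`, `p`, `permutations`, `method`, and `degenerate`.
#' @export
partial_mantel <- function(dm1, dm2, dm3, method = c("spearman", "pearson"),
                           permutations = 999, seed = 1) {
  method <- match.arg(method)
  .check_labels(dm1, dm2)
  .check_labels(dm1, dm3)
  v1 <- .utri(dm1); v2 <- .utri(dm2); v3 <- .utri(dm3)
  if (method == "spearman") { v1 <- rank(v1); v2 <- rank(v2); v3 <- rank(v3) }
  if (stats::sd(v1 - v3) < 1e-12 || stats::sd(v2 - v3) < 1e-12 ||
      (stats::cor(v2, v3) > 1 - 1e-12 && stats::cor(v1, v3) > 1 - 1e-12))
    return(list(r = 0, p = 1, permutations = permutations, method = method,
                degenerate = TRUE))
  res <- withr::with_seed(as.integer(seed),
    vegan::mantel.partial(as_dist(dm1), as_dist(dm2), as_dist(dm3),
                          method = method, permutations = permutations))
  list(r = unname(res$statistic), p = res$signif,
       permutations = permutations, method = method, degenerate = FALSE)
}

#' Analysis of similarities (ANOSIM)
#'
#' Global `R = (mean between-group rank - mean within-group rank) / (M / 4)`
#' with `M = n(n-1)/2` dissimilarity pairs; `R = 0` means no separation,
#' `R = 1` complete separation. Significance by permutation of group labels
#' ([vegan::anosim()]).
#'
#' @param dm A dissimilarity `dist_matrix`.
#' @param groups Group label per sample (>= 2 groups, each of size >= 2).
#' @param permutations Number of permutations.
#' @param seed Integer seed.
#' @return List with `R`, `p`, `permutations`.
#' @export
anosim_test <- function(dm, groups, permutations = 999, seed = 1) {
  stopifnot(inherits(dm, "dist_matrix"))
  groups <- as.factor(groups)
  if (length(groups) != nrow(dm)) stop("one group label per sample required")
  if (nlevels(droplevels(groups)) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2))
    stop("singleton group(s): ",
         paste(names(which(table(groups) < 2)), collapse = ", "))
  res <- withr::with_seed(as.integer(seed),
    vegan::anosim(as_dist(dm), groups, permutations = permutations))
  list(R = unname(res$statistic), p = res$signif,
       permutations = permutations)
}

#' Principal coordinates analysis (PCoA)
#'
#' Gower double-centering of the squared-distance matrix followed by
#' eigen-decomposition. Axes are sorted by eigenvalue; negative eigenvalues
#' (possible for non-Euclidean dissimilarities such as Bray-Curtis) are
#' reported as-is, not corrected.
#'
#' @param dm A dissimilarity `dist_matrix` with `n >= 3` samples.
#' @return List with `coordinates` (n x k matrix over positive-eigenvalue
#'   axes), `eigenvalues` (all n, sorted decreasing), and
#'   `relative_eig` (share of the positive-eigenvalue sum per positive axis).
#' @export
pcoa_ordination <- function(dm) {
  stopifnot(inherits(dm, "dist_matrix"))
  if (nrow(dm) < 3) stop("need at least 3 samples")
  n <- nrow(dm)
  A <- -0.5 * unclass(dm)^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  pos <- which(e$values > 1e-10)
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), length(pos))
  rownames(coords) <- rownames(dm)
  colnames(coords) <- paste0("PCoA", seq_along(pos))
  list(coordinates = coords,
       eigenvalues = e$values,
       relative_eig = e$values[pos] / sum(e$values[pos]))
}

#' Distance-decay relationship
#'
#' Ordinary least-squares regression of pairwise community similarity on
#' pairwise geographic distance over the `n(n-1)/2` unordered sample pairs,
#' with the correlation of the chosen method and a Mantel permutation
#' p-value (pairs are not independent, so the naive regression p is not
#' reported).
#'
#' @param sim A similarity `dist_matrix` (e.g. Bray-Curtis similarity).
#' @param dist A distance `dist_matrix` in km.
#' @param method Correlation method for `r` and the Mantel test.
#' @param permutations,seed Passed to [mantel_test()].
#' @return List with `slope`, `intercept`, `r`, `p`, `n_pairs`.
#' @export
distance_decay <- function(sim, dist, method = c("spearman", "pearson"),
                           permutations = 999, seed = 1) {
  method <- match.arg(method)
  .check_labels(sim, dist)
  s <- .utri(sim)
  d <- .utri(dist)
  fit <- stats::lm(s ~ d)
  r <- stats::cor(s, d, method = method)
  # decay = positive association between DISsimilarity and distance
  dissim <- dist_matrix(1 - unclass(sim), metric = "derived-dissim")
  mt <- mantel_test(dissim, dist, method = method,
                    permutations = permutations, seed = seed)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = r, p = mt$p, n_pairs = length(s))
}

# upper-triangle vector of a dist_matrix
.utri <- function(dm) {
  m <- unclass(dm)
  m[upper.tri(m)]
}

.check_labels <- function(a, b) {
  stopifnot(inherits(a, "dist_matrix"), inherits(b, "dist_matrix"))
  if (!identical(rownames(a), rownames(b)))
    stop("distance matrices have mismatching labels")
  invisible(TRUE)
}
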