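test_that("RDA R^2 has exact limits and matches the vegan oracle", {
  withr::with_seed(41, {
    n <- 25
    X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("x1", "x2", "x3")))
    B <- matrix(rnorm(6), 3, 2)
    Yexact <- X %*% B
    expect_equal(rda_adjusted_r2(Yexact, X)$r2, 1, tolerance = 1e-10)
    expect_equal(rda_adjusted_r2(Yexact, X)$adj_r2, 1, tolerance = 1e-10)
    expect_equal(rda_adjusted_r2(Yexact, NULL)$r2, 0)
    Y <- Yexact + matrix(rnorm(n * 2), n)
    ours <- rda_adjusted_r2(Y, X)
    vg <- vegan::RsquareAdj(vegan::rda(Y ~ X))
    expect_equal(ours$r2, vg$r.squared, tolerance = 1e-10)
    expect_equal(ours$adj_r2, vg$adj.r.squared, tolerance = 1e-10)
    expect_error(rda_adjusted_r2(Y, cbind(X, x1b = X[, 1])), "rank deficient")
  })
})

test_that("adjusted R^2 is centred on zero for pure-noise predictors", {
  vals <- vapply(1:60, function(s) {
    withr::with_seed(s, {
      Y <- matrix(rnorm(30 * 4), 30)
      X <- matrix(rnorm(30 * 3), 30)
      rda_adjusted_r2(Y, X)$adj_r2
    })
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.03)
})

test_that("VIF filtering removes exact and near collinearity", {
  withr::with_seed(42, {
    X <- matrix(rnorm(40 * 3), 40, dimnames = list(NULL, c("a", "b", "c")))
    dup <- cbind(X, d = X[, "a"])
    res <- vif_filter(dup)
    expect_true(("a" %in% res$removed) || ("d" %in% res$removed))
    expect_equal(ncol(res$X), 3)
    # orthonormal (centred) predictors all have VIF 1 and survive
    Q <- qr.Q(qr(cbind(1, matrix(rnorm(40 * 4), 40))))[, 2:5]
    colnames(Q) <- paste0("q", 1:4)
    res2 <- vif_filter(Q)
    expect_equal(unname(res2$vif), rep(1, 4), tolerance = 1e-10)
    expect_length(res2$removed, 0)
    # agreement with the car oracle on a correlated design
    Z <- matrix(rnorm(40 * 3), 40)
    Xc <- cbind(v1 = Z[, 1], v2 = 0.9 * Z[, 1] + sqrt(1 - 0.81) * Z[, 2],
                v3 = Z[, 3])
    y <- rnorm(40)
    df <- data.frame(y = y, Xc)
    oracle <- car::vif(lm(y ~ v1 + v2 + v3, data = df))
    ours <- vif_filter(Xc, threshold = 1e6)$vif
    expect_equal(unname(ours), unname(oracle), tolerance = 1e-8)
  })
})

test_that("forward selection finds a true predictor and respects the null", {
  withr::with_seed(43, {
    n <- 30
    X <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("x", 1:5)))
    Y <- cbind(2 * X[, "x3"] + rnorm(n, sd = 0.4),
               -X[, "x3"] + rnorm(n, sd = 0.4))
    sel <- forward_select(Y, X, permutations = 199, seed = 5)
    expect_equal(sel$selected[1], "x3")
    sel2 <- forward_select(Y, X, permutations = 199, seed = 5)
    expect_identical(sel, sel2)               # deterministic given seed
  })
  empties <- vapply(1:10, function(s) {
    withr::with_seed(100 + s, {
      Y <- matrix(rnorm(25 * 3), 25)
      X <- matrix(rnorm(25 * 4), 25, dimnames = list(NULL, paste0("x", 1:4)))
      length(forward_select(Y, X, permutations = 99, seed = s)$selected)
    })
  }, numeric(1))
  expect_gte(sum(empties == 0), 8)            # null keeps selection empty
})

test_that("varpart fractions obey the algebraic identity and match vegan", {
  withr::with_seed(44, {
    n <- 30
    Y <- matrix(rnorm(n * 6), n)
    Xe <- matrix(rnorm(n * 3), n)
    Xs <- matrix(rnorm(n * 2), n)
    vp <- varpart2(Y, Xe, Xs)
    expect_equal(unname(sum(vp$fractions)), 1, tolerance = 1e-10)
    # vegan rows are pure-X1, pure-X2, shared, residual
    vg <- vegan::varpart(Y, Xe, Xs)$part$indfract$Adj.R.squared
    expect_equal(unname(vp$fractions[c("a", "c", "b", "d")]), vg,
                 tolerance = 1e-10)
    # identical predictor sets: no pure fractions
    vp2 <- varpart2(Y, Xe, Xe)
    expect_equal(unname(vp2$fractions["a"]), 0, tolerance = 1e-10)
    expect_equal(unname(vp2$fractions["c"]), 0, tolerance = 1e-10)
    expect_equal(unname(vp2$fractions["b"]),
                 rda_adjusted_r2(Y, Xe)$adj_r2, tolerance = 1e-10)
  })
})

test_that("orthogonal spatial predictors claim no shared fraction", {
  withr::with_seed(45, {
    n <- 40
    Xe <- qr.Q(qr(matrix(rnorm(n * 2), n)))
    Xs <- qr.Q(qr(cbind(1, matrix(rnorm(n * 2), n))))[, 2:3]  # orthogonal-ish
    Y <- Xe %*% matrix(c(3, -1, 2, 1), 2) + matrix(rnorm(n * 2, sd = 0.2), n)
    vp <- varpart2(Y, Xe, Xs)
    expect_lt(abs(vp$fractions["b"]), 0.05)
    expect_gt(vp$fractions["a"], 0.5)
  })
})

test_that("degenerate varpart inputs give a flagged two-fraction report", {
  withr::with_seed(46, {
    Y <- matrix(rnorm(20 * 3), 20)
    Xs <- matrix(rnorm(20 * 2), 20)
    expect_warning(vp <- varpart2(Y, NULL, Xs), "degenerate|empty")
    expect_equal(unname(vp$fractions["a"]), 0)
    expect_equal(unname(sum(vp$fractions)), 1, tolerance = 1e-10)
  })
})

test_that("Mantel-based partitioning mirrors the construction of its inputs", {
  withr::with_seed(47, {
    n <- 16
    ids <- paste0("s", 1:n)
    env <- matrix(rnorm(n * 2), n)
    d_env <- dist_matrix(as.matrix(dist(env)), labels = ids, metric = "env")
    d_spa <- dist_matrix(as.matrix(dist(matrix(rnorm(n * 2), n))),
                         labels = ids, metric = "spa")
    # community distances built from the environmental distances
    d_comm <- dist_matrix(unclass(d_env) +
                            matrix(rnorm(n * n, sd = 1e-6), n) * 0,
                          labels = ids, metric = "comm")
    vp <- varpart_mantel(d_comm, d_env, d_spa, permutations = 99, seed = 1)
    expect_equal(unname(sum(vp$fractions)), 1, tolerance = 1e-10)
    expect_gt(vp$fractions["a"], 0.8)        # pure environment dominates
    vp2 <- varpart_mantel(d_comm, d_env, d_env, permutations = 99, seed = 1)
    expect_lt(abs(vp2$fractions["a"]), 1e-6)
    expect_lt(abs(vp2$fractions["c"]), 1e-6)
    # three mutually independent matrices explain almost nothing
    d_r <- dist_matrix(as.matrix(dist(matrix(rnorm(n * 2), n))),
                       labels = ids, metric = "r")
    vp3 <- varpart_mantel(d_r, d_env, d_spa, permutations = 99, seed = 1)
    expect_lt(sum(abs(vp3$fractions[c("a", "b", "c")])), 0.5)
  })
})
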