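test_that("PCNM vectors are centred, orthogonal, with decreasing eigenvalues", {
  xy <- data.frame(sample_id = paste0("s", 1:10),
                   longitude = seq(116, 116.9, by = 0.1), latitude = 25)
  dm <- geo_distances(xy, mode = "euclidean")
  b <- pcnm_vectors(dm)
  expect_lt(max(abs(colMeans(b$vectors))), 1e-8)
  gram <- crossprod(b$vectors)
  expect_lt(max(abs(gram - diag(diag(gram)))), 1e-8)
  expect_true(all(diff(b$eigenvalues) <= 1e-9))
  expect_true(all(b$eigenvalues > 0))
  expect_lte(ncol(b$vectors), 9)
})

test_that("PCNM is equivariant under site permutation", {
  withr::with_seed(21, {
    xy <- data.frame(sample_id = paste0("s", 1:8),
                     longitude = 116 + runif(8, 0, 0.5),
                     latitude = 25 + runif(8, 0, 0.5))
    dm <- geo_distances(xy, mode = "euclidean")
    b1 <- pcnm_vectors(dm)
    perm <- sample(8)
    m2 <- unclass(dm)[perm, perm]
    b2 <- pcnm_vectors(dist_matrix(m2, metric = "euclid-km"))
    expect_equal(b2$vectors, b1$vectors[perm, , drop = FALSE],
                 tolerance = 1e-8)
  })
})

test_that("PCNM agrees with a dense truncated-PCoA oracle", {
  withr::with_seed(22, {
    pts <- matrix(runif(12, 0, 10), 6, 2)
    m <- as.matrix(dist(pts))
    dimnames(m) <- list(paste0("s", 1:6), paste0("s", 1:6))
    dm <- dist_matrix(m, metric = "euclid-km")
    b <- pcnm_vectors(dm)
    thr <- b$params$truncation
    # independent oracle: truncate, Gower-centre, eigendecompose
    mt <- m
    mt[mt > thr] <- 4 * thr
    A <- -0.5 * mt^2
    J <- diag(6) - matrix(1 / 6, 6, 6)
    e <- eigen(J %*% A %*% J, symmetric = TRUE)
    pos <- e$values > 1e-8
    expect_equal(length(b$eigenvalues), sum(pos))
    expect_equal(b$eigenvalues, e$values[pos], tolerance = 1e-6)
    oracle_vec <- e$vectors[, pos, drop = FALSE]
    for (k in seq_len(ncol(oracle_vec))) {
      v1 <- b$vectors[, k] / sqrt(sum(b$vectors[, k]^2))
      v2 <- oracle_vec[, k]
      expect_equal(abs(sum(v1 * v2)), 1, tolerance = 1e-6)
    }
  })
})

test_that("site-by-edge encodes directed paths from the origin", {
  nodes <- data.frame(node = c("src", "A", "B"), longitude = 0:2,
                      latitude = 0)
  edges <- data.frame(from = c("src", "A"), to = c("A", "B"),
                      length_km = c(1, 2))
  net <- river_network(nodes, edges)
  m <- build_site_by_edge(net)
  expect_equal(unname(m["A", ]), c(1, 0))
  expect_equal(unname(m["B", ]), c(1, 1))
  expect_equal(unname(m["src", ]), c(0, 0))
  expect_equal(sum(m["A", ]), 1)           # headwater site just below origin
  # row sums never decrease moving downstream along a branch
  net2 <- y_network()
  m2 <- build_site_by_edge(net2)
  expect_true(sum(m2["a", ]) >= sum(m2["c", ]))
  expect_true(sum(m2["b", ]) >= sum(m2["c", ]))
})

test_that("AEM weights, orthogonality, and the SVD oracle", {
  net <- y_network()
  sbe <- build_site_by_edge(net)
  b <- aem_vectors(sbe, net$edges$length_km)
  expect_equal(min(b$params$weights), 0)           # d = d_max edge drops out
  expect_lt(max(abs(colMeans(b$vectors))), 1e-8)
  gram <- crossprod(b$vectors)
  expect_lt(max(abs(gram - diag(diag(gram)))), 1e-8)
  expect_lte(ncol(b$vectors), min(nrow(sbe) - 1, ncol(sbe)))
  # dense SVD oracle on the same weighted centred matrix
  w <- 1 - (net$edges$length_km / max(net$edges$length_km))^2
  wm <- scale(sweep(sbe, 2, w, `*`), center = TRUE, scale = FALSE)
  sv <- svd(wm)
  keep <- sv$d > max(sv$d) * 1e-9
  expect_equal(b$eigenvalues, sv$d[keep]^2 / (nrow(sbe) - 1),
               tolerance = 1e-9)
  for (k in seq_len(sum(keep)))
    expect_equal(abs(sum(b$vectors[, k] * sv$u[, k])), 1, tolerance = 1e-9)
})

test_that("uniform user weights span the unweighted basis", {
  sim <- simulate_river_network(10, seed = 5)
  sbe <- build_site_by_edge(sim$network)
  len <- sim$network$edges$length_km
  b_uni <- aem_vectors(sbe, len, weights = rep(1, length(len)))
  b_half <- aem_vectors(sbe, len, weights = rep(0.5, length(len)))
  # identical projection operators => identical spanned spaces
  P1 <- tcrossprod(b_uni$vectors)
  P2 <- tcrossprod(b_half$vectors)
  expect_equal(P1, P2, tolerance = 1e-8)
})

test_that("AEM responds to flow direction", {
  # Y-network flowing o -> {a, b} versus the reversed {a, b} -> o
  nodes <- data.frame(node = c("o", "c", "a", "b"), longitude = 0:3,
                      latitude = 0)
  fwd <- river_network(nodes, data.frame(from = c("o", "c", "c"),
                                         to = c("c", "a", "b"),
                                         length_km = c(2, 3, 4)))
  rev <- river_network(nodes, data.frame(from = c("a", "b", "c"),
                                         to = c("c", "c", "o"),
                                         length_km = c(3, 4, 2)))
  m_f <- build_site_by_edge(fwd, nodes$node)
  m_r <- build_site_by_edge(rev, nodes$node)
  expect_false(identical(m_f, m_r))
  b_f <- aem_vectors(m_f, c(2, 3, 4))
  b_r <- aem_vectors(m_r, c(3, 4, 2))
  expect_false(isTRUE(all.equal(tcrossprod(b_f$vectors),
                                tcrossprod(b_r$vectors), tolerance = 1e-6)))
})

test_that("degenerate site-by-edge matrices give an empty basis", {
  m <- matrix(1L, 4, 2)  # all sites identical
  expect_warning(b <- aem_vectors(m, c(1, 2)), "no spatial structure")
  expect_equal(ncol(b$vectors), 0)
})

test_that("eigenbasis writer emits TSV plus JSON sidecar", {
  sim <- simulate_river_network(6, seed = 3)
  sbe <- build_site_by_edge(sim$network)
  b <- aem_vectors(sbe, sim$network$edges$length_km)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_eigenbasis(b, tsv, js)
  back <- read.delim(tsv)
  expect_equal(nrow(back), nrow(b$vectors))
  side <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(side$kind, "aem")
  expect_equal(side$eigenvalues, b$eigenvalues, tolerance = 1e-9)
})
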