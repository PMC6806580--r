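test_that("Bray-Curtis matches hand computation and its bounds", {
  cm <- matrix(c(6, 2, 2, 2, 6, 2), 3, 2, byrow = TRUE,
               dimnames = list(c("x", "y", "z"), c("a", "b")))
  d <- bray_curtis(otu_table(cm))
  expect_equal(unname(d["x", "y"]), 1 / 3)          # (4+0)/(8+4)
  expect_equal(unname(d["x", "z"]), 0)              # identical samples
  s <- bray_curtis(otu_table(cm), similarity = TRUE)
  expect_equal(unclass(s)[upper.tri(s)], 1 - unclass(d)[upper.tri(d)])
  disjoint <- otu_table(matrix(c(5L, 0L, 0L, 7L), 2, 2))
  expect_equal(unname(bray_curtis(disjoint, similarity = TRUE)[1, 2]), 0)
  r <- bray_curtis(rand_table(2))
  expect_true(all(r >= 0 & r <= 1))
  expect_equal(unclass(r), t(unclass(r)))
})

test_that("haversine distances match the closed form", {
  meta <- data.frame(sample_id = c("p", "q", "r"),
                     longitude = c(0, 1, 0), latitude = c(0, 0, 0))
  d <- geo_distances(meta, mode = "euclidean")
  expect_equal(unname(d["p", "q"]), 111.19, tolerance = 0.1 / 111.19)
  expect_equal(unname(d["p", "r"]), 0)
})

test_that("dendritic distances sum branch lengths through confluences", {
  net <- y_network()
  meta <- data.frame(sample_id = c("a", "b", "o"), site = c("a", "b", "o"))
  d <- geo_distances(meta, network = net, mode = "dendritic")
  expect_equal(unname(d["a", "b"]), 7)   # 3 + 4 through the confluence
  expect_equal(unname(d["o", "a"]), 5)   # 2 + 3
  bad <- data.frame(sample_id = "zz", site = "zz")
  expect_error(geo_distances(bad, network = net, mode = "dendritic"), "zz")
})

test_that("river network validation rejects cycles and disconnection", {
  nodes <- data.frame(node = c("a", "b", "c"), longitude = 0, latitude = 0)
  cyc <- data.frame(from = c("a", "b", "c"), to = c("b", "c", "a"),
                    length_km = 1)
  expect_error(river_network(nodes, cyc), "tree|cycle")
  disc <- data.frame(from = "a", to = "b", length_km = 1)
  expect_error(river_network(nodes, disc), "connected")
})

test_that("Mantel recovers identity and anti-order, and needs matching labels", {
  dm <- bray_curtis(rand_table(4, n_samples = 10))
  res <- mantel_test(dm, dm, permutations = 199, seed = 1)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 200)
  # reversing the rank order of distances flips Spearman to -1
  m <- unclass(dm)
  rev_m <- max(m) - m
  diag(rev_m) <- 0
  res2 <- mantel_test(dm, dist_matrix(rev_m, metric = "reversed"),
                      method = "spearman", permutations = 99, seed = 1)
  expect_equal(res2$r, -1)
  other <- bray_curtis(rand_table(5, n_samples = 10))
  dimnames_new <- rev(rownames(other))
  m2 <- unclass(other)
  dimnames(m2) <- list(dimnames_new, dimnames_new)
  expect_error(mantel_test(dm, dist_matrix(m2, metric = "x")), "labels")
})

test_that("partial Mantel behaves under unrelated and collinear controls", {
  withr::with_seed(8, {
    n <- 14
    xy1 <- matrix(rnorm(n * 3), n)
    xy2 <- 2 * xy1 + matrix(rnorm(n * 3, sd = 0.05), n)
    ids <- paste0("s", 1:n)
    d1 <- dist_matrix(as.matrix(dist(xy1)), labels = ids, metric = "a")
    d2 <- dist_matrix(as.matrix(dist(xy2)), labels = ids, metric = "b")
    d3 <- dist_matrix(as.matrix(dist(matrix(rnorm(n * 3), n))), labels = ids,
                      metric = "c")
    plain <- mantel_test(d1, d2, permutations = 99, seed = 2)
    part <- partial_mantel(d1, d2, d3, permutations = 99, seed = 2)
    expect_lt(abs(part$r - plain$r), 0.15)   # unrelated conditioning matrix
    part2 <- partial_mantel(d1, d2, d2, permutations = 99, seed = 2)
    expect_lt(abs(part2$r), 0.25)            # dm2 fully explained by dm3
    deg <- partial_mantel(d1, d1, d1, permutations = 99, seed = 2)
    expect_true(deg$degenerate)
    expect_equal(deg$r, 0)
  })
})

test_that("ANOSIM spans no-separation to complete separation", {
  # two tight, widely separated clusters: all between > all within
  withr::with_seed(9, {
    pts <- rbind(matrix(rnorm(10, 0, 0.1), 5), matrix(rnorm(10, 10, 0.1), 5))
    dm <- dist_matrix(as.matrix(dist(pts)), labels = paste0("s", 1:10),
                      metric = "euclid")
    res <- anosim_test(dm, rep(c("g1", "g2"), each = 5), permutations = 199,
                       seed = 3)
    expect_equal(res$R, 1)
    expect_lt(res$p, 0.05)
    # random labels: R fluctuates around zero
    rs <- vapply(1:10, function(s) {
      g <- withr::with_seed(s, sample(rep(c("g1", "g2"), each = 5)))
      anosim_test(dm, g, permutations = 99, seed = s)$R
    }, numeric(1))
    expect_lt(abs(mean(rs)), 0.5)
    expect_error(anosim_test(dm, c(rep("g1", 9), "g2")), "singleton")
  })
})

test_that("PCoA reproduces Euclidean configurations and orders axes", {
  withr::with_seed(10, {
    pts <- matrix(rnorm(24), 12, 2)
    dm <- dist_matrix(as.matrix(dist(pts)), labels = paste0("s", 1:12),
                      metric = "euclid")
    ord <- pcoa_ordination(dm)
    rec <- as.matrix(dist(ord$coordinates))
    expect_equal(max(abs(rec - unclass(dm))), 0, tolerance = 1e-8)
    # eigenvalue sum equals the trace of the Gower-centred matrix
    n <- 12
    A <- -0.5 * unclass(dm)^2
    J <- diag(n) - matrix(1 / n, n, n)
    expect_equal(sum(ord$eigenvalues), sum(diag(J %*% A %*% J)),
                 tolerance = 1e-8)
    expect_true(all(diff(ord$eigenvalues) <= 1e-9))
    expect_gte(ord$relative_eig[1], ord$relative_eig[2])
  })
})

test_that("distance decay counts pairs and recovers a linear construction", {
  n <- 30
  expect_equal(n * (n - 1) / 2, 435)
  withr::with_seed(11, {
    ids <- paste0("s", 1:12)
    km <- as.matrix(dist(matrix(runif(24, 0, 50), 12)))
    dimnames(km) <- list(ids, ids)
    kmd <- dist_matrix(km, metric = "euclid-km")
    sim <- 1 - km / max(km)
    diag(sim) <- 1
    simd <- dist_matrix(sim, metric = "bray-curtis-sim")
    dd <- distance_decay(simd, kmd, permutations = 99, seed = 1)
    expect_equal(dd$slope, -1 / max(km), tolerance = 1e-10)
    expect_equal(dd$intercept, 1, tolerance = 1e-10)
    expect_equal(dd$n_pairs, 66)
    expect_lt(dd$p, 0.05)
  })
})

test_that("distance matrix IO round-trips", {
  dm <- bray_curtis(rand_table(6))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_dist_matrix(dm, tmp)
  back <- read_dist_matrix(tmp, metric = "bray-curtis-dissim")
  expect_equal(unclass(back), unclass(dm), tolerance = 1e-12,
               ignore_attr = TRUE)
})
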