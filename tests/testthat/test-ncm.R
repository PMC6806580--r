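test_that("predicted frequency honours its limits and monotonicity", {
  expect_equal(ncm_predicted_frequency(0.3, 50, 0), 1)
  expect_equal(ncm_predicted_frequency(0, 50, 0.001), 0)
  expect_equal(ncm_predicted_frequency(1, 50, 0.001), 1)
  expect_error(ncm_predicted_frequency(0.1, -1, 0.001), "Nm")
  p_grid <- seq(0.001, 0.999, length.out = 50)
  for (Nm in c(10, 1000)) {
    f <- ncm_predicted_frequency(p_grid, Nm, 1e-3)
    expect_true(all(diff(f) >= -1e-12))          # non-decreasing in p
  }
  d_grid <- seq(0, 0.5, length.out = 30)
  for (p in c(0.01, 0.2)) {
    f <- vapply(d_grid, function(d) ncm_predicted_frequency(p, 200, d),
                numeric(1))
    expect_true(all(diff(f) <= 1e-12))           # non-increasing in d
  }
  expect_true(all(ncm_predicted_frequency(p_grid, 3, 1e-4) >= 0 &
                  ncm_predicted_frequency(p_grid, 3, 1e-4) <= 1))
})

test_that("beta-tail prediction matches a Monte-Carlo beta oracle", {
  withr::with_seed(4, {
    p <- 0.001; Nm <- 1000; d <- 1 / 1000
    draws <- rbeta(2e5, Nm * p, Nm * (1 - p))
    mc <- mean(draws > d)
    se <- sqrt(mc * (1 - mc) / 2e5)
    expect_lt(abs(ncm_predicted_frequency(p, Nm, d) - mc), 4 * se)
  })
})

test_that("sampling detection equals the beta-binomial zero class", {
  withr::with_seed(5, {
    p <- 5e-4; Nm <- 300; N <- 5000
    x <- rbeta(2e5, Nm * p, Nm * (1 - p))
    mc <- mean(rbinom(2e5, N, x) > 0)
    se <- sqrt(mc * (1 - mc) / 2e5)
    expect_lt(abs(ncm_sampling_frequency(p, Nm, N) - mc), 4 * se)
  })
})

test_that("noiseless model data is refitted exactly", {
  p <- 10^seq(-5, -1, length.out = 100)
  N <- 1e4
  freq <- ncm_predicted_frequency(p, 1000, 1 / N)
  inp <- make_ncm_input(p, freq, N, 30)
  fit <- fit_ncm(inp)
  expect_lt(abs(fit$Nm / 1000 - 1), 1e-4)
  expect_gt(fit$r2, 0.999)
  expect_equal(fit$m, fit$Nm / N)
  # frequencies shuffled against p: association destroyed, R^2 collapses
  r2s <- vapply(1:10, function(s) {
    shuf <- withr::with_seed(s, sample(freq))
    fit_ncm(make_ncm_input(p, shuf, N, 30))$r2
  }, numeric(1))
  expect_lt(median(r2s), 0.1)
})

test_that("R^2 is invariant to OTU order and m = Nm/N holds exactly", {
  tbl <- simulate_neutral_samples(S = 400, Nm = 500, N = 2000, n_sites = 15,
                                  seed = 2)
  inp <- ncm_input(tbl)
  fit <- fit_ncm(inp)
  perm <- withr::with_seed(1, sample(nrow(inp)))
  inp2 <- inp[perm, ]
  attr(inp2, "N") <- attr(inp, "N")
  attr(inp2, "n_sites") <- attr(inp, "n_sites")
  class(inp2) <- class(inp)
  fit2 <- fit_ncm(inp2)
  expect_equal(fit$r2, fit2$r2, tolerance = 1e-9)
  expect_equal(fit$Nm, fit2$Nm, tolerance = 1e-9)
  expect_identical(fit$m, fit$Nm / fit$N)
})

test_that("partition labels follow the envelope", {
  p <- 10^seq(-4, -1.5, length.out = 60)
  N <- 5000
  freq <- ncm_predicted_frequency(p, 800, 1 / N)
  # keep frequencies representable as k/n with n = 20 close to prediction
  n <- 20
  fr <- round(freq * n) / n
  inp <- make_ncm_input(p, pmax(fr, 1 / n), N, n)
  fit <- fit_ncm(inp)
  # an OTU pinned at frequency 1 while the envelope tops out below 1
  low_idx <- which.min(fit$taxa$predicted)
  inp2 <- inp
  inp2$freq[low_idx] <- 1
  fit2 <- fit_ncm(inp2)
  if (fit2$taxa$upper[low_idx] < 1)
    expect_equal(as.character(fit2$taxa$partition[low_idx]), "above")
  # frequency exactly equal to the prediction is always neutral
  exact <- fit$taxa$freq == fit$taxa$predicted
  expect_true(all(fit$taxa$partition[exact] == "neutral"))
  labs <- partition_taxa(fit)
  expect_named(labs)
  expect_true(all(labs %in% c("above", "neutral", "below")))
})

test_that("bootstrap intervals are deterministic and bracket noiseless truth", {
  p <- 10^seq(-5, -1, length.out = 80)
  N <- 1e4
  freq <- ncm_predicted_frequency(p, 2000, 1 / N)
  inp <- make_ncm_input(p, freq, N, 30)
  fit <- fit_ncm(inp)
  ci1 <- bootstrap_ci(inp, fit, replicates = 60, seed = 42)
  ci2 <- bootstrap_ci(inp, fit, replicates = 60, seed = 42)
  expect_identical(ci1$Nm_ci, ci2$Nm_ci)
  expect_true(ci1$Nm_ci[1] <= 2000 && 2000 <= ci1$Nm_ci[2])
  expect_lt(diff(ci1$Nm_ci) / 2000, 0.2)
  single <- bootstrap_ci(inp, fit, replicates = 1, seed = 1)
  expect_equal(single$Nm_ci[1], single$Nm_ci[2])
  expect_equal(nrow(ci1$envelope), nrow(fit$taxa))
})

test_that("per-partition refits reproduce the global fit when undivided", {
  p <- 10^seq(-5, -1, length.out = 60)
  N <- 1e4
  freq <- ncm_predicted_frequency(p, 1500, 1 / N)
  inp <- make_ncm_input(p, freq, N, 30)
  fit <- fit_ncm(inp)
  expect_true(all(fit$taxa$partition == "neutral"))
  pm <- suppressWarnings(partition_migration_rates(inp, fit))
  expect_equal(pm$m[pm$partition == "neutral"], fit$m, tolerance = 1e-6)
  expect_true(all(is.na(pm$m[pm$partition != "neutral"])))
})

test_that("partition refits separate two dispersal classes", {
  # high-dispersal and low-dispersal taxa in one metacommunity
  withr::with_seed(31, {
    S <- 600; N <- 5000; n <- 25
    meta_p <- rlnorm(S, 0, 2); meta_p <- meta_p / sum(meta_p)
    cnt <- matrix(0L, n, S, dimnames = list(paste0("s", 1:n),
                                            paste0("o", 1:S)))
    nm_taxon <- rep(c(5000, 50), each = S / 2)  # fast vs slow dispersers
    for (i in 1:n) {
      x <- rbeta(S, nm_taxon * meta_p, nm_taxon * (1 - meta_p))
      cnt[i, ] <- as.integer(rmultinom(1, N, x / sum(x)))
    }
    inp <- ncm_input(otu_table(cnt))
    fit <- fit_ncm(inp, detection = "sampling")
    pm <- suppressWarnings(partition_migration_rates(inp, fit))
    m_above <- pm$m[pm$partition == "above"]
    m_below <- pm$m[pm$partition == "below"]
    if (!is.na(m_above) && !is.na(m_below)) expect_gt(m_above, m_below)
    # the above partition is enriched in fast dispersers
    fast <- inp$otu_id %in% paste0("o", 1:(S / 2))
    above <- fit$taxa$partition == "above"
    below <- fit$taxa$partition == "below"
    expect_gt(mean(fast[above]), mean(fast[below]))
  })
})

test_that("neutral partitions are calibrated on purely neutral data", {
  tbl <- simulate_neutral_samples(S = 1500, Nm = 1000, N = 1e4, n_sites = 30,
                                  seed = 77)
  fit <- fit_ncm(ncm_input(tbl), detection = "sampling")
  expect_gt(mean(fit$taxa$partition == "neutral"), 0.9)
})

test_that("the chain oracle agrees with the beta stationary approximation", {
  meta_p <- c(0.5, 0.3, 0.1, 0.05, 0.03, 0.02)
  m <- 0.3; size <- 200
  snaps <- sloan_chain_oracle(meta_p, m, community_size = size,
                              burnin = 2e4, n_snapshots = 60, thin = 800,
                              seed = 8)
  x <- snaps / size
  expect_equal(colMeans(x), meta_p, tolerance = 0.12)
  # stationary variance ~ p(1-p)/(Nm+1) with Nm = m(size-1)/(1-m)
  nm_eff <- m * (size - 1) / (1 - m)
  v_pred <- meta_p * (1 - meta_p) / (nm_eff + 1)
  ratio <- apply(x, 2, var) / v_pred
  expect_true(all(ratio > 0.4 & ratio < 2.5))
})
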