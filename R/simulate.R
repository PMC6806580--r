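#' Simulate local communities under Sloan's neutral model
#'
#' Generates a sample-by-OTU count table with known ground truth. A lognormal
#' metacommunity of `S` taxa is drawn once and normalized to proportions
#' `p`; each local community's composition is drawn from the stationary
#' distribution of Sloan's birth-death-immigration process, a Dirichlet with
#' concentration `Nm * p`; and `N` reads per site are drawn multinomially
#' from that composition. Large `Nm` makes local communities track the
#' metacommunity tightly; small `Nm` lets drift decouple them.
#'
#' @param S Number of taxa in the metacommunity (default 2000).
#' @param Nm Dispersal parameter (metacommunity size x immigration), `> 0`.
#' @param N Reads per sample (default `1e4`).
#' @param n_sites Number of local communities (default 30).
#' @param lognormal_meanlog,lognormal_sdlog Parameters of the lognormal
#'   species-abundance distribution of the metacommunity (defaults 0 and 2,
#'   a realistic right-skewed microbial SAD spanning ~4 orders of magnitude).
#' @param seed Integer seed; output is a pure function of the configuration
#'   and seed.
#' @param season Optional season label stored in the sample metadata.
#' @return An `otu_table` with attribute `provenance` recording every
#'   parameter (including the metacommunity proportions' seed).
#' @export
simulate_neutral_samples <- function(S = 2000, Nm, N = 1e4, n_sites = 30,
                                     lognormal_meanlog = 0,
                                     lognormal_sdlog = 2,
                                     seed, season = NULL) {
  if (Nm <= 0) stop("Nm must be > 0")
  stopifnot(S >= 2, N >= 1, n_sites >= 2)
  seed <- as.integer(seed)
  counts <- withr::with_seed(seed, {
    meta_p <- stats::rlnorm(S, lognormal_meanlog, lognormal_sdlog)
    meta_p <- meta_p / sum(meta_p)
    .sample_sites_dirichlet(meta_p, Nm, N, n_sites)
  })
  meta <- data.frame(sample_id = rownames(counts))
  if (!is.null(season)) meta$season <- season
  out <- otu_table(counts, sample_meta = meta)
  attr(out, "provenance") <- list(S = S, Nm = Nm, N = N, n_sites = n_sites,
                                  lognormal_meanlog = lognormal_meanlog,
                                  lognormal_sdlog = lognormal_sdlog,
                                  seed = seed, season = season)
  out
}

# Dirichlet(Nm * p) composition per site, then multinomial reads.
# Assumes the RNG state is already set by the caller.
.sample_sites_dirichlet <- function(meta_p, Nm, N, n_sites) {
  S <- length(meta_p)
  counts <- matrix(0L, n_sites, S,
                   dimnames = list(sprintf("site%02d", seq_len(n_sites)),
                                   sprintf("otu%05d", seq_len(S))))
  alpha <- Nm * meta_p
  for (i in seq_len(n_sites)) {
    g <- stats::rgamma(S, shape = alpha, rate = 1)
    if (sum(g) == 0) g[which.max(meta_p)] <- 1  # guard against underflow
    counts[i, ] <- as.integer(stats::rmultinom(1, N, g / sum(g)))
  }
  counts
}

#' Simulate a dendritic river network with coordinates
#'
#' Builds a random rooted tree: node 1 is the network origin (the most
#' upstream source) and each later node attaches to an existing node chosen
#' uniformly among those with fewer than `branching` children; edges point
#' downstream and carry gamma-distributed watercourse lengths. Coordinates
#' are laid out in a small geographic window so that each edge's straight
#' chord is shorter than its watercourse length, guaranteeing that the
#' along-network (dendritic) distance between any two sites is at least
#' their great-circle distance.
#'
#' @param n_sites Number of nodes (>= 3).
#' @param branching Maximum children per node (default 3).
#' @param mean_edge_km Mean watercourse edge length (default 5 km).
#' @param origin Longitude/latitude of the origin node (default a
#'   subtropical river basin window).
#' @param seed Integer seed.
#' @return List with `network` (a `river_network`) and `meta` (data.frame
#'   `sample_id`, `site`, `longitude`, `latitude`).
#' @export
simulate_river_network <- function(n_sites, branching = 3, mean_edge_km = 5,
                                   origin = c(116.5, 25.2), seed) {
  stopifnot(n_sites >= 3)
  seed <- as.integer(seed)
  withr::with_seed(seed, {
    parent <- integer(n_sites)
    n_children <- integer(n_sites)
    for (i in 2:n_sites) {
      open <- which(n_children[seq_len(i - 1)] < branching)
      parent[i] <- if (length(open) == 1) open else sample(open, 1)
      n_children[parent[i]] <- n_children[parent[i]] + 1L
    }
    len <- stats::rgamma(n_sites - 1, shape = 4,
                         rate = 4 / mean_edge_km)
    len <- pmax(len, 0.1)
    lon <- lat <- numeric(n_sites)
    lon[1] <- origin[1]; lat[1] <- origin[2]
    # meander factor < 1: the chord is shorter than the watercourse
    for (i in 2:n_sites) {
      chord <- 0.85 * len[i - 1]
      theta <- stats::runif(1, 0, 2 * pi)
      lat[i] <- lat[parent[i]] + chord * sin(theta) / 110.574
      lon[i] <- lon[parent[i]] +
        chord * cos(theta) / (111.320 * cos(lat[parent[i]] * pi / 180))
    }
    ids <- sprintf("site%02d", seq_len(n_sites))
    nodes <- data.frame(node = ids, longitude = lon, latitude = lat)
    edges <- data.frame(from = ids[parent[2:n_sites]], to = ids[2:n_sites],
                        length_km = len)
    net <- river_network(nodes, edges)
    meta <- data.frame(sample_id = ids, site = ids, longitude = lon,
                       latitude = lat)
    list(network = net, meta = meta)
  })
}

#' Simulate niche-structured communities on a river network
#'
#' The deterministic-assembly contrast to [simulate_neutral_samples()]:
#' expected abundance of each taxon is a Gaussian response to an
#' environmental gradient (species optima spread over the gradient range)
#' multiplied by a spatially autocorrelated lognormal noise field whose
#' correlation decays exponentially with watercourse distance. Counts are
#' multinomial at depth `N`. With `niche_width = Inf` and
#' `autocorr_range = 0` the communities carry no environmental or spatial
#' signal.
#'
#' @param network_sim Result of [simulate_river_network()].
#' @param S Number of taxa (default 300).
#' @param N Reads per sample (default `1e4`).
#' @param niche_width Standard deviation of the Gaussian response on the
#'   gradient scale (default 0.15 of the gradient range; `Inf` disables the
#'   niche effect).
#' @param gradient_strength Multiplier on the gradient (1 = as simulated).
#' @param autocorr_range Range (km) of the exponential spatial correlation of
#'   the noise field (0 disables autocorrelation).
#' @param noise_sdlog Lognormal sd of the noise field (default 0.6).
#' @param seed Integer seed.
#' @return List with `table` (an `otu_table`) and `env` (data.frame of the
#'   gradient plus three uninformative covariates, rows = samples).
#' @export
simulate_niche_communities <- function(network_sim, S = 300, N = 1e4,
                                       niche_width = 0.15,
                                       gradient_strength = 1,
                                       autocorr_range = 10,
                                       noise_sdlog = 0.6, seed) {
  net <- network_sim$network
  meta <- network_sim$meta
  n <- nrow(meta)
  seed <- as.integer(seed)
  D <- network_distances(net)[meta$site, meta$site]
  withr::with_seed(seed, {
    gradient <- as.numeric(scale(D[, 1]))  # distance from the origin
    gradient <- gradient * gradient_strength
    optima <- stats::runif(S, min(gradient) - 0.2, max(gradient) + 0.2)
    base <- stats::rlnorm(S, 0, 1)
    resp <- if (is.infinite(niche_width))
      matrix(1, n, S)
    else
      exp(-outer(gradient, optima, `-`)^2 / (2 * niche_width^2))
    noise <- if (autocorr_range > 0) {
      Sigma <- noise_sdlog^2 * exp(-D / autocorr_range)
      field <- MASS::mvrnorm(S, mu = rep(0, n), Sigma = Sigma)
      exp(t(field))
    } else {
      matrix(stats::rlnorm(n * S, 0, noise_sdlog), n, S)
    }
    lambda <- sweep(resp, 2, base, `*`) * noise
    counts <- t(vapply(seq_len(n), function(i) {
      pr <- lambda[i, ]
      if (sum(pr) == 0) pr <- rep(1, S)
      as.integer(stats::rmultinom(1, N, pr / sum(pr)))
    }, integer(S)))
    dimnames(counts) <- list(meta$sample_id, sprintf("otu%05d", seq_len(S)))
    env <- data.frame(gradient = gradient,
                      noise1 = stats::rnorm(n), noise2 = stats::rnorm(n),
                      noise3 = stats::rnorm(n),
                      row.names = meta$sample_id)
    tbl <- otu_table(counts, sample_meta = meta)
    list(table = tbl, env = env)
  })
}

#' Simulate a two-season neutral contrast
#'
#' Two sample-by-OTU tables drawn from the SAME lognormal metacommunity at
#' different dispersal parameters (`Nm_wet > Nm_dry` emulates the higher
#' hydrological connectivity of the wet season); all other settings shared.
#'
#' @param Nm_wet,Nm_dry Dispersal parameters for the two seasons.
#' @param S,N,n_sites,lognormal_meanlog,lognormal_sdlog As in
#'   [simulate_neutral_samples()].
#' @param seed Integer seed.
#' @return List with `wet` and `dry` (`otu_table`s tagged by season) and
#'   `provenance`.
#' @export
simulate_two_seasons <- function(Nm_wet, Nm_dry, S = 2000, N = 1e4,
                                 n_sites = 30, lognormal_meanlog = 0,
                                 lognormal_sdlog = 2, seed) {
  if (Nm_wet <= 0 || Nm_dry <= 0) stop("Nm must be > 0")
  seed <- as.integer(seed)
  res <- withr::with_seed(seed, {
    meta_p <- stats::rlnorm(S, lognormal_meanlog, lognormal_sdlog)
    meta_p <- meta_p / sum(meta_p)
    wet <- .sample_sites_dirichlet(meta_p, Nm_wet, N, n_sites)
    dry <- .sample_sites_dirichlet(meta_p, Nm_dry, N, n_sites)
    list(wet = wet, dry = dry)
  })
  mk <- function(cm, season) {
    rownames(cm) <- paste0(season, "_", rownames(cm))
    otu_table(cm, sample_meta = data.frame(sample_id = rownames(cm),
                                           season = season))
  }
  list(wet = mk(res$wet, "wet"), dry = mk(res$dry, "dry"),
       provenance = list(Nm_wet = Nm_wet, Nm_dry = Nm_dry, S = S, N = N,
                         n_sites = n_sites,
                         lognormal_meanlog = lognormal_meanlog,
                         lognormal_sdlog = lognormal_sdlog, seed = seed))
}

#' Explicit Sloan birth-death-immigration chain (reference oracle)
#'
#' Simulates the discrete Markov chain the neutral model approximates: a
#' local community of fixed size `community_size`; at each step one random
#' individual dies and is replaced, with probability `m`, by an immigrant
#' drawn from the metacommunity proportions, otherwise by the offspring of a
#' random surviving local individual. Slow by construction; intended only for
#' small cross-checks of the Dirichlet stationary approximation.
#'
#' @param meta_p Metacommunity proportions (sum to 1).
#' @param m Immigration probability per replacement, in (0, 1).
#' @param community_size Individuals in the local community.
#' @param burnin Replacement events to discard.
#' @param n_snapshots Number of stationary snapshots to return.
#' @param thin Replacement events between snapshots.
#' @param seed Integer seed.
#' @return Matrix `n_snapshots x length(meta_p)` of local counts.
#' @export
sloan_chain_oracle <- function(meta_p, m, community_size = 500,
                               burnin = 2e4, n_snapshots = 50, thin = 2000,
                               seed) {
  stopifnot(abs(sum(meta_p) - 1) < 1e-8, m > 0, m < 1)
  S <- length(meta_p)
  withr::with_seed(as.integer(seed), {
    comm <- as.integer(stats::rmultinom(1, community_size, meta_p))
    snaps <- matrix(0L, n_snapshots, S)
    total_steps <- burnin + n_snapshots * thin
    snap_at <- burnin + seq_len(n_snapshots) * thin
    k <- 1L
    for (step in seq_len(total_steps)) {
      dead <- sample.int(S, 1, prob = comm)
      comm[dead] <- comm[dead] - 1L
      repl <- if (stats::runif(1) < m)
        sample.int(S, 1, prob = meta_p)
      else
        sample.int(S, 1, prob = comm)
      comm[repl] <- comm[repl] + 1L
      if (k <= n_snapshots && step == snap_at[k]) {
        snaps[k, ] <- comm
        k <- k + 1L
      }
    }
    snaps
  })
}
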