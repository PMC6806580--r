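#' Predicted detection frequency under the neutral community model
#'
#' Under Sloan's neutral model, the relative abundance of a taxon in a local
#' community is, at stationarity, beta-distributed with shape parameters
#' `Nm * p` and `Nm * (1 - p)`, where `p` is its relative abundance in the
#' metacommunity and `Nm` the product of metacommunity size and immigration
#' rate. The probability of detecting the taxon in a sample with detection
#' limit `d` (the smallest observable relative abundance, one read at the
#' sequencing depth) is the upper tail of that beta distribution:
#' `1 - pbeta(d, Nm p, Nm (1 - p))`.
#'
#' Limits: `p = 0` gives 0, `p = 1` gives 1, and `d = 0` gives 1 for any
#' `p > 0`.
#'
#' @param p Metacommunity relative abundance(s), in `[0, 1]`. Vectorised.
#' @param Nm Dispersal parameter, `> 0`.
#' @param d Detection limit, in `[0, 1)`.
#' @return Predicted occurrence frequencies in `[0, 1]`.
#' @export
ncm_predicted_frequency <- function(p, Nm, d) {
  if (Nm <= 0) stop("Nm must be > 0")
  if (d < 0 || d >= 1) stop("d must be in [0, 1)")
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  out <- 1 - stats::pbeta(d, Nm * p, Nm * (1 - p))
  out[p == 0] <- 0
  out[p == 1] <- 1
  if (d == 0) out[p > 0] <- 1
  pmin(pmax(out, 0), 1)
}

#' Assemble neutral-model input from an OTU table
#'
#' Computes, per OTU, the mean relative abundance across local communities
#' (`p`) and the detection frequency (fraction of samples in which the OTU has
#' a nonzero count). OTUs absent from every sample are excluded. The table is
#' expected to be rarefied so all samples share depth `N`.
#'
#' @param x An `otu_table` whose rows all sum to the same depth (checked; a
#'   differing-depth table is an error unless `N` is supplied explicitly).
#' @param N Sequencing depth per sample; default the common row sum.
#' @return An object of class `ncm_input`: data.frame with columns `otu_id`,
#'   `p`, `freq`, plus attributes `N` and `n_sites`.
#' @export
ncm_input <- function(x, N = NULL) {
  stopifnot(inherits(x, "otu_table"))
  tot <- sample_depths(x)
  if (is.null(N)) {
    if (length(unique(tot)) != 1)
      stop("samples have unequal depths; rarefy first or pass N explicitly")
    N <- unique(tot)
  }
  rel <- relative_abundance(x)
  p <- colMeans(rel)
  freq <- colMeans(x$counts > 0)
  keep <- freq > 0
  out <- data.frame(otu_id = colnames(x$counts)[keep],
                    p = unname(p[keep]), freq = unname(freq[keep]))
  attr(out, "N") <- as.numeric(N)
  attr(out, "n_sites") <- nrow(x$counts)
  class(out) <- c("ncm_input", "data.frame")
  out
}

#' Detection probability under finite-depth count sampling
#'
#' The exact probability that a taxon with metacommunity relative abundance
#' `p` yields at least one read among `N`, when its local relative abundance
#' is beta-distributed with concentration `Nm` (the stationary distribution
#' of the neutral model) and reads are drawn binomially: one minus the
#' zero class of the beta-binomial,
#' `1 - B(Nm p, Nm(1-p) + N) / B(Nm p, Nm(1-p))`.
#'
#' Sloan's classic prediction ([ncm_predicted_frequency()]) replaces this
#' smooth detection curve with a hard threshold at the detection limit `d`;
#' the two agree closely for taxa far from the detection limit but differ in
#' the transition zone, which is why [fit_ncm()] offers both.
#'
#' @inheritParams ncm_predicted_frequency
#' @param N Reads per sample.
#' @return Detection probabilities in `[0, 1]`.
#' @export
ncm_sampling_frequency <- function(p, Nm, N) {
  if (Nm <= 0) stop("Nm must be > 0")
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  a <- Nm * p
  b <- Nm * (1 - p)
  out <- 1 - exp(lbeta(a, b + N) - lbeta(a, b))
  out[p == 0] <- 0
  out[p == 1] <- 1
  pmin(pmax(out, 0), 1)
}

# NCM frequency prediction under either detection model.
.ncm_pred <- function(p, Nm, d, N, detection) {
  if (detection == "threshold") ncm_predicted_frequency(p, Nm, d)
  else ncm_sampling_frequency(p, Nm, N)
}

# Sum of squared residuals of observed frequency around the NCM prediction.
.ncm_sse <- function(log_nm, p, freq, d, N, detection) {
  pred <- .ncm_pred(p, exp(log_nm), d, N, detection)
  sum((freq - pred)^2)
}

# Grid-started golden-section minimisation of the SSE in log(Nm).
.fit_nm <- function(p, freq, d, N, detection) {
  grid <- log(10^seq(-2, 9, by = 0.25))
  sse_grid <- vapply(grid, .ncm_sse, numeric(1), p = p, freq = freq, d = d,
                     N = N, detection = detection)
  i <- which.min(sse_grid)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(.ncm_sse, interval = c(lo, hi), p = p, freq = freq,
                         d = d, N = N, detection = detection, tol = 1e-10)
  list(Nm = exp(opt$minimum), sse = opt$objective)
}

#' Fit the neutral community model
#'
#' Estimates `Nm` by nonlinear least squares of observed detection frequency
#' on the beta-tail prediction, as a function of mean metacommunity relative
#' abundance. The single free parameter is optimised in log space over
#' `[1e-2, 1e9]`, started from a coarse grid so the fit is deterministic.
#' Goodness of fit is `R^2 = 1 - SSE / SStot` with `SStot` taken about the
#' mean observed frequency (it can be negative for data unlike the model).
#' The immigration rate is reported as `m = Nm / N`.
#'
#' A 95% prediction envelope around the fitted curve is computed per OTU:
#' the observed frequency is a binomial proportion over `n_sites` local
#' communities, so the default envelope is the exact binomial
#' quantile acceptance region `[qbinom(0.025), qbinom(0.975)]/n_sites` at the
#' predicted frequency. A Wilson score interval centred on the prediction is
#' available as an alternative (it is narrower and mislabels more truly
#' neutral taxa at small `n_sites`).
#'
#' @param input An `ncm_input`, or an `otu_table` (converted via
#'   [ncm_input()]).
#' @param d Detection limit; default `1/N`, one read at the sample depth.
#' @param conf Envelope confidence level (default 0.95).
#' @param detection `"threshold"` (Sloan's classic beta-tail prediction with
#'   detection limit `d`, the default) or `"sampling"` (the exact
#'   beta-binomial detection probability for finite-depth count data,
#'   [ncm_sampling_frequency()]; `d` is then unused).
#' @param bias_correct Apply a parametric-bootstrap bias correction: simulate
#'   `bias_reps` tables from the fitted model (Dirichlet-multinomial at the
#'   naive estimate, using the observed abundances as the metacommunity),
#'   refit each, and divide the naive estimate by the mean inflation factor.
#'   Removes the attenuation caused by estimating `p` from finitely many
#'   sites. Default `FALSE`.
#' @param bias_reps Bootstrap tables used for the correction (default 8).
#' @param seed Seed for the bias-correction simulations (required when
#'   `bias_correct = TRUE`).
#' @param envelope `"binomial"` (exact binomial quantile region, default) or
#'   `"wilson"` (Wilson score interval around the prediction).
#' @return An object of class `ncm_fit`: list with elements `Nm`, `m`, `r2`,
#'   `d`, `N`, `n_sites`, `detection`, `Nm_naive`, and `taxa` (data.frame
#'   with `otu_id`, `p`, `freq`, `predicted`, `lower`, `upper`, `partition`).
#' @export
fit_ncm <- function(input, d = NULL, conf = 0.95,
                    detection = c("threshold", "sampling"),
                    bias_correct = FALSE, bias_reps = 8, seed = NULL,
                    envelope = c("binomial", "wilson")) {
  if (inherits(input, "otu_table")) input <- ncm_input(input)
  stopifnot(inherits(input, "ncm_input"))
  detection <- match.arg(detection)
  envelope <- match.arg(envelope)
  N <- attr(input, "N")
  n_sites <- attr(input, "n_sites")
  if (is.null(d)) d <- 1 / N
  p <- input$p
  freq <- input$freq
  if (length(unique(p)) < 10)
    stop("need >= 10 OTUs with distinct p values to fit the model")
  base <- .fit_nm(p, freq, d, N, detection)
  Nm <- Nm_naive <- base$Nm
  sse <- base$sse
  if (bias_correct) {
    if (is.null(seed)) stop("bias_correct = TRUE requires a seed")
    meta_p <- p / sum(p)
    refits <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(bias_reps), function(k) {
        cnt <- .sample_sites_dirichlet(meta_p, Nm_naive, N, n_sites)
        ps <- colMeans(cnt / N)
        fr <- colMeans(cnt > 0)
        keep <- fr > 0
        .fit_nm(ps[keep], fr[keep], d, N, detection)$Nm
      }, numeric(1))
    })
    Nm <- Nm_naive^2 / mean(refits)
    sse <- .ncm_sse(log(Nm), p, freq, d, N, detection)
  }
  sstot <- sum((freq - mean(freq))^2)
  r2 <- if (sstot == 0) {
    warning("all observed frequencies equal; R^2 undefined")
    NA_real_
  } else 1 - sse / sstot
  pred <- .ncm_pred(p, Nm, d, N, detection)
  env <- if (envelope == "wilson") wilson_interval(pred, n_sites, conf = conf)
         else binomial_envelope(pred, n_sites, conf = conf)
  partition <- rep("neutral", length(p))
  partition[freq > env$upper] <- "above"
  partition[freq < env$lower] <- "below"
  # a point exactly on the fitted curve is never a deviation, even where a
  # discrete envelope is degenerate (e.g. [0, 0] at very small predictions)
  partition[abs(freq - pred) < 1e-7] <- "neutral"
  taxa <- data.frame(otu_id = input$otu_id, p = p, freq = freq,
                     predicted = pred, lower = env$lower, upper = env$upper,
                     partition = factor(partition,
                                        levels = c("above", "neutral",
                                                   "below")))
  structure(list(Nm = Nm, m = Nm / N, r2 = r2, d = d, N = N,
                 n_sites = n_sites, conf = conf, detection = detection,
                 envelope = envelope, Nm_naive = Nm_naive, taxa = taxa),
            class = "ncm_fit")
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf("Sloan neutral community model fit (%d OTUs, %d sites)\n",
              nrow(x$taxa), x$n_sites))
  cat(sprintf("  Nm = %.4g   m = Nm/N = %.4g (N = %g)\n", x$Nm, x$m, x$N))
  cat(sprintf("  R^2 = %.4f   detection limit d = %.3g\n", x$r2, x$d))
  print(table(x$taxa$partition))
  invisible(x)
}

#' Exact binomial quantile envelope
#'
#' Central acceptance region for an observed binomial proportion given the
#' hypothesised proportion `p` and `n` trials:
#' `[qbinom((1-conf)/2, n, p), qbinom(1-(1-conf)/2, n, p)] / n`.
#'
#' @param p Proportion(s) (here: NCM predicted frequencies).
#' @param n Number of trials (local communities).
#' @param conf Confidence level.
#' @return List with vectors `lower` and `upper`.
#' @export
binomial_envelope <- function(p, n, conf = 0.95) {
  alpha <- (1 - conf) / 2
  list(lower = stats::qbinom(alpha, n, p) / n,
       upper = stats::qbinom(1 - alpha, n, p) / n)
}

#' Wilson score interval for a binomial proportion
#'
#' @param p Proportion(s) (here: NCM predicted frequencies).
#' @param n Number of trials (local communities).
#' @param conf Confidence level.
#' @return List with vectors `lower` and `upper`, clamped to `[0, 1]`.
#' @export
wilson_interval <- function(p, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(lower = pmax(centre - half, 0), upper = pmin(centre + half, 1))
}

#' Bootstrap confidence intervals for the NCM fitting statistics
#'
#' Resamples OTUs with replacement, refits the model per replicate, and
#' returns percentile 2.5/97.5% bounds for `Nm` and `R^2`, together with the
#' replicate distributions. Replicates whose refit fails are dropped and
#' counted; more than 5% failures is an error. A per-OTU prediction envelope
#' derived from the bootstrap distribution of `Nm` is also returned, as an
#' alternative to the Wilson envelope of [fit_ncm()].
#'
#' @param input An `ncm_input`.
#' @param fit The corresponding `ncm_fit`.
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; intervals are deterministic given it.
#' @return List with `Nm_ci`, `r2_ci` (length-2 vectors), `boot`
#'   (data.frame of replicate `Nm` and `r2`), `dropped`, and `envelope`
#'   (per-OTU predicted-frequency bounds across bootstrap `Nm` values).
#' @export
bootstrap_ci <- function(input, fit, replicates = 1000, seed) {
  stopifnot(inherits(input, "ncm_input"), inherits(fit, "ncm_fit"))
  n <- nrow(input)
  draws <- withr::with_seed(as.integer(seed),
    matrix(sample.int(n, n * replicates, replace = TRUE), nrow = n))
  nm_b <- r2_b <- rep(NA_real_, replicates)
  for (b in seq_len(replicates)) {
    idx <- draws[, b]
    res <- tryCatch({
      sub <- input[idx, , drop = FALSE]
      attr(sub, "N") <- attr(input, "N")
      attr(sub, "n_sites") <- attr(input, "n_sites")
      class(sub) <- class(input)
      f <- fit_ncm(sub, d = fit$d, conf = fit$conf,
                   detection = fit$detection, envelope = fit$envelope)
      c(f$Nm, f$r2)
    }, error = function(e) c(NA_real_, NA_real_))
    nm_b[b] <- res[1]
    r2_b[b] <- res[2]
  }
  dropped <- sum(is.na(nm_b))
  if (dropped > 0.05 * replicates)
    stop(dropped, " of ", replicates, " bootstrap replicates failed")
  probs <- c((1 - fit$conf) / 2, 1 - (1 - fit$conf) / 2)
  nm_ok <- nm_b[!is.na(nm_b)]
  pred_lo <- .ncm_pred(fit$taxa$p, stats::quantile(nm_ok, probs[1]), fit$d,
                       attr(input, "N"), fit$detection)
  pred_hi <- .ncm_pred(fit$taxa$p, stats::quantile(nm_ok, probs[2]), fit$d,
                       attr(input, "N"), fit$detection)
  list(Nm_ci = unname(stats::quantile(nm_ok, probs)),
       r2_ci = unname(stats::quantile(r2_b[!is.na(r2_b)], probs)),
       boot = data.frame(Nm = nm_b, r2 = r2_b),
       dropped = dropped,
       envelope = data.frame(otu_id = fit$taxa$otu_id,
                             lower = pmin(pred_lo, pred_hi),
                             upper = pmax(pred_lo, pred_hi)))
}

#' Partition taxa against the neutral prediction envelope
#'
#' Labels each OTU `above`, `neutral`, or `below` according to whether its
#' observed detection frequency exceeds, falls inside, or falls short of the
#' 95% envelope around the fitted prediction (Wilson score interval with
#' `n_sites` trials, as stored in the fit).
#'
#' @param fit An `ncm_fit`.
#' @return Named factor of partition labels, one per OTU.
#' @export
partition_taxa <- function(fit) {
  stopifnot(inherits(fit, "ncm_fit"))
  stats::setNames(fit$taxa$partition, fit$taxa$otu_id)
}

#' Per-partition migration rates
#'
#' Refits the neutral model separately within each partition (above, neutral,
#' below) of a previous global fit, reporting the partition-specific `Nm` and
#' `m = Nm / N`. Partitions with fewer than `min_otus` OTUs are reported as
#' `NA` with a warning. A partition containing every OTU reproduces the
#' global fit.
#'
#' @param input The `ncm_input` used for the global fit.
#' @param fit The global `ncm_fit`.
#' @param min_otus Minimum OTUs required to refit a partition (default 10).
#' @return A `data.frame` with one row per partition: `partition`, `n_otus`,
#'   `Nm`, `m`, `r2`.
#' @export
partition_migration_rates <- function(input, fit, min_otus = 10) {
  stopifnot(inherits(input, "ncm_input"), inherits(fit, "ncm_fit"))
  labels <- fit$taxa$partition
  out <- lapply(levels(labels), function(lv) {
    idx <- which(labels == lv)
    if (length(idx) < min_otus ||
        length(unique(input$p[idx])) < min_otus) {
      warning("partition '", lv, "' has fewer than ", min_otus,
              " OTUs; migration rate reported as NA")
      return(data.frame(partition = lv, n_otus = length(idx),
                        Nm = NA_real_, m = NA_real_, r2 = NA_real_))
    }
    sub <- input[idx, , drop = FALSE]
    attr(sub, "N") <- attr(input, "N")
    attr(sub, "n_sites") <- attr(input, "n_sites")
    class(sub) <- class(input)
    f <- fit_ncm(sub, d = fit$d, conf = fit$conf,
                 detection = fit$detection, envelope = fit$envelope)
    data.frame(partition = lv, n_otus = length(idx), Nm = f$Nm, m = f$m,
               r2 = f$r2)
  })
  do.call(rbind, out)
}

#' Write an NCM fit report
#'
#' Emits a JSON summary (`Nm`, `m`, `R2`, `d`, optional bootstrap CIs) and a
#' per-OTU TSV (`p`, `freq`, `predicted`, `lower`, `upper`, `partition`).
#'
#' @param fit An `ncm_fit`.
#' @param json_path,tsv_path Output paths (either may be `NULL` to skip).
#' @param ci Optional result of [bootstrap_ci()] to embed.
#' @return Invisibly, the list written as JSON.
#' @export
write_ncm_report <- function(fit, json_path = NULL, tsv_path = NULL,
                             ci = NULL) {
  stopifnot(inherits(fit, "ncm_fit"))
  doc <- list(Nm = fit$Nm, m = fit$m, R2 = fit$r2, d = fit$d, N = fit$N,
              n_sites = fit$n_sites,
              partition_counts = as.list(table(fit$taxa$partition)))
  if (!is.null(ci)) doc$ci <- list(Nm = ci$Nm_ci, R2 = ci$r2_ci)
  if (!is.null(json_path))
    jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(tsv_path))
    utils::write.table(fit$taxa, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(doc)
}
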