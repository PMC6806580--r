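#' Alpha diversity and coverage indices per sample
#'
#' Computes, for every sample: observed OTU richness, Chao1 (classic
#' `S + F1^2/(2 F2)` and the bias-corrected `S + F1(F1-1)/(2(F2+1))` variant),
#' ACE (abundance-based coverage estimator, rare/abundant cutoff 10),
#' Shannon-Wiener entropy in nats, Pielou evenness `H / ln S`, the Gini-Simpson
#' index `1 - sum(p^2)`, and Good's coverage `1 - F1/N`. Richness, Chao1 and
#' ACE come from [vegan::estimateR()]; Shannon and Simpson from
#' [vegan::diversity()].
#'
#' Pielou evenness is undefined for a single-OTU sample and reported as `NA`
#' with a warning.
#'
#' @param x An `otu_table`.
#' @param ace_cutoff Abundance below or at which an OTU counts as "rare" for
#'   ACE (default 10, the conventional value).
#' @return A `data.frame`, one row per sample, columns `richness`,
#'   `chao1` (bias-corrected), `chao1_classic`, `ace`, `shannon`, `pielou`,
#'   `simpson`, `goods_coverage`.
#' @export
alpha_indices <- function(x, ace_cutoff = 10) {
  stopifnot(inherits(x, "otu_table"))
  cm <- x$counts
  if (any(rowSums(cm) == 0)) stop("all-zero sample(s) present")
  est <- vegan::estimateR(cm)  # S.obs, S.chao1, se, S.ACE, se
  S <- est["S.obs", ]
  f1 <- apply(cm, 1, function(r) sum(r == 1))
  f2 <- apply(cm, 1, function(r) sum(r == 2))
  chao1_classic <- ifelse(f2 > 0, S + f1^2 / (2 * f2),
                          S + f1 * (f1 - 1) / 2)
  chao1_bc <- S + f1 * (f1 - 1) / (2 * (f2 + 1))
  H <- vegan::diversity(cm, index = "shannon")
  simpson <- vegan::diversity(cm, index = "simpson")
  pielou <- ifelse(S > 1, H / log(S), NA_real_)
  if (any(S == 1))
    warning("Pielou evenness undefined for single-OTU sample(s): ",
            paste(rownames(cm)[S == 1], collapse = ", "))
  ace <- if (identical(ace_cutoff, 10)) est["S.ACE", ] else
    apply(cm, 1, .ace_one, cutoff = ace_cutoff)
  data.frame(sample_id = rownames(cm),
             richness = unname(S),
             chao1 = unname(chao1_bc),
             chao1_classic = unname(chao1_classic),
             ace = unname(ace),
             shannon = unname(H),
             pielou = unname(pielou),
             simpson = unname(simpson),
             goods_coverage = unname(goods_coverage(x)),
             row.names = rownames(cm))
}

# Chao & Lee ACE for one sample at an arbitrary rare/abundant cutoff.
.ace_one <- function(r, cutoff = 10) {
  r <- r[r > 0]
  rare <- r[r <= cutoff]
  s_abund <- sum(r > cutoff)
  s_rare <- length(rare)
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  if (n_rare == 0) return(s_abund)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) return(NA_real_)
  fk <- tabulate(rare, nbins = cutoff)
  gamma2 <- max(s_rare / c_ace *
                  sum(seq_len(cutoff) * (seq_len(cutoff) - 1) * fk) /
                  (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + f1 / c_ace * gamma2
}

#' Good's coverage
#'
#' `1 - F1/N`: the estimated fraction of the community's individuals belonging
#' to OTUs already observed, with `F1` the number of singleton OTUs and `N`
#' the sample's sequence total.
#'
#' @param x An `otu_table`.
#' @return Named numeric vector, one proportion per sample.
#' @export
goods_coverage <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  n <- rowSums(x$counts)
  if (any(n == 0)) stop("all-zero sample(s) present")
  f1 <- apply(x$counts, 1, function(r) sum(r == 1))
  1 - f1 / n
}

#' Rarefaction curves
#'
#' Mean observed richness per sample at a ladder of subsampling depths,
#' averaged over `repeats` independent rarefactions (sampling without
#' replacement). The analytic hypergeometric expectation
#' ([vegan::rarefy()]) is also returned for reference.
#'
#' @param x An `otu_table`.
#' @param depths Increasing integer vector of subsampling depths; all must be
#'   at most the smallest sample total unless `drop_small = TRUE` at use site.
#' @param repeats Rarefactions averaged per depth (default 10).
#' @param seed Integer seed.
#' @return A long `data.frame` with columns `sample_id`, `depth`,
#'   `mean_richness`, `expected_richness`.
#' @export
rarefaction_curve <- function(x, depths, repeats = 10, seed) {
  stopifnot(inherits(x, "otu_table"), all(diff(depths) > 0))
  tot <- sample_depths(x)
  if (max(depths) > min(tot))
    stop("max depth ", max(depths), " exceeds smallest sample total ",
         min(tot))
  res <- list()
  seed <- as.integer(seed)
  for (d in depths) {
    acc <- numeric(nrow(x$counts))
    for (r in seq_len(repeats)) {
      sub <- withr::with_seed(seed + 1000L * match(d, depths) + r,
                              .rrarefy_quiet(x$counts, d))
      acc <- acc + rowSums(sub > 0)
    }
    res[[length(res) + 1L]] <- data.frame(
      sample_id = rownames(x$counts),
      depth = d,
      mean_richness = acc / repeats,
      expected_richness = as.numeric(suppressWarnings(
        vegan::rarefy(x$counts, d))))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
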