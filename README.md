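# riverneutral

Tools for asking how riverine microbial (e.g. 18S micro-eukaryotic plankton)
communities are assembled: how much of the site-to-site variation in a
sample-by-OTU count table is explained by neutral processes — random birth,
death, drift and immigration along the flow network — and how much by
deterministic sorting along environmental gradients.

The package implements, end to end:

- **Sloan's neutral community model (NCM).** At stationarity a taxon's
  local relative abundance is `Beta(Nm·p, Nm·(1−p))`, with `p` its
  metacommunity relative abundance and `Nm` the metacommunity size times
  immigration rate. Its predicted occurrence frequency across sites is the
  upper beta tail above the detection limit `d` (one read at the rarefied
  depth, `d = 1/N`). `fit_ncm()` estimates `Nm` by nonlinear least squares,
  reports `R²` and the immigration rate `m = Nm/N`, draws a 95% prediction
  envelope, partitions taxa into above / neutral / below fractions,
  bootstraps confidence intervals, and refits `m` per partition. An exact
  finite-depth detection model (`detection = "sampling"`) and a
  parametric-bootstrap bias correction are available for unbiased `Nm`
  recovery from count data.
- **Rare-biosphere classification** of OTUs into AAT / CAT / MT / ART /
  CRT / CRAT at 0.01% / 1% per-sample relative-abundance thresholds, with
  pooled "dominant" (AAT+CAT+CRAT) subcommunities.
- **Alpha diversity**: richness, Chao1 (classic and bias-corrected), ACE,
  Shannon, Pielou, Gini-Simpson, Good's coverage, rarefaction curves.
- **Beta diversity and space**: Bray-Curtis matrices, PCoA, ANOSIM,
  Mantel / partial Mantel (Spearman or Pearson, permutation p-values),
  distance-decay regressions against both great-circle and dendritic
  (along-watercourse) distance on a river network.
- **Spatial eigenfunctions**: PCNM vectors from truncated geographic
  distances, and directional AEM vectors from a site-by-edge matrix of the
  flow network with edge weights `1 − (d/d_max)²`.
- **Variation partitioning**: Hellinger transform, VIF filtering (> 20
  removed), forward selection with a double stopping rule, and partial-RDA
  adjusted-R² fractions `[a]` pure environment, `[b]` shared, `[c]` pure
  space, `[d]` unexplained (plus a partial-Mantel analogue).
- **Synthetic data with known truth**: neutral metacommunities
  (Dirichlet-multinomial at specified `Nm`), two-season contrasts sharing
  one metacommunity, random dendritic river networks with coordinates, and
  niche-structured communities on environmental gradients.

See the methods vignette (`vignettes/community-assembly-methods.Rmd`) for
models, assumptions, parameter defaults and design decisions.

## Worked example

A small synthetic two-season data set (10 sites on a dendritic network,
wet season simulated at `Nm = 800`, dry at `Nm = 250`, shared
metacommunity) ships with the package:

```r
library(riverneutral)

otu  <- system.file("extdata", "synthetic_two_season_otu.tsv",
                    package = "riverneutral")
meta <- system.file("extdata", "synthetic_two_season_meta.json",
                    package = "riverneutral")
tbl <- read_otu_table(otu, meta_path = meta)
tbl <- rarefy_table(tbl, depth = 2000, seed = 1)

classify_taxa(relative_abundance(tbl))
#> rarity_assignment over 115 OTUs (rare < 0.0001, abundant >= 0.01)
#>  AAT  CAT   MT  ART  CRT CRAT
#>   12   28    0    0   62   13

for (ssn in c("wet", "dry")) {
  keep <- tbl$sample_meta$sample_id[tbl$sample_meta$season == ssn]
  sub  <- subset_otu_table(tbl, samples = keep)
  fit  <- fit_ncm(ncm_input(sub), detection = "sampling")
  cat(sprintf("%s season: Nm = %.0f, m = %.3f, R2 = %.3f\n",
              ssn, fit$Nm, fit$m, fit$r2))
}
#> wet season: Nm = 811, m = 0.405, R2 = 0.924
#> dry season: Nm = 309, m = 0.155, R2 = 0.891
```

The fits recover the simulated dispersal parameters (811 vs. truth 800;
309 vs. 250 — ten sites is a small design for the low-`Nm` regime), the
`R²` values say the neutral curve explains ~90% of the frequency-abundance
relationship, and the wet season shows the higher immigration rate
`m = Nm/N`, i.e. stronger dispersal, as simulated.

`run_pipeline()` orchestrates the whole analysis (alpha, rarity classes,
NCM per season and subcommunity, distance decay, Mantel against each
environmental variable, variation partitioning with PCNM and/or AEM
predictors) from a YAML/JSON config and writes a machine-readable summary;
`inst/scripts/riverneutral.R` is a thin command-line wrapper over the same
functions.

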