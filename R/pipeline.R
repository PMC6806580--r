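#' Read a pipeline configuration
#'
#' YAML or JSON document with the fields used by [run_pipeline()]:
#' `otu_table` (path, TSV), `metadata` (path, JSON keyed by sample id, with
#' `season`, `longitude`, `latitude`, `site`), optional `environment` (TSV,
#' samples x variables), optional `network_edges`/`network_nodes` (TSV),
#' `rarefaction: {depth, seed}`, `rarity: {rare_threshold,
#' abundant_threshold}`, `ncm: {envelope, bootstrap_replicates}`,
#' `mantel: {permutations}`, `spatial: pcnm|aem|both`, `output_dir`, `seed`.
#' Missing optional blocks get the defaults below.
#'
#' @param path Config file path (`.yaml`/`.yml` or `.json`).
#' @return A named list (class `pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  .fill_config_defaults(cfg)
}

.fill_config_defaults <- function(cfg) {
  defaults <- list(rarity = list(rare_threshold = 1e-4,
                                 abundant_threshold = 1e-2),
                   ncm = list(envelope = "binomial",
                              bootstrap_replicates = 1000),
                   mantel = list(permutations = 999),
                   spatial = "both", seed = 1)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]]))
      for (k in names(defaults[[nm]]))
        if (is.null(cfg[[nm]][[k]])) cfg[[nm]][[k]] <- defaults[[nm]][[k]]
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Run the full community-assembly analysis
#'
#' Orchestrates the package end-to-end, per season (each season label in the
#' metadata plus the pooled `"all"`) and per subcommunity (`total`,
#' `dominant`, `ART`, `CRT`): rarefaction, rarity classification, alpha
#' diversity, Bray-Curtis matrices, PCoA, ANOSIM between seasons,
#' distance-decay against Euclidean and (when a network is supplied)
#' dendritic distance, Mantel tests against each environmental variable
#' (square-root transformed except pH), the neutral-model fit with taxon
#' partitions and per-partition migration rates, and variation partitioning
#' of the Hellinger-transformed community against environmental and spatial
#' (PCNM and/or AEM) predictors. Every stage writes its table under
#' `output_dir` and contributes headline numbers to a JSON summary. Stages
#' whose inputs are absent (no coordinates, no network, no environment
#' table) are recorded as `"skipped"` entries, never silently dropped.
#'
#' @param config A `pipeline_config`, a path to one, or an equivalent named
#'   list. Alternatively pass `table` (an `otu_table`) and friends directly.
#' @param table Optional in-memory `otu_table` (overrides `config$otu_table`).
#' @param env Optional environment `data.frame` (rows = samples).
#' @param network Optional `river_network`.
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config, table = NULL, env = NULL, network = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- .fill_config_defaults(config)
  out_dir <- cfg$output_dir %||% stop("config needs output_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(config = cfg[setdiff(names(cfg), "output_dir")],
                  stages = list())
  note <- function(stage, value) summary$stages[[stage]] <<- value

  if (is.null(table))
    table <- read_otu_table(cfg$otu_table, meta_path = cfg$metadata)
  if (is.null(env) && !is.null(cfg$environment)) {
    env <- utils::read.delim(cfg$environment, row.names = 1)
  }
  if (is.null(network) && !is.null(cfg$network_edges))
    network <- read_river_network(cfg$network_edges, cfg$network_nodes)

  depth <- cfg$rarefaction$depth %||% min(sample_depths(table))
  rar <- rarefy_table(table, depth, seed = cfg$rarefaction$seed %||% cfg$seed,
                      drop_small = TRUE)
  note("rarefaction", list(depth = depth, n_samples = nrow(rar$counts)))

  assign <- classify_taxa(rar, cfg$rarity$rare_threshold,
                          cfg$rarity$abundant_threshold)
  write_rarity(assign, file.path(out_dir, "rarity.tsv"))
  note("rarity", as.list(table(assign$category)))

  alpha <- alpha_indices(rar)
  utils::write.table(alpha, file.path(out_dir, "alpha.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note("alpha", list(mean_richness = mean(alpha$richness),
                     goods_coverage_range = range(alpha$goods_coverage)))

  meta <- rar$sample_meta
  seasons <- if (!is.null(meta$season)) unique(as.character(meta$season))
             else character(0)
  season_sets <- c(stats::setNames(lapply(seasons, function(s)
    meta$sample_id[meta$season == s]), seasons),
    list(all = rownames(rar$counts)))

  communities <- function(tbl) {
    asg <- classify_taxa(tbl, cfg$rarity$rare_threshold,
                         cfg$rarity$abundant_threshold)
    list(total = tbl,
         dominant = suppressWarnings(pool_dominant(asg, tbl)),
         ART = suppressWarnings(pool_categories(asg, tbl, "ART")),
         CRT = suppressWarnings(pool_categories(asg, tbl, "CRT")))
  }

  # ANOSIM wet vs dry on the full table
  if (length(seasons) >= 2 && all(table(meta$season) >= 2)) {
    bc_all <- bray_curtis(rar)
    an <- anosim_test(bc_all, meta$season,
                      permutations = cfg$mantel$permutations, seed = cfg$seed)
    note("anosim_season", an)
  } else note("anosim_season", "skipped")

  have_coords <- !is.null(meta$longitude) && !is.null(meta$latitude)

  ncm_rows <- list()
  for (sn in names(season_sets)) {
    ids <- season_sets[[sn]]
    if (length(ids) < 3) { note(paste0("season_", sn), "skipped"); next }
    stbl <- suppressWarnings(subset_otu_table(rar, samples = ids))
    smeta <- stbl$sample_meta
    comms <- communities(stbl)
    for (cn in names(comms)) {
      ctbl <- comms[[cn]]
      key <- paste(sn, cn, sep = "_")
      if (ncol(ctbl$counts) < 10) { note(paste0("ncm_", key), "skipped"); next }
      inp <- ncm_input(ctbl, N = depth)
      fit <- tryCatch(fit_ncm(inp), error = function(e) NULL)
      if (is.null(fit)) { note(paste0("ncm_", key), "failed"); next }
      stopifnot(isTRUE(all.equal(fit$m, fit$Nm / fit$N)))
      write_ncm_report(fit,
                       json_path = file.path(out_dir,
                                             paste0("ncm_", key, ".json")),
                       tsv_path = file.path(out_dir,
                                            paste0("ncm_", key, ".tsv")))
      pm <- suppressWarnings(partition_migration_rates(inp, fit))
      ncm_rows[[key]] <- list(season = sn, community = cn, Nm = fit$Nm,
                              m = fit$m, r2 = fit$r2,
                              partition_m = stats::setNames(pm$m,
                                                            pm$partition))
      note(paste0("ncm_", key),
           list(Nm = fit$Nm, m = fit$m, r2 = fit$r2))
    }
    # distance-decay per season on the total community
    if (have_coords && length(ids) >= 4) {
      sim <- bray_curtis(stbl, similarity = TRUE)
      de <- geo_distances(smeta, mode = "euclidean")
      dd <- distance_decay(sim, de, permutations = cfg$mantel$permutations,
                           seed = cfg$seed)
      note(paste0("distance_decay_euclid_", sn), dd)
      if (!is.null(network)) {
        dn <- geo_distances(smeta, network = network, mode = "dendritic")
        ddn <- distance_decay(sim, dn,
                              permutations = cfg$mantel$permutations,
                              seed = cfg$seed)
        note(paste0("distance_decay_dendritic_", sn), ddn)
      } else note(paste0("distance_decay_dendritic_", sn), "skipped")
    } else {
      note(paste0("distance_decay_euclid_", sn), "skipped")
      note(paste0("distance_decay_dendritic_", sn), "skipped")
    }
    # Mantel against each environmental variable; varpart
    if (!is.null(env)) {
      senv <- env[intersect(rownames(env), ids), , drop = FALSE]
      if (nrow(senv) == length(ids) && length(ids) >= 5) {
        bcd <- bray_curtis(stbl)
        per_var <- lapply(names(senv), function(v) {
          dv <- env_distances(senv[, v, drop = FALSE],
                              sqrt_except = "pH")
          mt <- mantel_test(bcd, dv,
                            permutations = cfg$mantel$permutations,
                            seed = cfg$seed)
          list(variable = v, r = mt$r, p = mt$p)
        })
        note(paste0("mantel_env_", sn), per_var)
        if (have_coords) {
          Y <- hellinger_transform(stbl)
          Xe <- as.matrix(.transform_env(senv))
          vp <- .varpart_stage(Y, Xe, smeta, network, cfg)
          note(paste0("varpart_", sn), vp)
        } else note(paste0("varpart_", sn), "skipped")
      } else note(paste0("mantel_env_", sn), "skipped")
    } else {
      note(paste0("mantel_env_", sn), "skipped")
      note(paste0("varpart_", sn), "skipped")
    }
  }
  summary$ncm <- ncm_rows
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  invisible(summary)
}

# Square-root transform every environmental variable except pH.
.transform_env <- function(env) {
  for (cn in setdiff(names(env), "pH"))
    if (is.numeric(env[[cn]]) && all(env[[cn]] >= 0, na.rm = TRUE))
      env[[cn]] <- sqrt(env[[cn]])
  env
}

# Env-vs-spatial variation partitioning for one season subset.
.varpart_stage <- function(Y, Xe, smeta, network, cfg) {
  vf <- vif_filter(Xe, threshold = 20)
  fs_env <- forward_select(Y, vf$X, permutations = cfg$mantel$permutations,
                           seed = cfg$seed)
  Xe_sel <- if (length(fs_env$selected))
    vf$X[, fs_env$selected, drop = FALSE] else NULL
  out <- list()
  spatial_modes <- if (identical(cfg$spatial, "both")) c("pcnm", "aem")
                   else cfg$spatial
  for (mode in spatial_modes) {
    Xs <- tryCatch({
      if (mode == "pcnm") {
        de <- geo_distances(smeta, mode = "euclidean")
        pcnm_vectors(de)$vectors
      } else {
        if (is.null(network)) NULL else {
          sbe <- build_site_by_edge(network, smeta$site)
          aem_vectors(sbe, network$edges$length_km)$vectors
        }
      }
    }, error = function(e) NULL)
    if (is.null(Xs) || ncol(Xs) == 0) { out[[mode]] <- "skipped"; next }
    fs_spa <- forward_select(Y, Xs, permutations = cfg$mantel$permutations,
                             seed = cfg$seed + 1L)
    Xs_sel <- if (length(fs_spa$selected))
      Xs[, fs_spa$selected, drop = FALSE] else NULL
    vp <- suppressWarnings(varpart2(Y, Xe_sel, Xs_sel))
    out[[mode]] <- list(fractions = as.list(vp$fractions),
                        selected_env = fs_env$selected,
                        selected_spatial = fs_spa$selected)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
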