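#' Construct a tagged distance matrix
#'
#' A thin wrapper around a symmetric numeric matrix with zero diagonal,
#' carrying its sample labels and a metric tag so downstream statistics can
#' check they are being fed compatible objects.
#'
#' @param values Symmetric numeric matrix with zero diagonal, or a `dist`.
#' @param labels Sample ids (default: dimnames of `values`).
#' @param metric Tag, e.g. `"bray-curtis-dissim"`, `"bray-curtis-sim"`,
#'   `"euclid-km"`, `"dendritic-km"`, `"env-euclid"`.
#' @return A classed matrix (`dist_matrix`).
#' @export
dist_matrix <- function(values, labels = NULL, metric = "unknown") {
  if (inherits(values, "dist")) values <- as.matrix(values)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("distance matrix must be square")
  if (max(abs(values - t(values))) > 1e-8) stop("matrix is not symmetric")
  is_sim <- grepl("-sim$", metric)
  diag_value <- if (is_sim) 1 else 0
  if (max(abs(diag(values) - diag_value)) > 1e-8)
    stop("diagonal must be ", diag_value, " for metric '", metric, "'")
  values <- (values + t(values)) / 2
  diag(values) <- diag_value
  if (is.null(labels)) labels <- rownames(values)
  if (is.null(labels)) labels <- paste0("sample", seq_len(nrow(values)))
  dimnames(values) <- list(labels, labels)
  structure(values, metric = metric, class = c("dist_matrix", "matrix",
                                               "array"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("dist_matrix [", attr(x, "metric"), "] ", nrow(x), " x ", ncol(x),
      "\n", sep = "")
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

#' Convert to the compact `dist` form used by vegan
#' @param x A `dist_matrix`.
#' @return A `stats::dist` object.
#' @export
as_dist <- function(x) {
  stopifnot(inherits(x, "dist_matrix"))
  stats::as.dist(unclass(x))
}

#' Bray-Curtis dissimilarity and similarity
#'
#' `d(i, j) = sum |x_i - x_j| / sum (x_i + x_j)` on counts (computed with
#' [vegan::vegdist()]); the companion similarity is `1 - d`.
#'
#' @param x An `otu_table` or a numeric sample-by-OTU matrix.
#' @param similarity Return similarity `1 - d` instead of dissimilarity.
#' @return A `dist_matrix` tagged `bray-curtis-dissim` or `bray-curtis-sim`.
#' @export
bray_curtis <- function(x, similarity = FALSE) {
  cm <- if (inherits(x, "otu_table")) x$counts else as.matrix(x)
  if (any(rowSums(cm) == 0)) stop("all-zero sample(s) present")
  d <- as.matrix(vegan::vegdist(cm, method = "bray"))
  if (similarity)
    return(dist_matrix(1 - d, metric = "bray-curtis-sim"))
  dist_matrix(d, metric = "bray-curtis-dissim")
}

#' Pairwise great-circle and dendritic distances between samples
#'
#' In `euclidean` mode, great-circle (haversine) distance in km on the WGS84
#' mean Earth radius 6371.0088 km, via [geosphere::distHaversine()]. In
#' `dendritic` mode, the cumulative watercourse distance: the shortest path
#' along the (undirected) river tree, summing edge lengths, with each sample
#' mapped to its network node.
#'
#' @param meta `data.frame` with columns `sample_id`, `longitude`, `latitude`
#'   and, for dendritic mode, `site` naming the network node.
#' @param network A `river_network` (required for `mode = "dendritic"`).
#' @param mode `"euclidean"` or `"dendritic"`.
#' @return A `dist_matrix` tagged `euclid-km` or `dendritic-km`.
#' @export
geo_distances <- function(meta, network = NULL,
                          mode = c("euclidean", "dendritic")) {
  mode <- match.arg(mode)
  meta <- as.data.frame(meta)
  if (!all(c("sample_id") %in% names(meta))) stop("meta needs sample_id")
  n <- nrow(meta)
  if (mode == "euclidean") {
    if (!all(c("longitude", "latitude") %in% names(meta)))
      stop("meta needs longitude/latitude for euclidean mode")
    xy <- as.matrix(meta[, c("longitude", "latitude")])
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      j <- (i + 1):n
      d[i, j] <- d[j, i] <- geosphere::distHaversine(
        xy[i, , drop = FALSE], xy[j, , drop = FALSE], r = 6371.0088)
    }
    return(dist_matrix(d, labels = meta$sample_id, metric = "euclid-km"))
  }
  if (is.null(network)) stop("dendritic mode requires a river network")
  stopifnot(inherits(network, "river_network"))
  site_col <- if ("site" %in% names(meta)) "site" else "sample_id"
  sites <- as.character(meta[[site_col]])
  missing <- setdiff(sites, network$nodes$node)
  if (length(missing))
    stop("site(s) not on the network: ", paste(missing, collapse = ", "))
  nd <- network_distances(network)
  d <- nd[sites, sites]
  dist_matrix(d, labels = meta$sample_id, metric = "dendritic-km")
}

#' Euclidean distances between environmental profiles
#'
#' Standard practice before relating community similarity to the
#' environment: all variables except pH are square-root transformed (they are
#' concentrations and counts with right-skewed distributions), then
#' standardised to zero mean and unit variance, then Euclidean distance.
#'
#' @param env `data.frame` of numeric environmental variables, rows =
#'   samples (row names = sample ids).
#' @param sqrt_except Character vector of columns NOT to square-root
#'   transform (default `"pH"`).
#' @param standardize Scale columns to mean 0, sd 1 before the distance
#'   (default `TRUE`).
#' @return A `dist_matrix` tagged `env-euclid`.
#' @export
env_distances <- function(env, sqrt_except = "pH", standardize = TRUE) {
  env <- as.data.frame(env)
  num <- vapply(env, is.numeric, logical(1))
  env <- env[, num, drop = FALSE]
  for (cn in setdiff(names(env), sqrt_except)) {
    if (any(env[[cn]] < 0, na.rm = TRUE))
      stop("negative values in '", cn, "' cannot be sqrt-transformed")
    env[[cn]] <- sqrt(env[[cn]])
  }
  m <- as.matrix(env)
  if (standardize) m <- scale(m)
  m[is.nan(m)] <- 0  # constant columns carry no information
  dist_matrix(as.matrix(stats::dist(m)), labels = rownames(env),
              metric = "env-euclid")
}

#' Construct a dendritic river network
#'
#' A rooted directed tree: nodes are sites or junctions with coordinates,
#' edges carry watercourse lengths in km and point downstream (in the flow
#' direction, away from the origin). Connectivity and acyclicity are
#' enforced.
#'
#' @param nodes `data.frame` with columns `node`, `longitude`, `latitude`.
#' @param edges `data.frame` with columns `from`, `to`, `length_km`
#'   (all lengths `> 0`); direction `from -> to` is downstream.
#' @return An object of class `river_network` (list with `nodes`, `edges`,
#'   and the underlying `igraph` graphs).
#' @export
river_network <- function(nodes, edges) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  stopifnot(all(c("node") %in% names(nodes)),
            all(c("from", "to", "length_km") %in% names(edges)))
  nodes$node <- as.character(nodes$node)
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (any(edges$length_km <= 0)) stop("edge lengths must be > 0")
  if (!all(c(edges$from, edges$to) %in% nodes$node))
    stop("edge endpoints missing from node table")
  g_dir <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = TRUE,
    vertices = nodes[, "node", drop = FALSE])
  g_undir <- igraph::as_undirected(g_dir, mode = "each")
  if (!igraph::is_connected(g_undir)) stop("network is not connected")
  if (igraph::ecount(g_undir) != igraph::vcount(g_undir) - 1 ||
      any(igraph::count_multiple(g_undir) > 1))
    stop("network must be a tree (dendritic): cycles detected")
  igraph::E(g_dir)$length_km <- edges$length_km
  igraph::E(g_undir)$length_km <- edges$length_km
  structure(list(nodes = nodes, edges = edges, graph = g_dir,
                 graph_undirected = g_undir),
            class = "river_network")
}

#' @export
print.river_network <- function(x, ...) {
  cat("river_network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges, total length", round(sum(x$edges$length_km), 2), "km\n")
  invisible(x)
}

#' All-pairs watercourse distances on a river network
#'
#' @param network A `river_network`.
#' @return Symmetric matrix of shortest along-network path lengths (km),
#'   node by node.
#' @export
network_distances <- function(network) {
  stopifnot(inherits(network, "river_network"))
  d <- igraph::distances(network$graph_undirected,
                         weights = igraph::E(network$graph_undirected)$length_km)
  d[network$nodes$node, network$nodes$node]
}

#' Read/write helpers for river networks and distance matrices
#'
#' `read_river_network()` expects an edge-list TSV (`from`, `to`,
#' `length_km`) and a node TSV (`node`, `longitude`, `latitude`).
#' `write_dist_matrix()`/`read_dist_matrix()` store a square TSV with a
#' leading header row and column of sample ids.
#'
#' @param edges_path,nodes_path,path File paths.
#' @param x A `dist_matrix`.
#' @param metric Metric tag to attach on read.
#' @return The parsed object, or (writers) the path invisibly.
#' @export
read_river_network <- function(edges_path, nodes_path) {
  edges <- utils::read.delim(edges_path, stringsAsFactors = FALSE)
  nodes <- utils::read.delim(nodes_path, stringsAsFactors = FALSE)
  river_network(nodes, edges)
}

#' @rdname read_river_network
#' @export
write_dist_matrix <- function(x, path) {
  stopifnot(inherits(x, "dist_matrix"))
  m <- unclass(x)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_river_network
#' @export
read_dist_matrix <- function(path, metric = "unknown") {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  dist_matrix(m, metric = metric)
}
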