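#' Spatial eigenbasis container
#'
#' @param vectors n_sites x k matrix of eigenfunctions (columns centered and
#'   mutually orthogonal).
#' @param eigenvalues Length-k eigenvalues.
#' @param kind `"pcnm"` or `"aem"`.
#' @param params List of construction parameters (truncation distance,
#'   weighting, ...).
#' @return A `spatial_eigenbasis` object.
#' @keywords internal
spatial_eigenbasis <- function(vectors, eigenvalues, kind, params = list()) {
  vectors <- as.matrix(vectors)
  structure(list(vectors = vectors, eigenvalues = eigenvalues, kind = kind,
                 params = params),
            class = "spatial_eigenbasis")
}

#' @export
print.spatial_eigenbasis <- function(x, ...) {
  cat("spatial_eigenbasis [", x$kind, "]: ", nrow(x$vectors), " sites x ",
      ncol(x$vectors), " vectors\n", sep = "")
  invisible(x)
}

# Fix eigenvector signs for reproducibility: largest |loading| positive.
.fix_signs <- function(v) {
  apply(v, 2, function(col) {
    i <- which.max(abs(col))
    if (col[i] < 0) -col else col
  })
}

#' PCNM spatial eigenfunctions
#'
#' Principal coordinates of neighbour matrices: distances larger than the
#' truncation threshold are replaced by 4x the threshold, the truncated
#' matrix is subjected to principal coordinates analysis, and the axes with
#' positive eigenvalues are retained as spatial predictors (computation via
#' [vegan::pcnm()]). The default truncation is the longest edge of the
#' minimum spanning tree of the sites, which guarantees connectivity.
#'
#' @param dist A geographic `dist_matrix` (km), `n >= 4` sites.
#' @param truncation Truncation distance in km, or `NULL` for the MST rule.
#' @return A `spatial_eigenbasis` of kind `"pcnm"`; `params$truncation`
#'   records the threshold used.
#' @export
pcnm_vectors <- function(dist, truncation = NULL) {
  stopifnot(inherits(dist, "dist_matrix"))
  if (nrow(dist) < 4) stop("need at least 4 sites")
  d <- as_dist(dist)
  res <- if (is.null(truncation)) vegan::pcnm(d) else
    vegan::pcnm(d, threshold = truncation)
  # vegan::pcnm already returns only the positive-eigenvalue axes as vectors
  values <- res$values[seq_len(ncol(res$vectors))]
  keep <- values > sqrt(.Machine$double.eps)
  vectors <- .fix_signs(res$vectors[, keep, drop = FALSE])
  rownames(vectors) <- rownames(dist)
  colnames(vectors) <- paste0("PCNM", seq_len(ncol(vectors)))
  spatial_eigenbasis(vectors, values[keep], kind = "pcnm",
                     params = list(truncation = res$threshold))
}

#' Site-by-edge matrix of a directed river network
#'
#' Entry `(s, e)` is 1 when edge `e` lies on the directed path from the
#' network origin(s) down to site `s`, i.e. when water flowing along `e`
#' eventually reaches `s`. This is the incidence structure from which
#' asymmetric eigenvector maps are built.
#'
#' @param network A `river_network` (directed edges point downstream).
#' @param sites Ordered site ids (network node names); default all nodes.
#' @return Binary matrix, sites x edges, with edge names `from->to`.
#' @export
build_site_by_edge <- function(network, sites = NULL) {
  stopifnot(inherits(network, "river_network"))
  if (is.null(sites)) sites <- network$nodes$node
  missing <- setdiff(sites, network$nodes$node)
  if (length(missing))
    stop("site(s) not on the network: ", paste(missing, collapse = ", "))
  g <- network$graph
  edges <- network$edges
  m <- matrix(0L, nrow = length(sites), ncol = nrow(edges),
              dimnames = list(sites,
                              paste0(edges$from, "->", edges$to)))
  for (e in seq_len(nrow(edges))) {
    downstream <- names(igraph::subcomponent(g, edges$to[e], mode = "out"))
    m[sites %in% downstream, e] <- 1L
  }
  m
}

#' Asymmetric eigenvector maps (AEM)
#'
#' Directional spatial eigenfunctions for flow-connected sites. Each column
#' of the site-by-edge matrix is scaled by its edge weight
#' `w_e = 1 - (d_e / d_max)^2`, where `d_e` is the watercourse distance of
#' the link and `d_max` the maximum link distance; columns of the weighted
#' matrix are centered and the left singular vectors with positive singular
#' values form the basis. Because the site-by-edge matrix encodes flow
#' direction, the basis is not invariant to reversing the network — that
#' directionality is the point of the method.
#'
#' @param site_by_edge Binary matrix from [build_site_by_edge()].
#' @param edge_lengths Watercourse length (km) per edge, in column order.
#' @param weights Optional per-edge weights overriding the default
#'   `1 - (d/d_max)^2` rule (e.g. uniform weights for an unweighted basis).
#'   Note the default rule assigns weight 0 to the longest link, so a network
#'   whose links all share one length yields an empty basis.
#' @return A `spatial_eigenbasis` of kind `"aem"`; eigenvalues are the
#'   squared singular values divided by `n - 1`. All-equal rows (no spatial
#'   structure) give an empty basis with a warning.
#' @export
aem_vectors <- function(site_by_edge, edge_lengths, weights = NULL) {
  m <- as.matrix(site_by_edge)
  if (length(edge_lengths) != ncol(m))
    stop("need one edge length per column")
  if (any(edge_lengths <= 0)) stop("edge lengths must be > 0")
  d_max <- max(edge_lengths)
  w <- if (is.null(weights)) 1 - (edge_lengths / d_max)^2 else weights
  if (length(w) != ncol(m)) stop("need one weight per column")
  wm <- sweep(m, 2, w, `*`)
  wm <- scale(wm, center = TRUE, scale = FALSE)
  sv <- svd(wm)
  keep <- sv$d > max(sv$d) * 1e-9
  if (max(sv$d) == 0 || !any(keep)) {
    warning("no spatial structure: all rows identical; empty basis")
    return(spatial_eigenbasis(matrix(numeric(0), nrow(m), 0), numeric(0),
                              kind = "aem",
                              params = list(d_max = d_max, weights = w)))
  }
  vectors <- .fix_signs(sv$u[, keep, drop = FALSE])
  rownames(vectors) <- rownames(m)
  colnames(vectors) <- paste0("AEM", seq_len(ncol(vectors)))
  spatial_eigenbasis(vectors, sv$d[keep]^2 / (nrow(m) - 1), kind = "aem",
                     params = list(d_max = d_max, weights = w))
}

#' Write a spatial eigenbasis
#'
#' TSV of site rows x vector columns, plus a JSON sidecar holding
#' eigenvalues and construction parameters.
#'
#' @param basis A `spatial_eigenbasis`.
#' @param tsv_path,json_path Output paths (either may be `NULL`).
#' @return Invisibly, the sidecar list.
#' @export
write_eigenbasis <- function(basis, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(basis, "spatial_eigenbasis"))
  if (!is.null(tsv_path)) {
    df <- data.frame(site = rownames(basis$vectors), basis$vectors,
                     check.names = FALSE)
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  side <- list(kind = basis$kind, eigenvalues = basis$eigenvalues,
               params = basis$params)
  if (!is.null(json_path))
    jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA)
  invisible(side)
}
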