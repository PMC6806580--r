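#' Construct a sample-by-OTU count table
#'
#' The universal input container of the package: an integer count matrix with
#' samples as rows and OTUs as columns, optional per-OTU taxonomy lineages and
#' per-sample metadata (season, coordinates, site id).
#'
#' @param counts Non-negative integer matrix, samples in rows, OTUs in columns.
#'   Row and column names are used as sample and OTU identifiers; if missing
#'   they are generated.
#' @param taxonomy Optional named list or character vector mapping OTU ids to
#'   semicolon-delimited lineages ordered kingdom to genus, covering a subset
#'   of the OTUs.
#' @param sample_meta Optional `data.frame` keyed by a `sample_id` column (or
#'   row names) with columns such as `season`, `longitude`, `latitude`,
#'   `site`.
#' @return An object of class `otu_table`: a list with elements `counts`,
#'   `taxonomy` (named character vector or `NULL`) and `sample_meta`
#'   (`data.frame` or `NULL`).
#' @examples
#' x <- otu_table(matrix(c(5L, 0L, 2L, 3L), 2, 2,
#'                dimnames = list(c("s1", "s2"), c("otu1", "otu2"))))
#' sample_depths(x)
#' @export
otu_table <- function(counts, taxonomy = NULL, sample_meta = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) && nrow(counts) > 0)
    rownames(counts) <- paste0("sample", seq_len(nrow(counts)))
  if (is.null(colnames(counts)) && ncol(counts) > 0)
    colnames(counts) <- paste0("otu", seq_len(ncol(counts)))
  storage.mode(counts) <- "double"
  if (any(!is.finite(counts)))
    stop("counts must be finite numbers")
  if (any(counts < 0))
    stop("counts must be non-negative; first offending cell: ",
         paste(which(counts < 0, arr.ind = TRUE)[1, ], collapse = ","))
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  counts <- round(counts)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (!is.null(taxonomy)) {
    taxonomy <- unlist(taxonomy)
    if (is.null(names(taxonomy)) || !all(names(taxonomy) %in% colnames(counts)))
      stop("taxonomy names must be a subset of the OTU ids")
  }
  if (!is.null(sample_meta)) {
    sample_meta <- as.data.frame(sample_meta)
    if (!"sample_id" %in% names(sample_meta))
      sample_meta$sample_id <- rownames(sample_meta)
    if (!all(rownames(counts) %in% sample_meta$sample_id))
      stop("sample_meta must cover every sample id")
    sample_meta <- sample_meta[match(rownames(counts), sample_meta$sample_id), ,
                               drop = FALSE]
    rownames(sample_meta) <- sample_meta$sample_id
  }
  structure(list(counts = counts, taxonomy = taxonomy,
                 sample_meta = sample_meta),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat("otu_table:", nrow(x$counts), "samples x", ncol(x$counts), "OTUs\n")
  cat("  total sequences:", sum(x$counts), "\n")
  if (!is.null(x$taxonomy))
    cat("  taxonomy for", length(x$taxonomy), "OTUs\n")
  if (!is.null(x$sample_meta))
    cat("  metadata columns:", paste(setdiff(names(x$sample_meta), "sample_id"),
                                     collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Per-sample sequence totals
#' @param x An `otu_table`.
#' @return Named numeric vector of row sums.
#' @export
sample_depths <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  rowSums(x$counts)
}

#' Subset an OTU table
#'
#' Samples or OTUs left with zero total after subsetting are dropped with a
#' warning (never silently).
#'
#' @param x An `otu_table`.
#' @param samples,otus Character vectors of ids (default: keep all).
#' @param drop_empty Drop all-zero rows/columns after subsetting
#'   (default `TRUE`, with a warning naming what was dropped).
#' @return An `otu_table`.
#' @export
subset_otu_table <- function(x, samples = NULL, otus = NULL,
                             drop_empty = TRUE) {
  stopifnot(inherits(x, "otu_table"))
  cm <- x$counts
  if (!is.null(samples)) {
    missing <- setdiff(samples, rownames(cm))
    if (length(missing))
      stop("unknown sample ids: ", paste(missing, collapse = ", "))
    cm <- cm[samples, , drop = FALSE]
  }
  if (!is.null(otus)) {
    missing <- setdiff(otus, colnames(cm))
    if (length(missing))
      stop("unknown OTU ids: ", paste(missing, collapse = ", "))
    cm <- cm[, otus, drop = FALSE]
  }
  if (drop_empty) {
    empty_s <- rowSums(cm) == 0
    empty_o <- colSums(cm) == 0
    if (any(empty_s)) {
      warning("dropping all-zero samples: ",
              paste(rownames(cm)[empty_s], collapse = ", "))
      cm <- cm[!empty_s, , drop = FALSE]
    }
    if (any(empty_o)) {
      warning("dropping ", sum(empty_o), " all-zero OTUs")
      cm <- cm[, !empty_o, drop = FALSE]
    }
  }
  tax <- x$taxonomy
  if (!is.null(tax)) tax <- tax[names(tax) %in% colnames(cm)]
  meta <- x$sample_meta
  if (!is.null(meta)) meta <- meta[rownames(cm), , drop = FALSE]
  otu_table(cm, taxonomy = if (length(tax)) tax else NULL, sample_meta = meta)
}

#' Read an OTU table from disk
#'
#' Two on-disk forms are supported. `tsv`: OTU rows, first column the OTU id,
#' header row the sample ids, optional trailing `taxonomy` column holding a
#' semicolon-delimited lineage. `json-table`: the JSON interchange form
#' written by [write_otu_table()], carrying counts, ids, taxonomy and sample
#' metadata in one document.
#'
#' @param path File path.
#' @param format `"tsv"` or `"json-table"`.
#' @param meta_path Optional path to a JSON file keyed by sample id with
#'   per-sample metadata (season, longitude, latitude, site); only used with
#'   `format = "tsv"`.
#' @return An `otu_table`.
#' @export
read_otu_table <- function(path, format = c("tsv", "json-table"),
                           meta_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "json-table") {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    counts <- as.matrix(doc$counts)
    dimnames(counts) <- list(doc$sample_ids, doc$otu_ids)
    tax <- doc$taxonomy
    if (!is.null(tax) && length(tax)) tax <- unlist(tax) else tax <- NULL
    meta <- doc$sample_meta
    if (!is.null(meta)) meta <- as.data.frame(meta)
    return(otu_table(counts, taxonomy = tax, sample_meta = meta))
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2) stop("TSV must have an OTU id column and >= 1 sample")
  otu_ids <- raw[[1]]
  tax <- NULL
  value_cols <- names(raw)[-1]
  if (tolower(value_cols[length(value_cols)]) == "taxonomy") {
    tax <- raw[[length(value_cols) + 1]]
    names(tax) <- otu_ids
    tax <- tax[!is.na(tax) & nzchar(tax)]
    value_cols <- value_cols[-length(value_cols)]
  }
  num <- suppressWarnings(
    vapply(value_cols, function(cn) as.numeric(raw[[cn]]), numeric(nrow(raw))))
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(otu_ids, value_cols))
  bad <- which(is.na(num) | num < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid count at OTU '%s', sample '%s': '%s'",
                 otu_ids[bad[1, 1]], value_cols[bad[1, 2]],
                 raw[[value_cols[bad[1, 2]]]][bad[1, 1]]))
  }
  meta <- NULL
  if (!is.null(meta_path)) {
    m <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    meta <- as.data.frame(m)
  }
  otu_table(t(num), taxonomy = if (length(tax)) tax else NULL,
            sample_meta = meta)
}

#' Write an OTU table to disk
#'
#' The paired writer of [read_otu_table()]; round-trips counts, ids and
#' taxonomy losslessly. Output is UTF-8, tab-delimited with `\n` line
#' endings (TSV) or compact JSON (`json-table`).
#'
#' @param x An `otu_table`.
#' @param path Output file path.
#' @param format `"tsv"` or `"json-table"`.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path, format = c("tsv", "json-table")) {
  stopifnot(inherits(x, "otu_table"))
  format <- match.arg(format)
  if (format == "json-table") {
    doc <- list(counts = unname(x$counts),
                sample_ids = rownames(x$counts),
                otu_ids = colnames(x$counts))
    if (!is.null(x$taxonomy)) doc$taxonomy <- as.list(x$taxonomy)
    if (!is.null(x$sample_meta)) doc$sample_meta <- x$sample_meta
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  m <- t(x$counts)  # OTU rows on disk
  df <- data.frame(`#OTU_ID` = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(x$taxonomy)) {
    df$taxonomy <- unname(x$taxonomy[rownames(m)])
    df$taxonomy[is.na(df$taxonomy)] <- ""
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  body <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
  writeLines(body, con, sep = "\n")
  invisible(path)
}

#' Rarefy each sample to a common depth
#'
#' Subsamples every sample without replacement (multivariate hypergeometric
#' draw) to a fixed number of sequences so abundances are comparable across
#' samples. Sampling is delegated to [vegan::rrarefy()] under a caller-supplied
#' seed; there is no hidden random state.
#'
#' @param x An `otu_table`.
#' @param depth Target sequences per sample.
#' @param seed Integer seed; required, the draw is deterministic given it.
#' @param drop_small If `TRUE`, samples with fewer than `depth` sequences are
#'   dropped with a warning; otherwise (default) they are an error.
#' @param drop_empty_otus Drop OTUs with zero total after rarefaction
#'   (default `TRUE`, warning).
#' @return An `otu_table` in which every row sums to `depth`.
#' @export
rarefy_table <- function(x, depth, seed, drop_small = FALSE,
                         drop_empty_otus = TRUE) {
  stopifnot(inherits(x, "otu_table"))
  depth <- as.integer(depth)
  if (depth < 1) stop("depth must be >= 1")
  tot <- sample_depths(x)
  small <- names(tot)[tot < depth]
  if (length(small)) {
    if (!drop_small)
      stop("samples below depth ", depth, ": ",
           paste(small, collapse = ", "),
           " (use drop_small = TRUE to drop them)")
    warning("dropping samples below depth ", depth, ": ",
            paste(small, collapse = ", "))
    x <- subset_otu_table(x, samples = setdiff(rownames(x$counts), small),
                          drop_empty = FALSE)
  }
  if (nrow(x$counts) == 0)
    return(otu_table(x$counts, taxonomy = x$taxonomy,
                     sample_meta = x$sample_meta))
  rar <- withr::with_seed(as.integer(seed), .rrarefy_quiet(x$counts, depth))
  out <- otu_table(rar, taxonomy = x$taxonomy, sample_meta = x$sample_meta)
  if (drop_empty_otus && any(colSums(out$counts) == 0))
    out <- subset_otu_table(out, drop_empty = TRUE)
  out
}

#' Rarefy repeatedly and average
#'
#' Mean count matrix over `k` independent rarefactions (rounded to the nearest
#' integer table is *not* taken: fractional means are returned as a plain
#' matrix, since an averaged table is no longer a count table).
#'
#' @inheritParams rarefy_table
#' @param k Number of repeats.
#' @return Numeric matrix of mean rarefied counts.
#' @export
rarefy_mean <- function(x, depth, seed, k = 10) {
  stopifnot(inherits(x, "otu_table"), k >= 1)
  acc <- NULL
  for (i in seq_len(k)) {
    r <- rarefy_table(x, depth, seed = as.integer(seed) + i - 1L,
                      drop_empty_otus = FALSE)
    acc <- if (is.null(acc)) r$counts else acc + r$counts
  }
  acc / k
}

#' Relative abundance per sample
#'
#' @param x An `otu_table`.
#' @return Matrix of proportions; every row sums to 1.
#' @export
relative_abundance <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  tot <- rowSums(x$counts)
  if (any(tot == 0))
    stop("all-zero sample(s): ",
         paste(rownames(x$counts)[tot == 0], collapse = ", "))
  x$counts / tot
}

#' Hellinger transformation
#'
#' Square root of per-sample relative abundances, the standard pre-transform
#' that makes community composition data suitable for linear (RDA) ordination.
#' Row sums of squares equal 1.
#'
#' @param x An `otu_table`.
#' @return Numeric matrix, same dimnames as the counts.
#' @export
hellinger_transform <- function(x) {
  sqrt(relative_abundance(x))
}

#' Collapse OTUs at a taxonomic rank
#'
#' Sums counts of OTUs sharing the same lineage prefix down to `rank`. OTUs
#' lacking taxonomy, or whose lineage is shorter than the rank, pool into
#' `"unclassified"`. Total sequence count is conserved.
#'
#' @param x An `otu_table` with taxonomy.
#' @param rank One of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @return An `otu_table` whose OTU ids are lineage prefixes.
#' @export
collapse_taxonomy <- function(x, rank = c("kingdom", "phylum", "class",
                                          "order", "family", "genus")) {
  stopifnot(inherits(x, "otu_table"))
  rank <- match.arg(rank)
  if (is.null(x$taxonomy)) stop("table has no taxonomy")
  depth_needed <- match(rank, c("kingdom", "phylum", "class", "order",
                                "family", "genus"))
  lineages <- x$taxonomy[colnames(x$counts)]
  key <- vapply(lineages, function(l) {
    if (is.na(l) || !nzchar(l)) return("unclassified")
    parts <- trimws(strsplit(l, ";", fixed = TRUE)[[1]])
    if (length(parts) < depth_needed) return("unclassified")
    paste(parts[seq_len(depth_needed)], collapse = ";")
  }, character(1))
  groups <- split(seq_along(key), key)
  merged <- vapply(groups, function(idx)
    rowSums(x$counts[, idx, drop = FALSE]), numeric(nrow(x$counts)))
  merged <- matrix(merged, nrow = nrow(x$counts),
                   dimnames = list(rownames(x$counts), names(groups)))
  otu_table(merged, sample_meta = x$sample_meta)
}

# vegan::rrarefy warns informationally when the smallest nonzero count
# exceeds 1 (suspecting non-count data); our inputs are validated counts.
.rrarefy_quiet <- function(counts, depth) {
  withCallingHandlers(
    vegan::rrarefy(counts, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}
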