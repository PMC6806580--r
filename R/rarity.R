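#' Classify OTUs into six abundance categories
#'
#' Assigns every OTU one of the six mutually exclusive rarity categories used
#' in rare-biosphere studies, from its per-sample relative abundances at equal
#' sequencing depth:
#'
#' * `AAT` always abundant: `>= abundant_threshold` in all samples
#' * `ART` always rare: `< rare_threshold` in all samples
#' * `MT` moderate: in `[rare_threshold, abundant_threshold)` in all samples
#' * `CRT` conditionally rare: `< abundant_threshold` in all samples and
#'   `< rare_threshold` in some (but not all)
#' * `CAT` conditionally abundant: `>= rare_threshold` in all samples and
#'   `>= abundant_threshold` in some (but not all)
#' * `CRAT` conditionally rare and abundant: ranges from rare
#'   (`< rare_threshold`) to abundant (`>= abundant_threshold`)
#'
#' The boundary convention is `>=` for abundant and strict `<` for rare, so a
#' value exactly at the rare threshold counts as not rare.
#'
#' @param rel Matrix of per-sample relative abundances (samples x OTUs), as
#'   returned by [relative_abundance()], or an `otu_table` (converted
#'   internally).
#' @param rare_threshold Proportion below which a taxon is rare in a sample
#'   (default `1e-4`, i.e. 0.01%).
#' @param abundant_threshold Proportion at or above which a taxon is abundant
#'   (default `1e-2`, i.e. 1%).
#' @return An object of class `rarity_assignment`: list with `category`
#'   (named factor over `AAT, CAT, MT, ART, CRT, CRAT`) and the thresholds.
#' @export
classify_taxa <- function(rel, rare_threshold = 1e-4,
                          abundant_threshold = 1e-2) {
  if (inherits(rel, "otu_table")) rel <- relative_abundance(rel)
  if (!(rare_threshold > 0 && rare_threshold < abundant_threshold &&
        abundant_threshold < 1))
    stop("need 0 < rare_threshold < abundant_threshold < 1")
  rel <- as.matrix(rel)
  any_rare <- apply(rel < rare_threshold, 2, any)
  all_rare <- apply(rel < rare_threshold, 2, all)
  any_abund <- apply(rel >= abundant_threshold, 2, any)
  all_abund <- apply(rel >= abundant_threshold, 2, all)
  cat <- character(ncol(rel))
  cat[all_abund] <- "AAT"
  cat[all_rare] <- "ART"
  cat[!any_rare & !any_abund] <- "MT"
  cat[any_rare & any_abund] <- "CRAT"
  cat[!any_rare & any_abund & !all_abund] <- "CAT"
  cat[any_rare & !all_rare & !any_abund] <- "CRT"
  stopifnot(all(nzchar(cat)))
  category <- factor(cat, levels = c("AAT", "CAT", "MT", "ART", "CRT", "CRAT"))
  names(category) <- colnames(rel)
  structure(list(category = category,
                 thresholds = c(rare = rare_threshold,
                                abundant = abundant_threshold)),
            class = "rarity_assignment")
}

#' @export
print.rarity_assignment <- function(x, ...) {
  cat("rarity_assignment over", length(x$category), "OTUs",
      sprintf("(rare < %g, abundant >= %g)\n",
              x$thresholds["rare"], x$thresholds["abundant"]))
  print(table(x$category))
  invisible(x)
}

#' Pool OTUs of selected rarity categories into a subcommunity table
#'
#' `pool_dominant()` selects the pooled "dominant" set (AAT + CAT + CRAT);
#' `pool_categories()` selects any category combination. An empty selection
#' yields a zero-column table with a warning (studies commonly find no AAT at
#' all), never an error.
#'
#' @param assign A `rarity_assignment` derived from `table`.
#' @param table The source `otu_table`.
#' @param categories Character vector of category labels to keep.
#' @return An `otu_table` restricted to the selected OTUs.
#' @export
pool_categories <- function(assign, table, categories) {
  stopifnot(inherits(assign, "rarity_assignment"),
            inherits(table, "otu_table"))
  if (!setequal(names(assign$category), colnames(table$counts)))
    stop("assignment and table cover different OTU sets")
  bad <- setdiff(categories, levels(assign$category))
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
  keep <- names(assign$category)[assign$category %in% categories]
  keep <- colnames(table$counts)[colnames(table$counts) %in% keep]
  if (!length(keep)) {
    warning("no OTU falls in categories ", paste(categories, collapse = "+"),
            "; returning an empty table")
    empty <- table$counts[, integer(0), drop = FALSE]
    return(otu_table(empty, sample_meta = table$sample_meta))
  }
  subset_otu_table(table, otus = keep, drop_empty = FALSE)
}

#' @rdname pool_categories
#' @export
pool_dominant <- function(assign, table) {
  pool_categories(assign, table, c("AAT", "CAT", "CRAT"))
}

#' Write a rarity assignment as two-column TSV
#'
#' @param assign A `rarity_assignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rarity <- function(assign, path) {
  stopifnot(inherits(assign, "rarity_assignment"))
  df <- data.frame(otu_id = names(assign$category),
                   category = as.character(assign$category))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("otu_id\tcategory", con, sep = "\n")
  writeLines(paste(df$otu_id, df$category, sep = "\t"), con, sep = "\n")
  invisible(path)
}
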