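#' Construct a taxon count table
#'
#' The central container for 16S count data: a non-negative integer matrix of
#' `n` samples by `p` taxa plus a ranked taxonomy for every taxon. All
#' preprocessing steps (prevalence filtering, rarefaction, taxonomic
#' aggregation, relative abundance, centred log-ratio transform) consume and
#' return this class.
#'
#' @param counts Non-negative integer matrix, samples in rows, taxa in
#'   columns. Row and column names are used as sample and taxon ids when
#'   `sample_ids`/`taxon_ids` are not given.
#' @param taxonomy Optional tibble/data.frame of per-taxon ranked labels
#'   (e.g. phylum ... genus), one row per taxon, with a `taxon_id` column or
#'   rows in column order. Defaults to a minimal taxonomy of the taxon ids.
#' @param sample_ids,taxon_ids Optional character vectors overriding dimnames.
#' @return An object of class `taxon_table` with elements `counts` (named
#'   integer matrix) and `taxonomy` (tibble).
#' @export
taxon_table <- function(counts, taxonomy = NULL, sample_ids = NULL,
                        taxon_ids = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(sample_ids)) rownames(counts) <- sample_ids
  if (!is.null(taxon_ids)) colnames(counts) <- taxon_ids
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("T", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts)))
    abort(paste0("duplicate sample ids: ",
                 paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                       collapse = ", ")))
  if (anyDuplicated(colnames(counts)))
    abort(paste0("duplicate taxon ids: ",
                 paste(unique(colnames(counts)[duplicated(colnames(counts))]),
                       collapse = ", ")))
  if (!all(is.finite(counts)))
    abort("counts must be finite")
  if (any(counts < 0))
    abort("counts must be non-negative")
  if (any(counts != round(counts)))
    abort("counts must be integers")
  storage.mode(counts) <- "double"  # doubles avoid integer overflow on sums
  if (is.null(taxonomy)) {
    taxonomy <- tibble(taxon_id = colnames(counts))
  } else {
    taxonomy <- as_tibble(taxonomy)
    if (!"taxon_id" %in% names(taxonomy)) {
      if (nrow(taxonomy) != ncol(counts))
        abort("taxonomy must have one row per taxon")
      taxonomy <- dplyr::bind_cols(tibble(taxon_id = colnames(counts)),
                                   taxonomy)
    }
    if (nrow(taxonomy) != ncol(counts) ||
        !setequal(taxonomy$taxon_id, colnames(counts)))
      abort("taxonomy taxon_id must match count matrix columns")
    taxonomy <- taxonomy[match(colnames(counts), taxonomy$taxon_id), ]
  }
  structure(list(counts = counts, taxonomy = taxonomy),
            class = "taxon_table")
}

#' @export
print.taxon_table <- function(x, ...) {
  cat(sprintf("<taxon_table> %d samples x %d taxa (total reads %s)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  ranks <- setdiff(names(x$taxonomy), "taxon_id")
  if (length(ranks))
    cat("taxonomy ranks:", paste(ranks, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.taxon_table <- function(x) dim(x$counts)

#' Long-format view of a taxon table
#'
#' @param x A [taxon_table].
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `taxon_id`, `count` and any
#'   taxonomy ranks.
#' @export
tidy.taxon_table <- function(x, ...) {
  long <- as_tibble(x$counts, rownames = "sample_id") %>%
    tidyr::pivot_longer(-"sample_id", names_to = "taxon_id",
                        values_to = "count")
  left_join(long, x$taxonomy, by = "taxon_id")
}

#' @export
glance.taxon_table <- function(x, ...) {
  tibble(n_samples = nrow(x$counts), n_taxa = ncol(x$counts),
         total_reads = sum(x$counts),
         min_depth = min(rowSums(x$counts)),
         max_depth = max(rowSums(x$counts)),
         sparsity = mean(x$counts == 0))
}

sample_ids <- function(table) rownames(table$counts)
taxon_ids <- function(table) colnames(table$counts)
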