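#' Prevalence-filter taxa
#'
#' Keeps a taxon when it reaches at least `min_count` reads in at least
#' `ceiling(min_fraction * n)` samples. The defaults reproduce the common
#' "at least five sequences in 10% of the samples" rule for freshwater OTU
#' tables. Survivor order is preserved.
#'
#' @param table A [taxon_table].
#' @param min_count Minimum per-sample read count (>= 1).
#' @param min_fraction Minimum fraction of samples, in (0, 1].
#' @return A filtered [taxon_table].
#' @export
filter_taxa <- function(table, min_count = 5, min_fraction = 0.10) {
  if (min_count < 1) abort("min_count must be >= 1")
  if (min_fraction <= 0 || min_fraction > 1)
    abort("min_fraction must be in (0, 1]")
  n <- nrow(table$counts)
  need <- ceiling(min_fraction * n)
  keep <- colSums(table$counts >= min_count) >= need
  if (!any(keep))
    abort(paste0("all taxa removed; lower min_count (", min_count,
                 ") or min_fraction (", min_fraction, ")"))
  taxon_table(table$counts[, keep, drop = FALSE],
              taxonomy = table$taxonomy[keep, ])
}

#' Rarefy to an even sequencing depth
#'
#' Subsamples each sample's reads uniformly without replacement down to
#' `depth`. Samples with fewer than `depth` reads are dropped with a
#' warning, so every retained row sums exactly to `depth`.
#'
#' @param table A [taxon_table].
#' @param depth Target depth (>= 1).
#' @param seed Integer seed; the operation is deterministic given the seed.
#' @return A rarefied [taxon_table].
#' @export
rarefy_counts <- function(table, depth, seed = 1L) {
  if (depth < 1) abort("depth must be >= 1")
  totals <- rowSums(table$counts)
  keep <- totals >= depth
  if (!any(keep)) abort("all samples below rarefaction depth")
  if (!all(keep))
    warn(paste0("dropping ", sum(!keep), " sample(s) below depth ", depth,
                ": ", paste(sample_ids(table)[!keep], collapse = ", ")))
  counts <- table$counts[keep, , drop = FALSE]
  # vegan warns heuristically when the smallest count exceeds 1; counts
  # here are validated integers, so that advisory is noise
  rar <- withCallingHandlers(
    withr::with_seed(seed, vegan::rrarefy(counts, depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  taxon_table(rar, taxonomy = table$taxonomy)
}

#' Aggregate counts at a taxonomic rank
#'
#' Sums counts over taxa sharing all taxonomy labels from the highest rank
#' down to `level`; per-sample totals are conserved. Aggregating at the
#' finest rank (the taxon id itself) is the identity.
#'
#' @param table A [taxon_table] whose taxonomy contains `level`.
#' @param level Rank name (a column of the taxonomy, or `"taxon_id"`).
#' @return An aggregated [taxon_table]; the new taxon ids are the joined
#'   lineage labels down to `level`.
#' @export
aggregate_taxa <- function(table, level) {
  ranks <- names(table$taxonomy)
  if (!level %in% ranks)
    abort(paste0("unknown rank '", level, "'; available: ",
                 paste(ranks, collapse = ", ")))
  if (level == "taxon_id") return(table)
  upto <- setdiff(ranks[seq_len(match(level, ranks))], "taxon_id")
  key <- apply(table$taxonomy[, upto, drop = FALSE], 1, paste,
               collapse = ";")
  groups <- unique(key)  # first-appearance order
  agg <- vapply(groups, function(g)
    rowSums(table$counts[, key == g, drop = FALSE]),
    numeric(nrow(table$counts)))
  agg <- matrix(agg, nrow = nrow(table$counts),
                dimnames = list(sample_ids(table), groups))
  tax <- table$taxonomy[match(groups, key), c("taxon_id", upto)]
  tax$taxon_id <- groups
  taxon_table(agg, taxonomy = tax)
}

#' Convert counts to relative abundances
#'
#' @param table A [taxon_table] with positive row sums.
#' @return A `composition_matrix`: a samples-by-taxa matrix of relative
#'   abundances whose rows sum to 1.
#' @export
to_relative <- function(table) {
  totals <- rowSums(table$counts)
  zero <- totals <= 0
  if (any(zero))
    abort(paste0("zero-sum sample(s): ",
                 paste(sample_ids(table)[zero], collapse = ", ")))
  rel <- sweep(table$counts, 1, totals, "/")
  structure(rel, class = c("composition_matrix", "matrix", "array"))
}

#' Centred log-ratio transform
#'
#' Maps each compositional row to unconstrained real space:
#' `z_ij = log(x_ij) - mean_k log(x_ik)`, i.e. the log of each component
#' over the row's geometric mean. Zeros are replaced by `delta = 1/p^2`
#' before the logs are taken; the replaced row is not renormalised, so each
#' transformed row sums exactly to zero by construction.
#'
#' @param comp A relative-abundance matrix (rows = samples) as returned by
#'   [to_relative()], with `p >= 2` columns.
#' @param delta Zero replacement value; defaults to `1/p^2`.
#' @return A `clr_matrix` (samples by taxa) with attribute `delta`.
#' @export
clr_transform <- function(comp, delta = NULL) {
  comp <- as.matrix(comp)
  p <- ncol(comp)
  if (p < 2) abort("CLR needs at least 2 taxa")
  if (is.null(delta)) delta <- 1 / p^2
  if (delta <= 0) abort("delta must be positive")
  x <- comp
  x[x == 0] <- delta
  lx <- log(x)
  z <- lx - rowMeans(lx)
  structure(z, delta = delta, class = c("clr_matrix", "matrix", "array"))
}

#' Preprocess a taxon table for variable selection
#'
#' The fixed pipeline order: prevalence filter at the finest taxon level,
#' optional rarefaction to even depth, optional aggregation at a coarser
#' rank, relative abundance, and (optionally) the CLR transform. Skipping
#' CLR yields raw relative abundances, for comparing selection behaviour on
#' the two scales.
#'
#' @param table A [taxon_table].
#' @param min_count,min_fraction Prevalence-filter thresholds; see
#'   [filter_taxa()].
#' @param depth Rarefaction depth, or `NULL` to skip rarefaction.
#' @param level Aggregation rank, or `NULL` to stay at the taxon level.
#' @param clr Apply the CLR transform (`TRUE`) or return relative
#'   abundances (`FALSE`).
#' @param seed Seed for rarefaction.
#' @return A list with `table` (post filter/rarefy/aggregate), `comp`
#'   (relative abundances) and `x` (the predictor matrix: CLR or relative).
#' @export
preprocess_taxa <- function(table, min_count = 5, min_fraction = 0.10,
                            depth = NULL, level = NULL, clr = TRUE,
                            seed = 1L) {
  table <- filter_taxa(table, min_count, min_fraction)
  if (!is.null(depth)) table <- rarefy_counts(table, depth, seed = seed)
  if (!is.null(level)) table <- aggregate_taxa(table, level)
  comp <- to_relative(table)
  x <- if (clr) clr_transform(comp) else comp
  list(table = table, comp = comp, x = x)
}
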