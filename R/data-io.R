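#' Read a taxon count table from disk
#'
#' Supports two dialects: mothur "shared"-style TSV (`label`, `Group`,
#' `numOtus` header columns followed by one column per OTU; the `label` and
#' `numOtus` columns are dropped) and a plain wide CSV whose first column
#' holds sample ids and remaining columns hold per-taxon counts.
#'
#' @param path Path to the file.
#' @param format `"shared_tsv"` or `"wide_csv"`.
#' @param taxonomy Optional taxonomy tibble passed through to [taxon_table()].
#' @return A [taxon_table]; row and column order are preserved from the file.
#' @export
read_taxon_table <- function(path, format = c("wide_csv", "shared_tsv"),
                             taxonomy = NULL) {
  format <- arg_match(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "shared_tsv") {
    raw <- readr::read_tsv(path, show_col_types = FALSE,
                           name_repair = "minimal")
    needed <- c("label", "Group", "numOtus")
    if (!all(needed %in% names(raw)))
      abort("shared_tsv requires columns label, Group, numOtus")
    ids <- raw$Group
    mat <- as.matrix(raw[, setdiff(names(raw), needed), drop = FALSE])
  } else {
    raw <- readr::read_csv(path, show_col_types = FALSE,
                           name_repair = "minimal")
    ids <- as.character(raw[[1]])
    mat <- as.matrix(raw[, -1, drop = FALSE])
  }
  rownames(mat) <- ids
  taxon_table(mat, taxonomy = taxonomy)
}

#' Write a taxon table as wide CSV
#'
#' Inverse of [read_taxon_table()] with `format = "wide_csv"`: the round
#' trip reproduces integer counts exactly.
#'
#' @param table A [taxon_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxon_table <- function(table, path) {
  df <- as_tibble(table$counts, rownames = "sample_id")
  readr::write_csv(df, path)
  invisible(path)
}

#' Read sample metadata
#'
#' Expects a CSV with at least `sample_id`, `lake_system` and `group_id`
#' columns; `group_id` encodes the site-by-year blocking unit used by the
#' leave-one-group-out cross-validation scheme.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("sample_id", "lake_system", "group_id")
  missing <- setdiff(needed, names(meta))
  if (length(missing))
    abort(paste0("metadata missing columns: ", paste(missing, collapse = ", ")))
  if (anyDuplicated(meta$sample_id))
    abort("duplicate sample_id in metadata")
  meta
}

#' Read a target vector (cell counts or productivity)
#'
#' @param path CSV path with columns `sample_id` and one or more numeric
#'   target columns (e.g. `hnacc`, `lnacc`).
#' @return A tibble.
#' @export
read_targets <- function(path) {
  targets <- readr::read_csv(path, show_col_types = FALSE)
  if (!"sample_id" %in% names(targets))
    abort("targets must have a sample_id column")
  targets
}

#' Read flow-cytometry events for one replicate
#'
#' Reads an event table with green (`FL1`) and red (`FL3`) fluorescence
#' channels on the instrument scale, either from CSV or from an FCS 3.0/3.1
#' file with float-type data. The analysed volume is taken from the
#' `volume_ml` argument, a `volume_ml` column (CSV), or the `$VOL` keyword in
#' microlitres (FCS).
#'
#' @param path Path to the event file.
#' @param format `"csv"` or `"fcs"`.
#' @param sample_id,replicate_id Identifiers attached to the result.
#' @param volume_ml Analysed volume in ml; overrides any value in the file.
#' @param channels Names of the green and red fluorescence channels.
#' @return An `fcm_sample`: a tibble of events with attributes `sample_id`,
#'   `replicate_id` and `volume_ml`.
#' @export
read_fcm_events <- function(path, format = c("csv", "fcs"),
                            sample_id = NULL, replicate_id = NULL,
                            volume_ml = NULL,
                            channels = c("FL1", "FL3")) {
  format <- arg_match(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "csv") {
    raw <- readr::read_csv(path, show_col_types = FALSE)
    missing <- setdiff(channels, names(raw))
    if (length(missing))
      abort(paste0("missing channel(s) ", paste(missing, collapse = ", "),
                   "; available: ", paste(names(raw), collapse = ", ")))
    if (is.null(volume_ml) && "volume_ml" %in% names(raw))
      volume_ml <- raw$volume_ml[1]
    events <- raw[, channels]
  } else {
    fcs <- read_fcs(path)
    missing <- setdiff(channels, colnames(fcs$data))
    if (length(missing))
      abort(paste0("missing channel(s) ", paste(missing, collapse = ", "),
                   "; available: ", paste(colnames(fcs$data), collapse = ", ")))
    if (is.null(volume_ml) && !is.null(fcs$keywords[["$VOL"]]))
      volume_ml <- as.numeric(fcs$keywords[["$VOL"]]) / 1000  # $VOL is in uL
    events <- as_tibble(fcs$data[, channels, drop = FALSE])
  }
  if (nrow(events) == 0) abort("no events in file")
  if (!all(vapply(events, function(v) all(is.finite(v)), logical(1))))
    abort("non-finite channel values")
  fcm_sample(events, sample_id = sample_id %||% basename(path),
             replicate_id = replicate_id %||% 1L, volume_ml = volume_ml)
}

#' Construct an fcm_sample from an event table
#'
#' @param events Data frame with the fluorescence channels as columns.
#' @param sample_id,replicate_id Identifiers.
#' @param volume_ml Analysed volume in ml (required for absolute counts).
#' @return An `fcm_sample` tibble.
#' @export
fcm_sample <- function(events, sample_id, replicate_id = 1L,
                       volume_ml = NULL) {
  events <- as_tibble(events)
  if (nrow(events) < 1) abort("fcm_sample needs at least one event")
  structure(events, class = c("fcm_sample", class(events)),
            sample_id = sample_id, replicate_id = replicate_id,
            volume_ml = volume_ml)
}

#' Align a taxon table with metadata and targets
#'
#' Restricts all three inputs to their shared sample ids in canonical
#' (lexicographic) order, so every downstream matrix shares one row order.
#' Dropped ids are reported via a warning and the `dropped` element.
#'
#' @param table A [taxon_table].
#' @param metadata Tibble with a `sample_id` column.
#' @param targets Tibble with a `sample_id` column, or `NULL`.
#' @return A list with elements `table`, `metadata`, `targets`, `dropped`.
#' @export
align_samples <- function(table, metadata, targets = NULL) {
  ids <- list(sample_ids(table), metadata$sample_id)
  if (!is.null(targets)) {
    keep <- stats::complete.cases(targets)
    if (!all(keep)) {
      warn(paste0("dropping ", sum(!keep),
                  " sample(s) with missing target values: ",
                  paste(targets$sample_id[!keep], collapse = ", ")))
      targets <- targets[keep, ]
    }
    ids <- c(ids, list(targets$sample_id))
  }
  shared <- sort(Reduce(intersect, ids))
  if (length(shared) == 0) abort("no shared sample ids")
  dropped <- sort(setdiff(Reduce(union, ids), shared))
  if (length(dropped))
    warn(paste0("dropping unmatched sample(s): ",
                paste(dropped, collapse = ", ")))
  out <- list(
    table = taxon_table(table$counts[shared, , drop = FALSE],
                        taxonomy = table$taxonomy),
    metadata = metadata[match(shared, metadata$sample_id), ],
    targets = if (!is.null(targets))
      targets[match(shared, targets$sample_id), ],
    dropped = dropped
  )
  out
}
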