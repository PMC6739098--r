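#' Run the full association pipeline on a simulated or supplied dataset
#'
#' Orchestrates the stages end to end — preprocess (filter, relative
#' abundance, CLR), gate cytometry replicates into HNA/LNA concentrations,
#' Randomized-Lasso stability selection, recursive elimination under
#' blocked CV, optional nested CV, Boruta validation, optional fingerprint
#' bin correlations, and association summaries — writing one CSV per stage
#' plus a machine-readable run manifest. Stage failures abort with the
#' failing stage named; artifacts written before the failure are retained.
#'
#' @param data A list like the result of [simulate_dataset()]: `table`,
#'   `metadata`, `targets`, optionally `fcm` (and `truth`, ignored here).
#' @param out_dir Output directory (created if needed).
#' @param target Which target column of `targets` to model.
#' @param gate A [gate_config()] (required when `data$fcm` is present).
#' @param stability A [stability_config()].
#' @param boruta A [boruta_config()].
#' @param min_count,min_fraction,clr Preprocessing controls.
#' @param step Elimination step; `NULL` for the [nested_cv()] default.
#' @param run_nested_cv,run_fingerprint Toggle the expensive stages.
#' @param fingerprint_taxa Taxa to correlate with fingerprint bins;
#'   defaults to the top 3 RL-ranked taxa.
#' @param grid,bandwidth Fingerprint resolution and kernel bandwidth.
#' @param seed Master seed recorded in the manifest and used to derive all
#'   stage seeds.
#' @return Invisibly, a list of stage results plus `manifest`.
#' @export
run_pipeline <- function(data, out_dir, target = "hnacc",
                         gate = NULL,
                         stability = stability_config(),
                         boruta = boruta_config(),
                         min_count = 5, min_fraction = 0.10, clr = TRUE,
                         step = NULL, run_nested_cv = TRUE,
                         run_fingerprint = !is.null(data$fcm),
                         fingerprint_taxa = NULL,
                         grid = 128, bandwidth = 0.01, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  stages_done <- character()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e))))
    stages_done <<- c(stages_done, name)
    res
  }
  stability$seed <- seed
  boruta$seed <- seed + 1L

  if (run_fingerprint && is.null(data$fcm))
    abort("stage 'fingerprint' failed: no FCM events in input data")

  results$gate <- stage("gate", {
    if (!is.null(data$fcm)) {
      if (is.null(gate)) abort("gate_config required for FCM gating")
      counts <- dplyr::bind_rows(purrr::map(data$fcm, gate_counts,
                                            gate = gate))
      readr::write_csv(counts, file.path(out_dir, "functional_counts.csv"))
      counts
    }
  })

  results$preprocess <- stage("preprocess", {
    aligned <- align_samples(data$table, data$metadata, data$targets)
    prep <- preprocess_taxa(aligned$table, min_count = min_count,
                            min_fraction = min_fraction, clr = clr,
                            seed = seed)
    readr::write_csv(as_tibble(unclass(prep$x), rownames = "sample_id"),
                     file.path(out_dir, "predictors.csv"))
    c(prep, aligned[c("metadata", "targets")])
  })
  x <- results$preprocess$x
  meta <- results$preprocess$metadata
  y <- results$preprocess$targets[[target]]
  if (is.null(y)) abort(paste0("target '", target, "' not found"))
  y <- log(y)

  results$select <- stage("select", {
    rl <- randomized_lasso(x, y, stability)
    readr::write_csv(rl$scores, file.path(out_dir, "rl_scores.csv"))
    rl
  })

  results$elimination <- stage("elimination", {
    elim <- recursive_elimination(
      x, y, results$select, meta$group_id,
      step = step %||% max(1L, ceiling(ncol(x) / 25)))
    readr::write_csv(elim$trace, file.path(out_dir, "elimination_trace.csv"))
    readr::write_csv(tibble(taxon_id = elim$optimum$taxa),
                     file.path(out_dir, "selected_taxa.csv"))
    elim
  })

  if (run_nested_cv) {
    results$nestedcv <- stage("nestedcv", {
      ncv <- nested_cv(x, y, meta$group_id, config = stability, step = step)
      readr::write_csv(ncv$predictions,
                       file.path(out_dir, "nested_cv_predictions.csv"))
      ncv
    })
  }

  results$boruta <- stage("boruta", {
    bres <- boruta_select(x, y, boruta)
    readr::write_csv(bres$labels, file.path(out_dir, "boruta_labels.csv"))
    bres
  })

  results$assoc <- stage("assoc", {
    tau <- correlate_taxa(x, y)
    readr::write_csv(tau, file.path(out_dir, "taxon_correlations.csv"))
    tau
  })

  results$agreement <- stage("agreement", {
    agree <- compare_selections(
      results$elimination$optimum$taxa, results$boruta,
      results$assoc$taxon_id[!is.na(results$assoc$adjusted_p) &
                               results$assoc$adjusted_p < 0.05],
      universe = colnames(x))
    readr::write_csv(agree$membership,
                     file.path(out_dir, "selection_agreement.csv"))
    agree
  })

  if (run_fingerprint) {
    results$fingerprint <- stage("fingerprint", {
      ids <- intersect(names(data$fcm), rownames(results$preprocess$comp))
      grids <- purrr::map(setNames(ids, ids), function(s)
        fingerprint(data$fcm[[s]], gate, grid = grid,
                    bandwidth = bandwidth))
      taxa <- fingerprint_taxa %||%
        head(results$select$scores$taxon_id[
          order(results$select$scores$rank)], 3)
      bc <- bin_correlations(grids, results$preprocess$comp, taxa)
      readr::write_csv(as_tibble(bc),
                       file.path(out_dir, "bin_correlations.csv"))
      bc
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cytotaxa")),
    r_version = R.version.string,
    seed = seed,
    target = target,
    stages = stages_done,
    config = list(stability = unclass(stability)[c("B", "alpha", "seed")],
                  boruta = unclass(boruta),
                  preprocess = list(min_count = min_count,
                                    min_fraction = min_fraction, clr = clr)),
    config_hash = rlang::hash(list(stability, boruta, min_count,
                                   min_fraction, clr, step, seed, target))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
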