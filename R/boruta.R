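#' Boruta configuration
#'
#' Random-Forest settings follow common regression defaults: 200 trees,
#' a third of the design's variables tried at each split, and at least five
#' samples per leaf; the hit-count test is a two-sided binomial test at
#' `alpha` with Bonferroni correction over the variables under test.
#'
#' @param n_iterations Shadow-permutation iterations (>= 1; 300 by default).
#' @param rf_trees Trees per forest.
#' @param rf_max_features Fraction of design columns tried per split.
#' @param rf_min_leaf Minimum samples per leaf.
#' @param alpha Significance level before Bonferroni correction.
#' @param seed Integer seed.
#' @return A `boruta_config` list.
#' @export
boruta_config <- function(n_iterations = 300L, rf_trees = 200L,
                          rf_max_features = 1 / 3, rf_min_leaf = 5L,
                          alpha = 0.05, seed = 1L) {
  if (n_iterations < 1) abort("n_iterations must be >= 1")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  structure(list(n_iterations = as.integer(n_iterations),
                 rf_trees = as.integer(rf_trees),
                 rf_max_features = rf_max_features,
                 rf_min_leaf = as.integer(rf_min_leaf),
                 alpha = alpha, seed = as.integer(seed)),
            class = "boruta_config")
}

#' Boruta all-relevant variable selection
#'
#' Each iteration appends a freshly permuted "shadow" copy of every
#' still-undecided variable to the design, fits a Random-Forest regressor
#' (impurity importance), and scores a hit for every original variable whose
#' importance exceeds the best shadow importance. Hit counts are tested
#' against a Binomial(iterations, 1/2) null, two-sided with Bonferroni
#' correction: significantly many hits confirms a variable (it stays in the
#' design but is no longer tested), significantly few rejects it (it is
#' removed); variables still undecided after the last iteration are labelled
#' tentative.
#'
#' @param x Predictor matrix (samples x taxa), `n >= 10` rows.
#' @param y Numeric response.
#' @param config A [boruta_config()].
#' @return A `boruta_result`: tibble `labels` (`taxon_id`, `label`, `hits`,
#'   `n_iter`), plus `config`.
#' @export
boruta_select <- function(x, y, config = boruta_config()) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < 10) abort("need n >= 10 samples")
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("non-finite inputs")
  ids <- colnames(x) %||% paste0("V", seq_len(p))
  colnames(x) <- ids
  label <- setNames(rep("tentative", p), ids)
  hits <- setNames(integer(p), ids)
  iters <- setNames(integer(p), ids)
  withr::with_seed(config$seed, {
    for (it in seq_len(config$n_iterations)) {
      undecided <- names(label)[label == "tentative"]
      if (length(undecided) == 0) break
      keep <- names(label)[label != "rejected"]
      xk <- x[, keep, drop = FALSE]
      shadows <- apply(xk, 2, sample)
      colnames(shadows) <- paste0("shadow_", keep)
      design <- cbind(xk, shadows)
      mtry <- max(1L, floor(config$rf_max_features * ncol(design)))
      rf <- ranger::ranger(
        x = design, y = y, num.trees = config$rf_trees, mtry = mtry,
        min.node.size = config$rf_min_leaf, importance = "impurity",
        seed = sample.int(.Machine$integer.max, 1), num.threads = 1
      )
      imp <- rf$variable.importance
      shadow_max <- max(imp[paste0("shadow_", keep)])
      hit <- imp[undecided] > shadow_max
      hits[undecided] <- hits[undecided] + hit
      iters[undecided] <- iters[undecided] + 1L
      # two-sided binomial test, Bonferroni over the p original variables
      thr <- config$alpha / (2 * p)
      p_hi <- pbinom(hits[undecided] - 1L, iters[undecided], 0.5,
                     lower.tail = FALSE)
      p_lo <- pbinom(hits[undecided], iters[undecided], 0.5)
      label[undecided[p_hi < thr]] <- "confirmed"
      label[undecided[p_lo < thr]] <- "rejected"
    }
  })
  structure(list(labels = tibble(taxon_id = ids,
                                 label = unname(label[ids]),
                                 hits = unname(hits[ids]),
                                 n_iter = unname(iters[ids])),
                 config = config),
            class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  tab <- table(factor(x$labels$label,
                      levels = c("confirmed", "tentative", "rejected")))
  cat(sprintf("<boruta_result> confirmed %d, tentative %d, rejected %d\n",
              tab["confirmed"], tab["tentative"], tab["rejected"]))
  invisible(x)
}

#' @export
tidy.boruta_result <- function(x, ...) x$labels

#' @export
glance.boruta_result <- function(x, ...) {
  tibble(n_confirmed = sum(x$labels$label == "confirmed"),
         n_tentative = sum(x$labels$label == "tentative"),
         n_rejected = sum(x$labels$label == "rejected"),
         n_iterations = x$config$n_iterations)
}

#' Agreement between selection methods
#'
#' Summarises the consistency of the taxa selected by the Randomized Lasso,
#' confirmed by Boruta, and significantly rank-correlated with the target,
#' as the membership table and all intersection sizes (the numbers behind a
#' three-set Venn diagram).
#'
#' @param rl_taxa Character vector of RL-selected taxon ids.
#' @param boruta A `boruta_result` (its confirmed taxa are used) or a
#'   character vector.
#' @param tau_taxa Character vector of taxa significant by Kendall tau-b
#'   after multiplicity correction.
#' @param universe All taxon ids under consideration; defaults to the union.
#' @return A `selection_agreement`: `membership` tibble with logical
#'   columns `rl`, `boruta`, `tau`, and `regions` tibble of intersection
#'   counts.
#' @export
compare_selections <- function(rl_taxa, boruta, tau_taxa,
                               universe = NULL) {
  bor_taxa <- if (inherits(boruta, "boruta_result"))
    boruta$labels$taxon_id[boruta$labels$label == "confirmed"]
  else as.character(boruta)
  universe <- universe %||% sort(unique(c(rl_taxa, bor_taxa, tau_taxa)))
  membership <- tibble(taxon_id = universe,
                       rl = universe %in% rl_taxa,
                       boruta = universe %in% bor_taxa,
                       tau = universe %in% tau_taxa)
  regions <- membership %>%
    dplyr::count(.data$rl, .data$boruta, .data$tau, name = "n_taxa") %>%
    arrange(dplyr::desc(.data$rl), dplyr::desc(.data$boruta),
            dplyr::desc(.data$tau))
  structure(list(membership = membership, regions = regions),
            class = "selection_agreement")
}

#' @export
print.selection_agreement <- function(x, ...) {
  cat("<selection_agreement>\n")
  print(x$regions)
  invisible(x)
}
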