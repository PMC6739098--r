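#' Stability-selection configuration
#'
#' Parameters of the Randomized Lasso: `B` half-subsample repeats, the
#' weakness `alpha` that randomly doubles some variables' penalties (each
#' variable independently receives penalty multiplier `alpha` or 1 with
#' probability 1/2), and the logarithmic penalty grid over which the
#' stability path is traced. The defaults follow the published procedure:
#' `B = 500`, `alpha = 0.5`, 100 penalties log-spaced between 1e-3 and 1e3.
#'
#' @param B Number of subsample repeats (>= 1).
#' @param alpha Weakness in (0, 1]; `alpha = 1` disables the second
#'   randomisation.
#' @param lam_min,lam_max,n_lambda Penalty-grid limits and resolution.
#' @param seed Integer seed making the whole procedure deterministic.
#' @param tol,max_iter Coordinate-descent controls for the inner fits.
#' @return A `stability_config` list.
#' @export
stability_config <- function(B = 500L, alpha = 0.5, lam_min = 1e-3,
                             lam_max = 1e3, n_lambda = 100L, seed = 1L,
                             tol = 1e-5, max_iter = 1000L) {
  if (B < 1) abort("B must be >= 1")
  if (alpha <= 0 || alpha > 1) abort("alpha must be in (0, 1]")
  if (lam_min <= 0 || lam_max <= lam_min) abort("invalid lambda range")
  structure(list(B = as.integer(B), alpha = alpha,
                 lam_grid = exp(seq(log(lam_min), log(lam_max),
                                    length.out = n_lambda)),
                 seed = as.integer(seed), tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "stability_config")
}

# Standardise columns to mean 0 / sd 1; zero-variance columns become all-zero
# (they can never enter a Lasso model, matching "never selectable").
standardize_columns <- function(x) {
  m <- colMeans(x)
  s <- apply(x, 2, sd)
  xc <- sweep(x, 2, m)
  s_safe <- ifelse(s > 0, s, 1)
  xs <- sweep(xc, 2, s_safe, "/")
  xs[, s == 0] <- 0
  list(x = xs, center = m, scale = s_safe, constant = s == 0)
}

#' Randomized Lasso stability selection
#'
#' For each of `B` repeats, draws `floor(n/2)` samples without replacement,
#' draws a per-variable penalty multiplier from `{alpha, 1}`, standardises
#' columns within the subsample, centres the response, and fits the weighted
#' Lasso along the whole penalty grid. The stability path records, per
#' penalty, the fraction of repeats in which each variable's coefficient was
#' nonzero; the RL score of a variable is the maximum of its path.
#'
#' @param x Numeric predictor matrix (typically a CLR-transformed abundance
#'   matrix), samples in rows.
#' @param y Numeric response aligned to the rows of `x` (e.g. HNA cell
#'   concentration).
#' @param config A [stability_config()].
#' @return A `stability_result` with elements `scores` (tibble: `taxon_id`,
#'   `rl_score`, `rank`), `path` (penalty-by-taxon selection-frequency
#'   matrix), `lam_grid` and `config`.
#' @export
randomized_lasso <- function(x, y, config = stability_config()) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < 4) abort("need n >= 4 samples")
  if (length(y) != n) abort("x and y lengths differ")
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("non-finite inputs")
  half <- floor(n / 2)
  if (half < 2) abort("floor(n/2) must be >= 2")
  lam <- config$lam_grid
  lam_desc <- rev(lam)
  ids <- colnames(x) %||% paste0("V", seq_len(p))
  counts <- matrix(0, p, length(lam))
  withr::with_seed(config$seed, {
    for (b in seq_len(config$B)) {
      idx <- sample.int(n, half)
      w <- sample(c(config$alpha, 1), p, replace = TRUE)
      std <- standardize_columns(x[idx, , drop = FALSE])
      yc <- y[idx] - mean(y[idx])
      sel <- .cd_lasso_path_support(std$x, yc, lam_desc, w, config$tol,
                                    config$max_iter)
      counts <- counts + sel[, rev(seq_along(lam)), drop = FALSE]
    }
  })
  path <- t(counts) / config$B            # |lam_grid| x p, lambda ascending
  dimnames(path) <- list(NULL, ids)
  score <- apply(path, 2, max)
  scores <- tibble(taxon_id = ids, rl_score = unname(score)) %>%
    mutate(rank = rank_with_order_ties(.data$rl_score))
  structure(list(scores = scores, path = path, lam_grid = lam,
                 config = config),
            class = "stability_result")
}

# Dense ranking of scores, descending, ties broken by original position.
rank_with_order_ties <- function(score) {
  ord <- order(-score, seq_along(score))
  r <- integer(length(score))
  r[ord] <- seq_along(score)
  r
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("<stability_result> %d taxa, B = %d, alpha = %g\n",
              nrow(x$scores), x$config$B, x$config$alpha))
  cat(sprintf("scores > 0.5: %d; top taxon: %s (%.3f)\n",
              sum(x$scores$rl_score > 0.5),
              x$scores$taxon_id[x$scores$rank == 1],
              max(x$scores$rl_score)))
  invisible(x)
}

#' @export
tidy.stability_result <- function(x, ...) x$scores

#' @export
glance.stability_result <- function(x, ...) {
  tibble(n_taxa = nrow(x$scores), B = x$config$B, alpha = x$config$alpha,
         n_above_0.5 = sum(x$scores$rl_score > 0.5),
         max_score = max(x$scores$rl_score))
}

#' Stability-path plot
#'
#' Selection frequency against the penalty for every taxon; taxa whose RL
#' score exceeds `highlight` are coloured.
#'
#' @param object A `stability_result`.
#' @param highlight Score threshold above which taxa are labelled.
#' @param ... Unused.
#' @export
autoplot.stability_result <- function(object, highlight = 0.5, ...) {
  df <- as_tibble(object$path) %>%
    mutate(lambda = object$lam_grid) %>%
    tidyr::pivot_longer(-"lambda", names_to = "taxon_id",
                        values_to = "frequency") %>%
    left_join(object$scores, by = "taxon_id") %>%
    mutate(selected = .data$rl_score > highlight)
  ggplot2::ggplot(df, ggplot2::aes(.data$lambda, .data$frequency,
                                   group = .data$taxon_id,
                                   colour = .data$selected)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70",
                                            `TRUE` = "#B2182B")) +
    ggplot2::labs(x = expression(lambda), y = "selection frequency",
                  colour = paste0("RL score > ", highlight))
}

#' Select taxa by RL score
#'
#' @param result A `stability_result` (or its `scores` tibble).
#' @param threshold Score cutoff in `[0, 1]`; taxa with score strictly
#'   above it are returned, highest first (ties keep original column
#'   order). The 0.5 default is the level at which stability selection
#'   controls the number of falsely selected variables.
#' @return A tibble of selected taxa with scores and ranks.
#' @export
select_by_score <- function(result, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) abort("threshold must be in [0, 1]")
  scores <- if (inherits(result, "stability_result")) result$scores
            else as_tibble(result)
  scores %>% filter(.data$rl_score > threshold) %>% arrange(.data$rank)
}
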