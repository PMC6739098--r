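# Blocked (leave-one-group-out) evaluation of Lasso models ranked by RL
# score: RCV2, recursive variable elimination, and nested cross-validation.

check_groups <- function(groups, n) {
  groups <- as.character(groups)
  if (length(groups) != n) abort("group vector length must equal n")
  if (length(unique(groups)) < 2) abort("need >= 2 groups")
  if (any(table(groups) == n)) abort("a single group contains all samples")
  groups
}

pooled_r2 <- function(y_true, y_pred) {
  sse <- sum((y_true - y_pred)^2)
  sst <- sum((y_true - mean(y_true))^2)
  1 - sse / sst
}

# Inner model: on standardised training data, trace the Lasso path over a
# grid of n_lambda penalties from lambda_max down to eps * lambda_max and
# return held-out predictions for each penalty.
inner_lambda_grid <- function(xc, yc, eps, n_lambda) {
  lmax <- lambda_max(xc, yc)
  if (lmax <= 0) lmax <- 1
  exp(seq(log(lmax), log(eps * lmax), length.out = n_lambda))
}

# Fit on train, predict test, for every lambda in the train-derived grid;
# returns list(grid, pred: nrow(test) x n_lambda).
path_predictions <- function(x_tr, y_tr, x_te, eps, n_lambda, tol, max_iter) {
  std <- standardize_columns(x_tr)
  yc <- y_tr - mean(y_tr)
  grid <- inner_lambda_grid(std$x, yc, eps, n_lambda)
  betas <- .cd_lasso_path(std$x, yc, grid, rep(1, ncol(x_tr)), tol,
                          as.integer(max_iter))
  x_te_s <- sweep(sweep(as.matrix(x_te), 2, std$center), 2, std$scale, "/")
  x_te_s[, std$constant] <- 0
  pred <- x_te_s %*% betas + mean(y_tr)
  list(grid = grid, pred = pred)
}

# Choose lambda on training data by leave-one-group-out CV within the
# training groups (pooled squared error), then fit at that lambda.
fit_lasso_inner_cv <- function(x_tr, y_tr, groups_tr, eps, n_lambda,
                               tol = 1e-4, max_iter = 100L) {
  gids <- unique(groups_tr)
  if (length(gids) < 2) abort("inner CV needs >= 2 training groups")
  sse <- numeric(n_lambda)
  for (g in gids) {
    te <- groups_tr == g
    pp <- path_predictions(x_tr[!te, , drop = FALSE], y_tr[!te],
                           x_tr[te, , drop = FALSE], eps, n_lambda,
                           tol, max_iter)
    sse <- sse + colSums((y_tr[te] - pp$pred)^2)
  }
  std <- standardize_columns(x_tr)
  yc <- y_tr - mean(y_tr)
  grid <- inner_lambda_grid(std$x, yc, eps, n_lambda)
  best <- which.min(sse)
  beta <- .cd_lasso_path(std$x, yc, grid[seq_len(best)],
                         rep(1, ncol(x_tr)), tol,
                         as.integer(max_iter))[, best]
  list(beta = beta, std = std, ybar = mean(y_tr), lambda = grid[best])
}

predict_inner_fit <- function(fit, x_new) {
  xs <- sweep(sweep(as.matrix(x_new), 2, fit$std$center), 2,
              fit$std$scale, "/")
  xs[, fit$std$constant] <- 0
  drop(xs %*% fit$beta) + fit$ybar
}

#' Blocked cross-validated R-squared (RCV2)
#'
#' Leave-one-group-out evaluation respecting the spatiotemporal blocking of
#' the samples: for each group, a Lasso is fitted on all other groups with
#' its penalty chosen by an inner leave-one-group-out CV over a log grid of
#' `n_lambda` values spanning `[eps * lambda_max, lambda_max]`; the held-out
#' group is predicted, all held-out predictions are pooled, and
#' `R2 = 1 - SSE/SST` is computed on the pooled vectors (it can be
#' negative).
#'
#' @param x Predictor matrix (samples x taxa).
#' @param y Numeric response.
#' @param groups Blocking-group label per sample (site x year units).
#' @param eps Ratio of the smallest to the largest penalty in the grid.
#' @param n_lambda Number of grid points.
#' @return An `rcv2_result`: list with `r2` and a `predictions` tibble
#'   (`sample_id`, `group`, `y_true`, `y_pred`).
#' @export
rcv2 <- function(x, y, groups, eps = 1e-4, n_lambda = 400L) {
  x <- as.matrix(x)
  if (ncol(x) < 1) abort("empty predictor subset")
  groups <- check_groups(groups, nrow(x))
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  preds <- rep(NA_real_, nrow(x))
  for (g in unique(groups)) {
    te <- groups == g
    fit <- fit_lasso_inner_cv(x[!te, , drop = FALSE], y[!te], groups[!te],
                              eps, n_lambda)
    preds[te] <- predict_inner_fit(fit, x[te, , drop = FALSE])
  }
  structure(list(r2 = pooled_r2(y, preds),
                 predictions = tibble(sample_id = ids, group = groups,
                                      y_true = y, y_pred = preds)),
            class = "rcv2_result")
}

#' @export
print.rcv2_result <- function(x, ...) {
  cat(sprintf("<rcv2_result> pooled out-of-group R2 = %.4f over %d groups\n",
              x$r2, length(unique(x$predictions$group))))
  invisible(x)
}

#' Recursive variable elimination ranked by RL score
#'
#' Starting from all taxa ranked by RL score, repeatedly removes the
#' `step` lowest-ranked taxa and records the blocked cross-validated R2 of
#' a Lasso on the retained set. The optimum is minimal-optimal: the
#' smallest retained size whose RCV2 attains the trace maximum.
#'
#' @inheritParams rcv2
#' @param scores A `stability_result` or its scores tibble (`taxon_id`,
#'   `rl_score`, `rank`); ties in score keep original column order.
#' @param step Number of taxa removed per iteration (< p).
#' @return An `elimination_trace`: tibble `trace` (`n_retained`, `rcv2`),
#'   `ranked_taxa`, `optimum` (list with `n_retained`, `rcv2`, `taxa`).
#' @export
recursive_elimination <- function(x, y, scores, groups, step = 1L,
                                  eps = 1e-4, n_lambda = 400L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  p <- ncol(x)
  if (p < 2) abort("need p >= 2 taxa")
  if (step >= p) abort("step must be < p")
  scores <- if (inherits(scores, "stability_result")) scores$scores
            else as_tibble(scores)
  if (!setequal(scores$taxon_id, colnames(x)))
    abort("scores and x taxa differ")
  ranked <- scores$taxon_id[order(scores$rank)]
  sizes <- seq(p, 1L, by = -as.integer(step))
  if (sizes[length(sizes)] != 1L) sizes <- c(sizes, 1L)
  r2 <- vapply(sizes, function(k)
    rcv2(x[, ranked[seq_len(k)], drop = FALSE], y, groups,
         eps = eps, n_lambda = n_lambda)$r2, numeric(1))
  trace <- tibble(n_retained = sizes, rcv2 = r2)
  best_r2 <- max(r2)
  k_star <- min(sizes[r2 == best_r2])
  structure(list(trace = trace, ranked_taxa = ranked,
                 optimum = list(n_retained = k_star, rcv2 = best_r2,
                                taxa = ranked[seq_len(k_star)])),
            class = "elimination_trace")
}

#' @export
print.elimination_trace <- function(x, ...) {
  cat(sprintf(
    "<elimination_trace> %d steps; optimum: %d taxa, RCV2 = %.4f\n",
    nrow(x$trace), x$optimum$n_retained, x$optimum$rcv2))
  invisible(x)
}

#' @export
tidy.elimination_trace <- function(x, ...) x$trace

#' @export
glance.elimination_trace <- function(x, ...) {
  tibble(n_steps = nrow(x$trace),
         optimum_size = x$optimum$n_retained,
         optimum_rcv2 = x$optimum$rcv2,
         full_model_rcv2 = x$trace$rcv2[1])
}

#' @export
autoplot.elimination_trace <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(.data$n_retained, .data$rcv2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$optimum$n_retained,
                        linetype = "dashed") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "taxa retained", y = expression(RCV^2))
}

#' Nested blocked cross-validation (RNCV2)
#'
#' Tests the generalisability of the whole selection-and-fit procedure:
#' in the outer loop each blocking group is held out in turn; on the
#' remaining groups only, the Randomized Lasso is run, recursive
#' elimination picks the minimal-optimal subset, a Lasso tuned by inner CV
#' is fitted on that subset, and the held-out group is predicted. The
#' held-out predictions from all outer folds are concatenated and a single
#' pooled `R2` (RNCV2) is computed.
#'
#' @inheritParams rcv2
#' @param config A [stability_config()]; the per-fold RL seed is derived
#'   deterministically from `config$seed` and the fold index.
#' @param step Elimination step inside each outer fold; default removes
#'   about 1/8 of the taxa per step to keep the inner search tractable.
#' @param search_n_lambda,search_eps Penalty-grid resolution and depth used
#'   while ranking candidate subset sizes inside each fold; the shallower
#'   search grid covers the region where the cross-validated optimum lies,
#'   and the final per-fold model is always tuned on the full
#'   `n_lambda`-point, `eps`-deep grid.
#' @return A `nested_cv_result`: `rncv2`, `predictions` tibble, and a list
#'   of per-fold selections.
#' @export
nested_cv <- function(x, y, groups, config = stability_config(),
                      step = NULL, eps = 1e-4, n_lambda = 400L,
                      search_n_lambda = 100L, search_eps = 1e-2) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  groups <- check_groups(groups, nrow(x))
  gids <- unique(groups)
  if (length(gids) < 3) abort("nested CV needs >= 3 groups")
  if (is.null(step)) step <- max(1L, ceiling(ncol(x) / 8))
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  preds <- rep(NA_real_, nrow(x))
  fold_info <- list()
  for (k in seq_along(gids)) {
    te <- groups == gids[k]
    x_tr <- x[!te, , drop = FALSE]
    y_tr <- y[!te]
    g_tr <- groups[!te]
    cfg_k <- config
    cfg_k$seed <- (config$seed + 7919L * k) %% .Machine$integer.max
    rl <- randomized_lasso(x_tr, y_tr, cfg_k)
    elim <- recursive_elimination(x_tr, y_tr, rl, g_tr, step = step,
                                  eps = search_eps,
                                  n_lambda = search_n_lambda)
    sel <- elim$optimum$taxa
    fit <- fit_lasso_inner_cv(x_tr[, sel, drop = FALSE], y_tr, g_tr,
                              eps, n_lambda)
    preds[te] <- predict_inner_fit(fit, x[te, sel, drop = FALSE])
    fold_info[[gids[k]]] <- list(selected = sel,
                                 rcv2 = elim$optimum$rcv2)
  }
  structure(list(rncv2 = pooled_r2(y, preds),
                 predictions = tibble(sample_id = ids, group = groups,
                                      y_true = y, y_pred = preds),
                 folds = fold_info),
            class = "nested_cv_result")
}

#' @export
print.nested_cv_result <- function(x, ...) {
  cat(sprintf("<nested_cv_result> RNCV2 = %.4f over %d outer folds\n",
              x$rncv2, length(x$folds)))
  invisible(x)
}

#' @export
tidy.nested_cv_result <- function(x, ...) x$predictions

#' @export
glance.nested_cv_result <- function(x, ...) {
  tibble(rncv2 = x$rncv2, n_folds = length(x$folds),
         median_selected = stats::median(
           vapply(x$folds, function(f) length(f$selected), numeric(1))))
}

#' @export
autoplot.nested_cv_result <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(.data$y_true, .data$y_pred,
                               colour = .data$group)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "observed", y = "out-of-group prediction")
}
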