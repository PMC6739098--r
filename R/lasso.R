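#' Weighted Lasso by coordinate descent
#'
#' Minimises `||y - b0 - X beta||_2^2 + lambda * sum_j w_j |beta_j|` by
#' cyclic coordinate descent with soft-thresholding. Note the penalty
#' convention: the residual sum of squares is not scaled by `1/(2n)`, so
#' `lambda` here is `2 n lambda'` of solvers that use the scaled objective.
#' The intercept is handled by centring `X` and `y`; coefficients are
#' reported on the scale of the supplied `X`.
#'
#' @param x Numeric predictor matrix (n x p).
#' @param y Numeric response vector.
#' @param lambda Penalty level (>= 0).
#' @param weights Per-variable penalty multipliers (> 0), recycled to p.
#' @param intercept Fit an unpenalised intercept (default `TRUE`).
#' @param tol Convergence tolerance on the largest coefficient update.
#' @param max_iter Maximum coordinate-descent sweeps.
#' @return A `lasso_fit`: list with `beta` (named), `intercept`, `lambda`,
#'   `converged`.
#' @export
lasso_fit <- function(x, y, lambda, weights = 1, intercept = TRUE,
                      tol = 1e-8, max_iter = 10000L) {
  x <- as.matrix(x)
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("non-finite inputs")
  if (length(y) != nrow(x)) abort("x and y lengths differ")
  if (lambda < 0) abort("lambda must be >= 0")
  w <- rep_len(weights, ncol(x))
  if (any(w <= 0)) abort("weights must be positive")
  if (intercept) {
    xm <- colMeans(x); ym <- mean(y)
    xc <- sweep(x, 2, xm); yc <- y - ym
  } else {
    xc <- x; yc <- y
  }
  fit <- .cd_lasso_single(xc, yc, lambda, w, tol, as.integer(max_iter),
                          numeric(ncol(x)))
  if (!fit$converged)
    warn(paste0("lasso_fit did not converge in ", max_iter, " sweeps"))
  beta <- setNames(as.numeric(fit$beta),
                   colnames(x) %||% paste0("V", seq_len(ncol(x))))
  b0 <- if (intercept) ym - sum(xm * beta) else 0
  structure(list(beta = beta, intercept = b0, lambda = lambda,
                 converged = fit$converged),
            class = "lasso_fit")
}

#' @export
predict.lasso_fit <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$beta) + object$intercept
}

#' @export
tidy.lasso_fit <- function(x, ...) {
  tibble(term = names(x$beta), estimate = unname(x$beta))
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("<lasso_fit> lambda = %g, %d/%d nonzero%s\n", x$lambda,
              sum(x$beta != 0), length(x$beta),
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Coefficient path over a lambda grid
#'
#' Solves the weighted Lasso at every value of `lambdas` with warm starts
#' from large to small penalties.
#'
#' @inheritParams lasso_fit
#' @param lambdas Positive penalty grid (any order).
#' @return A p x length(lambdas) coefficient matrix, columns in the order
#'   of `lambdas`; attribute `intercepts` carries the per-lambda intercepts.
#' @export
lasso_path <- function(x, y, lambdas, weights = 1, intercept = TRUE,
                       tol = 1e-7, max_iter = 10000L) {
  x <- as.matrix(x)
  w <- rep_len(weights, ncol(x))
  ord <- order(lambdas, decreasing = TRUE)
  if (intercept) {
    xm <- colMeans(x); ym <- mean(y)
    xc <- sweep(x, 2, xm); yc <- y - ym
  } else {
    xm <- numeric(ncol(x)); ym <- 0; xc <- x; yc <- y
  }
  betas <- .cd_lasso_path(xc, yc, lambdas[ord], w, tol,
                          as.integer(max_iter))
  out <- matrix(0, ncol(x), length(lambdas),
                dimnames = list(colnames(x), NULL))
  out[, ord] <- betas
  attr(out, "intercepts") <- ym - drop(crossprod(out, xm))
  out
}

# Smallest penalty at which all coefficients are zero (KKT bound for the
# unscaled objective): lambda_max = 2 * max_j |x_j' y| on centred data.
lambda_max <- function(xc, yc) 2 * max(abs(crossprod(xc, yc)))
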