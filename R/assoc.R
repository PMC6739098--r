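#' Kendall tau-b rank correlation
#'
#' Pair-counting implementation with tie corrections:
#' `tau_b = (C - D) / sqrt((n0 - n1)(n0 - n2))`, where `C`/`D` are the
#' concordant/discordant pair counts, `n0 = n(n-1)/2`, and `n1`, `n2` are
#' the tied-pair counts in `x` and `y`. The p-value uses the large-sample
#' normal approximation with the tie-corrected variance of `C - D`; for
#' `n <= 8`, `method = "exact"` enumerates all permutations of `y` instead.
#' If either vector is entirely tied the statistic is undefined and `NA` is
#' returned (not 0).
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @param method `"asymptotic"` (default) or `"exact"` (n <= 8 only).
#' @return A one-row tibble: `tau_b`, `p_value`, `n`.
#' @export
kendall_tau_b <- function(x, y, method = c("asymptotic", "exact")) {
  method <- arg_match(method)
  n <- length(x)
  if (length(y) != n) abort("x and y lengths differ")
  if (n < 3) abort("need n >= 3")
  if (anyNA(x) || anyNA(y)) abort("missing values not allowed")
  stat <- tau_b_stat(x, y)
  if (is.na(stat$tau)) {
    warn("tau-b undefined: a vector is entirely tied")
    return(tibble(tau_b = NA_real_, p_value = NA_real_, n = n))
  }
  p <- if (method == "exact") {
    if (n > 8) abort("exact p only for n <= 8")
    perms <- all_permutations(n)
    taus <- apply(perms, 1, function(idx) tau_b_stat(x, y[idx])$tau)
    mean(abs(taus) >= abs(stat$tau) - 1e-12)
  } else {
    v <- tau_b_variance(x, y, n)
    if (v <= 0) NA_real_ else 2 * pnorm(-abs(stat$S) / sqrt(v))
  }
  tibble(tau_b = stat$tau, p_value = p, n = n)
}

tau_b_stat <- function(x, y) {
  n <- length(x)
  pr <- utils::combn(n, 2)
  sx <- sign(x[pr[1, ]] - x[pr[2, ]])
  sy <- sign(y[pr[1, ]] - y[pr[2, ]])
  S <- sum(sx * sy)
  n0 <- ncol(pr)
  n1 <- sum(sx == 0)
  n2 <- sum(sy == 0)
  denom <- sqrt((n0 - n1) * (n0 - n2))
  list(tau = if (denom > 0) S / denom else NA_real_, S = S)
}

# Tie-corrected variance of S = C - D under the null (Kendall 1976).
tau_b_variance <- function(x, y, n) {
  tx <- as.numeric(table(x)); ty <- as.numeric(table(y))
  f <- function(t, k) sum(t * (t - 1) * if (k == 3) (t - 2) else
                            if (k == 25) (2 * t + 5) else 1)
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- f(tx, 25); vu <- f(ty, 25)
  v1 <- f(tx, 2) * f(ty, 2) / (2 * n * (n - 1))
  v2 <- f(tx, 3) * f(ty, 3) / (9 * n * (n - 1) * (n - 2))
  (v0 - vt - vu) / 18 + v1 + v2
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector (monotone
#' enforced, clipped at 1, input order preserved). Undefined tests (`NA`)
#' propagate and are excluded from the correction denominator.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH", n = sum(ok))
}

#' Single-predictor OLS summary
#'
#' Fits `y ~ x` by ordinary least squares and reports the slope test and
#' both R-squared flavours (`adjusted_r2 = 1 - (1 - r2)(n - 1)/(n - 2)` for
#' one predictor).
#'
#' @param x,y Numeric vectors, `n >= 3`, `x` non-constant.
#' @return A one-row tibble: `slope`, `intercept`, `r2`, `adjusted_r2`,
#'   `p_value`, `n`.
#' @export
ols_summary <- function(x, y) {
  n <- length(x)
  if (length(y) != n) abort("x and y lengths differ")
  if (n < 3) abort("need n >= 3")
  if (sd(x) == 0) abort("x has zero variance")
  fit <- lm(y ~ x)
  s <- summary(fit)
  tibble(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r2 = s$r.squared, adjusted_r2 = s$adj.r.squared,
         p_value = s$coefficients[2, 4], n = n)
}

#' Pearson similarity of two RL score vectors
#'
#' Correlates two per-taxon score vectors over their shared taxa, used to
#' quantify how similar the selection signals are between lake systems or
#' between the HNA and LNA targets.
#'
#' @param scores_a,scores_b Named numeric vectors (names = taxon ids) or
#'   `stability_result` objects.
#' @return A one-row tibble: `pearson_r`, `p_value`, `n_common`; `NA` with
#'   a warning when either vector is constant.
#' @export
score_similarity <- function(scores_a, scores_b) {
  as_vec <- function(s) {
    if (inherits(s, "stability_result"))
      setNames(s$scores$rl_score, s$scores$taxon_id)
    else s
  }
  a <- as_vec(scores_a); b <- as_vec(scores_b)
  common <- intersect(names(a), names(b))
  if (length(common) < 3) abort("need >= 3 common taxa")
  a <- a[common]; b <- b[common]
  if (sd(a) == 0 || sd(b) == 0) {
    warn("similarity undefined: constant score vector")
    return(tibble(pearson_r = NA_real_, p_value = NA_real_,
                  n_common = length(common)))
  }
  ct <- stats::cor.test(a, b, method = "pearson")
  tibble(pearson_r = unname(ct$estimate), p_value = ct$p.value,
         n_common = length(common))
}

#' Complete-linkage clustering of RL scores
#'
#' Hierarchically clusters the rows of a score matrix (taxa by
#' system/target combinations) on Euclidean distances with complete
#' linkage, as used to arrange selection heatmaps.
#'
#' @param score_matrix Numeric matrix with at least 2 rows; row names are
#'   the leaf labels.
#' @return A list with the `hclust` object, the deterministic `leaf_order`
#'   (labels in dendrogram order) and `newick`, a Newick-style nested
#'   string with merge heights as branch lengths.
#' @export
cluster_scores <- function(score_matrix) {
  m <- as.matrix(score_matrix)
  if (nrow(m) < 2) abort("need >= 2 rows")
  if (is.null(rownames(m))) rownames(m) <- paste0("R", seq_len(nrow(m)))
  hc <- hclust(dist(m, method = "euclidean"), method = "complete")
  list(hclust = hc, leaf_order = hc$labels[hc$order],
       newick = hclust_newick(hc))
}

# Nested-parenthesis serialisation of an hclust tree; branch lengths are
# differences of merge heights.
hclust_newick <- function(hc) {
  node <- function(i, parent_h) {
    if (i < 0) return(paste0(hc$labels[-i], ":", format(parent_h)))
    h <- hc$height[i]
    paste0("(", node(hc$merge[i, 1], h), ",", node(hc$merge[i, 2], h),
           "):", format(parent_h - h))
  }
  root <- length(hc$height)
  paste0("(", node(hc$merge[root, 1], hc$height[root]), ",",
         node(hc$merge[root, 2], hc$height[root]), ");")
}

#' Overlap of per-system taxon selections
#'
#' @param selections Named list (>= 2 systems) of character vectors of
#'   selected taxon ids.
#' @return A list with `pairwise` (tibble: `system_a`, `system_b`,
#'   `n_shared`, `pct_of_a`, `pct_of_b`; percentages are `NA` when a
#'   selection is empty) and `global` (taxa selected in every system).
#' @export
selection_overlap <- function(selections) {
  if (length(selections) < 2) abort("need >= 2 systems")
  if (is.null(names(selections)))
    names(selections) <- paste0("system", seq_along(selections))
  combos <- utils::combn(names(selections), 2)
  pairwise <- purrr::map(seq_len(ncol(combos)), function(i) {
    a <- combos[1, i]; b <- combos[2, i]
    shared <- length(intersect(selections[[a]], selections[[b]]))
    tibble(system_a = a, system_b = b, n_shared = shared,
           pct_of_a = if (length(selections[[a]]))
             100 * shared / length(selections[[a]]) else NA_real_,
           pct_of_b = if (length(selections[[b]]))
             100 * shared / length(selections[[b]]) else NA_real_)
  }) %>% dplyr::bind_rows()
  list(pairwise = pairwise,
       global = Reduce(intersect, selections))
}

#' Taxon-target correlation screen
#'
#' Kendall tau-b of every taxon (columns of `x`) against a target, with
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param x Matrix of per-sample taxon values (CLR or relative abundance).
#' @param y Numeric target vector.
#' @return A tibble: `taxon_id`, `tau_b`, `p_value`, `adjusted_p`, sorted
#'   by the input column order.
#' @export
correlate_taxa <- function(x, y) {
  x <- as.matrix(x)
  ids <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  res <- purrr::map(seq_len(ncol(x)), function(j) {
    xj <- x[, j]
    if (length(unique(xj)) == 1 || length(unique(y)) == 1)
      tibble(tau_b = NA_real_, p_value = NA_real_, n = length(y))
    else kendall_tau_b(xj, y)
  }) %>% dplyr::bind_rows()
  tibble(taxon_id = ids, tau_b = res$tau_b, p_value = res$p_value,
         adjusted_p = bh_adjust(res$p_value))
}
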