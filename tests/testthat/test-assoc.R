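test_that("tau-b handles perfect agreement, reversal, and the tied closed form", {
  expect_equal(kendall_tau_b(1:3, c(10, 20, 30))$tau_b, 1)
  expect_equal(kendall_tau_b(1:3, c(30, 20, 10))$tau_b, -1)
  # C = 4, D = 0, one tie in each vector: 4 / sqrt(5 * 5) = 0.8
  expect_equal(kendall_tau_b(c(1, 2, 2, 3), c(1, 2, 3, 3))$tau_b, 0.8)
})

test_that("tau-b matches the brute-force pair-counting oracle on tied data", {
  withr::local_seed(101)
  for (i in 1:500) {
    n <- sample(4:12, 1)
    x <- sample(1:5, n, replace = TRUE) + stats::runif(n) * (i %% 2)
    y <- sample(1:4, n, replace = TRUE)
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    expect_equal(kendall_tau_b(x, y)$tau_b, tau_b_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("tau-b agrees with the standard implementation including p-values", {
  withr::local_seed(102)
  for (i in 1:20) {
    x <- sample(1:6, 15, replace = TRUE)
    y <- sample(1:6, 15, replace = TRUE)
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    ours <- kendall_tau_b(x, y)
    ref <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
    expect_equal(ours$tau_b, unname(ref$estimate), tolerance = 1e-12)
  }
  # asymptotic p against cor.test's normal approximation (ties present)
  x <- c(1, 2, 2, 3, 4, 5, 5, 6, 7, 8)
  y <- c(2, 1, 3, 3, 5, 4, 6, 7, 7, 9)
  ours <- kendall_tau_b(x, y)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("tau-b is symmetric, flags all-tied input, and supports exact p", {
  withr::local_seed(103)
  x <- rnorm(6); y <- rnorm(6)
  expect_equal(kendall_tau_b(x, y)$tau_b, kendall_tau_b(y, x)$tau_b)
  expect_warning(res <- kendall_tau_b(rep(1, 5), 1:5), "undefined")
  expect_true(is.na(res$tau_b))
  ex <- kendall_tau_b(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4), method = "exact")
  # exact p: proportion of permutations with |tau| >= observed
  expect_true(ex$p_value > 0 && ex$p_value <= 1)
  expect_error(kendall_tau_b(rnorm(9), rnorm(9), method = "exact"), "n <= 8")
})

test_that("BH adjustment equals the step-up oracle and preserves order", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  withr::local_seed(104)
  for (i in 1:20) {
    p <- stats::runif(sample(3:30, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
    expect_true(all(bh_adjust(p) >= p))
    # permutation equivariance
    perm <- sample(length(p))
    expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # NAs propagate and shrink the denominator
  p <- c(0.01, NA, 0.04)
  adj <- bh_adjust(p)
  expect_true(is.na(adj[2]))
  expect_equal(adj[c(1, 3)], bh_oracle(c(0.01, 0.04)))
})

test_that("OLS summary matches closed forms and the adjusted-R2 formula", {
  x <- 1:10
  y <- 2 * x + 1
  s <- suppressWarnings(ols_summary(x, y))  # lm warns on an exact fit
  expect_equal(s$slope, 2)
  expect_equal(s$intercept, 1)
  expect_equal(s$r2, 1)
  expect_equal(s$adjusted_r2, 1)
  # adjusted R2 = 1 - (1 - r2)(n - 1)/(n - 2)
  withr::local_seed(105)
  x2 <- rnorm(12); y2 <- x2 + rnorm(12)
  s2 <- ols_summary(x2, y2)
  expect_equal(s2$adjusted_r2, 1 - (1 - s2$r2) * 11 / 10)
  # normal-equations oracle
  X <- cbind(1, x2)
  beta <- solve(t(X) %*% X, t(X) %*% y2)
  expect_equal(c(s2$intercept, s2$slope), as.numeric(beta),
               tolerance = 1e-10)
  expect_error(ols_summary(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("score similarity matches the definition and flags degeneracy", {
  a <- c(t1 = 0.1, t2 = 0.5, t3 = 0.9, t4 = 0.3)
  expect_equal(score_similarity(a, a)$pearson_r, 1)
  expect_equal(score_similarity(a, -a)$pearson_r, -1)
  b <- c(t1 = 0.2, t2 = 0.4, t3 = 0.7, t4 = 0.1)
  expect_equal(score_similarity(a, b)$pearson_r,
               cov(a, b) / (sd(a) * sd(b)), tolerance = 1e-12)
  expect_warning(res <- score_similarity(a, c(t1 = 1, t2 = 1, t3 = 1, t4 = 1)),
                 "constant")
  expect_true(is.na(res$pearson_r))
  expect_error(score_similarity(a, c(t1 = 1, t9 = 2)), "3 common")
})

test_that("complete-linkage clustering orders leaves deterministically", {
  m <- rbind(a = c(0, 0), b = c(0, 0), c = c(10, 10))
  cl <- cluster_scores(m)
  expect_equal(cl$hclust$height[1], 0)        # identical rows merge at 0
  # outlier joins in the final merge, so it sits at one end of the order
  expect_true(cl$leaf_order[1] == "c" || cl$leaf_order[3] == "c")
  expect_true(all(cl$hclust$merge[2, ] %in% c(1, -match("c", rownames(m)))))
  expect_true(all(diff(cl$hclust$height) >= 0))
  expect_match(cl$newick, "^\\(.*\\);$")
  # pairwise-distance oracle: first merge joins the closest pair
  withr::local_seed(106)
  m2 <- matrix(rnorm(20), 5, 4, dimnames = list(letters[1:5], NULL))
  cl2 <- cluster_scores(m2)
  d <- as.matrix(dist(m2))
  diag(d) <- Inf
  closest <- sort(rownames(which(d == min(d), arr.ind = TRUE)))
  first <- sort(cl2$hclust$labels[-cl2$hclust$merge[1, ]])
  expect_equal(first, closest)
})

test_that("selection overlap computes pairwise and global intersections", {
  sel <- list(A = paste0("t", 1:10), B = paste0("t", 1:10))
  ov <- selection_overlap(sel)
  expect_equal(ov$pairwise$n_shared, 10)
  expect_equal(ov$pairwise$pct_of_a, 100)
  sel2 <- list(A = paste0("t", 1:5), B = paste0("u", 1:5))
  expect_equal(selection_overlap(sel2)$pairwise$n_shared, 0)
  sel3 <- list(A = c("x", "y", "z"), B = c("y", "z"), C = c("z", "q"))
  ov3 <- selection_overlap(sel3)
  expect_equal(ov3$global, "z")
  ab <- ov3$pairwise[ov3$pairwise$system_a == "A" &
                       ov3$pairwise$system_b == "B", ]
  expect_equal(ab$n_shared, length(intersect(sel3$A, sel3$B)))
  expect_equal(ab$pct_of_b, 100)
  sel4 <- list(A = character(), B = "x")
  expect_true(is.na(selection_overlap(sel4)$pairwise$pct_of_a))
})

test_that("correlate_taxa screens columns with BH control", {
  withr::local_seed(107)
  n <- 20
  x <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("T", 1:5)))
  y <- x[, 1] + rnorm(n, 0, 0.1)
  res <- correlate_taxa(x, y)
  expect_equal(res$taxon_id, paste0("T", 1:5))
  expect_lt(res$adjusted_p[1], 0.05)
  expect_true(all(res$adjusted_p >= res$p_value, na.rm = TRUE))
})
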