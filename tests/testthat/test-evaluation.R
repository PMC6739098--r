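# Small blocked fixture with a strong planted linear signal.
cv_fixture <- function(n = 36, p = 8, n_groups = 6, sigma = 0, seed = 21) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(paste0("S", 1:n), paste0("V", 1:p)))
    groups <- rep(paste0("G", seq_len(n_groups)), length.out = n)
    y <- drop(x[, 1] * 2 - x[, 2] + rnorm(n, 0, sigma))
    list(x = x, y = y, groups = groups)
  })
}

test_that("pooled R2 matches the hand-computed definition and edge cases", {
  y <- c(1, 2, 3, 4)
  expect_equal(cytotaxa:::pooled_r2(y, y), 1)
  # constant predictor at the pooled mean gives exactly 0
  expect_equal(cytotaxa:::pooled_r2(y, rep(mean(y), 4)), 0)
  # any other constant is negative
  expect_lt(cytotaxa:::pooled_r2(y, rep(10, 4)), 0)
  pred <- c(1.1, 1.9, 3.2, 3.8)
  expect_equal(cytotaxa:::pooled_r2(y, pred),
               1 - sum((y - pred)^2) / sum((y - mean(y))^2))
})

test_that("rcv2 recovers a noiseless planted signal and validates groups", {
  fx <- cv_fixture(sigma = 0)
  res <- rcv2(fx$x, fx$y, fx$groups, n_lambda = 100)
  expect_gte(res$r2, 0.99)
  # predictions pool to one per sample
  expect_equal(nrow(res$predictions), length(fx$y))
  expect_false(anyNA(res$predictions$y_pred))
  expect_equal(res$r2, cytotaxa:::pooled_r2(res$predictions$y_true,
                                            res$predictions$y_pred))
  expect_error(rcv2(fx$x, fx$y, rep("G1", 36)), "2 groups")
  expect_error(rcv2(fx$x[, 0], fx$y, fx$groups), "empty")
})

test_that("recursive elimination finds the perfect predictor among noise", {
  withr::local_seed(31)
  n <- 30
  x <- cbind(signal = rnorm(n), noise = rnorm(n))
  rownames(x) <- paste0("S", 1:n)
  y <- x[, "signal"] * 3
  groups <- rep(paste0("G", 1:5), 6)
  scores <- tibble::tibble(taxon_id = c("signal", "noise"),
                           rl_score = c(1, 0.1), rank = c(1L, 2L))
  tr <- recursive_elimination(x, y, scores, groups, n_lambda = 100)
  expect_equal(tr$optimum$n_retained, 1)
  expect_equal(tr$optimum$taxa, "signal")
  expect_gte(tr$optimum$rcv2, 0.99)
})

test_that("elimination trace length and minimal-optimal tie rule", {
  fx <- cv_fixture(n = 24, p = 7, n_groups = 4, sigma = 0.2)
  scores <- tibble::tibble(taxon_id = colnames(fx$x),
                           rl_score = seq(1, 0.4, length.out = 7),
                           rank = 1:7)
  for (step in c(1, 2, 3)) {
    tr <- recursive_elimination(fx$x, fx$y, scores, fx$groups, step = step,
                                n_lambda = 60)
    expect_equal(nrow(tr$trace), ceiling((7 - 1) / step) + 1)
    expect_true(all(diff(tr$trace$n_retained) < 0))
  }
  expect_error(recursive_elimination(fx$x, fx$y, scores, fx$groups,
                                     step = 7), "step")
  # minimal-optimal: smallest size attaining the maximum
  fake <- tibble::tibble(n_retained = c(7, 5, 3, 1),
                         rcv2 = c(0.2, 0.8, 0.8, 0.1))
  expect_equal(min(fake$n_retained[fake$rcv2 == max(fake$rcv2)]), 3)
})

test_that("nested CV predicts every sample exactly once and recovers signal", {
  fx <- cv_fixture(n = 40, p = 6, n_groups = 5, sigma = 0)
  ncv <- nested_cv(fx$x, fx$y, fx$groups,
                   config = stability_config(B = 25, seed = 8),
                   step = 2, n_lambda = 60)
  expect_gte(ncv$rncv2, 0.99)
  expect_equal(sort(ncv$predictions$sample_id), sort(rownames(fx$x)))
  expect_equal(anyDuplicated(ncv$predictions$sample_id), 0)
  expect_false(anyNA(ncv$predictions$y_pred))
  expect_error(nested_cv(fx$x, fx$y, rep(c("a", "b"), 20)), "3 groups")
})

test_that("held-out selection is leak-free: poisoning held-out y leaves fold selection unchanged", {
  fx <- cv_fixture(n = 30, p = 6, n_groups = 5, sigma = 0.3)
  cfg <- stability_config(B = 20, seed = 5)
  ncv1 <- nested_cv(fx$x, fx$y, fx$groups, config = cfg, step = 2,
                    n_lambda = 40)
  g1 <- unique(fx$groups)[1]
  y_poison <- fx$y
  y_poison[fx$groups == g1] <- rnorm(sum(fx$groups == g1), 100, 50)
  ncv2 <- nested_cv(fx$x, y_poison, fx$groups, config = cfg, step = 2,
                    n_lambda = 40)
  expect_identical(ncv1$folds[[g1]]$selected, ncv2$folds[[g1]]$selected)
})

test_that("null data yield RNCV2 near or below zero", {
  r2s <- vapply(1:3, function(s) {
    withr::with_seed(s * 101, {
      x <- matrix(rnorm(30 * 10), 30, 10)
      y <- rnorm(30)
    })
    nested_cv(x, y, rep(paste0("G", 1:5), 6),
              config = stability_config(B = 15, seed = s), step = 3,
              n_lambda = 40)$rncv2
  }, numeric(1))
  expect_lte(stats::median(r2s), 0.1)
})

test_that("adding a perfect predictor cannot reduce the best trace RCV2", {
  fx <- cv_fixture(n = 24, p = 4, n_groups = 4, sigma = 0.5)
  scores <- tibble::tibble(taxon_id = colnames(fx$x),
                           rl_score = 4:1 / 4, rank = 1:4)
  tr1 <- recursive_elimination(fx$x, fx$y, scores, fx$groups, n_lambda = 60)
  x2 <- cbind(fx$x, perfect = fx$y)
  scores2 <- tibble::tibble(taxon_id = colnames(x2),
                            rl_score = c(4:1 / 4, 1), rank = c(2:5, 1L))
  tr2 <- recursive_elimination(x2, fx$y, scores2, fx$groups, n_lambda = 60)
  expect_gte(tr2$optimum$rcv2, tr1$optimum$rcv2 - 0.05)
})
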