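simple_gate <- function(threshold = 1000) {
  gate_config(hna_threshold = threshold, cofactor = 150)
}

make_rep <- function(fl1, fl3 = rep(500, length(fl1)), vol = 0.001,
                     id = "A", rep_id = 1) {
  fcm_sample(tibble::tibble(FL1 = fl1, FL3 = fl3), sample_id = id,
             replicate_id = rep_id, volume_ml = vol)
}

test_that("gating counts events per population and scales by volume", {
  # 10 events above threshold, 0.001 ml -> 10,000 cells/ml, all HNA
  s <- make_rep(rep(2000, 10))
  fc <- gate_counts(s, simple_gate())
  expect_equal(fc$hnacc, 10000)
  expect_equal(fc$lnacc, 0)
  expect_equal(fc$totalcc, 10000)

  # replicate averaging: 100, 200, 300 -> 200
  reps <- lapply(1:3, function(r)
    make_rep(rep(2000, r * 100), vol = 1, rep_id = r))
  fc3 <- gate_counts(reps, simple_gate())
  expect_equal(fc3$hnacc, 200)
  expect_equal(fc3$n_replicates, 3)
})

test_that("threshold sweep: below event minimum all cells are HNA", {
  withr::local_seed(12)
  fl1 <- runif(200, 500, 3000)
  s <- make_rep(fl1, vol = 0.01)
  fc <- gate_counts(s, simple_gate(threshold = min(fl1) - 1))
  expect_equal(fc$lnacc, 0)
  expect_equal(fc$hnacc, fc$totalcc)
  # above the maximum, all LNA
  fc2 <- gate_counts(s, simple_gate(threshold = max(fl1) + 1))
  expect_equal(fc2$hnacc, 0)
  # conservation and event-order invariance at any cut
  fc3 <- gate_counts(make_rep(rev(fl1), vol = 0.01), simple_gate(1500))
  fc4 <- gate_counts(make_rep(fl1, vol = 0.01), simple_gate(1500))
  expect_equal(fc3, fc4)
  expect_equal(fc3$hnacc + fc3$lnacc, 200 / 0.01)
})

test_that("noise gate excludes events outside the polygon", {
  gate <- gate_config(noise_gate = rbind(c(100, 100), c(5000, 100),
                                         c(5000, 5000), c(100, 5000)),
                      hna_threshold = 1000)
  ev <- tibble::tibble(FL1 = c(50, 200, 2000, 6000),
                       FL3 = c(50, 200, 2000, 2000))
  s <- fcm_sample(ev, "A", 1, volume_ml = 1)
  fc <- gate_counts(s, gate)
  expect_equal(fc$totalcc, 2)   # the 50 and 6000 FL1 events fall outside
  expect_equal(fc$hnacc, 1)
  expect_error(gate_counts(fcm_sample(ev, "A", 1), gate), "volume")
})

test_that("fingerprints are normalised densities with mass where events sit", {
  gate <- simple_gate()
  hi <- asinh(2^18 / 150)
  to_raw <- function(u) sinh(u * hi) * 150
  withr::local_seed(13)
  # tight cluster at the centre of the transformed plane
  ev <- tibble::tibble(FL1 = to_raw(rnorm(500, 0.5, 0.003)),
                       FL3 = to_raw(rnorm(500, 0.5, 0.003)))
  fp <- fingerprint(fcm_sample(ev, "A", 1), gate)
  expect_equal(dim(fp), c(128, 128))
  expect_equal(sum(fp), 1, tolerance = 1e-9)
  am <- which(fp == max(fp), arr.ind = TRUE)
  expect_true(abs(am[1] - 64.5) <= 1.5 && abs(am[2] - 64.5) <= 1.5)
  expect_error(fingerprint(fcm_sample(ev[1, ], "A", 1), gate), ">= 2 events")
})

test_that("mirrored clusters produce a mirror-symmetric fingerprint", {
  gate <- simple_gate()
  hi <- asinh(2^18 / 150)
  to_raw <- function(u) sinh(u * hi) * 150
  withr::local_seed(14)
  u <- rnorm(400, 0.3, 0.02); v <- rnorm(400, 0.5, 0.02)
  ev <- tibble::tibble(FL1 = to_raw(c(u, 1 - u)), FL3 = to_raw(c(v, v)))
  fp <- fingerprint(fcm_sample(ev, "A", 1), gate)
  flipped <- fp[128:1, ]
  expect_lt(max(abs(fp - flipped)), 1e-6)
})

test_that("bin correlations reproduce perfect concordance and the tau oracle", {
  withr::local_seed(15)
  n <- 5
  grids <- lapply(1:n, function(i) {
    g <- matrix(stats::runif(16), 4, 4)
    g / sum(g)
  })
  names(grids) <- paste0("S", 1:n)
  # taxon 1 tracks bin (2,3) density exactly; taxon 2 reverses its ranking
  d <- vapply(grids, function(g) g[2, 3], numeric(1))
  comp <- cbind(T1 = d, T2 = max(d) + min(d) - d,
                T3 = stats::runif(n))
  rownames(comp) <- names(grids)
  bc <- bin_correlations(grids, comp, c("T1", "T2", "T3"))
  at <- function(tx) bc$tau_b[bc$taxon_id == tx & bc$fl1_bin == 2 &
                                bc$fl3_bin == 3]
  expect_equal(at("T1"), tau_b_oracle(d, d))
  expect_equal(at("T1"), 1)
  expect_equal(at("T2"), -1)
  # every defined bin value matches the brute-force oracle
  D <- do.call(rbind, lapply(grids, as.vector))
  t3 <- bc[bc$taxon_id == "T3", ]
  for (i in seq_len(nrow(t3))) {
    bin <- (t3$fl3_bin[i] - 1) * 4 + t3$fl1_bin[i]
    expect_equal(t3$tau_b[i], tau_b_oracle(comp[, "T3"], D[, bin]),
                 tolerance = 1e-12)
  }
  expect_error(bin_correlations(grids[1:2], comp), ">= 3 samples")
  expect_error(bin_correlations(grids, comp, "nope"), "not in composition")
})

test_that("constant bins are flagged undefined, not zero", {
  grids <- lapply(1:4, function(i) matrix(c(0.25, 0.25, 0.25, 0.25), 2, 2))
  names(grids) <- paste0("S", 1:4)
  comp <- matrix(stats::runif(8), 4, 2,
                 dimnames = list(names(grids), c("A", "B")))
  bc <- bin_correlations(grids, comp, "A")
  expect_true(all(is.na(bc$tau_b)))
})

test_that("gate configuration round-trips through YAML", {
  gate <- gate_config(noise_gate = rbind(c(1, 1), c(10, 1), c(10, 10)),
                      hna_threshold = 5, cofactor = 100,
                      transform_range = c(0, 8))
  path <- withr::local_tempfile(fileext = ".yml")
  yaml::write_yaml(list(
    noise_gate = apply(gate$noise_gate, 1, as.list),
    hna_threshold = gate$hna_threshold, cofactor = gate$cofactor,
    transform_range = gate$transform_range), path)
  back <- read_gate_config(path)
  expect_equal(back$hna_threshold, 5)
  expect_equal(back$noise_gate, gate$noise_gate)
  expect_equal(back$transform_range, c(0, 8))
})
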