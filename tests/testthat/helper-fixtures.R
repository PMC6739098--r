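# Shared in-code fixtures. Everything is generated programmatically so the
# suite carries no data files.

tiny_table <- function() {
  counts <- matrix(c(5, 0, 2, 7, 1, 1), nrow = 3, byrow = TRUE,
                   dimnames = list(c("S1", "S2", "S3"), c("OTU1", "OTU2")))
  taxon_table(counts)
}

random_table <- function(n = 8, p = 12, seed = 42, depth = 200) {
  withr::with_seed(seed, {
    counts <- t(rmultinom(n, depth, prob = rexp(p)))
    dimnames(counts) <- list(sprintf("S%02d", seq_len(n)),
                             sprintf("OTU%02d", seq_len(p)))
    taxon_table(counts)
  })
}

random_composition <- function(n = 10, p = 6, seed = 1, zeros = FALSE) {
  withr::with_seed(seed, {
    m <- matrix(rexp(n * p), n, p)
    if (zeros) m[sample(length(m), round(0.2 * length(m)))] <- 0
    m <- m / rowSums(m)
    dimnames(m) <- list(paste0("S", seq_len(n)), paste0("T", seq_len(p)))
    structure(m, class = c("composition_matrix", "matrix", "array"))
  })
}

# Brute-force tau-b oracle: direct pair enumeration, independent of the
# package's vectorised implementation.
tau_b_oracle <- function(x, y) {
  n <- length(x)
  C <- D <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- x[i] - x[j]; dy <- y[i] - y[j]
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (sign(dx) == sign(dy)) C <- C + 1
    else D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# Step-up BH oracle from the defining formula.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

small_sim <- function(seed = 7, ...) {
  simulate_dataset(sim_config(n_samples = 30L, p_taxa = 60L, n_groups = 5L,
                              depth = 2000L, n_drivers = 4L,
                              events_per_sample = 600L, seed = seed, ...))
}
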