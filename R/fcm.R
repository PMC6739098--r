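#' Gating and channel-transform configuration
#'
#' Bundles the three fixed decisions applied identically to every sample:
#' the polygon separating bacterial cells from background noise in raw
#' (FL1, FL3) space, the single FL1 threshold separating high- from
#' low-nucleic-acid (HNA/LNA) cells, and the channel transform used for
#' fingerprinting (asinh with a cofactor, then a fixed min-max rescale of
#' the transformed values to [0, 1] so bins are comparable across samples).
#'
#' @param noise_gate Two-column matrix of polygon vertices in (FL1, FL3)
#'   instrument units, or `NULL` to keep all events.
#' @param hna_threshold FL1 cutoff in instrument units: events strictly
#'   above it are HNA.
#' @param cofactor asinh cofactor for the channel transform.
#' @param transform_range Length-2 numeric: the asinh-scale values mapped to
#'   0 and 1 by the rescale. Must be fixed across samples.
#' @return A `gate_config` list.
#' @export
gate_config <- function(noise_gate = NULL, hna_threshold,
                        cofactor = 150, transform_range = NULL) {
  if (!is.null(noise_gate)) {
    noise_gate <- as.matrix(noise_gate)
    if (ncol(noise_gate) != 2 || nrow(noise_gate) < 3)
      abort("noise_gate must be a polygon: >= 3 rows of (FL1, FL3)")
  }
  if (is.null(transform_range)) transform_range <- c(0, asinh(2^18 / cofactor))
  if (transform_range[2] <= transform_range[1])
    abort("transform_range must be increasing")
  structure(list(noise_gate = noise_gate, hna_threshold = hna_threshold,
                 cofactor = cofactor, transform_range = transform_range),
            class = "gate_config")
}

#' Read a gate configuration from YAML
#'
#' @param path YAML file with keys `hna_threshold`, optional `noise_gate`
#'   (list of `[FL1, FL3]` vertices), `cofactor`, `transform_range`.
#' @return A [gate_config()].
#' @export
read_gate_config <- function(path) {
  y <- yaml::read_yaml(path)
  gate_config(
    noise_gate = if (!is.null(y$noise_gate))
      do.call(rbind, lapply(y$noise_gate, as.numeric)),
    hna_threshold = y$hna_threshold,
    cofactor = y$cofactor %||% 150,
    transform_range = if (!is.null(y$transform_range))
      as.numeric(y$transform_range)
  )
}

# Even-odd rule point-in-polygon; boundary points count as inside.
points_in_polygon <- function(x, y, poly) {
  nv <- nrow(poly)
  inside <- logical(length(x))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

apply_noise_gate <- function(events, gate) {
  if (is.null(gate$noise_gate)) return(events)
  keep <- points_in_polygon(events[[1]], events[[2]], gate$noise_gate)
  events[keep, , drop = FALSE]
}

#' Gate replicates into HNA/LNA cell concentrations
#'
#' Applies the fixed noise gate, splits surviving events at the FL1
#' threshold, converts counts to cells per ml using each replicate's
#' analysed volume, and averages across replicates. By construction
#' `hnacc + lnacc = totalcc`.
#'
#' @param rep_samples A single `fcm_sample` or a list of replicate
#'   `fcm_sample`s for one biological sample.
#' @param gate A [gate_config()].
#' @return A one-row tibble: `sample_id`, `hnacc`, `lnacc`, `totalcc`
#'   (cells/ml) and `n_replicates`.
#' @export
gate_counts <- function(rep_samples, gate) {
  if (inherits(rep_samples, "fcm_sample")) rep_samples <- list(rep_samples)
  if (length(rep_samples) < 1) abort("need at least one replicate")
  per_rep <- purrr::map(rep_samples, function(rep) {
    vol <- attr(rep, "volume_ml")
    if (is.null(vol) || !is.finite(vol) || vol <= 0)
      abort("replicate is missing a positive volume_ml")
    ev <- apply_noise_gate(rep, gate)
    if (nrow(ev) == 0)
      warn(paste0("no events after noise gating in replicate ",
                  attr(rep, "replicate_id")))
    hna <- sum(ev[[1]] > gate$hna_threshold)
    lna <- nrow(ev) - hna
    c(hnacc = hna / vol, lnacc = lna / vol)
  })
  m <- do.call(rbind, per_rep)
  tibble(sample_id = attr(rep_samples[[1]], "sample_id"),
         hnacc = mean(m[, "hnacc"]), lnacc = mean(m[, "lnacc"]),
         totalcc = mean(m[, "hnacc"] + m[, "lnacc"]),
         n_replicates = length(rep_samples))
}

transform_channels <- function(events, gate) {
  tr <- asinh(as.matrix(events) / gate$cofactor)
  lo <- gate$transform_range[1]
  hi <- gate$transform_range[2]
  pmin(pmax((tr - lo) / (hi - lo), 0), 1)
}

#' Kernel-density cytometric fingerprint
#'
#' Builds the per-sample density image over a fixed `grid x grid` binning of
#' the transformed (green, red) fluorescence plane. Events pass the noise
#' gate, channels are asinh-transformed and rescaled to [0, 1], and a
#' Gaussian product kernel of bandwidth `bandwidth` (on the rescaled scale)
#' is evaluated at the bin centres. Each grid is normalised to sum 1.
#'
#' @param sample An `fcm_sample` (one replicate) or list of replicates,
#'   whose events are pooled.
#' @param gate A [gate_config()].
#' @param grid Grid resolution per channel (default 128).
#' @param bandwidth Gaussian kernel bandwidth on the [0, 1] scale.
#' @return A `fingerprint_grid`: `grid x grid` matrix (rows = green FL1
#'   bins, columns = red FL3 bins) summing to 1, with attributes
#'   `bandwidth` and `sample_id`.
#' @export
fingerprint <- function(sample, gate, grid = 128, bandwidth = 0.01) {
  if (inherits(sample, "fcm_sample")) sample <- list(sample)
  events <- dplyr::bind_rows(lapply(sample, function(s)
    as_tibble(as.matrix(s))))
  events <- apply_noise_gate(events, gate)
  if (nrow(events) < 2) abort("need >= 2 events after noise gating for KDE")
  z <- transform_channels(events, gate)
  centers <- (seq_len(grid) - 0.5) / grid
  # separable product kernel: density at (c_i, c_j) = sum_e k(c_i - x_e) k(c_j - y_e)
  kx <- dnorm(outer(centers, z[, 1], "-") / bandwidth)
  ky <- dnorm(outer(centers, z[, 2], "-") / bandwidth)
  dens <- kx %*% t(ky)
  dens <- dens / sum(dens)
  structure(dens, bandwidth = bandwidth,
            sample_id = attr(sample[[1]], "sample_id"),
            class = c("fingerprint_grid", "matrix", "array"))
}

# Vectorised Kendall tau-b of one numeric vector against every column of a
# matrix, with tie corrections; constant columns yield NA (undefined).
tau_b_vector_matrix <- function(t, D) {
  n <- length(t)
  pr <- utils::combn(n, 2)
  st <- sign(t[pr[1, ]] - t[pr[2, ]])
  SD <- sign(D[pr[1, ], , drop = FALSE] - D[pr[2, ], , drop = FALSE])
  n0 <- ncol(pr)
  n1 <- sum(st == 0)
  n2 <- colSums(SD == 0)
  S <- colSums(st * SD)
  denom <- sqrt((n0 - n1) * (n0 - n2))
  out <- ifelse(denom > 0, S / denom, NA_real_)
  out[n0 == n1] <- NA_real_
  out
}

#' Correlate taxa with fingerprint bins
#'
#' For each requested taxon, computes Kendall tau-b across samples between
#' the taxon's relative abundance and the density in every fingerprint bin,
#' mapping where in the (green, red) fluorescence plane a taxon's dynamics
#' are mirrored. Bins whose density is constant across samples are flagged
#' undefined (`NA`), not zero.
#'
#' @param grids Named list of per-sample [fingerprint()] grids (names =
#'   sample ids), all the same resolution.
#' @param comp Relative-abundance matrix with matching sample rows.
#' @param taxa Character vector of taxon ids (columns of `comp`).
#' @return A `bin_correlation_map` tibble: `taxon_id`, `fl1_bin`, `fl3_bin`,
#'   `tau_b`.
#' @export
bin_correlations <- function(grids, comp, taxa = colnames(comp)) {
  if (length(grids) < 3) abort("need >= 3 samples for bin correlations")
  ids <- names(grids)
  if (is.null(ids) || !all(ids %in% rownames(comp)))
    abort("grids must be named by sample ids present in comp")
  missing <- setdiff(taxa, colnames(comp))
  if (length(missing))
    abort(paste0("taxa not in composition: ", paste(missing, collapse = ", ")))
  g <- nrow(grids[[1]])
  D <- do.call(rbind, lapply(grids, as.vector))  # samples x bins
  res <- purrr::map(taxa, function(tx) {
    tau <- tau_b_vector_matrix(comp[ids, tx], D)
    tibble(taxon_id = tx,
           fl1_bin = rep(seq_len(g), times = g),
           fl3_bin = rep(seq_len(g), each = g),
           tau_b = tau)
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("bin_correlation_map", class(out))
  attr(out, "grid") <- g
  out
}

#' @rdname bin_correlations
#' @param object A `bin_correlation_map`.
#' @param ... Unused.
#' @export
autoplot.bin_correlation_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$fl1_bin, .data$fl3_bin,
                                       fill = .data$tau_b)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", na.value = "grey90") +
    ggplot2::facet_wrap(~taxon_id) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "green fluorescence bin", y = "red fluorescence bin",
                  fill = "Kendall\ntau-b")
}

#' @export
autoplot.fingerprint_grid <- function(object, ...) {
  df <- tibble(
    fl1_bin = rep(seq_len(nrow(object)), times = ncol(object)),
    fl3_bin = rep(seq_len(ncol(object)), each = nrow(object)),
    density = as.vector(object)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$fl1_bin, .data$fl3_bin,
                                   fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "green fluorescence bin", y = "red fluorescence bin")
}
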