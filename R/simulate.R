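#' Simulation configuration
#'
#' Defines a synthetic study emulating paired 16S sequencing and flow
#' cytometry of lake bacterioplankton: compositional counts with
#' site-by-year group structure, a sparse set of driver taxa that linearly
#' determine HNA/LNA cell concentrations on the CLR scale, and two-cloud
#' cytometry events with driver-specific subregions. The default group
#' count (10) sits inside the 5-16 range typical of blocked lake surveys;
#' noise is calibrated so that the oracle linear model attains a pooled
#' `R2` of about `target_r2`.
#'
#' @param n_samples,p_taxa,n_groups Community dimensions; `n_groups >= 3`.
#' @param depth Sequencing depth per sample (multinomial size).
#' @param n_drivers Number of driver taxa per target.
#' @param effect_range Range of driver coefficients on the log scale.
#' @param overlap_fraction Fraction of drivers shared between the HNA and
#'   LNA driver sets.
#' @param target_r2 Oracle linear-model R2 used to calibrate the target
#'   noise SD.
#' @param events_per_sample Expected cytometry events per replicate at the
#'   mean total cell count.
#' @param n_replicates Cytometry replicates per sample.
#' @param base_sd,group_sd,sample_sd SDs of the log-abundance components
#'   (taxon baseline, group effect, residual).
#' @param guild_sd SD of the shared per-sample "bloom" factor loaded onto
#'   each driver guild's log-abundances, making drivers of one functional
#'   group co-vary (within-guild correlation about
#'   `guild_sd^2 / (guild_sd^2 + group_sd^2 + sample_sd^2)`).
#' @param seed Master seed; all randomness derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 60L, p_taxa = 300L, n_groups = 10L,
                       depth = 9000L, n_drivers = 10L,
                       effect_range = c(0.3, 0.6),
                       overlap_fraction = 0.2, target_r2 = 0.6,
                       events_per_sample = 3000L, n_replicates = 3L,
                       base_sd = 2, group_sd = 0.5, sample_sd = 0.5,
                       guild_sd = 1, seed = 1L) {
  if (n_groups < 3) abort("n_groups must be >= 3")
  if (p_taxa <= n_drivers) abort("p_taxa must exceed n_drivers")
  if (target_r2 <= 0 || target_r2 > 1) abort("target_r2 must be in (0, 1]")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a grouped microbial community
#'
#' Latent per-sample log-abundances are `base_j + group_gj + eps_ij`
#' (taxon baselines are Gaussian on the log scale, giving a log-normal
#' rank-abundance skew); the softmax of each latent row is the true
#' composition, and observed counts are multinomial draws of `depth` reads.
#' Driver taxa are drawn from the quantifiable upper tier of the community
#' (baseline between the 60th and 97th percentile, i.e. detectable but not
#' dominant) and each driver guild additionally loads a
#' shared per-sample bloom factor (`guild_sd`), so the taxa of one
#' functional group rise and fall together the way co-blooming freshwater
#' clades do.
#'
#' @param cfg A [sim_config()].
#' @return A list: `table` ([taxon_table]), `metadata` tibble
#'   (`sample_id`, `lake_system`, `group_id`), and `truth` (`sim_truth`)
#'   carrying the true compositions, driver sets, coefficients and
#'   fingerprint subregion assignments.
#' @export
simulate_community <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_samples; p <- cfg$p_taxa
    taxa <- sprintf("OTU%03d", seq_len(p))
    samples <- sprintf("S%03d", seq_len(n))
    group <- sprintf("G%02d", rep_len(seq_len(cfg$n_groups), n))
    base <- rnorm(p, 0, cfg$base_sd)

    # planted drivers come from the quantifiable upper tier of the
    # community (but not the few dominants) and form two (possibly
    # overlapping) co-blooming guilds
    qs <- stats::quantile(base, c(0.60, 0.97))
    eligible <- which(base >= qs[1] & base <= qs[2])
    n_overlap <- round(cfg$overlap_fraction * cfg$n_drivers)
    pick <- sample(eligible, 2 * cfg$n_drivers - n_overlap)
    s_hna <- taxa[pick[seq_len(cfg$n_drivers)]]
    s_lna <- taxa[pick[(cfg$n_drivers - n_overlap + 1):
                         (2 * cfg$n_drivers - n_overlap)]]

    group_eff <- matrix(rnorm(cfg$n_groups * p, 0, cfg$group_sd),
                        cfg$n_groups, p)
    lat <- matrix(rnorm(n * p, 0, cfg$sample_sd), n, p)
    lat <- sweep(lat, 2, base, "+") +
      group_eff[match(group, sort(unique(group))), , drop = FALSE]
    # shared bloom factor per guild; overlapping drivers split the loading
    # across their guilds so every driver keeps the same latent variance
    f_hna <- rnorm(n); f_lna <- rnorm(n)
    n_guilds <- (taxa %in% s_hna) + (taxa %in% s_lna)
    for (j in which(n_guilds > 0)) {
      load <- cfg$guild_sd / sqrt(n_guilds[j])
      if (taxa[j] %in% s_hna) lat[, j] <- lat[, j] + load * f_hna
      if (taxa[j] %in% s_lna) lat[, j] <- lat[, j] + load * f_lna
    }
    comp <- exp(lat - apply(lat, 1, max))
    comp <- comp / rowSums(comp)
    dimnames(comp) <- list(samples, taxa)
    counts <- t(vapply(seq_len(n), function(i)
      as.numeric(rmultinom(1, cfg$depth, comp[i, ])), numeric(p)))
    dimnames(counts) <- list(samples, taxa)
    b_hna <- setNames(runif(cfg$n_drivers, cfg$effect_range[1],
                            cfg$effect_range[2]), s_hna)
    b_lna <- setNames(runif(cfg$n_drivers, cfg$effect_range[1],
                            cfg$effect_range[2]), s_lna)

    # fingerprint subregions on the transformed [0,1]^2 plane: HNA drivers
    # sit above the FL1 threshold (0.5), LNA drivers below; red-channel
    # positions stay clear of the base clouds (FL3 ~ 0.45-0.55)
    sub_centers <- function(side, k) {
      fl1 <- if (side == "hna") seq(0.62, 0.92, length.out = max(k, 2))
             else seq(0.08, 0.38, length.out = max(k, 2))
      tibble(fl1 = fl1[seq_len(k)],
             fl3 = rep(c(0.15, 0.85), length.out = k))
    }
    truth <- structure(list(
      composition = comp,
      s_hna = s_hna, s_lna = s_lna,
      b_hna = b_hna, b_lna = b_lna,
      subregions = dplyr::bind_rows(
        sub_centers("hna", length(s_hna)) %>%
          mutate(taxon_id = s_hna, side = "hna"),
        sub_centers("lna", length(s_lna)) %>%
          mutate(taxon_id = s_lna, side = "lna")),
      seed = cfg$seed), class = "sim_truth")

    list(table = taxon_table(counts),
         metadata = tibble(sample_id = samples, lake_system = "simulated",
                           group_id = group),
         truth = truth)
  })
}

#' Simulate HNA/LNA cell concentrations from planted drivers
#'
#' On the log scale, each target is an affine function of the CLR of the
#' true (latent) composition restricted to its driver set, plus Gaussian
#' noise: `log(HNAcc_i) = a0 + sum_j b_j z_ij + eps_i`. The noise SD is
#' calibrated from the realised linear-predictor variance so that the
#' oracle model's `R2` is `cfg$target_r2` (exactly noiseless when
#' `target_r2 = 1`). Cell concentrations are positive by construction.
#'
#' @param truth A `sim_truth` from [simulate_community()].
#' @param cfg The same [sim_config()].
#' @return A tibble `sample_id`, `hnacc`, `lnacc` (cells/ml) with
#'   attributes `sigma_hna`, `sigma_lna`.
#' @export
simulate_targets <- function(truth, cfg) {
  z <- clr_transform(truth$composition, delta = 1 / ncol(truth$composition)^2)
  eta <- function(drv, b, a0) a0 + drop(z[, drv, drop = FALSE] %*% b)
  calibrate <- function(eta) {
    if (cfg$target_r2 >= 1) return(0)
    sd(eta) * sqrt((1 - cfg$target_r2) / cfg$target_r2)
  }
  withr::with_seed(cfg$seed + 1L, {
    eta_h <- eta(truth$s_hna, truth$b_hna, log(3e5))
    eta_l <- eta(truth$s_lna, truth$b_lna, log(5e5))
    sig_h <- calibrate(eta_h); sig_l <- calibrate(eta_l)
    hnacc <- exp(eta_h + rnorm(length(eta_h), 0, sig_h))
    lnacc <- exp(eta_l + rnorm(length(eta_l), 0, sig_l))
  })
  structure(tibble(sample_id = rownames(truth$composition),
                   hnacc = hnacc, lnacc = lnacc),
            sigma_hna = sig_h, sigma_lna = sig_l)
}

#' Gate configuration matching the simulator's event geometry
#'
#' The simulator places events on the transformed `[0, 1]^2` plane (HNA/LNA
#' threshold at transformed green fluorescence 0.5, background noise below
#' 0.05) and maps them back to instrument units via the inverse asinh
#' transform; this gate inverts that mapping.
#'
#' @param cofactor asinh cofactor shared with [simulate_fcm()].
#' @return A [gate_config()] whose noise polygon excludes the simulated
#'   background cluster and whose threshold splits the two clouds.
#' @export
sim_gate_config <- function(cofactor = 150) {
  hi <- asinh(2^18 / cofactor)
  raw <- function(u) sinh(u * hi) * cofactor
  gate_config(
    noise_gate = cbind(raw(c(0.05, 1, 1, 0.05)),
                       raw(c(0.05, 0.05, 1, 1))),
    hna_threshold = raw(0.5),
    cofactor = cofactor
  )
}

#' Simulate flow-cytometry event clouds
#'
#' For each sample, `n_replicates` event tables are drawn from a 2-D
#' Gaussian mixture on the transformed plane: an LNA base cloud below the
#' green-fluorescence threshold, an HNA base cloud above it, one
#' subcomponent per driver centred in its assigned subregion with weight
#' increasing in the driver's relative abundance, and a small background
#' noise cluster outside the noise gate. Replicate event totals are
#' Poisson around a value proportional to the sample's total cell count,
#' and each replicate's analysed volume is chosen so that gated counts
#' estimate the generating concentrations.
#'
#' @param truth A `sim_truth`.
#' @param targets Tibble from [simulate_targets()].
#' @param cfg The [sim_config()].
#' @param driver_boost Multiplier turning a driver's cell share (its
#'   relative abundance) into its subcomponent's event share; 1 means the
#'   subcomponent is exactly the taxon's own cells.
#' @return A named list (by sample id) of lists of `fcm_sample` replicates,
#'   in instrument units compatible with [sim_gate_config()].
#' @export
simulate_fcm <- function(truth, targets, cfg, driver_boost = 1) {
  comp <- truth$composition
  cofactor <- 150
  hi <- asinh(2^18 / cofactor)
  to_raw <- function(u) sinh(pmin(pmax(u, 0), 0.999) * hi) * cofactor
  totalcc <- targets$hnacc + targets$lnacc
  lam <- cfg$events_per_sample * totalcc / mean(totalcc)
  volume <- cfg$events_per_sample / mean(totalcc)  # ml per replicate
  withr::with_seed(cfg$seed + 2L, {
    out <- purrr::map(seq_len(nrow(targets)), function(i) {
      sid <- targets$sample_id[i]
      w_h <- targets$hnacc[i] / totalcc[i]
      # mixture components: centre fl1/fl3, sd, weight. A driver's
      # subcomponent represents that taxon's own cells, so its weight is
      # directly proportional to the taxon's relative abundance; the base
      # cloud of each side absorbs the remainder (keeping >= 20% of the
      # side), so the side totals still reproduce the HNA/LNA split.
      build_side <- function(side, w_side, base_center) {
        sub <- truth$subregions[truth$subregions$side == side, ]
        u <- driver_boost * comp[sid, sub$taxon_id]
        cap <- 0.8 * w_side
        if (sum(u) > cap) u <- u * cap / sum(u)
        tibble(fl1 = c(base_center[1], sub$fl1),
               fl3 = c(base_center[2], sub$fl3),
               sd = c(0.06, rep(0.03, nrow(sub))),
               w = c(w_side - sum(u), u))
      }
      mix <- dplyr::bind_rows(
        build_side("hna", w_h, c(0.68, 0.55)),
        build_side("lna", 1 - w_h, c(0.32, 0.45)))
      purrr::map(seq_len(cfg$n_replicates), function(r) {
        m <- rpois(1, lam[i])
        comp_idx <- sample.int(nrow(mix), m, replace = TRUE, prob = mix$w)
        fl1 <- rnorm(m, mix$fl1[comp_idx], mix$sd[comp_idx])
        fl3 <- rnorm(m, mix$fl3[comp_idx], mix$sd[comp_idx])
        # clamp signal events into the gated region so none leak into the
        # noise gate (keeps gated totals Poisson-consistent with lam)
        fl1 <- pmin(pmax(fl1, 0.06), 0.999)
        fl3 <- pmin(pmax(fl3, 0.06), 0.999)
        n_noise <- rpois(1, 0.05 * lam[i])
        ev <- tibble(
          FL1 = to_raw(c(fl1, rnorm(n_noise, 0.02, 0.008))),
          FL3 = to_raw(c(fl3, rnorm(n_noise, 0.02, 0.008))))
        fcm_sample(ev, sample_id = sid, replicate_id = r,
                   volume_ml = volume)
      })
    })
  })
  setNames(out, targets$sample_id)
}

#' Simulate a complete paired dataset
#'
#' Runs [simulate_community()], [simulate_targets()] and (optionally)
#' [simulate_fcm()] under one master seed.
#'
#' @param cfg A [sim_config()].
#' @param fcm Also generate cytometry events (slower).
#' @return A list: `table`, `metadata`, `targets`, `truth`, and `fcm`
#'   (or `NULL`).
#' @export
simulate_dataset <- function(cfg = sim_config(), fcm = FALSE) {
  com <- simulate_community(cfg)
  targets <- simulate_targets(com$truth, cfg)
  events <- if (fcm) simulate_fcm(com$truth, targets, cfg)
  list(table = com$table, metadata = com$metadata, targets = targets,
       truth = com$truth, fcm = events)
}
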