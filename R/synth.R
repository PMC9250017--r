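#' Configuration for the synthetic smFISH generator
#'
#' The generator emulates the statistical structure the variability
#' decomposition assumes, with closed-form ground truth:
#' counts are a Poisson-lognormal mixture. Per cell, a lognormal volume
#' \eqn{V} (mean 1, scaled by `mean_volume`) and a shared lognormal
#' expression factor \eqn{E} (mean 1, log-variance \eqn{\sigma_E^2}) are
#' drawn; a fraction `volume_coupling` of \eqn{\log E}'s variance is the
#' standardized log-volume, so volume correction removes exactly that share
#' of correlated variability when `sigma_V = sqrt(volume_coupling) *
#' sigma_E` (the default calibration). Given \eqn{E}, her1 and her7 are
#' independent Poisson with means \eqn{\mu_1(s) E}, \eqn{\mu_7(s) E}, where
#' \eqn{\mu(s)} follows a kinematic-wave spatial profile. Hence the expected
#' per-slice statistics are
#' correlated \eqn{= e^{\sigma_E^2} - 1} and
#' uncorrelated \eqn{= \frac{1}{2}(1/\mu_1(s) + 1/\mu_7(s))}.
#'
#' @param n_embryos number of embryos (default 6).
#' @param n_slices posterior-to-anterior slices per half (default 30).
#' @param cells_per_slice cells per slice (default 12).
#' @param mu1,mu7 baseline (spatial-profile peak-trough midpoint scale) mean
#'   counts per cell (defaults 25 each, so mean total her is about 49
#'   molecules at the profile average).
#' @param wave_count kinematic waves across the slice range (default 3).
#' @param sigma_E log-SD of the shared extrinsic factor (default 0.5, so
#'   expected correlated variability is e^0.25 - 1 = 0.284).
#' @param sigma_V log-SD of cell volume. Default
#'   `sqrt(volume_coupling) * sigma_E`, the calibration under which volume
#'   correction removes exactly the `volume_coupling` share.
#' @param volume_coupling fraction of the shared factor's log-variance
#'   contributed by log-volume (default 0.38).
#' @param mean_volume mean cell volume in um^3 (default 1000).
#' @param genotype genotype label stamped on generated cells.
#' @param seed integer seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_embryos = 6L, n_slices = 30L, cells_per_slice = 12L,
                         mu1 = 25, mu7 = 25, wave_count = 3,
                         sigma_E = 0.5,
                         sigma_V = sqrt(volume_coupling) * sigma_E,
                         volume_coupling = 0.38,
                         mean_volume = 1000, genotype = "wt", seed = 1L) {
  stopifnot(n_embryos >= 1L, n_slices >= 1L, cells_per_slice >= 1L,
            mu1 > 0, mu7 > 0, wave_count >= 0, sigma_E >= 0, sigma_V >= 0,
            volume_coupling >= 0, volume_coupling <= 1, mean_volume > 0)
  if (volume_coupling > 0 && sigma_E > 0 && sigma_V <= 0) {
    stop("volume_coupling > 0 requires sigma_V > 0", call. = FALSE)
  }
  structure(list(
    n_embryos = as.integer(n_embryos), n_slices = as.integer(n_slices),
    cells_per_slice = as.integer(cells_per_slice),
    mu1 = mu1, mu7 = mu7, wave_count = wave_count,
    sigma_E = sigma_E, sigma_V = sigma_V,
    volume_coupling = volume_coupling, mean_volume = mean_volume,
    genotype = genotype, seed = as.integer(seed)),
    class = "synth_config")
}

#' Kinematic-wave spatial mean profile
#'
#' Mean expression along the posterior-to-anterior axis: 2-3 waves of clock
#' expression are visible across the tissue at any instant, from the
#' posterior-to-anterior phase gradient. The profile is
#' `mu * (0.55 + 0.45 * cos(2 * pi * wave_count * phi))` with
#' `phi = slice_index / n_slices`, strictly positive everywhere.
#'
#' @param slice_index integer (vector) in `[0, n_slices)`.
#' @param n_slices number of slices.
#' @param mu baseline mean count.
#' @param wave_count number of waves across the slice range.
#' @return Mean count(s), strictly positive.
#' @export
spatial_mean <- function(slice_index, n_slices, mu, wave_count = 3) {
  stopifnot(all(slice_index >= 0), all(slice_index < n_slices), mu > 0)
  phi <- slice_index / n_slices
  mu * (0.55 + 0.45 * cos(2 * pi * wave_count * phi))
}

#' Generate a synthetic smFISH cell table with known ground truth
#'
#' @param config a [synth_config()].
#' @return A [cell_table()] with attribute `ground_truth`: a list holding
#'   the expected correlated variability (`correlated`), its expected value
#'   after volume correction (`correlated_volume_corrected`), and a
#'   data.frame `per_slice` with the expected uncorrelated variability and
#'   mean her per slice.
#' @export
generate_cells <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  set.seed(cfg$seed)

  sE2 <- cfg$sigma_E^2
  c_frac <- if (sE2 > 0) cfg$volume_coupling else 0
  rows <- vector("list", cfg$n_embryos * 2L * cfg$n_slices)
  k <- 0L
  for (e in seq_len(cfg$n_embryos)) {
    set.seed(derive_seed(cfg$seed, e))  # distinct embryos: derived substreams
    for (half in c("left", "right")) {
      for (s in 0:(cfg$n_slices - 1L)) {
        n <- cfg$cells_per_slice
        zv <- rnorm(n)                       # standardized log-volume
        ze <- rnorm(n)                       # volume-independent extrinsic part
        volume <- cfg$mean_volume * exp(-cfg$sigma_V^2 / 2 + cfg$sigma_V * zv)
        logE <- -sE2 / 2 +
          cfg$sigma_E * (sqrt(c_frac) * zv + sqrt(1 - c_frac) * ze)
        E <- exp(logE)
        m1 <- spatial_mean(s, cfg$n_slices, cfg$mu1, cfg$wave_count)
        m7 <- spatial_mean(s, cfg$n_slices, cfg$mu7, cfg$wave_count)
        k <- k + 1L
        rows[[k]] <- data.frame(
          embryo_id = sprintf("E%02d", e), genotype = cfg$genotype,
          half = half, slice_index = s,
          cell_id = sprintf("c%03d", seq_len(n)),
          her1_count = rpois(n, m1 * E), her7_count = rpois(n, m7 * E),
          volume = volume, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- cell_table(do.call(rbind, rows), provenance = "synthetic")

  s <- 0:(cfg$n_slices - 1L)
  mu1s <- spatial_mean(s, cfg$n_slices, cfg$mu1, cfg$wave_count)
  mu7s <- spatial_mean(s, cfg$n_slices, cfg$mu7, cfg$wave_count)
  # residual shared log-variance after dividing counts by volume:
  # (sqrt(c) * sigma_E - sigma_V)^2 + (1 - c) * sigma_E^2
  resid_var <- (sqrt(c_frac) * cfg$sigma_E - cfg$sigma_V)^2 + (1 - c_frac) * sE2
  attr(tab, "ground_truth") <- list(
    correlated = exp(sE2) - 1,
    correlated_volume_corrected = exp(resid_var) - 1,
    per_slice = data.frame(
      slice_index = s, mu1 = mu1s, mu7 = mu7s,
      mean_her = mu1s + mu7s,
      uncorrelated = 0.5 * (1 / mu1s + 1 / mu7s)))
  tab
}

#' Generate a matched genotype pair with prescribed effects
#'
#' Regenerates a second table from the same configuration with the expected
#' mean level scaled by `level_scale`, the expected correlated variability
#' scaled by `correlated_scale` (through sigma_E), and the expected
#' uncorrelated variability scaled by `uncorrelated_scale` (through the
#' Poisson means: uncorrelated variability is counting noise, so scaling it
#' by u scales the means by 1/u; the net mean multiplier is
#' `level_scale / uncorrelated_scale`).
#'
#' @param config a [synth_config()] for the reference genotype.
#' @param level_scale,correlated_scale,uncorrelated_scale positive effect
#'   sizes (1 = no change).
#' @param genotype_b label for the second table (default `"mut"`).
#' @return list of two [generate_cells()] tables, `a` and `b`, each with
#'   its own ground truth.
#' @export
make_genotype_pair <- function(config, level_scale = 1, correlated_scale = 1,
                               uncorrelated_scale = 1, genotype_b = "mut") {
  stopifnot(inherits(config, "synth_config"),
            level_scale > 0, correlated_scale > 0, uncorrelated_scale > 0)
  v_a <- exp(config$sigma_E^2) - 1
  v_b <- correlated_scale * v_a
  sE2_b <- log1p(v_b)                 # always >= 0 for positive scales
  mu_mult <- level_scale / uncorrelated_scale
  cfg_b <- config
  cfg_b$mu1 <- config$mu1 * mu_mult
  cfg_b$mu7 <- config$mu7 * mu_mult
  cfg_b$sigma_E <- sqrt(sE2_b)
  # keep the volume-coupled share calibrated for the new sigma_E
  cfg_b$sigma_V <- sqrt(cfg_b$volume_coupling) * cfg_b$sigma_E
  cfg_b$genotype <- genotype_b
  cfg_b$seed <- derive_seed(config$seed, 7919L)
  list(a = generate_cells(config), b = generate_cells(cfg_b))
}
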