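#' Simulate one cell of the stochastic clock
#'
#' Evolves the full reaction network by the exact (direct-method) Gillespie
#' algorithm from the all-zero initial condition and records the mature
#' species at `T0, T0 + dt_obs, ..., Tmax`. Burn-in before `T0` is
#' discarded. Deterministic given `seed`.
#'
#' @param params a [sim_params()].
#' @param seed integer seed.
#' @return data.frame with columns `time`, `m1n`, `m7n`, `p1`, `p7`, `p17`.
#' @export
simulate_cell <- function(params, seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(seed)
  out <- sim_cell_cpp(unclass(params))
  as.data.frame(out)
}

#' Simulate a population of independent cells
#'
#' Many trajectories from the same initial condition; one trajectory is one
#' cell. Cells use independent RNG substreams derived from the master seed,
#' so the population is reproducible and cells dephase freely.
#'
#' @param params a [sim_params()].
#' @param n_cells number of cells (>= 2; variability across a single cell
#'   is undefined).
#' @param seed master integer seed.
#' @return A `population_snapshots` list: `time` (observation times),
#'   `m1`, `m7` (matrices, time x cell, mature mRNA counts), `params`.
#' @export
simulate_population <- function(params, n_cells, seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  if (n_cells < 2L) {
    stop("need at least 2 cells: population variability is undefined for 1",
         call. = FALSE)
  }
  cells <- lapply(seq_len(n_cells), function(i) {
    simulate_cell(params, seed = derive_seed(seed, i))
  })
  structure(list(
    time = cells[[1]]$time,
    m1 = vapply(cells, `[[`, numeric(nrow(cells[[1]])), "m1n"),
    m7 = vapply(cells, `[[`, numeric(nrow(cells[[1]])), "m7n"),
    params = params),
    class = "population_snapshots")
}

#' @export
print.population_snapshots <- function(x, ...) {
  cat(sprintf("<population_snapshots> %d cells x %d times (t = %g..%g min)\n",
              ncol(x$m1), length(x$time), min(x$time), max(x$time)))
  invisible(x)
}

#' Variability-versus-mean curve from simulated snapshots
#'
#' At each observation time the correlated and uncorrelated variability are
#' computed across cells (m1 against m7, the in-silico analogue of a
#' phase-grouped slice); time points are then binned by the mean total
#' mature mRNA `<m1n> + <m7n>` into `n_bins` equal-count bins and averaged,
#' exactly as the per-slice analysis bins slices by mean her expression.
#' Time points where either gene has zero mean are skipped.
#'
#' @param snapshots a [simulate_population()] result.
#' @param n_bins number of bins (default 5).
#' @return A [bin_curve()] `binned_curve`; the underlying per-time points
#'   are attached as attribute `points`.
#' @export
sim_variability_curve <- function(snapshots, n_bins = 5L) {
  stopifnot(inherits(snapshots, "population_snapshots"))
  n_t <- length(snapshots$time)
  rows <- lapply(seq_len(n_t), function(i) {
    x <- snapshots$m1[i, ]; y <- snapshots$m7[i, ]
    if (mean(x) <= 0 || mean(y) <= 0) return(NULL)
    data.frame(time = snapshots$time[i],
               mean_her = mean(x) + mean(y),
               correlated = correlated_variability(x, y),
               uncorrelated = uncorrelated_variability(x, y))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) < n_bins) {
    stop("fewer than n_bins usable observation times", call. = FALSE)
  }
  points <- do.call(rbind, rows)
  points$total <- points$correlated + points$uncorrelated
  curve <- bin_curve(points, n_bins = n_bins, genotype = "simulated")
  attr(curve, "points") <- points
  curve
}

#' Compare wild-type and deletion-mutant simulations
#'
#' Runs matched wild-type and deletion-mutant (`Bmax` halved) populations
#' over several seeds and measures, for each variability component, the
#' relative reduction of its bin-averaged value (mutant versus wild type on
#' matched bins of each genotype's own 5-bin curve — the negative feedback
#' partially buffers the mean, so the two genotypes' expression ranges need
#' not overlap).
#'
#' @param params wild-type [sim_params()].
#' @param n_cells cells per population.
#' @param seeds integer vector of master seeds (one replicate each).
#' @param n_bins bins per curve.
#' @return data.frame, one row per seed: `seed`, `correlated_reduction`,
#'   `uncorrelated_reduction` (1 - mutant/wild-type bin-averaged value).
#' @export
dosage_comparison <- function(params, n_cells = 60L, seeds = 1:10,
                              n_bins = 5L) {
  stopifnot(inherits(params, "sim_params"))
  mut <- deletion_mutant(params)
  rows <- lapply(seeds, function(sd) {
    cw <- sim_variability_curve(simulate_population(params, n_cells, seed = sd),
                                n_bins = n_bins)
    cm <- sim_variability_curve(simulate_population(mut, n_cells,
                                                    seed = derive_seed(sd, 5e5)),
                                n_bins = n_bins)
    data.frame(
      seed = sd,
      correlated_reduction = 1 - mean(cm$mean_correlated) /
                                 mean(cw$mean_correlated),
      uncorrelated_reduction = 1 - mean(cm$mean_uncorrelated) /
                                   mean(cw$mean_uncorrelated))
  })
  do.call(rbind, rows)
}

#' Dominant oscillation period from a long trajectory
#'
#' Estimates the period of the mature her1 mRNA trajectory as the lag of
#' the first local maximum of its autocorrelation function.
#'
#' @param trajectory a [simulate_cell()] data.frame.
#' @param column which species column (default `"m1n"`).
#' @return Estimated period in minutes (NA if no interior ACF peak).
#' @export
estimate_period <- function(trajectory, column = "m1n") {
  v <- trajectory[[column]]
  dt <- diff(trajectory$time[1:2])
  a <- acf(v, lag.max = min(length(v) - 2L, ceiling(120 / dt)),
           plot = FALSE)$acf[, 1, 1]
  # first local maximum after the zero-lag peak
  for (i in 3:(length(a) - 1L)) {
    if (a[i] >= a[i - 1L] && a[i] >= a[i + 1L] && a[i] > 0) {
      return((i - 1L) * dt)
    }
  }
  NA_real_
}
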