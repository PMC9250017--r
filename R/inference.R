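#' Area under a binned variability curve
#'
#' Trapezoidal integral of one variability component over the bin mean
#' expression axis. With only five bins a higher-order rule is unwarranted.
#'
#' @param curve a [bin_curve()] result (or data.frame with `bin_mean_her`
#'   and the `mean_*` columns).
#' @param component `"correlated"`, `"uncorrelated"`, or `"total"`.
#' @return The AUC (units: variability x expression).
#' @export
curve_auc <- function(curve,
                      component = c("correlated", "uncorrelated", "total")) {
  component <- match.arg(component)
  x <- curve$bin_mean_her
  y <- curve[[paste0("mean_", component)]]
  if (length(x) < 2L) stop("AUC needs at least 2 bins", call. = FALSE)
  if (is.unsorted(x)) {
    ord <- order(x)
    x <- x[ord]; y <- y[ord]
  }
  pracma::trapz(x, y)
}

# Trapezoid integral of the piecewise-linear curve (x, y) restricted to
# [lo, hi]; endpoints inside a segment are obtained by linear interpolation.
auc_on_range <- function(x, y, lo, hi) {
  stopifnot(lo < hi, lo >= x[1], hi <= x[length(x)])
  inner <- x > lo & x < hi
  xs <- c(lo, x[inner], hi)
  ys <- c(stats::approx(x, y, xout = lo)$y, y[inner],
          stats::approx(x, y, xout = hi)$y)
  pracma::trapz(xs, ys)
}

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + i * 1009) %% 2147483647)
}

#' Bootstrap AUC comparison of variability between two genotypes
#'
#' Because variability depends on mean expression, genotypes are compared at
#' similar mean RNA levels: each bootstrap resample draws slices with
#' replacement within each genotype, rebins both into `n_bins` bins, and
#' integrates the chosen variability component over the overlap of the two
#' curves' mean-expression ranges (curves are linearly truncated at the
#' overlap endpoints). The paired t-test is then applied across the
#' `n_resamples` AUC pairs, paired by resample index. Within a resample both
#' genotypes draw from identically seeded substreams, so two identical
#' inputs yield identical resamples and an exactly zero difference.
#'
#' Two p-values are reported. The primary `p_value` treats the bootstrap
#' spread of the paired AUC differences as the standard error of the
#' observed difference (`t = mean(d) / sd(d)`, t reference with
#' `n_resamples - 1` df): this is the calibrated bootstrap test of whether
#' the two genotypes' curves differ. The naive paired t-test across the
#' resample pairs (`paired_t_p_value`), which additionally divides the
#' spread by `sqrt(n_resamples)`, is kept for reference; it treats
#' resamples of the same data as independent replicates and is strongly
#' anticonservative, which is why it is not the primary result.
#'
#' @param points_a,points_b `variability_points` for the two genotypes
#'   (reference first: the percent difference is relative to `points_a`).
#' @param component which variability component to compare.
#' @param n_resamples number of bootstrap resamples (default 100).
#' @param seed integer seed; the comparison is fully reproducible given it.
#' @param n_bins bins per curve (default 5).
#' @return An `auc_comparison` list: `auc_a`, `auc_b` (paired vectors),
#'   `mean_percent_difference` (100 * (mean(auc_b) - mean(auc_a)) /
#'   mean(auc_a)), `full_data_percent_difference` (same ratio from the two
#'   un-resampled curves over their overlap), `t_statistic`, `p_value`
#'   (calibrated bootstrap test), `paired_t_statistic`, `paired_t_p_value`
#'   (naive paired t-test), `n_resamples`, `n_redraws`, `seed`,
#'   `component`.
#' @export
bootstrap_auc_compare <- function(points_a, points_b,
                                  component = c("correlated", "uncorrelated",
                                                "total"),
                                  n_resamples = 100L, seed = 1L,
                                  n_bins = 5L) {
  component <- match.arg(component)
  stopifnot(nrow(points_a) >= n_bins, nrow(points_b) >= n_bins)

  resample_curve <- function(points, sub_seed) {
    set.seed(sub_seed)
    idx <- sample.int(nrow(points), replace = TRUE)
    bin_curve(points[idx, , drop = FALSE], n_bins = n_bins)
  }
  overlap_aucs <- function(ca, cb) {
    lo <- max(ca$bin_mean_her[1], cb$bin_mean_her[1])
    hi <- min(ca$bin_mean_her[n_bins], cb$bin_mean_her[n_bins])
    if (!(lo < hi)) return(NULL)
    col <- paste0("mean_", component)
    c(auc_on_range(ca$bin_mean_her, ca[[col]], lo, hi),
      auc_on_range(cb$bin_mean_her, cb[[col]], lo, hi))
  }

  auc_a <- auc_b <- numeric(n_resamples)
  n_redraws <- 0L
  draw <- 0L
  for (r in seq_len(n_resamples)) {
    repeat {
      draw <- draw + 1L
      sub <- derive_seed(seed, draw)
      # same substream for both arms: identical inputs => identical draws
      ab <- overlap_aucs(resample_curve(points_a, sub),
                         resample_curve(points_b, sub))
      if (!is.null(ab)) break
      n_redraws <- n_redraws + 1L
      if (n_redraws > 100L * n_resamples) {
        stop("bootstrap failed: curves never overlap in mean expression",
             call. = FALSE)
      }
    }
    auc_a[r] <- ab[1]; auc_b[r] <- ab[2]
  }

  diffs <- auc_b - auc_a
  if (isTRUE(all.equal(var(diffs), 0)) || all(diffs == 0)) {
    warning("degenerate comparison: zero-variance AUC differences; p = 1")
    t_stat <- 0; p_val <- 1
    pt_stat <- 0; pt_p <- 1
  } else {
    t_stat <- mean(diffs) / sd(diffs)
    p_val <- 2 * stats::pt(-abs(t_stat), df = n_resamples - 1L)
    tt <- t.test(auc_b, auc_a, paired = TRUE)
    pt_stat <- unname(tt$statistic); pt_p <- tt$p.value
  }

  full <- overlap_aucs(bin_curve(points_a, n_bins = n_bins),
                       bin_curve(points_b, n_bins = n_bins))
  full_pct <- if (is.null(full)) NA_real_ else 100 * (full[2] - full[1]) / full[1]

  structure(list(
    auc_a = auc_a, auc_b = auc_b,
    mean_percent_difference = 100 * (mean(auc_b) - mean(auc_a)) / mean(auc_a),
    full_data_percent_difference = full_pct,
    t_statistic = t_stat, p_value = p_val,
    n_resamples = n_resamples, n_redraws = n_redraws,
    seed = seed, component = component),
    class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf(
    paste0("<auc_comparison> %s variability: %+.1f%% (bootstrap mean, n = %d)",
           " / %+.1f%% (full data)\n  paired t = %.3f, p = %.3g\n"),
    x$component, x$mean_percent_difference, x$n_resamples,
    x$full_data_percent_difference, x$t_statistic, x$p_value))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison of per-cell totals
#'
#' Compares the distributions of total her (her1 + her7) per cell between
#' two genotypes.
#'
#' @param x,y numeric vectors of per-cell total her for the two genotypes.
#' @return list with `D` and `p_value`.
#' @export
ks_compare <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  kt <- suppressWarnings(ks.test(x, y))
  list(D = unname(kt$statistic), p_value = kt$p.value)
}

#' Shapiro-Wilk normality check
#'
#' Advisory normality assessment of (for instance) bootstrap AUC
#' differences; it does not gate the paired t-test.
#'
#' @param values numeric vector, 3 <= n <= 5000, non-constant.
#' @return list with `W` and `p_value`.
#' @export
normality_check <- function(values) {
  n <- length(values)
  if (n < 3L || n > 5000L) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000, got ", n, call. = FALSE)
  }
  if (length(unique(values)) == 1L) {
    stop("normality check undefined for a constant vector", call. = FALSE)
  }
  st <- shapiro.test(values)
  list(W = unname(st$statistic), p_value = st$p.value)
}
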