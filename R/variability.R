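#' Correlated, uncorrelated and total transcriptional variability
#'
#' Across a population of cells at the same oscillation phase, cell-to-cell
#' variability of the paired clock transcripts decomposes, in the spirit of
#' dual-reporter noise analysis, into
#' \itemize{
#'   \item \emph{uncorrelated} variability (intrinsic-like):
#'     \eqn{\frac{1}{2}\langle (x_i/\langle x\rangle - y_i/\langle y\rangle)^2 \rangle}
#'   \item \emph{correlated} variability (extrinsic-like):
#'     \eqn{(\langle xy\rangle - \langle x\rangle\langle y\rangle) /
#'          (\langle x\rangle\langle y\rangle)}
#' }
#' and their sum, the total variability, equals the average squared
#' coefficient of variation \eqn{\frac{1}{2}(CV^2_x + CV^2_y)}.
#' All angle brackets are plain population averages (1/n moments).
#'
#' @param x numeric vector of per-cell her1 counts (or concentrations).
#' @param y matched numeric vector of per-cell her7 values; same length.
#' @return A single number. `correlated_variability()` may be negative;
#'   the other two are non-negative.
#' @examples
#' x <- c(10, 20); y <- c(20, 10)
#' uncorrelated_variability(x, y)  # 2/9
#' correlated_variability(x, y)    # -1/9
#' total_variability(x, y)         # 1/9
#' @export
uncorrelated_variability <- function(x, y) {
  check_pair(x, y)
  0.5 * mean((x / mean(x) - y / mean(y))^2)
}

#' @rdname uncorrelated_variability
#' @export
correlated_variability <- function(x, y) {
  check_pair(x, y)
  (mean(x * y) - mean(x) * mean(y)) / (mean(x) * mean(y))
}

#' @rdname uncorrelated_variability
#' @export
total_variability <- function(x, y) {
  correlated_variability(x, y) + uncorrelated_variability(x, y)
}

check_pair <- function(x, y) {
  if (length(x) != length(y)) {
    stop("her1 and her7 vectors must have equal length", call. = FALSE)
  }
  if (length(x) < 2L) {
    stop("need at least 2 cells", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("missing values in counts", call. = FALSE)
  if (mean(x) <= 0 || mean(y) <= 0) {
    stop("variability undefined: zero mean expression in a gene",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Convert counts to concentrations by cell volume
#'
#' Replaces `her1_count` and `her7_count` with `count / volume`
#' (molecules/um^3). Concentration-based variability removes the share of
#' correlated variability attributable to cell-volume differences;
#' uncorrelated variability is volume-independent.
#'
#' @param table a [cell_table()] with raw counts.
#' @return A [cell_table()] flagged `volume_corrected`.
#' @export
volume_correct <- function(table) {
  stopifnot(inherits(table, "cell_table"))
  if (isTRUE(attr(table, "volume_corrected"))) {
    stop("table is already volume-corrected", call. = FALSE)
  }
  df <- as.data.frame(table)
  df$her1_count <- df$her1_count / df$volume
  df$her7_count <- df$her7_count / df$volume
  cell_table(df, volume_corrected = TRUE,
             provenance = attr(table, "provenance"))
}

#' Per-slice variability statistics
#'
#' Groups cells by `(embryo_id, half, slice_index)` — a single-cell-wide
#' posterior-to-anterior slice holds cells at the same oscillation phase —
#' and evaluates the variability decomposition within each group. Groups
#' with fewer than `min_cells` cells, or with zero mean expression in either
#' gene, are dropped and counted in the `dropped` attribute.
#'
#' @param table a [cell_table()], raw or volume-corrected.
#' @param min_cells minimum cells per slice for a slice to be retained
#'   (default 5).
#' @return A data.frame of class `variability_points` with one row per
#'   retained slice: `embryo_id`, `half`, `slice_index`, `mean_her`
#'   (mean of her1 + her7 per cell), `correlated`, `uncorrelated`, `total`,
#'   `n_cells`; attribute `dropped` reports excluded groups.
#' @export
slice_statistics <- function(table, min_cells = 5L) {
  stopifnot(inherits(table, "cell_table"), min_cells >= 2L)
  df <- as.data.frame(table)
  key <- interaction(df$embryo_id, df$half, df$slice_index, drop = TRUE)
  groups <- split(df, key)

  rows <- vector("list", length(groups))
  dropped <- character(0)
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    label <- sprintf("%s/%s/slice %d", g$embryo_id[1], g$half[1],
                     g$slice_index[1])
    if (nrow(g) < min_cells) {
      dropped <- c(dropped, sprintf("%s: %d cells < min_cells", label, nrow(g)))
      next
    }
    if (mean(g$her1_count) <= 0 || mean(g$her7_count) <= 0) {
      dropped <- c(dropped, sprintf("%s: zero mean expression", label))
      next
    }
    rows[[i]] <- data.frame(
      embryo_id = g$embryo_id[1], half = g$half[1],
      slice_index = g$slice_index[1], genotype = g$genotype[1],
      mean_her = mean(g$her1_count + g$her7_count),
      correlated = correlated_variability(g$her1_count, g$her7_count),
      uncorrelated = uncorrelated_variability(g$her1_count, g$her7_count),
      n_cells = nrow(g),
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    stop("no slice passed the min_cells threshold (", min_cells, ")",
         call. = FALSE)
  }
  out <- do.call(rbind, rows)
  out$total <- out$correlated + out$uncorrelated
  rownames(out) <- NULL
  structure(out,
            class = c("variability_points", "data.frame"),
            dropped = dropped,
            volume_corrected = isTRUE(attr(table, "volume_corrected")))
}

#' Bin per-slice variability points into a variability-versus-mean curve
#'
#' Slices are sorted by mean her expression and split into `n_bins`
#' equal-count (quantile) bins; ties are broken by stable sort order. Per
#' bin the mean of `mean_her` and the mean and standard error of each
#' variability component are reported. Error bars in plots are conventionally
#' two standard errors; the curve stores one SE.
#'
#' @param points a `variability_points` data.frame from [slice_statistics()]
#'   (or any data.frame with `mean_her`, `correlated`, `uncorrelated`,
#'   `total` columns).
#' @param n_bins number of bins (default 5).
#' @param genotype optional genotype label attached to the curve.
#' @return A data.frame of class `binned_curve` with one row per bin:
#'   `bin`, `bin_mean_her`, `mean_correlated`, `mean_uncorrelated`,
#'   `mean_total`, `se_correlated`, `se_uncorrelated`, `se_total`,
#'   `n_slices`.
#' @export
bin_curve <- function(points, n_bins = 5L, genotype = NULL) {
  stopifnot(is.data.frame(points), n_bins >= 1L)
  n <- nrow(points)
  if (n < n_bins) {
    stop("need at least n_bins (", n_bins, ") points, got ", n, call. = FALSE)
  }
  if (is.null(genotype)) {
    genotype <- if ("genotype" %in% names(points)) {
      paste(unique(points$genotype), collapse = "+")
    } else NA_character_
  }
  ord <- order(points$mean_her)  # stable in base R
  # near-equal bin sizes: first (n mod n_bins) bins get the extra point
  sizes <- diff(round(seq(0, n, length.out = n_bins + 1)))
  bin_of <- rep(seq_len(n_bins), times = sizes)

  se <- function(v) if (length(v) > 1L) sd(v) / sqrt(length(v)) else 0
  rows <- lapply(seq_len(n_bins), function(b) {
    p <- points[ord[bin_of == b], , drop = FALSE]
    data.frame(
      bin = b,
      bin_mean_her = mean(p$mean_her),
      mean_correlated = mean(p$correlated),
      mean_uncorrelated = mean(p$uncorrelated),
      mean_total = mean(p$total),
      se_correlated = se(p$correlated),
      se_uncorrelated = se(p$uncorrelated),
      se_total = se(p$total),
      n_slices = nrow(p))
  })
  out <- do.call(rbind, rows)
  structure(out,
            class = c("binned_curve", "data.frame"),
            n_bins = n_bins,
            genotype = genotype,
            volume_corrected = isTRUE(attr(points, "volume_corrected")))
}

#' Posterior-to-anterior mean expression profile
#'
#' Mean transcript number per slice for one embryo half, ordered posterior
#' (slice 0) to anterior, with twice the standard error of the mean — the
#' spatial profile in which the clock's kinematic waves are visible.
#'
#' @param table a [cell_table()].
#' @param embryo embryo id to select.
#' @param half `"left"` or `"right"`.
#' @param gene `"her7"` (default), `"her1"`, or `"total"`.
#' @return data.frame with `slice_index`, `mean_count`, `two_sem`, `n_cells`.
#' @export
mean_spatial_profile <- function(table, embryo, half = c("right", "left"),
                                 gene = c("her7", "her1", "total")) {
  stopifnot(inherits(table, "cell_table"))
  half <- match.arg(half)
  gene <- match.arg(gene)
  df <- as.data.frame(table)
  df <- df[df$embryo_id == embryo & df$half == half, , drop = FALSE]
  if (nrow(df) == 0L) {
    stop("no cells for embryo '", embryo, "', half '", half, "'",
         call. = FALSE)
  }
  v <- switch(gene,
              her7 = df$her7_count,
              her1 = df$her1_count,
              total = df$her1_count + df$her7_count)
  sl <- split(v, df$slice_index)
  out <- data.frame(
    slice_index = as.integer(names(sl)),
    mean_count = vapply(sl, mean, numeric(1)),
    two_sem = vapply(sl, function(z) {
      if (length(z) > 1L) 2 * sd(z) / sqrt(length(z)) else 0
    }, numeric(1)),
    n_cells = lengths(sl))
  out <- out[order(out$slice_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}
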