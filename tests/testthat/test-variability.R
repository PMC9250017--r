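test_that("hand-evaluated variability values are reproduced exactly", {
  x <- c(10, 20); y <- c(20, 10)
  expect_equal(uncorrelated_variability(x, y), 2 / 9)
  expect_equal(correlated_variability(x, y), -1 / 9)
  expect_equal(total_variability(x, y), 1 / 9)

  expect_equal(uncorrelated_variability(c(1, 2, 3, 4), c(4, 3, 2, 1)), 0.4)
  expect_equal(correlated_variability(c(10, 20), c(10, 20)), 1 / 9)

  # identical normalized profiles and constant genes
  expect_equal(uncorrelated_variability(c(10, 20, 30), c(10, 20, 30)), 0)
  expect_equal(correlated_variability(c(5, 5, 5), c(3, 9, 27)), 0)
  expect_equal(total_variability(c(7, 7, 7), c(7, 7, 7)), 0)
})

test_that("decomposition identity holds to 1e-10 on random inputs", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(2:200, 1)
    x <- rpois(n, runif(1, 1, 80)) + 1
    y <- rpois(n, runif(1, 1, 80)) + 1
    tot <- total_variability(x, y)
    cv2 <- function(v) mean((v - mean(v))^2) / mean(v)^2  # population moments
    expect_equal(tot, 0.5 * (cv2(x) + cv2(y)), tolerance = 1e-10)
    expect_equal(tot,
                 correlated_variability(x, y) + uncorrelated_variability(x, y),
                 tolerance = 1e-12)
    expect_gte(uncorrelated_variability(x, y), 0)
  }
})

test_that("degenerate inputs raise errors", {
  expect_error(uncorrelated_variability(c(0, 0), c(1, 2)), "zero mean")
  expect_error(correlated_variability(c(1, 2, 3), c(1, 2)), "equal length")
  expect_error(total_variability(c(1), c(1)), "at least 2")
})

test_that("breaking the pairing removes correlated but not total variability", {
  sl <- big_slice(mu1 = 25, mu7 = 25, sigma_E = 0.5, n = 20000L, seed = 7L)
  corr_paired <- correlated_variability(sl$x, sl$y)
  set.seed(8)
  y_perm <- sample(sl$y)
  corr_broken <- correlated_variability(sl$x, y_perm)
  expect_gt(corr_paired, 0.2)               # near exp(0.25) - 1
  expect_lt(abs(corr_broken), 0.02)         # -> 0 in expectation
  expect_equal(total_variability(sl$x, y_perm), total_variability(sl$x, sl$y),
               tolerance = 1e-12)           # totals are permutation-invariant
})

test_that("volume correction rescales counts and is scale-invariant", {
  df <- toy_cell_df(n_cells = 8L, n_slices = 2L)
  df$volume <- 1
  tab1 <- cell_table(df)
  cc <- volume_correct(tab1)
  expect_equal(cc$her1_count, tab1$her1_count)
  expect_true(attr(cc, "volume_corrected"))
  expect_error(volume_correct(cc), "already")

  df$volume <- 2
  expect_equal(volume_correct(cell_table(df))$her1_count[1],
               df$her1_count[1] / 2)

  # scaling every volume by c scales concentrations by 1/c and leaves
  # both variability statistics unchanged
  tab <- generate_cells(small_config(seed = 3L))
  scaled <- as.data.frame(tab); scaled$volume <- scaled$volume * 3.7
  s1 <- slice_statistics(volume_correct(tab))
  s2 <- slice_statistics(volume_correct(cell_table(scaled)))
  expect_equal(s2$correlated, s1$correlated, tolerance = 1e-12)
  expect_equal(s2$uncorrelated, s1$uncorrelated, tolerance = 1e-12)
  expect_equal(s2$mean_her, s1$mean_her * 1 / 3.7, tolerance = 1e-12)
})

test_that("slice statistics match direct per-slice evaluation and report drops", {
  df <- toy_cell_df(n_cells = 10L, n_slices = 2L)
  # a third slice too small to keep
  small <- toy_cell_df(n_cells = 3L, n_slices = 1L)
  small$slice_index <- 2L
  tab <- cell_table(rbind(df, small))

  pts <- slice_statistics(tab, min_cells = 5L)
  expect_equal(nrow(pts), 2L)
  expect_match(attr(pts, "dropped"), "slice 2", all = FALSE)

  g0 <- df[df$slice_index == 0, ]
  expect_equal(pts$correlated[pts$slice_index == 0],
               correlated_variability(g0$her1_count, g0$her7_count))
  expect_equal(pts$uncorrelated[pts$slice_index == 0],
               uncorrelated_variability(g0$her1_count, g0$her7_count))
  expect_equal(pts$mean_her[pts$slice_index == 0],
               mean(g0$her1_count + g0$her7_count))
  expect_equal(pts$total, pts$correlated + pts$uncorrelated)

  expect_error(slice_statistics(tab, min_cells = 50L), "no slice passed")
})

test_that("binning is equal-count, ordered, and brackets member points", {
  pts <- data.frame(mean_her = c(10, 3, 8, 1, 5, 9, 2, 7, 4, 6),
                    correlated = runif(10), uncorrelated = runif(10))
  pts$total <- pts$correlated + pts$uncorrelated
  cv <- bin_curve(pts, n_bins = 5L)
  expect_equal(cv$n_slices, rep(2L, 5))
  expect_false(is.unsorted(cv$bin_mean_her))
  expect_equal(cv$bin_mean_her, c(1.5, 3.5, 5.5, 7.5, 9.5))

  # identical points: identical bins, zero SE
  same <- data.frame(mean_her = rep(4, 7), correlated = rep(0.2, 7),
                     uncorrelated = rep(0.1, 7), total = rep(0.3, 7))
  cs <- bin_curve(same, n_bins = 5L)
  expect_equal(unique(cs$mean_correlated), 0.2)
  expect_equal(cs$se_correlated, rep(0, 5))
  expect_equal(sum(cs$n_slices), 7L)

  # bin means bracketed by member extremes
  pts2 <- slice_statistics(generate_cells(small_config(seed = 5L)))
  cv2 <- bin_curve(pts2, n_bins = 5L)
  sorted <- sort(pts2$mean_her)
  sizes <- diff(round(seq(0, length(sorted), length.out = 6)))
  idx <- split(seq_along(sorted), rep(1:5, sizes))
  for (b in 1:5) {
    expect_gte(cv2$bin_mean_her[b], min(sorted[idx[[b]]]))
    expect_lte(cv2$bin_mean_her[b], max(sorted[idx[[b]]]))
  }

  expect_error(bin_curve(pts[1:3, ], n_bins = 5L), "at least n_bins")
})

test_that("spatial profile is posterior-to-anterior with 2 SEM errors", {
  df <- toy_cell_df(n_cells = 6L, n_slices = 4L)
  df$her7_count <- 20L  # constant
  tab <- cell_table(df)
  prof <- mean_spatial_profile(tab, "E01", "right", "her7")
  expect_equal(prof$slice_index, 0:3)
  expect_equal(prof$mean_count, rep(20, 4))
  expect_equal(prof$two_sem, rep(0, 4))

  expect_error(mean_spatial_profile(tab, "nope", "right"), "no cells")

  # single slice -> single-point series
  one <- cell_table(toy_cell_df(n_cells = 6L, n_slices = 1L))
  expect_equal(nrow(mean_spatial_profile(one, "E01", "right")), 1L)

  # kinematic-wave table shows the configured number of interior maxima
  tabw <- generate_cells(synth_config(n_embryos = 1L, n_slices = 60L,
                                      cells_per_slice = 40L, wave_count = 3,
                                      sigma_E = 0.1, seed = 21L))
  profw <- mean_spatial_profile(tabw, "E01", "right", "her7")
  # short running mean so slice-level noise does not split flat crests
  m <- as.numeric(stats::filter(profw$mean_count, rep(1 / 5, 5)))
  m <- m[!is.na(m)]
  peaks <- sum(diff(sign(diff(m))) < 0)  # interior local maxima
  expect_gte(peaks, 2L)
  expect_lte(peaks, 4L)
})
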