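# shared fixtures and Monte-Carlo helpers, all built in code

# minimal hand-built cell table
toy_cell_df <- function(n_cells = 6L, n_slices = 2L, genotype = "wt",
                        embryo = "E01", volume = 1000) {
  do.call(rbind, lapply(0:(n_slices - 1L), function(s) {
    data.frame(embryo_id = embryo, genotype = genotype, half = "right",
               slice_index = s, cell_id = sprintf("c%02d", seq_len(n_cells)),
               her1_count = 10L + s + seq_len(n_cells),
               her7_count = 12L + s + seq_len(n_cells),
               volume = volume, stringsAsFactors = FALSE)
  }))
}

# Monte-Carlo standard error of a paired statistic by subgroup splitting:
# point estimate from the full sample, SE from the spread of K disjoint
# subgroup estimates
mc_se_stat <- function(x, y, fun, K = 20L) {
  n <- length(x)
  grp <- rep(seq_len(K), length.out = n)
  sub <- vapply(seq_len(K), function(k) fun(x[grp == k], y[grp == k]),
                numeric(1))
  list(value = fun(x, y), se = sd(sub) / sqrt(K))
}

# one big phase-homogeneous synthetic slice: returns her1/her7 vectors
big_slice <- function(mu1, mu7, sigma_E, n = 10000L, seed = 1L) {
  set.seed(seed)
  E <- exp(rnorm(n, -sigma_E^2 / 2, sigma_E))
  list(x = rpois(n, mu1 * E), y = rpois(n, mu7 * E))
}

# small synthetic config used across tests
small_config <- function(seed = 1L, ...) {
  synth_config(n_embryos = 2L, n_slices = 15L, cells_per_slice = 8L,
               seed = seed, ...)
}

# fast simulator parameterization for tests that only need short runs
fast_params <- function(...) {
  sim_params(T0 = 100, Tmax = 400, ...)
}
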