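test_that("Hill repression and mean burst size follow the closed form", {
  expect_equal(hill_repression(0, 250), 1)
  expect_equal(hill_repression(250, 250), 0.5)
  expect_equal(hill_repression(500, 250, hill_n = 2L), 0.2)
  expect_error(hill_repression(10, 0), "pdcrit")

  p <- sim_params(Bmax = 10)
  expect_equal(mean_burst_size(0, p), 10)
  expect_equal(mean_burst_size(p$pdcrit, p), 5)
  p0 <- sim_params(Bmax = 0)
  expect_equal(mean_burst_size(1e6, p0), 0)
})

test_that("burst sizes are geometric above mean 1, Bernoulli below", {
  set.seed(1)
  expect_true(all(draw_burst_size(1, n = 200L) == 1L))  # s = 1
  expect_error(draw_burst_size(-1), ">= 0")

  set.seed(2)
  b <- draw_burst_size(4, n = 1e5L)
  se <- sd(b) / sqrt(length(b))
  expect_lt(abs(mean(b) - 4), 3 * se)

  # chi-square against geometric(s = 0.25) on {1..12, 13+}
  obs <- tabulate(pmin(b, 13L), nbins = 13L)
  pr <- c(0.25 * 0.75^(0:11), 0.75^12)
  cs <- suppressWarnings(stats::chisq.test(obs, p = pr))
  expect_gt(cs$p.value, 0.01)

  set.seed(3)
  small <- draw_burst_size(0.3, n = 1e5L)
  expect_true(all(small %in% c(0L, 1L)))
  expect_lt(abs(mean(small) - 0.3), 3 * sd(small) / sqrt(length(small)))
})

test_that("burst propensities partition km between private and joint channels", {
  st <- sim_state(sim_params())
  for (alpha in c(0, 0.3, 1)) {
    a <- propensities(st, sim_params(alpha = alpha, km = 1.5))
    expect_equal(unname(a["burst1"] + a["burst17"]), 1.5)  # total per gene
    expect_equal(unname(a["burst7"] + a["burst17"]), 1.5)
  }
  expect_equal(unname(propensities(st, sim_params(alpha = 1))[c("burst1", "burst7")]),
               c(0, 0))
  expect_equal(unname(propensities(st, sim_params(alpha = 0))["burst17"]), 0)
})

test_that("an all-zero-propensity state is flagged absorbing", {
  p <- sim_params(km = 0, kp1 = 0, kp7 = 0)
  st <- sim_state(p)  # empty state, no production: nothing can fire
  out <- gillespie_step(st, p)
  expect_true(isTRUE(attr(out, "absorbing")))
  expect_equal(out$t, st$t)
})

test_that("reference stepper reproduces exponential decay of a pure-death process", {
  p <- sim_params(km = 0, kp1 = 0, kp7 = 0, gamma_m1 = 0.2,
                  gamma_m7 = 1e-9, gamma_p1 = 1e-9, gamma_p7 = 1e-9,
                  gamma_p17 = 1e-9, kb = 0)
  n0 <- 40L
  set.seed(11)
  # per-replicate count remaining at t = 5 min
  remaining <- vapply(1:120, function(r) {
    st <- sim_state(p); st$m1n <- n0
    repeat {
      nxt <- gillespie_step(st, p)
      if (isTRUE(attr(nxt, "absorbing")) || nxt$t > 5) break
      st <- nxt
    }
    st$m1n
  }, numeric(1))
  expected <- n0 * exp(-0.2 * 5)
  se <- sd(remaining) / sqrt(length(remaining))
  expect_lt(abs(mean(remaining) - expected), 3 * se)
})

test_that("Erlang delay chain has mean tau and variance tau^2/n (tracer)", {
  tau <- 8; n <- 10L
  p <- sim_params(km = 0, kp1 = 0, kp7 = 0, tau_m = tau, n_delay = n,
                  gamma_m1 = 1e-12, gamma_m7 = 1e-12, gamma_p1 = 1e-12,
                  gamma_p7 = 1e-12, gamma_p17 = 1e-12, kb = 0, ku = 0)
  set.seed(12)
  transit <- vapply(1:400, function(r) {
    st <- sim_state(p); st$m1_chain[1] <- 1L
    while (st$m1n < 1L) st <- gillespie_step(st, p)
    st$t
  }, numeric(1))
  se_mean <- sd(transit) / sqrt(length(transit))
  expect_lt(abs(mean(transit) - tau), 3 * se_mean)
  # var(s^2) ~ 2 sigma^4 / (N - 1) near normality (Erlang with n = 10)
  se_var <- sqrt(2) * var(transit) / sqrt(length(transit) - 1)
  expect_lt(abs(var(transit) - tau^2 / n), 4 * se_var)
})

test_that("compiled engine matches the bursty birth-death closed form", {
  # feedback off (huge pdcrit), protein machinery off
  # tau = 0: bursts reach the mature pool instantly, the regime in which
  # the compound-Poisson closed forms (mean km*Bmax/gamma, Fano = <B>) hold
  p <- sim_params(km = 0.5, alpha = 0, Bmax = 4, pdcrit = 1e12,
                  tau_m = 0, tau_p = 0,
                  kp1 = 0, kp7 = 0, gamma_m1 = 0.2, gamma_m7 = 0.2,
                  T0 = 60, Tmax = 1200, dt_obs = 4)
  snaps <- simulate_population(p, n_cells = 24L, seed = 21L)
  cell_means <- colMeans(snaps$m1)
  expected_mean <- 0.5 * 4 / 0.2   # km * Bmax / gamma = 10
  se <- sd(cell_means) / sqrt(length(cell_means))
  expect_lt(abs(mean(cell_means) - expected_mean), 3 * se)

  # Fano factor ~ mean burst size for geometric bursts
  cell_fano <- apply(snaps$m1, 2, function(v) var(v) / mean(v))
  se_f <- sd(cell_fano) / sqrt(length(cell_fano))
  expect_lt(abs(mean(cell_fano) - 4), 3 * se_f)
})

test_that("trajectories are seed-deterministic and silent when production is off", {
  p <- fast_params()
  expect_identical(simulate_cell(p, seed = 5L), simulate_cell(p, seed = 5L))
  expect_false(identical(simulate_cell(p, seed = 5L)$m1n,
                         simulate_cell(p, seed = 6L)$m1n))

  off <- sim_params(km = 0, kp1 = 0, kp7 = 0, T0 = 10, Tmax = 50)
  tr <- simulate_cell(off, seed = 1L)
  expect_true(all(tr[c("m1n", "m7n", "p1", "p7", "p17")] == 0))
  expect_equal(tr$time, seq(10, 50, by = off$dt_obs))
  expect_error(sim_params(T0 = 100, Tmax = 100), "Tmax")
})

test_that("default parameters oscillate with a period near 30 minutes", {
  tr <- simulate_cell(sim_params(Tmax = 3000), seed = 2L)
  period <- estimate_period(tr)
  expect_false(is.na(period))
  expect_lt(abs(period - 30), 0.2 * 30)
})

test_that("population snapshots have one entry per cell and dephase over time", {
  p <- sim_params(T0 = 0, Tmax = 300)
  expect_error(simulate_population(p, n_cells = 1L), "at least 2")
  snaps <- simulate_population(p, n_cells = 30L, seed = 3L)
  expect_equal(dim(snaps$m1), c(length(snaps$time), 30L))
  expect_equal(dim(snaps$m7), dim(snaps$m1))
  expect_true(all(snaps$m1 >= 0) && all(snaps$m7 >= 0))

  # from a common initial condition the population mean first swings, then
  # damps toward the cycle average as cells dephase
  pop_mean <- rowMeans(snaps$m1)
  early <- pop_mean[snaps$time <= 100 & snaps$time >= 20]
  late <- pop_mean[snaps$time >= 200]
  expect_gt(sd(early), sd(late))
})

test_that("simulated variability curve separates alpha = 1 from alpha = 0", {
  # identical m1/m7 in every cell: uncorrelated curve is exactly zero
  fake <- structure(list(time = seq(0, 58, by = 2),
                         m1 = matrix(rpois(300, 20) + 1, 30, 10),
                         m7 = NULL, params = sim_params()),
                    class = "population_snapshots")
  fake$m7 <- fake$m1
  cv <- sim_variability_curve(fake)
  expect_equal(cv$mean_uncorrelated, rep(0, 5))

  # independent bursts, no feedback: correlated ~ 0 within 3 SE
  p0 <- sim_params(alpha = 0, pdcrit = 1e12, Bmax = 4, km = 1,
                   kp1 = 0, kp7 = 0, T0 = 60, Tmax = 960, dt_obs = 6)
  s0 <- simulate_population(p0, n_cells = 50L, seed = 8L)
  pts0 <- attr(sim_variability_curve(s0), "points")
  se0 <- sd(pts0$correlated) / sqrt(nrow(pts0))
  expect_lt(abs(mean(pts0$correlated)), 3 * se0)

  # full co-firing produces strictly more correlated variability
  p1 <- sim_params(alpha = 1, pdcrit = 1e12, Bmax = 4, km = 1,
                   kp1 = 0, kp7 = 0, T0 = 60, Tmax = 960, dt_obs = 6)
  s1 <- simulate_population(p1, n_cells = 50L, seed = 9L)
  c0 <- sim_variability_curve(s0); c1 <- sim_variability_curve(s1)
  expect_gt(curve_auc(c1, "correlated"), curve_auc(c0, "correlated"))
})

test_that("deletion mutant halves Bmax and nothing else", {
  p <- sim_params(Bmax = 10)
  m <- deletion_mutant(p)
  expect_equal(m$Bmax, 5)
  expect_equal(deletion_mutant(m)$Bmax, 2.5)
  other <- setdiff(names(p), "Bmax")
  expect_identical(p[other], m[other])
})
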