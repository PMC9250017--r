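#' Parameters of the stochastic her1/her7 clock model
#'
#' A delayed negative-feedback oscillator with bursty transcription. her1
#' and her7 mRNAs are produced in bursts: each gene bursts alone at rate
#' `km * (1 - alpha)` and both co-fire at rate `km * alpha`, so the total
#' burst frequency per gene is `km` for every `alpha`. The Her1-Her7
#' heterodimer p17 represses the mean burst size through a Hill function,
#' `<B> = Bmax / (1 + (p17 / pdcrit)^hill_n)`; burst sizes are geometric.
#' Transcriptional and translational delays `tau_m`, `tau_p` are realized
#' as Erlang chains of `n_delay` sequential first-order steps with per-step
#' rate `n_delay / tau` (mean delay tau, variance tau^2 / n_delay).
#' Translation reads mature mRNA; monomers dimerize reversibly (`kb`,
#' `ku`); mature species degrade at the `gamma_*` rates (intermediates do
#' not degrade by default).
#'
#' Default rates honor the biology of the zebrafish segmentation clock:
#' mRNA and protein half-lives of 3-5 min (`gamma = log(2)/4` per minute),
#' an oscillation period near 30 min, and a cycle-averaged mean total
#' mature mRNA (m1n + m7n) near 49 molecules.
#'
#' @param km total burst frequency per gene (1/min).
#' @param alpha correlated-burst fraction in `[0, 1]`.
#' @param Bmax maximum mean burst size (molecules).
#' @param pdcrit heterodimer count at half-maximal repression.
#' @param n_delay intermediate steps per delay chain (default 10).
#' @param tau_m,tau_p transcriptional and translational delays (min).
#' @param kp1,kp7 translation rates (1/min per mRNA).
#' @param gamma_m1,gamma_m7,gamma_p1,gamma_p7,gamma_p17 degradation rates
#'   (1/min) of the mature species.
#' @param kb dimerization rate (1/(molecule min)); `ku` dissociation rate
#'   (1/min; restores one Her1 and one Her7 monomer).
#' @param hill_n Hill exponent (default 2).
#' @param T0 burn-in (min) before observations start (default 10 periods,
#'   300 min).
#' @param Tmax end time (min).
#' @param dt_obs observation interval (min), well below the ~30 min period.
#' @param shared_burst_size if `TRUE`, a co-firing event draws one burst
#'   size shared by both genes instead of two independent draws.
#' @param degrade_intermediates if `TRUE`, delay-chain intermediates also
#'   degrade at their species' gamma.
#' @return A `sim_params` list.
#' @export
sim_params <- function(km = 1.5, alpha = 0.85, Bmax = 12, pdcrit = 250,
                       n_delay = 10L, tau_m = 5, tau_p = 1,
                       kp1 = 4.5, kp7 = 4.5,
                       gamma_m1 = log(2) / 4, gamma_m7 = log(2) / 4,
                       gamma_p1 = log(2) / 4, gamma_p7 = log(2) / 4,
                       gamma_p17 = log(2) / 4,
                       kb = 0.01, ku = 0.1, hill_n = 2L,
                       T0 = 300, Tmax = 700, dt_obs = 2,
                       shared_burst_size = FALSE,
                       degrade_intermediates = FALSE) {
  p <- list(km = km, alpha = alpha, Bmax = Bmax, pdcrit = pdcrit,
            n_delay = as.integer(n_delay), tau_m = tau_m, tau_p = tau_p,
            kp1 = kp1, kp7 = kp7,
            gamma_m1 = gamma_m1, gamma_m7 = gamma_m7,
            gamma_p1 = gamma_p1, gamma_p7 = gamma_p7, gamma_p17 = gamma_p17,
            kb = kb, ku = ku, hill_n = as.integer(hill_n),
            T0 = T0, Tmax = Tmax, dt_obs = dt_obs,
            shared_burst_size = isTRUE(shared_burst_size),
            degrade_intermediates = isTRUE(degrade_intermediates))
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  rates <- c("km", "Bmax", "tau_m", "tau_p", "kp1", "kp7", "kb", "ku")
  for (nm in rates) {
    if (p[[nm]] < 0) stop(nm, " must be >= 0", call. = FALSE)
  }
  for (nm in c("gamma_m1", "gamma_m7", "gamma_p1", "gamma_p7", "gamma_p17")) {
    if (p[[nm]] <= 0) stop(nm, " must be > 0", call. = FALSE)
  }
  if (p$alpha < 0 || p$alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  if (p$pdcrit <= 0) stop("pdcrit must be > 0", call. = FALSE)
  if (p$n_delay < 1L) stop("n_delay must be >= 1", call. = FALSE)
  if (p$Tmax <= p$T0) stop("Tmax must exceed T0", call. = FALSE)
  if (p$dt_obs <= 0) stop("dt_obs must be > 0", call. = FALSE)
  invisible(p)
}

#' Hill repression of burst size by the heterodimer
#'
#' `f(p17) = 1 / (1 + (p17 / pdcrit)^hill_n)`: 1 with no heterodimer, 1/2
#' at `p17 = pdcrit`.
#'
#' @param p17 heterodimer count (>= 0, vectorized).
#' @param pdcrit half-repression heterodimer count (> 0).
#' @param hill_n Hill exponent (default 2).
#' @return Repression factor in `(0, 1]`.
#' @export
hill_repression <- function(p17, pdcrit, hill_n = 2L) {
  if (pdcrit <= 0) stop("pdcrit must be > 0", call. = FALSE)
  1 / (1 + (p17 / pdcrit)^hill_n)
}

#' Mean burst size under feedback
#'
#' `<B> = Bmax * f(p17)`.
#'
#' @param p17 heterodimer count.
#' @param params a [sim_params()].
#' @return Mean burst size (molecules).
#' @export
mean_burst_size <- function(p17, params) {
  params$Bmax * hill_repression(p17, params$pdcrit, params$hill_n)
}

#' Draw a transcriptional burst size
#'
#' For mean burst size `<B> >= 1`, sizes are geometric on \{1, 2, ...\}
#' with success probability `1 / <B>`. For `<B> < 1` the geometric
#' parameterization is unavailable, so a Bernoulli(`<B>`) draw on \{0, 1\}
#' preserves the mean continuously.
#'
#' @param mean_b mean burst size (>= 0).
#' @param n number of draws.
#' @return Integer vector of burst sizes.
#' @export
draw_burst_size <- function(mean_b, n = 1L) {
  if (mean_b < 0) stop("mean burst size must be >= 0", call. = FALSE)
  if (mean_b < 1) {
    as.integer(runif(n) < mean_b)
  } else {
    1L + rgeom(n, prob = 1 / mean_b)
  }
}

#' Deletion-mutant parameterization
#'
#' The chromosomal deletion removes one copy of the her1-her7 locus; with
#' co-firing of the homologous alleles this halves the maximum burst size,
#' leaving every other parameter unchanged.
#'
#' @param params a [sim_params()].
#' @return A `sim_params` with `Bmax` halved.
#' @export
deletion_mutant <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  params$Bmax <- params$Bmax / 2
  params
}

#' Initial state of the clock model
#'
#' All species start at zero: delay-chain intermediates (length `n_delay`
#' each), mature mRNAs `m1n`/`m7n`, monomers `p1`/`p7`, heterodimer `p17`.
#'
#' @param params a [sim_params()].
#' @return A `sim_state` list with a time field `t = 0`.
#' @export
sim_state <- function(params) {
  n <- params$n_delay
  structure(list(
    m1_chain = integer(n), m7_chain = integer(n),
    p1_chain = integer(n), p7_chain = integer(n),
    m1n = 0L, m7n = 0L, p1 = 0L, p7 = 0L, p17 = 0L, t = 0),
    class = "sim_state")
}

#' Reaction propensities of the clock model
#'
#' One rate per reaction channel: her1-only, her7-only and joint bursts;
#' per-step delay-chain conversions at `n_delay / tau` per molecule;
#' translation of mature mRNAs; degradation of mature species;
#' dimerization and dissociation.
#'
#' @param state a [sim_state()].
#' @param params a [sim_params()].
#' @return Named numeric vector of propensities (1/min).
#' @export
propensities <- function(state, params) {
  p <- params; s <- state
  n <- p$n_delay
  # zero delay: bursts and translation bypass the (empty) chains entirely
  rate_m <- if (p$tau_m > 0) n / p$tau_m else 0
  rate_p <- if (p$tau_p > 0) n / p$tau_p else 0
  a <- c(
    burst1 = p$km * (1 - p$alpha),
    burst7 = p$km * (1 - p$alpha),
    burst17 = p$km * p$alpha,
    stats::setNames(rate_m * s$m1_chain, paste0("m1_step", seq_len(n))),
    stats::setNames(rate_m * s$m7_chain, paste0("m7_step", seq_len(n))),
    translate1 = p$kp1 * s$m1n,
    translate7 = p$kp7 * s$m7n,
    stats::setNames(rate_p * s$p1_chain, paste0("p1_step", seq_len(n))),
    stats::setNames(rate_p * s$p7_chain, paste0("p7_step", seq_len(n))),
    deg_m1 = p$gamma_m1 * s$m1n,
    deg_m7 = p$gamma_m7 * s$m7n,
    deg_p1 = p$gamma_p1 * s$p1,
    deg_p7 = p$gamma_p7 * s$p7,
    deg_p17 = p$gamma_p17 * s$p17,
    dimerize = p$kb * s$p1 * s$p7,
    dissociate = p$ku * s$p17)
  if (p$degrade_intermediates) {
    a <- c(a,
      stats::setNames(p$gamma_m1 * s$m1_chain, paste0("deg_m1_int", seq_len(n))),
      stats::setNames(p$gamma_m7 * s$m7_chain, paste0("deg_m7_int", seq_len(n))),
      stats::setNames(p$gamma_p1 * s$p1_chain, paste0("deg_p1_int", seq_len(n))),
      stats::setNames(p$gamma_p7 * s$p7_chain, paste0("deg_p7_int", seq_len(n))))
  }
  a
}

# apply one named reaction channel to a state (reference implementation)
apply_channel <- function(state, params, channel) {
  s <- state; n <- params$n_delay
  push_burst <- function(s, gene) {
    b <- draw_burst_size(mean_burst_size(s$p17, params))
    chain <- paste0(gene, "_chain")
    mature <- paste0(gene, "n")
    if (params$tau_m > 0) s[[chain]][1] <- s[[chain]][1] + b
    else s[[mature]] <- s[[mature]] + b
    s
  }
  step_chain <- function(s, chain, mature, i) {
    s[[chain]][i] <- s[[chain]][i] - 1L
    if (i < n) s[[chain]][i + 1] <- s[[chain]][i + 1] + 1L
    else s[[mature]] <- s[[mature]] + 1L
    s
  }
  if (channel == "burst1") s <- push_burst(s, "m1")
  else if (channel == "burst7") s <- push_burst(s, "m7")
  else if (channel == "burst17") {
    if (params$shared_burst_size) {
      b <- draw_burst_size(mean_burst_size(s$p17, params))
      if (params$tau_m > 0) {
        s$m1_chain[1] <- s$m1_chain[1] + b; s$m7_chain[1] <- s$m7_chain[1] + b
      } else { s$m1n <- s$m1n + b; s$m7n <- s$m7n + b }
    } else {
      s <- push_burst(s, "m1"); s <- push_burst(s, "m7")
    }
  }
  else if (grepl("^m1_step", channel))
    s <- step_chain(s, "m1_chain", "m1n", as.integer(sub("m1_step", "", channel)))
  else if (grepl("^m7_step", channel))
    s <- step_chain(s, "m7_chain", "m7n", as.integer(sub("m7_step", "", channel)))
  else if (channel == "translate1") {
    if (params$tau_p > 0) s$p1_chain[1] <- s$p1_chain[1] + 1L
    else s$p1 <- s$p1 + 1L
  }
  else if (channel == "translate7") {
    if (params$tau_p > 0) s$p7_chain[1] <- s$p7_chain[1] + 1L
    else s$p7 <- s$p7 + 1L
  }
  else if (grepl("^p1_step", channel))
    s <- step_chain(s, "p1_chain", "p1", as.integer(sub("p1_step", "", channel)))
  else if (grepl("^p7_step", channel))
    s <- step_chain(s, "p7_chain", "p7", as.integer(sub("p7_step", "", channel)))
  else if (channel == "deg_m1") s$m1n <- s$m1n - 1L
  else if (channel == "deg_m7") s$m7n <- s$m7n - 1L
  else if (channel == "deg_p1") s$p1 <- s$p1 - 1L
  else if (channel == "deg_p7") s$p7 <- s$p7 - 1L
  else if (channel == "deg_p17") s$p17 <- s$p17 - 1L
  else if (channel == "dimerize") {
    s$p1 <- s$p1 - 1L; s$p7 <- s$p7 - 1L; s$p17 <- s$p17 + 1L
  }
  else if (channel == "dissociate") {
    s$p17 <- s$p17 - 1L; s$p1 <- s$p1 + 1L; s$p7 <- s$p7 + 1L
  }
  else if (grepl("^deg_(m1|m7|p1|p7)_int", channel)) {
    gene <- sub("^deg_([mp][17])_int[0-9]+$", "\\1", channel)
    i <- as.integer(sub("^deg_[mp][17]_int", "", channel))
    s[[paste0(gene, "_chain")]][i] <- s[[paste0(gene, "_chain")]][i] - 1L
  }
  else stop("unknown channel: ", channel)
  s
}

#' One exact (direct-method) Gillespie step
#'
#' Reference implementation in plain R: exponential waiting time at the
#' total propensity, channel chosen proportionally, state updated. The
#' compiled engine used by [simulate_cell()] implements the same system;
#' this function exists for inspection, tracer experiments and tests at
#' small scale.
#'
#' @param state a [sim_state()].
#' @param params a [sim_params()].
#' @return The updated state (time advanced). If every propensity is zero
#'   the state is returned unchanged with attribute `absorbing = TRUE`.
#' @export
gillespie_step <- function(state, params) {
  a <- propensities(state, params)
  total <- sum(a)
  if (total <= 0) {
    attr(state, "absorbing") <- TRUE
    return(state)
  }
  state$t <- state$t + stats::rexp(1, rate = total)
  channel <- names(a)[sample.int(length(a), 1L, prob = a)]
  state <- apply_channel(state, params, channel)
  stopifnot(all(unlist(state[c("m1_chain", "m7_chain", "p1_chain",
                               "p7_chain", "m1n", "m7n", "p1", "p7",
                               "p17")]) >= 0))
  state
}
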