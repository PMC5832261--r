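# Beat-to-beat map surrogate: exponential restitution plus an exponentially
# relaxing memory store. Produces APD/DI/CL trains in milliseconds without
# ODE integration, so the metric and stability layers can be exercised in
# unit tests. Not a quantitative stand-in for the ionic model; its defaults
# are tuned to the same operating point (APD ~230 ms at CL 350 ms with a
# restitution slope ~0.45) so metric behaviour is realistic.

#' Surrogate map parameters
#'
#' The surrogate iterates
#' \deqn{APD_{n+1} = APD_{max} - a e^{-DI_n / \tau_r} - \gamma M_n + \epsilon_n}
#' with memory
#' \deqn{M_{n+1} = M_n e^{-CL_n / \tau_m} + (1 - e^{-CL_n / \tau_m}) APD_n / APD_{max}.}
#' With `gamma = 0` the map is memoryless: APD is a pure function of the
#' preceding DI, so no hysteresis can appear in the (DI, APD) or (CL, APD)
#' spaces. With `gamma > 0` the accumulated-memory term lags the pacing
#' history and vs_CL hysteresis emerges under fast periodic pacing --
#' the structural mechanism the package quantifies.
#'
#' @param APD_max maximal APD (ms).
#' @param a restitution amplitude (ms).
#' @param tau_r restitution time constant (ms).
#' @param gamma memory gain (ms per unit normalized memory; 0 = memoryless).
#' @param tau_m memory relaxation time constant (ms).
#' @param noise_sd Gaussian APD noise sd (ms).
#' @return list of class `surrogate_params`.
#' @export
surrogate_params <- function(APD_max = 320, a = 165, tau_r = 200,
                             gamma = 40, tau_m = 1500, noise_sd = 0) {
  stopifnot(APD_max > 0, a > 0, tau_r > 0, gamma >= 0, tau_m > 0,
            noise_sd >= 0)
  structure(list(APD_max = APD_max, a = a, tau_r = tau_r, gamma = gamma,
                 tau_m = tau_m, noise_sd = noise_sd),
            class = "surrogate_params")
}

#' Fixed point of the memoryless surrogate map at a constant CL
#'
#' Solves `APD = APD_max - a exp(-(CL - APD)/tau_r)` by bisection (the
#' gamma = 0 steady state), used as an independent check of the iterated
#' map.
#'
#' @param params a `surrogate_params`.
#' @param CL constant cycle length (ms).
#' @return the fixed-point APD (ms).
#' @export
surrogate_fixed_point <- function(params, CL) {
  f <- function(apd) params$APD_max - params$a * exp(-(CL - apd) / params$tau_r) - apd
  lo <- 1; hi <- min(params$APD_max, CL - 1e-6)
  if (f(hi) > 0) return(hi)
  while (hi - lo > 1e-10) {
    mid <- (hi + lo) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (hi + lo) / 2
}

#' Iterate the surrogate map over a pacing schedule
#'
#' Returns the same `ap_train` shape as [run_train()] (minus upstroke times
#' and snapshots), so every metric in the package runs unchanged on
#' surrogate data. A beat whose DI would be non-positive is flagged as a
#' capture failure (APD `NA`) and the memory store carries over.
#'
#' @param params a `surrogate_params`.
#' @param schedule a `pacing_schedule`.
#' @param seed integer seed for the APD noise.
#' @param APD0,M0 initial APD (default: memoryless fixed point at the first
#'   CL) and memory load (default 0.7, a paced steady-state level).
#' @return an `ap_train` (with `final_state = NULL`-like placeholder state).
#' @export
surrogate_train <- function(params, schedule, seed = 1, APD0 = NULL,
                            M0 = 0.7) {
  stopifnot(inherits(params, "surrogate_params"),
            inherits(schedule, "pacing_schedule"))
  n <- nrow(schedule)
  # cycle initiated by beat k (same bookkeeping as the ODE engine)
  cl <- c(schedule$CL_ms[-1], schedule$CL_ms[n])
  enabled <- schedule$stim_enabled
  eps <- if (params$noise_sd > 0)
    withr::with_seed(seed, stats::rnorm(n, 0, params$noise_sd))
  else rep(0, n)

  apd <- rep(NA_real_, n)
  captured <- logical(n)
  M <- M0
  apd_prev <- APD0 %||% surrogate_fixed_point(params, schedule$CL_ms[1])
  di_prev <- max(schedule$CL_ms[1] - apd_prev, 1)
  for (k in seq_len(n)) {
    if (enabled[k]) {
      a_k <- params$APD_max - params$a * exp(-di_prev / params$tau_r) -
        params$gamma * M + eps[k]
      if (a_k <= 0) stop("surrogate produced non-positive APD; adjust parameters")
      apd[k] <- a_k
      captured[k] <- TRUE
    }
    # memory relaxes toward the normalized APD of the beat just delivered
    # (an undelivered beat contributes nothing and the store decays)
    lam <- exp(-cl[k] / params$tau_m)
    target <- if (enabled[k]) apd[k] / params$APD_max else 0
    M <- M * lam + (1 - lam) * target
    di_prev <- if (enabled[k]) cl[k] - apd[k] else di_prev + cl[k]
    if (enabled[k] && di_prev <= 0) {
      captured[k] <- FALSE  # encroached on refractoriness: flag the beat
      apd[k] <- NA_real_
      di_prev <- 1
    }
    if (enabled[k] && captured[k]) apd_prev <- apd[k]
  }
  beats <- data.frame(
    index = seq_len(n), CL_ms = cl, APD_ms = apd, DI_ms = cl - apd,
    upstroke_ms = schedule$stim_time_ms, captured = captured,
    merged = FALSE, stim_enabled = enabled)
  attr(beats, "final_state") <- NULL
  attr(beats, "states") <- NULL
  attr(beats, "meta") <- c(schedule_meta(schedule), list(surrogate = TRUE))
  attr(beats, "stim") <- NULL
  attr(beats, "dt") <- NA_real_
  class(beats) <- c("ap_train", "data.frame")
  beats
}

#' Canned surrogate fixtures
#'
#' Deterministic bundle of APD trains covering the cases the metric and
#' stability layers must handle: constant pacing, slow and fast periodic
#' pacing with and without memory, random pacing, alternating pacing, and a
#' constructed alternans series.
#'
#' @param n_beats beats per train (default 300).
#' @param CL_star,clv central CL and variability (ms).
#' @param seed seed for the random train.
#' @return named list of `ap_train` objects (plus `alternans_apd`, a plain
#'   numeric alternating APD series).
#' @export
fixture_suite <- function(n_beats = 300, CL_star = 350, clv = 35, seed = 42) {
  mem <- surrogate_params()
  nomem <- surrogate_params(gamma = 0)
  list(
    constant = surrogate_train(mem, constant_schedule(CL_star, n_beats)),
    periodic_fast = surrogate_train(mem, periodic_schedule(CL_star, clv, 2.4, n_beats)),
    periodic_slow = surrogate_train(mem, periodic_schedule(CL_star, clv, 0.1, n_beats)),
    periodic_fast_nomem = surrogate_train(nomem, periodic_schedule(CL_star, clv, 2.4, n_beats)),
    random = surrogate_train(mem, random_schedule(CL_star, clv, n_beats, seed)),
    alternating = surrogate_train(mem, alternating_schedule(CL_star, clv, n_beats)),
    alternans_apd = rep(c(200, 260), length.out = n_beats)
  )
}
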