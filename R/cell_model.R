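#' @useDynLib apmem, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# canonical state order, mirrored in src/tp06.cpp
TP06_STATE_NAMES <- c(
  "V", "Xr1", "Xr2", "Xs", "m", "h", "j", "d", "f", "f2", "fCass",
  "s", "r", "Ca_i", "Ca_SR", "Ca_ss", "Rq", "Na_i", "K_i"
)
TP06_GATE_NAMES <- c("Xr1", "Xr2", "Xs", "m", "h", "j", "d", "f", "f2",
                     "fCass", "s", "r", "Rq")
TP06_CONC_NAMES <- c("Ca_i", "Ca_SR", "Ca_ss", "Na_i", "K_i")

# conductance field addressed by each current name
TP06_CONDUCTANCE_MAP <- c(
  ICaL = "g_CaL", IKr = "g_Kr", IKs = "g_Ks", INa = "g_Na",
  Ito = "g_to", IK1 = "g_K1", IpK = "g_pK", IpCa = "g_pCa",
  IbNa = "g_bNa", IbCa = "g_bCa"
)

#' Parameter set of the TP06 human ventricular myocyte model
#'
#' Returns the full constant set of the ten Tusscher-Panfilov (2006) human
#' ventricular action-potential model (epicardial formulation), optionally
#' with maximal conductances rescaled. Conductance units follow the model's
#' published formulation (nS/pF; the L-type permeability in cm^3 uF^-1 s^-1),
#' concentrations in mM, time in ms, voltage in mV, currents in pA/pF.
#'
#' @param scale named numeric vector of multiplicative factors applied to
#'   maximal conductances, named by current: `"ICaL"`, `"IKr"`, `"IKs"`,
#'   `"INa"`, `"Ito"`, `"IK1"`, `"IpK"`, `"IpCa"`, `"IbNa"`, `"IbCa"`.
#' @return an object of class `tp06_params`: a named list of model constants
#'   with the applied scale factors recorded in `attr(, "scale_factors")`.
#' @examples
#' p <- tp06_params()
#' p_lqt1 <- tp06_params(scale = c(IKs = 0.4))  # 60% I_Ks loss
#' @export
tp06_params <- function(scale = NULL) {
  p <- list(
    # physical constants
    R = 8314.472, T = 310, F = 96485.3415,
    Cm = 0.185, V_c = 0.016404, V_sr = 0.001094, V_ss = 0.00005468,
    # external ion concentrations (mM)
    K_o = 5.4, Na_o = 140, Ca_o = 2,
    # maximal conductances (epicardial)
    g_Na = 14.838, g_K1 = 5.405, g_to = 0.294, g_Kr = 0.153, g_Ks = 0.392,
    g_CaL = 3.98e-5, g_bNa = 0.00029, g_bCa = 0.000592,
    g_pK = 0.0146, g_pCa = 0.1238, K_pCa = 0.0005,
    # exchangers / pumps
    p_KNa = 0.03, P_NaK = 2.724, K_mK = 1, K_mNa = 40,
    k_NaCa = 1000, K_mNai = 87.5, K_mCa = 1.38, k_sat = 0.1,
    alpha_ncx = 2.5, gamma_ncx = 0.35,
    # SR calcium cycling
    V_maxup = 0.006375, K_up = 0.00025, V_rel = 0.102,
    k1_prime = 0.15, k2_prime = 0.045, k3 = 0.06, k4 = 0.005,
    EC = 1.5, max_sr = 2.5, min_sr = 1, V_leak = 0.00036, V_xfer = 0.0038,
    # buffering
    Buf_c = 0.2, K_bufc = 0.001, Buf_sr = 10, K_bufsr = 0.3,
    Buf_ss = 0.4, K_bufss = 0.00025
  )
  class(p) <- "tp06_params"
  attr(p, "scale_factors") <- c(
    ICaL = 1, IKr = 1, IKs = 1, INa = 1, Ito = 1, IK1 = 1,
    IpK = 1, IpCa = 1, IbNa = 1, IbCa = 1
  )
  if (!is.null(scale)) p <- scale_conductances(p, scale)
  p
}

#' Rescale maximal conductances
#'
#' Multiplies the maximal conductance of the named currents; all other
#' parameters are untouched. Scaling is multiplicative, so applying factors
#' `a` then `b` equals applying `a * b`.
#'
#' @param params a `tp06_params` object.
#' @param factors named numeric vector of positive multipliers (names as in
#'   [tp06_params()]).
#' @return a new `tp06_params` object.
#' @export
scale_conductances <- function(params, factors) {
  stopifnot(inherits(params, "tp06_params"))
  if (length(factors) == 0) return(params)
  if (is.null(names(factors)) || any(!nzchar(names(factors))))
    stop("conductance factors must be named by current")
  unknown <- setdiff(names(factors), names(TP06_CONDUCTANCE_MAP))
  if (length(unknown))
    stop("unknown current name(s): ", paste(unknown, collapse = ", "))
  if (any(!is.finite(factors)) || any(factors <= 0))
    stop("conductance factors must be positive and finite")
  sf <- attr(params, "scale_factors")
  for (nm in names(factors)) {
    field <- TP06_CONDUCTANCE_MAP[[nm]]
    params[[field]] <- params[[field]] * factors[[nm]]
    sf[[nm]] <- sf[[nm]] * factors[[nm]]
  }
  attr(params, "scale_factors") <- sf
  params
}

#' Default initial state of the TP06 model
#'
#' The published resting state of the epicardial cell variant. A short
#' quiescent settle (see [settle_to_rest()]) brings it to the model's exact
#' fixed point under the running parameter set.
#'
#' @return named numeric vector of length 19 (class `tp06_state`); see the
#'   package vignette for the state roster and units.
#' @export
tp06_initial_state <- function() {
  y <- c(
    V = -85.23, Xr1 = 0.00621, Xr2 = 0.4712, Xs = 0.0095,
    m = 0.00172, h = 0.7444, j = 0.7045,
    d = 3.373e-5, f = 0.7888, f2 = 0.9755, fCass = 0.9953,
    s = 0.999998, r = 2.42e-8,
    Ca_i = 0.000126, Ca_SR = 3.64, Ca_ss = 0.00036, Rq = 0.9073,
    Na_i = 8.604, K_i = 136.89
  )
  stopifnot(identical(names(y), TP06_STATE_NAMES))
  class(y) <- c("tp06_state", "numeric")
  y
}

#' Validate a TP06 state vector
#'
#' Checks length (19), finiteness, gate bounds \code{[0, 1]} and positive
#' concentrations.
#' @param state numeric vector of length 19 (named or in canonical order).
#' @return the state, invisibly, named in canonical order.
#' @export
validate_state <- function(state) {
  state <- as_tp06_state(state)
  if (any(!is.finite(state))) stop("non-finite state entries")
  g <- state[TP06_GATE_NAMES]
  if (any(g < 0 | g > 1))
    stop("gating variables outside [0, 1]: ",
         paste(TP06_GATE_NAMES[g < 0 | g > 1], collapse = ", "))
  conc <- state[TP06_CONC_NAMES]
  if (any(conc <= 0))
    stop("non-positive concentrations: ",
         paste(TP06_CONC_NAMES[conc <= 0], collapse = ", "))
  invisible(state)
}

#' Coerce a numeric vector to a canonical TP06 state
#'
#' Accepts a length-19 vector (named in any order, or unnamed in canonical
#' order) and returns it named and ordered as documented in
#' [tp06_initial_state()].
#' @param state numeric vector of length 19.
#' @return a `tp06_state`.
#' @export
as_tp06_state <- function(state) {
  state <- unclass(state)
  if (length(state) != 19) stop("state vector must have 19 entries")
  if (!is.null(names(state)) && all(TP06_STATE_NAMES %in% names(state)))
    state <- state[TP06_STATE_NAMES]
  names(state) <- TP06_STATE_NAMES
  structure(state, class = c("tp06_state", "numeric"))
}

#' Time-derivatives of the TP06 state
#'
#' Evaluates the model right-hand side at one state. The signature is
#' compatible with `deSolve` solvers when called as
#' `function(t, y, parms) list(tp06_derivatives(y, t, parms))`.
#'
#' @param state numeric vector of length 19.
#' @param t time (ms); the autonomous equations ignore it, it is accepted for
#'   solver compatibility.
#' @param params a `tp06_params` object.
#' @param i_stim stimulus current density (pA/pF, positive magnitude is
#'   passed as a depolarizing current).
#' @param clamps optional list of `clamped_current` objects
#'   (see [fit_current_clamp()]).
#' @param time_since_upstroke ms elapsed since the last upstroke; a clamp is
#'   applied only when this exceeds its blanking window (default `Inf`:
#'   all supplied clamps active).
#' @return named numeric vector of 19 derivatives (per ms).
#' @export
tp06_derivatives <- function(state, t = 0, params = tp06_params(),
                             i_stim = 0, clamps = NULL,
                             time_since_upstroke = Inf) {
  state <- as_tp06_state(state)
  cl <- clamps %||% list()
  active <- vapply(cl, function(c) time_since_upstroke > c$blank_ms, logical(1))
  dy <- tp06_rhs_cpp(as.numeric(state), unclass(params), -abs(i_stim),
                     lapply(cl, unclass), active)
  names(dy) <- TP06_STATE_NAMES
  dy
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Native membrane currents at one state
#'
#' Returns the three plateau currents the analysis manipulates (I_CaL, I_Kr,
#' I_Ks; pA/pF) and dV/dt at the given state, without stimulus.
#' @inheritParams tp06_derivatives
#' @return named numeric vector (`ICaL`, `IKr`, `IKs`, `dVdt`).
#' @export
tp06_currents <- function(state, params = tp06_params()) {
  tp06_currents_cpp(as.numeric(as_tp06_state(state)), unclass(params))
}

#' Relax the model to its quiescent fixed point
#'
#' Integrates without stimulation until the state stops moving.
#'
#' @param params a `tp06_params` object.
#' @param state starting state (default the published resting state).
#' @param duration_ms quiescent integration time (default 10000 ms).
#' @param dt integration step (ms).
#' @return the settled state (class `tp06_state`).
#' @export
settle_to_rest <- function(params = tp06_params(), state = tp06_initial_state(),
                           duration_ms = 10000, dt = 0.02) {
  res <- tp06_run_cpp(as.numeric(as_tp06_state(state)), unclass(params),
                      numeric(0), logical(0), duration_ms, 0, 3, dt,
                      list(), FALSE, 1, FALSE)
  as_tp06_state(res$final_state)
}

#' Diastolic stimulus-current threshold
#'
#' Minimal amplitude of a square current pulse that elicits a full action
#' potential (V_m above 0 mV within 20 ms of onset), found by bisection to
#' 1% relative width. Protocols stimulate at a multiple of this threshold
#' (1.5x by default elsewhere in the package).
#'
#' @param state resting or end-diastolic state to stimulate from.
#' @param params a `tp06_params` object.
#' @param duration pulse width (ms, default 3).
#' @param upper upper search bound (pA/pF).
#' @param rel_tol relative bisection width (default 0.01).
#' @param dt integration step (ms).
#' @return threshold amplitude (pA/pF).
#' @export
find_threshold <- function(state, params = tp06_params(), duration = 3,
                           upper = 200, rel_tol = 0.01, dt = 0.02) {
  state <- as.numeric(as_tp06_state(state))
  elicits <- function(amp) {
    r <- tp06_run_cpp(state, unclass(params), 0, TRUE, 25, amp, duration, dt,
                      list(), FALSE, 1, FALSE)
    isTRUE(r$captured[1])
  }
  lo <- 0
  hi <- upper
  if (!elicits(hi)) stop("no capture at the upper search bound (", upper, " pA/pF)")
  while ((hi - lo) > rel_tol * hi) {
    mid <- (hi + lo) / 2
    if (elicits(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Stimulus specification
#'
#' Bundles pulse duration and amplitude. When `threshold` is missing it is
#' measured from the supplied state by [find_threshold()].
#'
#' @param params a `tp06_params` object.
#' @param state end-diastolic state used to measure the threshold.
#' @param duration pulse width (ms, default 3).
#' @param amplitude_factor multiple of threshold (default 1.5).
#' @param threshold known threshold amplitude (pA/pF), skips the search.
#' @return list with `duration`, `amplitude_factor`, `threshold_amplitude`,
#'   `amplitude` (class `stimulus_spec`).
#' @export
stimulus_spec <- function(params = tp06_params(), state = NULL, duration = 3,
                          amplitude_factor = 1.5, threshold = NULL) {
  stopifnot(duration > 0, amplitude_factor >= 1)
  if (is.null(threshold)) {
    if (is.null(state)) state <- settle_to_rest(params, duration_ms = 2000)
    threshold <- find_threshold(state, params, duration)
  }
  structure(list(duration = duration, amplitude_factor = amplitude_factor,
                 threshold_amplitude = threshold,
                 amplitude = amplitude_factor * threshold),
            class = "stimulus_spec")
}

#' Remove the time-dependence of a plateau current
#'
#' Fits the current-voltage trajectory of one current (I_CaL, I_Kr or I_Ks)
#' recorded during a steady-state action potential with a polynomial in V_m,
#' excluding the first `blank_ms` after the upstroke. Simulations run with
#' the returned clamp replace the gated current by this voltage-only function
#' (held at its boundary value outside the fitted voltage range), which
#' freezes the current's kinetic memory while preserving its mean
#' contribution to the action potential.
#'
#' The lowest polynomial order in `orders` whose fit RMSE is below
#' `rmse_tol` (as a fraction of the current's peak-to-peak range) is chosen.
#' If none reaches it, behaviour follows `tol_action`: `"error"` aborts,
#' `"best"` keeps the best-fitting order and records its RMSE.
#'
#' @param params a `tp06_params` object.
#' @param current one of `"ICaL"`, `"IKr"`, `"IKs"`.
#' @param reference_CL conditioning cycle length (ms, default 350).
#' @param n_cond conditioning beats before the fitted beat (default 300).
#' @param state optional pre-conditioned end-diastolic state at
#'   `reference_CL`; skips conditioning.
#' @param stim a `stimulus_spec` (made on demand when `NULL`).
#' @param blank_ms blanking window after the upstroke (ms, default 9).
#' @param orders candidate polynomial orders (default 3:12).
#' @param rmse_tol RMSE tolerance, fraction of peak-to-peak current.
#' @param tol_action `"error"` or `"best"` when the tolerance is unreachable.
#' @param dt integration step (ms).
#' @return object of class `clamped_current`: list with `current`,
#'   `coefficients` (low to high degree), `fit_order`, `v_range`, `blank_ms`,
#'   `reference_CL`, `rmse`, `rmse_tol_abs`.
#' @export
fit_current_clamp <- function(params = tp06_params(),
                              current = c("ICaL", "IKr", "IKs"),
                              reference_CL = 350, n_cond = 300, state = NULL,
                              stim = NULL, blank_ms = 9, orders = 3:12,
                              rmse_tol = 0.02, tol_action = c("error", "best"),
                              dt = 0.02) {
  current <- match.arg(current)
  tol_action <- match.arg(tol_action)
  if (is.null(state)) {
    tr <- run_train(params, constant_schedule(reference_CL, n_cond),
                    stim = stim, dt = dt)
    state <- final_state(tr)
    if (is.null(stim)) stim <- attr(tr, "stim")
  }
  if (is.null(stim)) stim <- stimulus_spec(params, state)

  # one clamped-free beat at the reference CL, sampled densely
  run <- tp06_run_cpp(as.numeric(as_tp06_state(state)), unclass(params),
                      0, TRUE, reference_CL, stim$amplitude, stim$duration,
                      dt, list(), TRUE, 0.1, FALSE)
  if (!isTRUE(run$captured[1]))
    stop("reference beat not captured; cannot fit clamp")
  tr <- run$trace
  colnames(tr) <- c("t", "V", "dVdt", "ICaL", "IKr", "IKs")
  ups <- run$upstroke_ms[1]
  keep <- which(tr[, "t"] > ups + blank_ms)
  # fit on the monotone repolarization limb (from the post-blanking voltage
  # maximum through diastole): there V(t) is single-valued in V, so the
  # current-voltage relation is a function; the early-plateau branch, where
  # the dome still rises, is the multivalued part the blanking policy aims
  # to exclude and late repolarization is what the clamp must preserve
  keep <- keep[seq(which.max(tr[keep, "V"]), length(keep))]
  v <- tr[keep, "V"]
  i <- tr[keep, current]
  ptp <- diff(range(i))
  tol_abs <- rmse_tol * ptp

  # fit in a centered/scaled variable: raw powers of V up to order 12 are
  # numerically degenerate over a ~120 mV range
  vc <- mean(range(v))
  vs <- diff(range(v)) / 2
  u <- (v - vc) / vs

  best <- NULL
  for (ord in sort(orders)) {
    fit <- stats::lm.fit(outer(u, 0:ord, "^"), i)
    rmse <- sqrt(mean(fit$residuals^2))
    if (is.null(best) || rmse < best$rmse)
      best <- list(order = ord, coef = unname(fit$coefficients), rmse = rmse)
    if (rmse <= tol_abs) break
  }
  if (best$rmse > tol_abs && tol_action == "error")
    stop(sprintf("clamp fit for %s did not reach RMSE tolerance (best %.4g > %.4g at order %d)",
                 current, best$rmse, tol_abs, best$order))

  structure(list(current = current, coefficients = best$coef,
                 fit_order = best$order, v_range = range(v),
                 v_center = vc, v_scale = vs,
                 blank_ms = blank_ms, reference_CL = reference_CL,
                 rmse = best$rmse, rmse_tol_abs = tol_abs),
            class = "clamped_current")
}

#' Evaluate a fitted current clamp at given voltages
#'
#' @param clamp a `clamped_current` object.
#' @param v voltages (mV); values outside the fitted range use the boundary
#'   value.
#' @return current density (pA/pF).
#' @export
eval_clamp <- function(clamp, v) {
  v <- pmin(pmax(v, clamp$v_range[1]), clamp$v_range[2])
  u <- (v - clamp$v_center) / clamp$v_scale
  vapply(u, function(x) sum(clamp$coefficients * x^(seq_along(clamp$coefficients) - 1)),
         numeric(1))
}

#' Serialize / read clamp fits and states as JSON
#'
#' @param x a `clamped_current` or `tp06_state` object.
#' @param path file path.
#' @return `write_clamp_json`/`write_state_json` return `path` invisibly;
#'   the readers return the reconstructed object.
#' @export
write_clamp_json <- function(x, path) {
  stopifnot(inherits(x, "clamped_current"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_clamp_json
#' @export
read_clamp_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$v_range <- as.numeric(x$v_range)
  structure(x, class = "clamped_current")
}

#' @rdname write_clamp_json
#' @export
write_state_json <- function(x, path) {
  x <- as_tp06_state(x)
  jsonlite::write_json(as.list(unclass(x)), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_clamp_json
#' @export
read_state_json <- function(path) {
  x <- unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  as_tp06_state(x)
}

#' @export
print.tp06_params <- function(x, ...) {
  sf <- attr(x, "scale_factors")
  cat("TP06 parameter set (epicardial)\n")
  mod <- sf[sf != 1]
  if (length(mod)) {
    cat("  scaled conductances:",
        paste(sprintf("%s x%.3g", names(mod), mod), collapse = ", "), "\n")
  } else cat("  control conductances\n")
  invisible(x)
}

#' @export
print.clamped_current <- function(x, ...) {
  cat(sprintf("voltage clamp of %s: order %d polynomial on [%.1f, %.1f] mV, RMSE %.4g (tol %.4g), blanked %g ms after upstroke\n",
              x$current, x$fit_order, x$v_range[1], x$v_range[2],
              x$rmse, x$rmse_tol_abs, x$blank_ms))
  invisible(x)
}
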