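# Spaces of states and their descriptors: Shift_CL / Shift_DI, dynamic
# restitution slopes, hysteresis-loop principal-axis slope, relaxation beat
# counts and mono-exponential fits.

#' Space of states of an AP train
#'
#' Pairs each beat's APD with the preceding cycle length (`mode = "vs_CL"`)
#' or the preceding diastolic interval (`mode = "vs_DI"`): the point of beat
#' n is (x_{n-1}, APD_n). Under constant pacing the space collapses to one
#' point; under periodic pacing it is traversed as a closed loop; under
#' random pacing it fills a band. The direction flag records whether x was
#' rising or falling at each point (defined for the lag-1 difference of x).
#'
#' @param train an `ap_train` (from [run_train()] or [surrogate_train()]).
#' @param mode `"vs_CL"` or `"vs_DI"`.
#' @return a `space_of_states`: data.frame with columns `beat`, `x_ms`,
#'   `APD_ms`, `direction` (+1 rising, -1 falling, 0 flat), and the source
#'   schedule metadata in `attr(, "meta")`.
#' @export
space_of_states <- function(train, mode = c("vs_CL", "vs_DI")) {
  mode <- match.arg(mode)
  ok <- train$captured & !is.na(train$APD_ms)
  x_prev <- if (mode == "vs_CL") train$CL_ms else train$DI_ms
  n <- nrow(train)
  if (n < 2 || sum(ok) < 2) stop("train has fewer than 2 usable beats")
  # beat n pairs with x_{n-1}
  idx <- which(ok[-1] & ok[-n]) + 1L
  if (!length(idx)) stop("no consecutive captured beat pairs (empty space)")
  x <- x_prev[idx - 1L]
  apd <- train$APD_ms[idx]
  dir <- rep(0, length(idx))
  if (length(idx) > 1) {
    dx <- c(NA, diff(x))
    dir <- sign(ifelse(is.na(dx), 0, dx))
  }
  structure(
    data.frame(beat = idx, x_ms = x, APD_ms = apd, direction = dir),
    mode = mode, meta = attr(train, "meta"),
    class = c("space_of_states", "data.frame"))
}

#' Vertical width of a space of states (Shift)
#'
#' The memory/hysteresis measure: the vertical distance between the upper
#' and lower edges of the space of states at a reference x (CL* for vs_CL
#' spaces). For periodic sources the x-rising and x-falling branches are
#' interpolated at `reference_x` and the absolute difference returned; for
#' random sources the APD range within `|x - reference_x| <= tol_bin` is
#' used; constant sources give 0.
#'
#' @param space a `space_of_states`.
#' @param reference_x x at which the width is measured (ms); default: the
#'   source CL* (vs_CL) or its median x.
#' @param tol_bin half-width of the x-bin for random/branchless sources
#'   (ms, default 2).
#' @return shift (ms, >= 0), with attribute `method` (`"branches"` or
#'   `"bin"`).
#' @export
shift <- function(space, reference_x = NULL, tol_bin = 2) {
  law <- attr(space, "meta")$law %||% "unknown"
  if (is.null(reference_x)) {
    reference_x <- attr(space, "meta")$CL_star %||% stats::median(space$x_ms)
    if (attr(space, "mode") == "vs_DI")
      reference_x <- stats::median(space$x_ms)
  }
  if (law == "constant")
    return(structure(0, method = "constant"))
  if (law %in% c("periodic", "alternating")) {
    up <- space[space$direction > 0, ]
    dn <- space[space$direction < 0, ]
    if (nrow(up) >= 2 && nrow(dn) >= 2 &&
        min(up$x_ms) <= reference_x && max(up$x_ms) >= reference_x &&
        min(dn$x_ms) <= reference_x && max(dn$x_ms) >= reference_x) {
      a_up <- stats::approx(up$x_ms, up$APD_ms, xout = reference_x,
                            ties = mean)$y
      a_dn <- stats::approx(dn$x_ms, dn$APD_ms, xout = reference_x,
                            ties = mean)$y
      return(structure(abs(a_up - a_dn), method = "branches"))
    }
  }
  near <- abs(space$x_ms - reference_x) <= tol_bin
  if (sum(near) < 2)
    stop("no points within ", tol_bin, " ms of reference_x = ", reference_x)
  structure(diff(range(space$APD_ms[near])), method = "bin")
}

# mean vertical distance between rising and falling branches over the
# central 50% of the x-range; the unimodal-vs-loop classifier
loop_width <- function(space) {
  up <- space[space$direction > 0, ]
  dn <- space[space$direction < 0, ]
  if (nrow(up) < 2 || nrow(dn) < 2) return(0)
  xr <- range(space$x_ms)
  grid <- seq(xr[1] + 0.25 * diff(xr), xr[2] - 0.25 * diff(xr), length.out = 21)
  a_up <- stats::approx(up$x_ms, up$APD_ms, xout = grid, ties = mean)$y
  a_dn <- stats::approx(dn$x_ms, dn$APD_ms, xout = grid, ties = mean)$y
  mean(abs(a_up - a_dn), na.rm = TRUE)
}

#' Slope of a unimodal dynamic-restitution cloud
#'
#' Ordinary-least-squares slope of APD on x over the whole cloud, for
#' spaces that collapse to a single curve (typically vs_DI under fast
#' periodic pacing). Errors if the space forms a loop (mean branch
#' separation above `loop_tol`); use [major_axis_slope()] then. The maximum
#' local slope (window of `window` x-sorted points) is returned as an
#' attribute to quantify "reaches values up to" behaviour.
#'
#' @param space a `space_of_states`.
#' @param loop_tol loop-width threshold (ms, default 2) above which the
#'   cloud is treated as a hysteresis loop.
#' @return OLS slope (dimensionless) with attributes `max_local_slope` and
#'   `loop_width`.
#' @export
der_slope <- function(space, loop_tol = 2) {
  lw <- loop_width(space)
  if (lw > loop_tol)
    stop(sprintf("space forms a hysteresis loop (width %.1f ms > %.1f); use major_axis_slope()",
                 lw, loop_tol))
  fit <- stats::lm.fit(cbind(1, space$x_ms), space$APD_ms)
  structure(unname(fit$coefficients[2]),
            max_local_slope = max_local_slope(space),
            loop_width = lw)
}

#' @rdname der_slope
#' @param span width (ms) of the sliding x-window used for local slopes
#'   (default 8); windows with fewer than `min_pts` points or covering less
#'   than half the span are skipped, so near-duplicate x values cannot
#'   produce spurious slopes.
#' @param min_pts minimum points per local-slope window (default 4).
#' @export
max_local_slope <- function(space, span = 8, min_pts = 4, window = NULL) {
  o <- order(space$x_ms)
  x <- space$x_ms[o]
  y <- space$APD_ms[o]
  n <- length(x)
  if (n < min_pts) stop("fewer points than a local-slope window")
  best <- -Inf
  for (i in seq_len(n)) {
    sel <- which(abs(x - x[i]) <= span / 2)
    if (length(sel) < min_pts || diff(range(x[sel])) < span / 2) next
    sl <- stats::cov(x[sel], y[sel]) / stats::var(x[sel])
    if (is.finite(sl) && sl > best) best <- sl
  }
  if (!is.finite(best)) stop("no window with enough x-spread for a local slope")
  best
}

#' Principal-axis slope of a hysteresis loop
#'
#' Slope of the first principal axis of the mean-centered (x, APD) cloud
#' (both in ms, no standardization): the ratio of the APD- to the
#' x-component of the leading eigenvector of the covariance matrix. For a
#' degenerate (collinear) cloud it falls back to the OLS slope with a
#' warning attribute.
#'
#' @param space a `space_of_states`.
#' @return slope (dimensionless); attribute `degenerate` flags the OLS
#'   fallback.
#' @export
major_axis_slope <- function(space) {
  m <- cbind(space$x_ms, space$APD_ms)
  cv <- stats::cov(m)
  ev <- eigen(cv, symmetric = TRUE)
  if (ev$values[2] / max(ev$values[1], .Machine$double.eps) < 1e-12) {
    fit <- stats::lm.fit(cbind(1, space$x_ms), space$APD_ms)
    return(structure(unname(fit$coefficients[2]), degenerate = TRUE))
  }
  v <- ev$vectors[, 1]
  structure(v[2] / v[1], degenerate = FALSE)
}

#' Beats for restitution to relax into rate dependence after a CL step
#'
#' Conditions to steady state at `CL_cond`, steps to constant pacing at
#' `CL_target`, and counts the beats until the APD stays within `tol` of
#' the steady-state APD at the target CL for `sustain` consecutive beats.
#'
#' @param params a `tp06_params` object.
#' @param CL_cond,CL_target conditioning and post-step cycle lengths (ms).
#' @param tol recovery tolerance (ms, default 2).
#' @param sustain consecutive in-tolerance beats required (default 10).
#' @param n_cond conditioning beats (each CL).
#' @param n_follow beats simulated after the step.
#' @param stim,dt as in [run_train()].
#' @return Nb (beats, 0 when already at target); `NA` if never sustained
#'   within `n_follow` beats.
#' @export
er_to_rd_beats <- function(params, CL_cond, CL_target, tol = 2, sustain = 10,
                           n_cond = 300, n_follow = 60, stim = NULL,
                           dt = 0.02) {
  if (CL_cond == CL_target) return(0)
  cond <- condition_at(params, CL_cond, n_cond, stim = stim, dt = dt)
  stim <- attr(cond, "stim")
  # single post-step run; the steady APD at the target rate is read from the
  # same run just past the recovery horizon, so the model's slow ionic drift
  # (a few ms over hundreds of beats) cannot masquerade as non-recovery
  tr <- resume_train(params, final_state(cond),
                     rep(CL_target, n_follow + 20), stim, dt = dt)
  apd_ss <- mean(tr$APD_ms[(n_follow + 1):(n_follow + 20)], na.rm = TRUE)
  recovery_index(tr$APD_ms[seq_len(n_follow)] - apd_ss, tol, sustain)
}

# first index k with |delta| < tol from k through k+sustain-1 (NA entries
# fail; runs truncated by the series end count); returns k - 1, the number
# of beats spent out of tolerance, or NA if recovery never sustains
recovery_index <- function(delta, tol, sustain) {
  ok <- is.finite(delta) & abs(delta) < tol
  n <- length(ok)
  for (k in seq_len(n)) {
    if (all(ok[k:min(n, k + sustain - 1)])) return(k - 1L)
  }
  NA_integer_
}

#' Mono-exponential fit
#'
#' Nonlinear least squares of `y = a * exp(-x / tau) + c` (Levenberg-
#' Marquardt, with self-starting heuristics), as used for relaxation-vs-CL
#' and Shift-vs-omega trends.
#'
#' @param x,y data vectors (>= 4 points).
#' @param tau_start optional starting value for the decay constant.
#' @return list `a`, `tau`, `c`, `r_squared`, `fitted`.
#' @export
fit_monoexponential <- function(x, y, tau_start = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  # constant data: the decay constant is unidentifiable; return the
  # degenerate fit (a = 0, c = mean) directly
  if (stats::sd(y) <= 1e-10 * max(1, abs(mean(y)))) {
    return(list(a = 0, tau = if (is.null(tau_start)) diff(range(x)) else tau_start,
                c = mean(y), r_squared = 1, fitted = rep(mean(y), length(y))))
  }
  # initialize by matching the two x-extremes for a grid of candidate decay
  # constants (both signs, so decaying, saturating and accelerating trends
  # all get a workable start)
  o <- order(x)
  x1 <- x[o[1]]; y1 <- y[o[1]]
  x2 <- x[o[length(o)]]; y2 <- y[o[length(o)]]
  taus <- if (is.null(tau_start)) diff(range(x)) * c(0.25, 0.75, 2, -0.5, -2)
          else tau_start
  fit <- NULL
  for (t0 in taus) {
    den <- exp(-x1 / t0) - exp(-x2 / t0)
    if (!is.finite(den) || abs(den) < 1e-12) next
    a0 <- (y1 - y2) / den
    c0 <- y1 - a0 * exp(-x1 / t0)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(-x / tau) + c,
                        start = list(a = a0, tau = t0, c = c0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("mono-exponential fit failed to converge from all starting values")
  co <- stats::coef(fit)
  fitted <- co["a"] * exp(-x / co["tau"]) + co["c"]
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(a = unname(co["a"]), tau = unname(co["tau"]), c = unname(co["c"]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
       fitted = unname(fitted))
}

#' Write a space of states to CSV
#' @param space a `space_of_states`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_space_csv <- function(space, path) {
  utils::write.csv(as.data.frame(space), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.space_of_states <- function(x, ...) {
  cat(sprintf("space of states (%s): %d points, x in [%.1f, %.1f] ms, APD in [%.1f, %.1f] ms\n",
              attr(x, "mode"), nrow(x), min(x$x_ms), max(x$x_ms),
              min(x$APD_ms), max(x$APD_ms)))
  invisible(x)
}
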