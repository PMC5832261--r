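# Beat-by-beat driver: run schedules through the compiled TP06 stepper,
# detect upstrokes / APD(-60 mV) / DI, snapshot and restore full model state,
# and run the rate-dependence and classic-restitution measurement protocols.

new_ap_train <- function(beats, final_state, states, meta, stim, dt,
                         trace = NULL) {
  attr(beats, "final_state") <- as_tp06_state(final_state)
  attr(beats, "states") <- states
  attr(beats, "meta") <- meta
  attr(beats, "stim") <- stim
  attr(beats, "dt") <- dt
  if (!is.null(trace)) attr(beats, "trace") <- trace
  class(beats) <- c("ap_train", "data.frame")
  beats
}

make_beat_records <- function(res, stim_times, enabled, total_ms) {
  n <- length(stim_times)
  # CL_n is the cycle initiated by stimulus n (to the next stimulus; the
  # last beat gets the remaining integration time), DI_n = CL_n - APD_n
  cl <- c(diff(stim_times), total_ms - stim_times[n])
  apd <- res$apd_ms
  data.frame(
    index = seq_len(n),
    CL_ms = cl,
    APD_ms = apd,
    DI_ms = cl - apd,
    upstroke_ms = res$upstroke_ms,
    captured = res$captured,
    merged = res$merged,
    stim_enabled = enabled
  )
}

#' Run a pacing schedule through the TP06 model
#'
#' Integrates the full schedule and returns per-beat records: cycle length,
#' APD to -60 mV (from the refined maximum-dV/dt upstroke), diastolic
#' interval, capture flag. A beat is captured iff V_m exceeds 0 mV within
#' 20 ms of its stimulus onset; an uncaptured enabled stimulus is recorded,
#' not an error. Snapshots of the full 19-variable state immediately before
#' every stimulus are kept, so any beat can be replayed with
#' [resume_train()].
#'
#' @param params a `tp06_params` object.
#' @param schedule a `pacing_schedule`.
#' @param initial_state starting state; default: the settled resting state of
#'   `params` (2 s quiescence from the published state).
#' @param stim a `stimulus_spec`; default: 3 ms pulse at 1.5x the measured
#'   diastolic threshold of `initial_state`.
#' @param clamps optional list of `clamped_current` objects active
#'   throughout the run (outside each beat's blanking window).
#' @param dt integration step (ms, default 0.02).
#' @param tail_ms integration time after the last stimulus (default: the last
#'   scheduled CL, so the final state sits exactly one cycle after the last
#'   stimulus and can seed a resumed run).
#' @param record_traces sample (t, V_m, dV/dt, I_CaL, I_Kr, I_Ks) every
#'   `trace_dt` ms.
#' @param trace_dt trace sampling interval (ms).
#' @param record_states keep the per-beat snapshots (default `TRUE`).
#' @return an `ap_train`: data.frame of beat records with attributes
#'   `final_state`, `states` (snapshot matrix), `meta`, `stim`, and
#'   optionally `trace`.
#' @export
run_train <- function(params, schedule, initial_state = NULL, stim = NULL,
                      clamps = NULL, dt = 0.02, tail_ms = NULL,
                      record_traces = FALSE, trace_dt = 0.5,
                      record_states = TRUE) {
  stopifnot(inherits(schedule, "pacing_schedule"))
  if (is.null(initial_state))
    initial_state <- settle_to_rest(params, duration_ms = 2000, dt = dt)
  initial_state <- validate_state(initial_state)
  if (is.null(stim)) stim <- stimulus_spec(params, initial_state)
  st <- schedule$stim_time_ms
  if (is.null(tail_ms)) tail_ms <- schedule$CL_ms[nrow(schedule)]
  total <- st[length(st)] + tail_ms
  res <- tp06_run_cpp(as.numeric(initial_state), unclass(params), st,
                      schedule$stim_enabled, total, stim$amplitude,
                      stim$duration, dt, lapply(clamps %||% list(), unclass),
                      record_traces, trace_dt, record_states)
  tr <- NULL
  if (record_traces) {
    tr <- as.data.frame(res$trace)
    names(tr) <- c("t_ms", "Vm_mV", "dVdt", "ICaL", "IKr", "IKs")
  }
  beats <- make_beat_records(res, st, schedule$stim_enabled, total)
  new_ap_train(beats, res$final_state,
               if (record_states) res$states else NULL,
               schedule_meta(schedule), stim, dt, tr)
}

#' Resume integration from a cycle-boundary snapshot
#'
#' A snapshot taken immediately before a stimulus is, by construction, an
#' end-of-cycle state, so the resumed run fires its first stimulus at t = 0
#' and then paces with the supplied cycle lengths (`cl_seq[k]` is the
#' interval from stimulus k to stimulus k+1).
#'
#' @param params a `tp06_params` object.
#' @param state a 19-variable snapshot at a cycle boundary.
#' @param cl_seq cycle lengths initiated by each stimulus (ms).
#' @param stim a `stimulus_spec` (required: the threshold must match the run
#'   the snapshot came from for exact replay).
#' @param enabled logical vector of stimulus-enabled flags (recycled).
#' @param tail_ms extra integration time after the last cycle (default 0).
#' @inheritParams run_train
#' @return an `ap_train`.
#' @export
resume_train <- function(params, state, cl_seq, stim, enabled = TRUE,
                         clamps = NULL, dt = 0.02, tail_ms = 0,
                         record_traces = FALSE, trace_dt = 0.5,
                         record_states = FALSE) {
  state <- validate_state(state)
  stopifnot(all(cl_seq > 0))
  n <- length(cl_seq)
  enabled <- rep_len(enabled, n)
  st <- c(0, cumsum(cl_seq)[-n])
  total <- sum(cl_seq) + tail_ms
  res <- tp06_run_cpp(as.numeric(state), unclass(params), st, enabled, total,
                      stim$amplitude, stim$duration, dt,
                      lapply(clamps %||% list(), unclass),
                      record_traces, trace_dt, record_states)
  tr <- NULL
  if (record_traces) {
    tr <- as.data.frame(res$trace)
    names(tr) <- c("t_ms", "Vm_mV", "dVdt", "ICaL", "IKr", "IKs")
  }
  beats <- make_beat_records(res, st, enabled, total)
  beats$CL_ms <- c(cl_seq[-n], cl_seq[n])  # last beat keeps its scheduled CL
  beats$DI_ms <- beats$CL_ms - beats$APD_ms
  new_ap_train(beats, res$final_state,
               if (record_states) res$states else NULL,
               list(law = "resumed"), stim, dt, tr)
}

#' Snapshot accessors for an AP train
#'
#' `final_state()` is the exact state at the end of the run; `beat_states()`
#' the matrix of snapshots taken immediately before each stimulus (row =
#' beat). Restoring a snapshot and replaying the same cycle lengths
#' reproduces the original APDs to solver reproducibility.
#'
#' @param train an `ap_train`.
#' @return a `tp06_state` / numeric matrix.
#' @export
final_state <- function(train) attr(train, "final_state")

#' @rdname final_state
#' @export
beat_states <- function(train) attr(train, "states")

#' @rdname final_state
#' @param beat beat index.
#' @export
snapshot <- function(train, beat = NULL) {
  if (is.null(beat)) return(final_state(train))
  s <- beat_states(train)
  if (is.null(s)) stop("train was run with record_states = FALSE")
  as_tp06_state(s[beat, ])
}

#' Restore a snapshot and measure one extra-stimulus beat
#'
#' Delivers the last conditioning beat immediately (the snapshot sits at a
#' cycle boundary) followed by the test beat after `test_CL`, and returns
#' the test beat's APD: one point of the classic restitution sweep.
#' Replaying `test_CL` equal to the conditioning CL reproduces the
#' uninterrupted steady APD.
#'
#' @param state a cycle-boundary snapshot.
#' @param test_CL interval between the conditioning and test stimuli (ms).
#' @param params a `tp06_params` object.
#' @param stim a `stimulus_spec`.
#' @param ... passed to [resume_train()].
#' @return the test-beat APD (ms; NA on capture failure).
#' @export
restore_and_stimulate <- function(state, test_CL, params, stim, ...) {
  tr <- resume_train(params, state, c(test_CL, 500), stim, ...)
  tr$APD_ms[2]
}

#' Measure upstroke and APD from a sampled voltage trace
#'
#' Pure-R measurement used for externally produced traces (and as an
#' independent check of the in-engine detection): the upstroke is the
#' quadratically refined argmax of the finite-difference dV/dt within 20 ms
#' of the stimulus, the APD ends at the linearly interpolated downward
#' -60 mV crossing.
#'
#' @param trace data.frame or matrix with time (ms) and V_m (mV) in the
#'   first two columns (a `t_ms`/`Vm_mV` trace from [run_train()] works).
#' @param stim_time stimulus onset (ms).
#' @param next_stim_time optional next stimulus onset; a missing crossing
#'   before it flags a merged beat.
#' @return list with `upstroke_time`, `APD`, `captured`, `merged`.
#' @export
measure_apd <- function(trace, stim_time, next_stim_time = Inf) {
  t <- as.numeric(trace[[1]])
  v <- as.numeric(trace[[2]])
  win <- which(t >= stim_time & t <= stim_time + 20)
  if (length(win) < 3 || max(v[win]) <= 0)
    return(list(upstroke_time = NA_real_, APD = NA_real_,
                captured = FALSE, merged = FALSE))
  dv <- diff(v[win]) / diff(t[win])
  k <- which.max(dv)
  tu <- (t[win][k] + t[win][k + 1]) / 2
  if (k > 1 && k < length(dv)) {
    den <- dv[k - 1] - 2 * dv[k] + dv[k + 1]
    if (den < 0) {
      delta <- 0.5 * (dv[k - 1] - dv[k + 1]) / den
      if (abs(delta) <= 1) tu <- tu + delta * mean(diff(t[win]))
    }
  }
  after <- which(t > tu + 1 & t < next_stim_time)
  cross <- after[which(v[after - 1] >= -60 & v[after] < -60)[1]]
  if (is.na(cross))
    return(list(upstroke_time = tu, APD = NA_real_, captured = TRUE,
                merged = TRUE))
  tc <- t[cross - 1] + (t[cross] - t[cross - 1]) *
    (v[cross - 1] + 60) / (v[cross - 1] - v[cross])
  list(upstroke_time = tu, APD = tc - tu, captured = TRUE, merged = FALSE)
}

#' Steady-state APD of a train
#'
#' Mean (and sd) of the APD over the last `n_avg` captured beats.
#' @param train an `ap_train`.
#' @param n_avg number of final beats to average (default 20).
#' @return named vector `c(APD, sd, DI)` using the scheduled CL of those
#'   beats for DI.
#' @export
steady_apd <- function(train, n_avg = 20) {
  ok <- which(train$captured & !is.na(train$APD_ms))
  if (length(ok) < n_avg) stop("fewer than n_avg captured beats")
  tail_idx <- utils::tail(ok, n_avg)
  apd <- train$APD_ms[tail_idx]
  c(APD = mean(apd), sd = stats::sd(apd),
    DI = mean(train$CL_ms[tail_idx]) - mean(apd))
}

#' Condition the model at a constant cycle length
#'
#' Convenience wrapper: paces `n_cond` beats at `CL` and returns the train
#' (whose `final_state` is the end-diastolic snapshot one cycle after the
#' last stimulus, ready for [resume_train()]).
#'
#' @inheritParams run_train
#' @param CL conditioning cycle length (ms).
#' @param n_cond number of conditioning beats (default 300; see the vignette
#'   for the convergence check backing this default against 1000).
#' @return an `ap_train`.
#' @export
condition_at <- function(params, CL, n_cond = 300, initial_state = NULL,
                         stim = NULL, clamps = NULL, dt = 0.02) {
  run_train(params, constant_schedule(CL, n_cond), initial_state, stim,
            clamps = clamps, dt = dt, record_states = FALSE)
}

new_restitution_curve <- function(x, apd, mode, conditioning, flagged) {
  o <- order(x)
  structure(data.frame(x_ms = x[o], APD_ms = apd[o], flagged = flagged[o]),
            mode = mode, conditioning = conditioning,
            class = c("restitution_curve", "data.frame"))
}

#' Rate-dependence (RD) curve
#'
#' Steady-state APD as a function of constant pacing CL: for each CL a
#' conditioning train is run and the last `n_avg` beats averaged. A CL that
#' loses 1:1 capture (any uncaptured or merged beat in the averaged window)
#' is flagged, not dropped.
#'
#' @inheritParams run_train
#' @param cl_values cycle lengths (ms); the protocol grid is
#'   `seq(300, 1400, by = 20)`.
#' @param n_cond conditioning beats per CL.
#' @param n_avg beats averaged at the end of each train.
#' @param warm_start start each CL from the previous CL's final state
#'   (default `TRUE`; much faster, identical steady values).
#' @return a `restitution_curve` (mode `"vs_CL"`) with columns `x_ms`,
#'   `APD_ms`, `flagged`.
#' @export
rd_curve <- function(params, cl_values = seq(300, 1400, by = 20),
                     n_cond = 300, n_avg = 20, warm_start = TRUE,
                     initial_state = NULL, stim = NULL, dt = 0.02) {
  if (is.null(initial_state))
    initial_state <- settle_to_rest(params, duration_ms = 2000, dt = dt)
  if (is.null(stim)) stim <- stimulus_spec(params, initial_state)
  apd <- flag <- rep(NA, length(cl_values))
  state <- initial_state
  for (k in seq_along(cl_values)) {
    tr <- run_train(params, constant_schedule(cl_values[k], n_cond),
                    initial_state = state, stim = stim, dt = dt,
                    record_states = FALSE)
    last <- utils::tail(seq_len(nrow(tr)), n_avg)
    flag[k] <- any(!tr$captured[last]) || any(tr$merged[last])
    apd[k] <- mean(tr$APD_ms[last], na.rm = TRUE)
    if (warm_start) state <- final_state(tr)
  }
  new_restitution_curve(cl_values, apd, "vs_CL",
                        list(n_cond = n_cond, n_avg = n_avg), flag)
}

#' Classic electrical-restitution sweep from a conditioned state
#'
#' Implements the extra-stimulus protocol: condition at CL*, snapshot the
#' end-of-cycle state, then for each test CL restore the snapshot, deliver
#' the last conditioning beat and the test beat with the varied interval
#' between them, and record the test-beat APD against the test CL (ER_CL)
#' and against the preceding diastolic interval (ER_DI). Both curves come
#' from the same sweep, so point-wise DI = CL - APD(conditioning beat).
#'
#' @inheritParams run_train
#' @param CL_star conditioning cycle length (ms).
#' @param half_width sweep half-range around CL* (ms; 35 for the
#'   perturbation-figure protocols, 20 in the base protocol).
#' @param step sweep step (ms).
#' @param n_cond conditioning beats (ignored when `state` is given).
#' @param state optional pre-conditioned end-of-cycle snapshot at CL*.
#' @return list with `vs_CL` and `vs_DI` (`restitution_curve`s), the
#'   conditioning APD `apd_cond`, and the steady point
#'   `c(CL_star, apd_star)`.
#' @export
classic_er <- function(params, CL_star, half_width = 20, step = 5,
                       n_cond = 300, state = NULL, stim = NULL, dt = 0.02) {
  if (is.null(state)) {
    cond <- condition_at(params, CL_star, n_cond, stim = stim, dt = dt)
    state <- final_state(cond)
    if (is.null(stim)) stim <- attr(cond, "stim")
  }
  if (is.null(stim)) stop("supply `stim` when passing a pre-conditioned state")
  test_cl <- seq(CL_star - half_width, CL_star + half_width, by = step)
  apd <- di <- rep(NA_real_, length(test_cl))
  flag <- rep(FALSE, length(test_cl))
  for (k in seq_along(test_cl)) {
    tr <- resume_train(params, state, c(test_cl[k], CL_star), stim, dt = dt)
    apd[k] <- tr$APD_ms[2]
    di[k] <- test_cl[k] - tr$APD_ms[1]
    flag[k] <- !tr$captured[2] || isTRUE(tr$merged[2]) || !tr$captured[1]
  }
  cond_info <- list(CL_star = CL_star, n_cond = n_cond)
  star <- which(test_cl == CL_star)
  list(
    vs_CL = new_restitution_curve(test_cl, apd, "vs_CL", cond_info, flag),
    vs_DI = new_restitution_curve(di, apd, "vs_DI", cond_info, flag),
    apd_cond = if (length(star)) test_cl[star] - di[star] else NA_real_,
    steady = c(CL = CL_star, APD = if (length(star)) apd[star] else NA_real_)
  )
}

#' Local slope of a restitution curve
#'
#' Central-difference slope at `at`, from the two sweep points bracketing it
#' (for ER_DI curves `at` defaults to the conditioning DI, i.e. the x of the
#' point closest to the steady state).
#'
#' @param curve a `restitution_curve`.
#' @param at x-value (ms) at which to evaluate the slope.
#' @return dimensionless slope (ms APD per ms x).
#' @export
er_local_slope <- function(curve, at) {
  x <- curve$x_ms[!curve$flagged]
  y <- curve$APD_ms[!curve$flagged]
  if (length(x) < 3) stop("not enough unflagged points")
  below <- which(x < at)
  above <- which(x > at)
  if (!length(below) || !length(above))
    stop("`at` outside the sweep range")
  i <- below[which.max(x[below])]
  j <- above[which.min(x[above])]
  (y[j] - y[i]) / (x[j] - x[i])
}

#' Family of classic ER curves along a dynamic train
#'
#' At every `stride`-th beat of a dynamic pacing train, restores the beat's
#' snapshot and runs a classic-ER sweep, yielding the family of curves whose
#' envelope bounds the space of states.
#'
#' @inheritParams run_train
#' @param schedule a dynamic `pacing_schedule`.
#' @param half_width,step sweep geometry (ms), as in [classic_er()].
#' @param stride beat spacing of the family (default 1: every beat).
#' @param beats explicit beat indices (overrides `stride`).
#' @return list of elements `list(beat, vs_CL, vs_DI)`.
#' @export
dynamic_er_family <- function(params, schedule, half_width = 35, step = 5,
                              stride = 1, beats = NULL, initial_state = NULL,
                              stim = NULL, dt = 0.02) {
  train <- run_train(params, schedule, initial_state, stim, dt = dt)
  stim <- attr(train, "stim")
  states <- beat_states(train)
  if (is.null(beats)) beats <- seq(2, nrow(train), by = stride)
  cl_star <- schedule_meta(schedule)$CL_star %||% mean(schedule$CL_ms)
  lapply(beats, function(b) {
    er <- classic_er(params, cl_star, half_width, step,
                     state = as_tp06_state(states[b, ]), stim = stim, dt = dt)
    list(beat = b, vs_CL = er$vs_CL, vs_DI = er$vs_DI)
  })
}

#' Write an AP train / restitution curve to CSV
#'
#' @param x an `ap_train` or `restitution_curve`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_train_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.ap_train <- function(x, ...) {
  ok <- sum(x$captured)
  cat(sprintf("AP train: %d beats (%d captured), law = %s\n",
              nrow(x), ok, attr(x, "meta")$law %||% "?"))
  if (ok >= 20) {
    s <- steady_apd(x)
    cat(sprintf("  last-20-beat APD = %.1f ms (sd %.2f), DI = %.1f ms\n",
                s["APD"], s["sd"], s["DI"]))
  }
  invisible(x)
}
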