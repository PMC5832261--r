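# Perturbation experiments: missing-beat recovery, alternans detection and
# quenching by dynamic pacing, constant-to-dynamic switch protocols, and
# beat-to-beat |dCL| distribution statistics.

#' Detect APD alternans
#'
#' Alternans is present when the sign of the beat-to-beat APD difference
#' alternates over at least `min_run` consecutive beats with a mean
#' absolute difference above `amp_tol`. It is sustained when the qualifying
#' run extends to the end of the series. `NA` APDs (capture failures) break
#' a run.
#'
#' @param apd_series numeric APD sequence (ms).
#' @param amp_tol amplitude threshold (ms, default 2).
#' @param min_run minimal alternating run length in beats (default 40).
#' @return list `present`, `amplitude` (mean |difference| over the longest
#'   qualifying run; `NA` when absent), `sustained`, `run_beats`.
#' @export
detect_alternans <- function(apd_series, amp_tol = 2, min_run = 40) {
  if (sum(is.finite(apd_series)) < min_run)
    stop("fewer than min_run finite APDs")
  d <- diff(apd_series)
  s <- sign(d)
  s[!is.finite(d)] <- NA
  nd <- length(d)
  # maximal runs of alternating non-zero signs
  runs <- list()
  k <- 1
  while (k <= nd) {
    if (is.na(s[k]) || s[k] == 0) { k <- k + 1; next }
    j <- k
    while (j < nd && !is.na(s[j + 1]) && s[j + 1] == -s[j]) j <- j + 1
    runs[[length(runs) + 1]] <- c(from = k, to = j)
    k <- j + 1
  }
  best <- NULL
  for (r in runs) {
    beats <- r["to"] - r["from"] + 2  # n differences span n+1 beats
    amp <- mean(abs(d[r["from"]:r["to"]]))
    if (beats >= min_run && amp > amp_tol &&
        (is.null(best) || beats > best$run_beats))
      best <- list(run_beats = unname(beats), amplitude = amp,
                   to = unname(r["to"]))
  }
  if (is.null(best))
    return(list(present = FALSE, amplitude = NA_real_, sustained = FALSE,
                run_beats = 0L))
  list(present = TRUE, amplitude = best$amplitude,
       sustained = best$to == nd, run_beats = as.integer(best$run_beats))
}

# shared core: intact train with snapshots + replay from the pre-drop
# snapshot with the dropped stimulus disabled
paired_drop_delta <- function(params, schedule, intact, drop_index, stim,
                              follow, sustain, clamps = NULL, dt = 0.02) {
  n <- nrow(schedule)
  m <- min(n, drop_index + follow + sustain)
  states <- beat_states(intact)
  cl <- schedule$CL_ms
  cl_seq <- c(cl[seq(drop_index + 1, length.out = m - drop_index)], cl[m])
  enabled <- schedule$stim_enabled[drop_index:m]
  enabled[1] <- FALSE
  pert <- resume_train(params, states[drop_index, ], cl_seq, stim,
                       enabled = enabled, clamps = clamps, dt = dt)
  idx <- drop_index:m
  delta <- pert$APD_ms - intact$APD_ms[idx]
  list(delta = delta, perturbed_apd = pert$APD_ms, beats = idx)
}

#' Missing-beat perturbation experiment
#'
#' Runs the schedule twice -- intact, and with the stimulus of one beat
#' turned off (the pacing clock is not reset) -- and compares APDs aligned
#' by stimulus index. Nb is the number of beats after the missing one
#' before |dAPD| stays below `tol` for `sustain` consecutive beats; if the
#' perturbation triggers sustained alternans Nb is `NA` (not recovered).
#'
#' @param params a `tp06_params` object.
#' @param schedule a `pacing_schedule` (for random laws the same seed is
#'   shared by construction: the intact train is replayed).
#' @param drop_index beat whose stimulus is disabled.
#' @param tol recovery tolerance (ms, default 2).
#' @param follow beats of dAPD profile kept after the drop (default 50).
#' @param sustain consecutive in-tolerance beats required (default 10).
#' @param intact optional precomputed intact `ap_train` of `schedule` (with
#'   snapshots); supply it when scanning many drop positions.
#' @param alternans_min_run run length for the alternans check on the
#'   perturbed tail.
#' @param initial_state,stim,clamps,dt as in [run_train()].
#' @return list of class `perturbation_result`: `Nb`, `delta_apd`
#'   (length-`follow` profile), `alternans` (from [detect_alternans()]),
#'   `drop_index`.
#' @export
missing_beat_experiment <- function(params, schedule, drop_index, tol = 2,
                                    follow = 50, sustain = 10,
                                    intact = NULL, initial_state = NULL,
                                    stim = NULL, clamps = NULL,
                                    alternans_min_run = 40, dt = 0.02) {
  n <- nrow(schedule)
  if (drop_index < 1 || drop_index > n) stop("drop_index out of range")
  if (n - drop_index < follow)
    stop("fewer than `follow` beats remain after the drop")
  if (is.null(intact)) {
    intact <- run_train(params, schedule, initial_state, stim,
                        clamps = clamps, dt = dt)
  }
  stim <- stim %||% attr(intact, "stim")
  pd <- paired_drop_delta(params, schedule, intact, drop_index, stim,
                          follow, sustain, clamps, dt)
  # profile and recovery start at the first beat after the missing one
  after <- pd$delta[-1]
  profile <- after[seq_len(follow)]
  apd_tail <- pd$perturbed_apd[-1]
  alt <- if (sum(is.finite(apd_tail)) >= alternans_min_run)
    detect_alternans(apd_tail, amp_tol = tol, min_run = alternans_min_run)
  else list(present = FALSE, amplitude = NA_real_, sustained = FALSE,
            run_beats = 0L)
  nb <- recovery_index(after, tol, sustain)
  if (isTRUE(alt$sustained)) nb <- NA_integer_
  structure(list(Nb = nb, delta_apd = profile, alternans = alt,
                 drop_index = drop_index),
            class = "perturbation_result")
}

#' Missing-beat recovery over many drop positions
#'
#' Efficient scan: the intact train is simulated once and each perturbed
#' run restarts from the stored pre-drop snapshot. Returns per-drop results
#' and the mean Nb (dropping non-recovered `NA`s unless all are `NA`).
#'
#' @inheritParams missing_beat_experiment
#' @param drop_positions beat indices to drop (default 20 consecutive beats
#'   starting at `first_drop`).
#' @param first_drop first drop position (used when `drop_positions` is
#'   `NULL`).
#' @return list: `Nb` (vector), `mean_Nb`, `results` (list of
#'   `perturbation_result`), `intact` (the intact train).
#' @export
missing_beat_scan <- function(params, schedule, drop_positions = NULL,
                              first_drop = NULL, tol = 2, follow = 50,
                              sustain = 10, initial_state = NULL,
                              stim = NULL, clamps = NULL,
                              alternans_min_run = 40, dt = 0.02) {
  n <- nrow(schedule)
  if (is.null(drop_positions)) {
    if (is.null(first_drop)) first_drop <- n - follow - sustain - 20
    drop_positions <- first_drop + 0:19
  }
  intact <- run_train(params, schedule, initial_state, stim,
                      clamps = clamps, dt = dt)
  stim <- stim %||% attr(intact, "stim")
  results <- lapply(drop_positions, function(dpos)
    missing_beat_experiment(params, schedule, dpos, tol, follow, sustain,
                            intact = intact, stim = stim, clamps = clamps,
                            alternans_min_run = alternans_min_run, dt = dt))
  nb <- vapply(results, function(r) as.numeric(r$Nb %||% NA_real_),
               numeric(1))
  list(Nb = nb,
       mean_Nb = if (all(is.na(nb))) NA_real_ else mean(nb, na.rm = TRUE),
       results = results, intact = intact)
}

#' Mean APD-displacement profile after a missing beat
#'
#' Averages the per-beat dAPD profiles of consecutive drop positions
#' (default 20), each from a paired intact/perturbed run.
#'
#' @inheritParams missing_beat_scan
#' @return list: `mean_profile` (length `follow`), `profiles` (matrix,
#'   drops x beats), `drop_positions`.
#' @export
average_delta_profile <- function(params, schedule, drop_positions = NULL,
                                  first_drop = NULL, follow = 50,
                                  initial_state = NULL, stim = NULL,
                                  clamps = NULL, dt = 0.02) {
  scan <- missing_beat_scan(params, schedule, drop_positions, first_drop,
                            follow = follow, initial_state = initial_state,
                            stim = stim, clamps = clamps, dt = dt)
  profiles <- do.call(rbind, lapply(scan$results, `[[`, "delta_apd"))
  list(mean_profile = colMeans(profiles),
       profiles = profiles,
       drop_positions = vapply(scan$results, `[[`, numeric(1), "drop_index"))
}

#' Constant-to-dynamic switch experiment
#'
#' Reproduces the alternans-quenching protocol: pace at a constant CL, drop
#' one stimulus to trigger alternans, keep pacing constant until the switch,
#' then continue with a dynamic (periodic or random) law. Quenching is
#' judged against a paired reference run (same switch, no drop): the
#' post-switch APD difference must fall below `tol` for `sustain` beats
#' within the dynamic segment.
#'
#' @param params a `tp06_params` object (typically with reduced G_Ks).
#' @param constant_CL cycle length of the constant phase (ms).
#' @param n_const beats in the constant phase (48 beats at 350 ms is ~17 s).
#' @param dynamic a `pacing_schedule` for the post-switch phase.
#' @param drop_index beat (within the constant phase) whose stimulus is
#'   dropped.
#' @param state conditioned end-of-cycle state at `constant_CL` (conditioned
#'   on demand when `NULL`).
#' @param clamps_at_switch optional `clamped_current` list activated at the
#'   switch (time-dependence removal during the dynamic phase only).
#' @param tol,sustain recovery criterion on the post-switch dAPD (ms,
#'   beats).
#' @param n_cond conditioning beats when `state` is `NULL`.
#' @param stim,dt as in [run_train()].
#' @return list of class `switch_result`: `quenched`, `beats_to_quench`,
#'   `alternans_established` (on the pre-switch perturbed segment),
#'   `pre_alternans`, `delta_post` (post-switch dAPD), `apd_perturbed`,
#'   `apd_reference`.
#' @export
switch_experiment <- function(params, constant_CL = 350, n_const = 48,
                              dynamic = NULL, drop_index = 10, state = NULL,
                              clamps_at_switch = NULL, tol = 2, sustain = 10,
                              n_cond = 300, stim = NULL, dt = 0.02) {
  stopifnot(inherits(dynamic, "pacing_schedule"))
  if (is.null(state)) {
    cond <- condition_at(params, constant_CL, n_cond, stim = stim, dt = dt)
    state <- final_state(cond)
    stim <- attr(cond, "stim")
  }
  if (is.null(stim)) stop("supply `stim` with a pre-conditioned state")

  run_branch <- function(with_drop) {
    enabled <- rep(TRUE, n_const)
    if (with_drop) enabled[drop_index] <- FALSE
    pre <- resume_train(params, state, rep(constant_CL, n_const), stim,
                        enabled = enabled, dt = dt, tail_ms = 0)
    post <- resume_train(params, final_state(pre), dynamic$CL_ms, stim,
                         enabled = dynamic$stim_enabled,
                         clamps = clamps_at_switch, dt = dt)
    list(pre = pre, post = post)
  }
  pert <- run_branch(TRUE)
  ref <- run_branch(FALSE)

  pre_apd <- pert$pre$APD_ms[(drop_index + 1):n_const]
  pre_alt <- if (sum(is.finite(pre_apd)) >= 20)
    detect_alternans(pre_apd, amp_tol = tol, min_run = 20)
  else list(present = FALSE, amplitude = NA_real_, sustained = FALSE,
            run_beats = 0L)

  delta_post <- pert$post$APD_ms - ref$post$APD_ms
  k <- recovery_index(delta_post, tol, sustain)
  structure(list(
    quenched = !is.na(k),
    beats_to_quench = k,
    alternans_established = isTRUE(pre_alt$present) && isTRUE(pre_alt$sustained),
    pre_alternans = pre_alt,
    delta_post = delta_post,
    apd_perturbed = c(pert$pre$APD_ms, pert$post$APD_ms),
    apd_reference = c(ref$pre$APD_ms, ref$post$APD_ms)
  ), class = "switch_result")
}

#' Alternans onset under constant pacing
#'
#' Scans constant pacing CLs downward, conditioning at each CL (warm-started
#' from the previous one), and reports the period-doubling onset: the
#' largest CL below which sustained APD alternans appears.
#'
#' @param params a `tp06_params` object.
#' @param cl_from,cl_to scan limits (ms), scanned downward.
#' @param step scan step (ms, default 5).
#' @param n_cond conditioning beats per CL (default 200).
#' @param n_detect trailing beats inspected for alternans (default 100).
#' @param amp_tol alternans amplitude threshold (ms).
#' @param min_run alternating run length required (beats).
#' @param initial_state,stim,dt as in [run_train()].
#' @return list: `onset_CL` (ms; the scan CL just above the first positive),
#'   `table` (data.frame CL, alternans flag, amplitude).
#' @export
alternans_onset_scan <- function(params, cl_from = 280, cl_to = 230,
                                 step = 5, n_cond = 200, n_detect = 100,
                                 amp_tol = 2, min_run = 40,
                                 initial_state = NULL, stim = NULL,
                                 dt = 0.02) {
  cls <- seq(cl_from, cl_to, by = -abs(step))
  if (is.null(initial_state))
    initial_state <- settle_to_rest(params, duration_ms = 2000, dt = dt)
  if (is.null(stim)) stim <- stimulus_spec(params, initial_state)
  state <- final_state(condition_at(params, cl_from + 50, 50,
                                    initial_state = initial_state,
                                    stim = stim, dt = dt))
  present <- logical(length(cls))
  amp <- rep(NA_real_, length(cls))
  for (k in seq_along(cls)) {
    tr <- resume_train(params, state, rep(cls[k], n_cond + n_detect), stim,
                       dt = dt)
    tail_apd <- utils::tail(tr$APD_ms, n_detect)
    if (sum(is.finite(tail_apd)) >= min_run) {
      alt <- detect_alternans(tail_apd, amp_tol = amp_tol, min_run = min_run)
      present[k] <- alt$present
      amp[k] <- alt$amplitude
    } else {
      present[k] <- NA  # lost 1:1 capture entirely (beyond period doubling)
    }
    state <- final_state(tr)
  }
  first <- which(present)[1]
  onset <- if (is.na(first)) NA_real_ else if (first == 1) cls[1] + abs(step)
           else cls[first - 1]
  list(onset_CL = onset,
       table = data.frame(CL_ms = cls, alternans = present,
                          amplitude_ms = amp))
}

#' Beat-to-beat |dCL| statistics of pacing schedules
#'
#' For each schedule, the fraction of beats whose absolute beat-to-beat CL
#' change exceeds each threshold, and the ratio between the first
#' (periodic) and second (random) schedule -- the statistic explaining why
#' matched-clv periodic pacing produces larger beat-to-beat CL jumps than
#' random pacing.
#'
#' @param schedules named list of two `pacing_schedule`s (conventionally
#'   `periodic` and `random`, sharing CL* and clv).
#' @param thresholds ms grid (default 0 to 70 by 1).
#' @return data.frame: `threshold_ms`, one exceedance-fraction column per
#'   schedule, and `ratio` (first / second; `Inf` when the denominator is 0).
#' @export
cl_change_statistics <- function(schedules, thresholds = 0:70) {
  stopifnot(is.list(schedules), length(schedules) >= 2)
  frac <- vapply(schedules, function(s) {
    dcl <- abs(diff(s$CL_ms))
    vapply(thresholds, function(th) mean(dcl > th), numeric(1))
  }, numeric(length(thresholds)))
  frac <- matrix(frac, ncol = length(schedules),
                 dimnames = list(NULL, paste0("A_", names(schedules))))
  ratio <- ifelse(frac[, 2] == 0, Inf, frac[, 1] / frac[, 2])
  out <- data.frame(threshold_ms = thresholds, frac, ratio = ratio)
  out
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat(sprintf("missing-beat perturbation at beat %d: Nb = %s%s\n",
              x$drop_index,
              if (is.na(x$Nb)) "not recovered" else x$Nb,
              if (isTRUE(x$alternans$present))
                sprintf(" (alternans: amplitude %.1f ms, %s)",
                        x$alternans$amplitude,
                        if (x$alternans$sustained) "sustained" else "transient")
              else ""))
  invisible(x)
}

#' @export
print.switch_result <- function(x, ...) {
  cat(sprintf("switch experiment: alternans %s, %s%s\n",
              if (x$alternans_established) "established" else "NOT established",
              if (x$quenched) "quenched" else "not quenched",
              if (x$quenched) sprintf(" after %d beats", x$beats_to_quench)
              else ""))
  invisible(x)
}
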