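# Pacing-law generators. A schedule is a data.frame (index, CL_ms,
# stim_time_ms, stim_enabled) with a meta attribute; beat N is stimulated at
# t(N) = sum_{i<=N} CL(i), i.e. the first stimulus falls one CL after the
# start of the run (the conditioning snapshot).

new_schedule <- function(CL, law, meta = list()) {
  n <- length(CL)
  if (n < 1) stop("a schedule needs at least one beat")
  if (any(CL <= 0)) stop("non-positive cycle length in schedule")
  sched <- data.frame(
    index = seq_len(n),
    CL_ms = as.numeric(CL),
    stim_time_ms = cumsum(as.numeric(CL)),
    stim_enabled = TRUE
  )
  attr(sched, "meta") <- c(list(law = law), meta)
  class(sched) <- c("pacing_schedule", "data.frame")
  sched
}

#' Pacing schedules: constant, random, periodic, alternating
#'
#' Beat-timing generators for the pacing laws used throughout the package.
#' In every law the beat index N starts at 1 and beat N is stimulated at
#' t(N), the cumulative sum of the cycle lengths, so the first stimulus
#' falls one cycle length after the start of the run.
#'
#' * `constant_schedule`: CL(N) = CL.
#' * `random_schedule`: CL(N) = CL* + clv * u_N with u_N i.i.d. uniform on
#'   \[-1, 1\] from a seeded generator; every CL lies in \[CL* - clv, CL* + clv\].
#' * `periodic_schedule`: CL(N) = CL* + clv * sin(omega * N), omega in
#'   radians per beat; 2*pi/omega beats complete one oscillation.
#' * `alternating_schedule`: CL(N) = CL* + (-1)^N * clv, the degenerate
#'   periodic law visiting only the two extreme cycle lengths.
#'
#' @param CL,CL_star cycle length / central cycle length (ms).
#' @param clv half-range of cycle-length variability (ms, `clv < CL_star`).
#' @param omega angular frequency (rad/beat, `>= 0`).
#' @param n_beats number of beats.
#' @param seed integer seed for the random law (recorded in the metadata).
#' @return a `pacing_schedule`: data.frame with columns `index`, `CL_ms`,
#'   `stim_time_ms`, `stim_enabled` and a `meta` attribute.
#' @examples
#' periodic_schedule(350, 35, 2.4, 5)
#' @export
constant_schedule <- function(CL, n_beats) {
  stopifnot(CL > 0, n_beats >= 1)
  new_schedule(rep(CL, n_beats), "constant", list(CL_star = CL))
}

#' @rdname constant_schedule
#' @export
random_schedule <- function(CL_star, clv, n_beats, seed) {
  stopifnot(CL_star > 0, clv >= 0, n_beats >= 1)
  if (clv >= CL_star)
    stop("clv must be smaller than CL_star (cycle lengths could be non-positive)")
  cl <- withr::with_seed(seed, CL_star + clv * stats::runif(n_beats, -1, 1))
  new_schedule(cl, "random", list(CL_star = CL_star, clv = clv, seed = seed))
}

#' @rdname constant_schedule
#' @export
periodic_schedule <- function(CL_star, clv, omega, n_beats) {
  stopifnot(CL_star > 0, clv >= 0, omega >= 0, n_beats >= 1)
  if (clv >= CL_star)
    stop("clv must be smaller than CL_star (cycle lengths could be non-positive)")
  n <- seq_len(n_beats)
  new_schedule(CL_star + clv * sin(omega * n), "periodic",
               list(CL_star = CL_star, clv = clv, omega = omega))
}

#' @rdname constant_schedule
#' @export
alternating_schedule <- function(CL_star, clv, n_beats) {
  stopifnot(CL_star > 0, clv >= 0, n_beats >= 1)
  if (clv >= CL_star) stop("clv must be smaller than CL_star")
  n <- seq_len(n_beats)
  new_schedule(CL_star + (-1)^n * clv, "alternating",
               list(CL_star = CL_star, clv = clv))
}

#' Disable the stimulus of one beat
#'
#' Marks the beat's stimulus as off without touching the pacing clock: the
#' slot keeps its index and stimulus time so later beats are unmoved (the
#' missing-beat perturbation). Re-applying with `enable = TRUE` restores the
#' original schedule; dropping an already disabled beat is a no-op.
#'
#' @param schedule a `pacing_schedule`.
#' @param beat_index beat to silence (1-based).
#' @param enable set `TRUE` to re-enable instead.
#' @return the modified schedule.
#' @export
drop_beat <- function(schedule, beat_index, enable = FALSE) {
  stopifnot(inherits(schedule, "pacing_schedule"))
  if (beat_index < 1 || beat_index > nrow(schedule))
    stop("beat_index out of range")
  schedule$stim_enabled[beat_index] <- enable
  schedule
}

#' Concatenate a constant run-in with a dynamic schedule
#'
#' Builds the constant-to-dynamic switch protocol: constant pacing at `CL`
#' for `duration_ms` (floor(duration_ms / CL) beats), then the supplied
#' dynamic schedule on a continuous time axis. The switch beat index is
#' recorded in the metadata.
#'
#' @param CL constant cycle length (ms).
#' @param duration_ms length of the constant phase (ms).
#' @param dynamic a `pacing_schedule` for the dynamic phase.
#' @return a `pacing_schedule` with `meta$switch_index` marking the first
#'   dynamic beat.
#' @export
switch_schedule <- function(CL, duration_ms, dynamic) {
  stopifnot(inherits(dynamic, "pacing_schedule"), CL > 0, duration_ms >= CL)
  n_const <- floor(duration_ms / CL)
  cl <- c(rep(CL, n_const), dynamic$CL_ms)
  sched <- new_schedule(cl, "composite",
                        list(constant_CL = CL,
                             switch_index = n_const + 1,
                             dynamic_meta = schedule_meta(dynamic)))
  sched$stim_enabled <- c(rep(TRUE, n_const), dynamic$stim_enabled)
  sched
}

#' Schedule metadata
#' @param schedule a `pacing_schedule`.
#' @return the meta list (law, CL*, clv, omega, seed, ... as applicable).
#' @export
schedule_meta <- function(schedule) attr(schedule, "meta")

#' Schedule round-trip to CSV / JSON
#'
#' CSV holds the four beat columns; JSON additionally carries the meta block.
#' @param schedule a `pacing_schedule`.
#' @param path file path.
#' @return writers return `path` invisibly; readers the schedule.
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  df <- utils::read.csv(path)
  sched <- new_schedule(df$CL_ms, "unknown")
  sched$stim_enabled <- as.logical(df$stim_enabled)
  if (max(abs(sched$stim_time_ms - df$stim_time_ms)) > 1e-6)
    warning("stimulus times in file are not the cumulative CL sums; recomputed")
  sched
}

#' @rdname write_schedule_csv
#' @export
write_schedule_json <- function(schedule, path) {
  jsonlite::write_json(
    list(meta = schedule_meta(schedule), beats = as.data.frame(schedule)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sched <- new_schedule(x$beats$CL_ms, x$meta$law %||% "unknown",
                        x$meta[setdiff(names(x$meta), "law")])
  sched$stim_enabled <- as.logical(x$beats$stim_enabled)
  sched
}

#' @export
print.pacing_schedule <- function(x, ...) {
  m <- schedule_meta(x)
  cat(sprintf("pacing schedule: %d beats, law = %s", nrow(x), m$law))
  if (!is.null(m$CL_star)) cat(sprintf(", CL* = %g ms", m$CL_star))
  if (!is.null(m$clv)) cat(sprintf(", clv = %g ms", m$clv))
  if (!is.null(m$omega)) cat(sprintf(", omega = %g rad/beat", m$omega))
  if (!is.null(m$seed)) cat(sprintf(", seed = %d", m$seed))
  cat("\n")
  print(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ...\n")
  invisible(x)
}
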