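#' Acquisition schedule for burst time-lapse imaging
#'
#' Growth cones are typically imaged in short high-frequency bursts (to
#' resolve comet motion) repeated at long intervals (to score migration).
#' An `acq_schedule` maps a (burst, frame) index pair to absolute time:
#' `t(b, f) = b * burst_interval + f * frame_interval` with `b`, `f`
#' counted from zero.
#'
#' @param frames_per_burst number of frames acquired per burst.
#' @param frame_interval time between frames within a burst, seconds.
#' @param burst_interval time between burst starts, seconds; must be at
#'   least `frames_per_burst * frame_interval`.
#' @param n_bursts number of bursts.
#' @param pixel_size lateral pixel size, micrometres per pixel.
#'
#' @return An object of class `acq_schedule`.
#' @examples
#' sched <- make_schedule(33, 2, 600, 4, 0.211)
#' frame_time(sched, burst = 1, frame = 0)   # 600 s
#' @export
make_schedule <- function(frames_per_burst, frame_interval, burst_interval,
                          n_bursts, pixel_size) {
  args <- c(frames_per_burst = frames_per_burst,
            frame_interval = frame_interval,
            burst_interval = burst_interval,
            n_bursts = n_bursts, pixel_size = pixel_size)
  if (any(!is.finite(args)) || any(args <= 0))
    stop("all schedule arguments must be positive and finite")
  if (frames_per_burst != round(frames_per_burst) || n_bursts != round(n_bursts))
    stop("frames_per_burst and n_bursts must be whole numbers")
  if (burst_interval < frames_per_burst * frame_interval)
    stop("burst_interval must cover the burst: >= frames_per_burst * frame_interval")
  structure(list(frames_per_burst = as.integer(frames_per_burst),
                 frame_interval = frame_interval,
                 burst_interval = burst_interval,
                 n_bursts = as.integer(n_bursts),
                 pixel_size = pixel_size),
            class = "acq_schedule")
}

#' Absolute time of a frame
#'
#' @param schedule an [make_schedule()] object.
#' @param burst zero-based burst index (vectorised).
#' @param frame zero-based frame-within-burst index (vectorised).
#' @return Time in seconds since the first frame.
#' @export
frame_time <- function(schedule, burst, frame) {
  stopifnot(inherits(schedule, "acq_schedule"))
  if (any(burst < 0) || any(burst >= schedule$n_bursts) ||
      any(frame < 0) || any(frame >= schedule$frames_per_burst))
    stop("burst/frame index out of range")
  burst * schedule$burst_interval + frame * schedule$frame_interval
}

#' All frame times of a schedule as a table
#'
#' @param schedule an [make_schedule()] object.
#' @return data.frame with zero-based `burst`, `frame` and `time` (s).
#' @export
schedule_frames <- function(schedule) {
  stopifnot(inherits(schedule, "acq_schedule"))
  g <- expand.grid(frame = seq_len(schedule$frames_per_burst) - 1L,
                   burst = seq_len(schedule$n_bursts) - 1L)
  data.frame(burst = g$burst, frame = g$frame,
             time = frame_time(schedule, g$burst, g$frame))
}

#' @export
print.acq_schedule <- function(x, ...) {
  cat(sprintf(
    "acquisition schedule: %d bursts of %d frames @ %g s, every %g s; pixel %g um\n",
    x$n_bursts, x$frames_per_burst, x$frame_interval, x$burst_interval,
    x$pixel_size))
  invisible(x)
}
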