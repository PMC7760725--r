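#' Frame schedule of a dynamic PET acquisition
#'
#' A frame schedule holds the per-frame start times and durations (seconds)
#' that anchor every time-activity curve and running integral in the package.
#' Frames must be contiguous (each frame starts where the previous one ends),
#' non-overlapping and of positive duration.
#'
#' @param start_s numeric vector of frame start times in seconds; the first
#'   frame must start at 0.
#' @param duration_s numeric vector of frame durations in seconds.
#' @return A `frame_schedule` data frame with columns `start_s`, `duration_s`,
#'   `mid_s`, `end_s` and the derived columns `mid_min` (frame midpoints in
#'   minutes, the time grid used by all kinetic analyses) and `duration_min`.
#' @seealso [pib_frame_schedule()] for the default 70-min schedule.
#' @export
#' @examples
#' frame_schedule(c(0, 5, 10), c(5, 5, 10))
frame_schedule <- function(start_s, duration_s) {
  start_s <- as.numeric(start_s)
  duration_s <- as.numeric(duration_s)
  if (length(start_s) != length(duration_s) || length(start_s) == 0L)
    stop("start_s and duration_s must be non-empty and of equal length")
  if (any(!is.finite(start_s)) || any(!is.finite(duration_s)))
    stop("frame times must be finite")
  if (any(duration_s <= 0)) stop("frame durations must be positive")
  if (start_s[1L] != 0) stop("the first frame must start at 0 s")
  if (is.unsorted(start_s, strictly = TRUE))
    stop("frame start times must be strictly increasing")
  end_s <- start_s + duration_s
  if (length(start_s) > 1L &&
      max(abs(start_s[-1L] - end_s[-length(end_s)])) > 1e-9)
    stop("frames must be contiguous: each frame must start where the previous ends")
  out <- data.frame(
    start_s = start_s,
    duration_s = duration_s,
    mid_s = start_s + duration_s / 2,
    end_s = end_s
  )
  out$mid_min <- out$mid_s / 60
  out$duration_min <- out$duration_s / 60
  class(out) <- c("frame_schedule", "data.frame")
  out
}

#' The 70-min dynamic PiB reconstruction schedule
#'
#' Returns the frame schedule used for 70-min dynamic \[11C\]PiB acquisitions:
#' 12 x 5 s, 6 x 10 s, 3 x 20 s, 4 x 30 s, 5 x 60 s, 4 x 5 min and 4 x 10 min
#' frames (38 frames, 4200 s in total).
#'
#' @return A [frame_schedule()] with 38 rows summing to 4200 s.
#' @export
#' @examples
#' sched <- pib_frame_schedule()
#' sum(sched$duration_s) / 60   # 70 minutes
pib_frame_schedule <- function() {
  durations <- c(rep(5, 12), rep(10, 6), rep(20, 3), rep(30, 4),
                 rep(60, 5), rep(300, 4), rep(600, 4))
  starts <- cumsum(c(0, durations))[seq_along(durations)]
  frame_schedule(starts, durations)
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("Frame schedule: %d frames, total %.0f s (%.1f min)\n",
              nrow(x), sum(x$duration_s), sum(x$duration_s) / 60))
  print.data.frame(head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more frames\n", nrow(x) - 6L))
  invisible(x)
}

#' Read / write a frame schedule as JSON
#'
#' The on-disk format is a JSON object
#' `{"frame_start_s": [...], "frame_duration_s": [...]}` with times in seconds.
#'
#' @param path file path.
#' @return `read_frame_schedule` returns a [frame_schedule()];
#'   `write_frame_schedule` returns `path` invisibly.
#' @export
read_frame_schedule <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$frame_start_s) || is.null(j$frame_duration_s))
    stop("frame JSON must contain 'frame_start_s' and 'frame_duration_s'")
  frame_schedule(j$frame_start_s, j$frame_duration_s)
}

#' @rdname read_frame_schedule
#' @param schedule a [frame_schedule()].
#' @export
write_frame_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "frame_schedule"))
  jsonlite::write_json(
    list(frame_start_s = schedule$start_s, frame_duration_s = schedule$duration_s),
    path, digits = NA
  )
  invisible(path)
}

# seconds of overlap between each frame and the window [w1, w2] (seconds)
frame_overlap_s <- function(schedule, window_s) {
  stopifnot(length(window_s) == 2L, window_s[2] > window_s[1])
  pmax(0, pmin(schedule$end_s, window_s[2]) - pmax(schedule$start_s, window_s[1]))
}
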