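#' Time-activity curve
#'
#' A time-activity curve (TAC) is stored as a data frame with columns
#' `time_min` (frame midpoints, minutes, strictly increasing), `activity`
#' (kBq/mL) and `duration_min` (frame durations, minutes).
#'
#' @param time_min frame midpoints in minutes.
#' @param activity activity concentration in kBq/mL.
#' @param duration_min frame durations in minutes.
#' @return A `tac` data frame.
#' @export
tac <- function(time_min, activity, duration_min) {
  if (length(time_min) != length(activity) ||
      length(time_min) != length(duration_min))
    stop("time_min, activity and duration_min must have equal lengths")
  if (is.unsorted(time_min, strictly = TRUE))
    stop("time_min must be strictly increasing")
  if (any(!is.finite(activity))) stop("activity must be finite")
  out <- data.frame(time_min = time_min, activity = activity,
                    duration_min = duration_min)
  class(out) <- c("tac", "data.frame")
  out
}

as_tac <- function(x) {
  if (inherits(x, "tac")) return(x)
  if (is.data.frame(x) &&
      all(c("time_min", "activity", "duration_min") %in% names(x)))
    return(tac(x$time_min, x$activity, x$duration_min))
  stop("cannot interpret object as a time-activity curve")
}

#' @export
plot.tac <- function(x, xlab = "Time (min)", ylab = "Activity (kBq/mL)",
                     type = "b", ...) {
  plot(x$time_min, x$activity, xlab = xlab, ylab = ylab, type = type, ...)
  invisible(x)
}
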