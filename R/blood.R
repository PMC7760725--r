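#' Parametric arterial whole-blood input curve
#'
#' A bolus-shaped whole-blood activity curve: a linear rise from zero at
#' injection to a peak at `peak_time_min`, followed by a sum of decaying
#' exponentials.  The defaults emulate the shape of a carotid \[11C\]PiB
#' image-derived input function after a 700-750 MBq bolus: a sharp peak of
#' about 50 kBq/mL at 45 s, a fast capillary-phase washout, and a slow tail of
#' roughly 2 kBq/mL at the end of a 70-min scan.
#'
#' @param peak_time_min time of the peak in minutes (> 0).
#' @param amplitudes_kbq nonnegative exponential amplitudes (kBq/mL); their sum
#'   is the peak activity.
#' @param decay_per_min positive decay rates (1/min), one per amplitude.
#' @return `blood_input_params` returns a parameter list of class
#'   `blood_input_params`; `blood_input` returns whole-blood activity (kBq/mL)
#'   at the requested times.
#' @export
#' @examples
#' t <- seq(0, 70, by = 0.1)
#' cb <- blood_input(t)
#' t[which.max(cb)]   # peak at 0.75 min
blood_input_params <- function(peak_time_min = 0.75,
                               amplitudes_kbq = c(35, 10, 5),
                               decay_per_min = c(4, 0.6, 0.008)) {
  if (length(peak_time_min) != 1L || !is.finite(peak_time_min) || peak_time_min <= 0)
    stop("peak_time_min must be a single positive number")
  if (length(amplitudes_kbq) != length(decay_per_min))
    stop("amplitudes_kbq and decay_per_min must have the same length")
  if (any(amplitudes_kbq < 0)) stop("amplitudes must be nonnegative")
  if (any(decay_per_min <= 0)) stop("decay rates must be positive")
  structure(list(peak_time_min = peak_time_min,
                 amplitudes_kbq = amplitudes_kbq,
                 decay_per_min = decay_per_min),
            class = "blood_input_params")
}

#' @rdname blood_input_params
#' @param t_min times after injection in minutes (>= 0).
#' @param params a `blood_input_params` object.
#' @export
blood_input <- function(t_min, params = blood_input_params()) {
  stopifnot(inherits(params, "blood_input_params"))
  if (any(t_min < 0)) stop("t_min must be nonnegative")
  peak <- sum(params$amplitudes_kbq)
  out <- numeric(length(t_min))
  rising <- t_min <= params$peak_time_min
  out[rising] <- peak * t_min[rising] / params$peak_time_min
  if (any(!rising)) {
    dt <- t_min[!rising] - params$peak_time_min
    out[!rising] <- colSums(params$amplitudes_kbq *
                              exp(-outer(params$decay_per_min, dt)))
  }
  out
}
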