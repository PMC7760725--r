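#' Logan graphical analysis of a reversible tracer
#'
#' Fits the Logan plot for a single tissue TAC.  With a metabolite-corrected
#' plasma input the slope estimates the total distribution volume DV (mL/g);
#' with a reference-tissue TAC in place of the input the slope estimates the
#' distribution volume ratio DVR (the reference form used here omits the
#' population `k2'` term; an optional `k2_ref` restores it).
#'
#' The transform is `y(T) = int_0^T Ct / Ct(T)` against
#' `x(T) = int_0^T Cin / Ct(T)`, with running integrals computed by the
#' trapezoid rule from an implied `(0, 0)` sample, and an ordinary
#' least-squares line fitted over the frames with midpoint `>= t_star` where
#' the plot is linear.
#'
#' @param ct tissue [tac()].
#' @param input plasma input or reference-tissue [tac()] on the same grid.
#' @param t_star start of the linear phase in minutes (default 50, i.e. the
#'   last 50-70 min of a 70-min study).
#' @param k2_ref optional reference-tissue efflux constant (1/min) adding the
#'   `Cref/k2'` term to the running input integral (reference form only).
#' @return An object of class `logan`: list with `slope` (DV or DVR),
#'   `intercept`, `r.squared`, `n_points`, `t_star`, and the plot
#'   coordinates `x`, `y`, `used`.  Supports `coef`, `print` and `plot`.
#' @export
#' @examples
#' sched <- pib_frame_schedule()
#' t <- sched$mid_min
#' cp <- tac(t, blood_input(t), sched$duration_min)
#' ct <- tac(t, 4 * cp$activity, sched$duration_min)
#' coef(logan_fit(ct, cp))       # proportional TACs: slope 4, intercept 0
logan_fit <- function(ct, input, t_star = 50, k2_ref = NULL) {
  ct <- as_tac(ct); input <- as_tac(input)
  if (nrow(ct) != nrow(input) ||
      max(abs(ct$time_min - input$time_min)) > 1e-9)
    stop("tissue and input curves must share the same time grid")
  t <- ct$time_min
  int_ct <- cumtrapz0(t, ct$activity)
  int_in <- cumtrapz0(t, input$activity)
  if (!is.null(k2_ref)) int_in <- int_in + input$activity / k2_ref
  late <- t >= t_star
  used <- late & ct$activity > 0
  if (sum(used) < 2L)
    stop("fewer than 2 usable frames at or after t* = ", t_star, " min")
  x <- int_in[used] / ct$activity[used]
  y <- int_ct[used] / ct$activity[used]
  if (var(x) <= 0) stop("degenerate Logan plot: no spread in x")
  fit <- lsfit(x, y)
  res <- fit$residuals
  r2 <- if (var(y) > 0) 1 - sum(res^2) / sum((y - mean(y))^2) else 1
  structure(list(slope = unname(fit$coefficients[2L]),
                 intercept = unname(fit$coefficients[1L]),
                 r.squared = r2, n_points = sum(used), t_star = t_star,
                 x = int_in / ct$activity, y = int_ct / ct$activity,
                 used = used),
            class = "logan")
}

#' @export
coef.logan <- function(object, ...)
  c(slope = object$slope, intercept = object$intercept)

#' @export
print.logan <- function(x, ...) {
  cat(sprintf(
    "Logan graphical fit: slope %.4f, intercept %.3f, r^2 %.5f (%d frames, t* = %g min)\n",
    x$slope, x$intercept, x$r.squared, x$n_points, x$t_star))
  invisible(x)
}

#' @export
plot.logan <- function(x, xlab = "int(Cin)/Ct", ylab = "int(Ct)/Ct", ...) {
  plot(x$x, x$y, xlab = xlab, ylab = ylab,
       pch = ifelse(x$used, 19, 1), ...)
  abline(x$intercept, x$slope)
  legend("topleft", bty = "n",
         legend = sprintf("slope = %.3f, r2 = %.4f", x$slope, x$r.squared))
  invisible(x)
}

#' Voxel-wise Logan metric image
#'
#' Applies the Logan graphical transform voxel by voxel to a dynamic image,
#' producing a DV image (plasma input) or a reference-Logan DVR image
#' (reference-tissue input).  Voxels with nonpositive activity in any frame
#' used for the fit, or with a degenerate plot, are flagged invalid and set
#' to 0.
#'
#' @param dyn a [dynamic_image()].
#' @param input plasma input or reference [tac()] on the image's frame grid.
#' @param t_star start of the linear phase (minutes).
#' @param kind metric label stored on the result (`"DV"` or `"DVR_r"`).
#' @param k2_ref optional reference-tissue efflux constant, as [logan_fit()].
#'
#' @details
#' Validity requires positive tissue activity at every used frame and a
#' strictly increasing Logan abscissa over those frames.  The abscissa
#' `int(Cin)/Ct(T)` is strictly increasing in continuous time whenever the
#' input and tissue activities are positive, so a voxel that violates
#' monotonicity is noise-dominated and its two-point slope would be
#' meaningless; such voxels are masked out and counted in the QC report.
#'
#' A slope is likewise non-identifiable when noise collapses (without quite
#' inverting) the abscissa span: the expected relative span over the linear
#' phase is input-driven (roughly `Cin * dT / int(Cin)`, ~0.15-0.2 on the
#' default schedule) and essentially independent of the voxel's kinetics, so
#' voxels whose observed relative span falls below `min_rel_span` are masked
#' as failed fits rather than returned as unbounded slopes.
#' @return A `metric_image`: list with `values` (3D array), `valid` (logical
#'   3D array), `kind`, `n_invalid` and `reference_value` (NA until
#'   normalized).
#' @export
#' @param min_rel_span minimal observed abscissa span, relative to the mean
#'   abscissa, below which a voxel's slope is treated as non-identifiable.
logan_image <- function(dyn, input, t_star = 50, kind = "DV", k2_ref = NULL,
                        min_rel_span = 0.05) {
  stopifnot(inherits(dyn, "dynamic_image"))
  input <- as_tac(input)
  d <- dim(dyn$img)
  if (nrow(input) != d[4] ||
      max(abs(input$time_min - dyn$schedule$mid_min)) > 1e-9)
    stop("input curve is not on the image's frame grid")
  t <- dyn$schedule$mid_min
  late <- which(t >= t_star)
  if (length(late) < 2L)
    stop("fewer than 2 frames at or after t* = ", t_star, " min")
  V <- matrix(dyn$img, prod(d[1:3]), d[4])
  int_ct <- cumtrapz0_rows(t, V)
  int_in <- cumtrapz0(t, input$activity)
  if (!is.null(k2_ref)) int_in <- int_in + input$activity / k2_ref

  ctL <- V[, late, drop = FALSE]
  valid <- rowSums(ctL <= 0) == 0L
  ctL[ctL <= 0] <- NA_real_
  x <- sweep(1 / ctL, 2, int_in[late], `*`)
  y <- int_ct[, late, drop = FALSE] / ctL
  n <- length(late)
  if (n > 1L) {
    mono <- rowSums(x[, -1L, drop = FALSE] <=
                      x[, -n, drop = FALSE]) == 0L
    valid <- valid & !is.na(mono) & mono
    span <- (x[, n] - x[, 1L]) / rowMeans(x)
    valid <- valid & !is.na(span) & span >= min_rel_span
  }
  sx <- rowSums(x); sy <- rowSums(y)
  sxx <- rowSums(x * x); sxy <- rowSums(x * y)
  denom <- sxx - sx^2 / n
  slope <- (sxy - sx * sy / n) / denom
  valid <- valid & is.finite(slope) & denom > 0
  slope[!valid] <- 0
  metric_image(array(slope, d[1:3]), array(valid, d[1:3]), kind)
}

metric_image <- function(values, valid, kind, reference_value = NA_real_) {
  structure(list(values = values, valid = valid, kind = kind,
                 n_invalid = sum(!valid), reference_value = reference_value),
            class = "metric_image")
}

#' @export
print.metric_image <- function(x, ...) {
  v <- x$values[x$valid]
  cat(sprintf("%s image: %s voxels, %d invalid; valid range [%.3g, %.3g]",
              x$kind, paste(dim(x$values), collapse = "x"),
              x$n_invalid, min(v), max(v)))
  if (!is.na(x$reference_value))
    cat(sprintf("; reference mean %.4g", x$reference_value))
  cat("\n")
  invisible(x)
}

#' Normalize a metric image to a reference region
#'
#' Divides every valid voxel by the mean of the metric over the reference
#' region (e.g. converting a DV image to a DVR image with the cerebellar
#' cortex mean, or an SUV image to SUVR).
#'
#' @param metric a `metric_image`.
#' @param labels integer 3D label volume on the same grid.
#' @param label_id reference-region label.
#' @param kind metric label for the result (default appends `"R"` logic is
#'   left to the caller; `"DVR_L"` for a DV input).
#' @return A `metric_image` with `reference_value` set to the reference mean.
#' @export
normalize_to_reference <- function(metric, labels, label_id, kind = "DVR_L") {
  stopifnot(inherits(metric, "metric_image"))
  if (!identical(dim(labels), dim(metric$values)))
    stop("label grid does not match the metric image grid")
  sel <- labels == label_id & metric$valid
  if (!any(sel)) stop("reference region has no valid voxels")
  ref <- mean(metric$values[sel])
  if (ref <= 0) stop("nonpositive reference-region mean: ", format(ref))
  out <- metric$values / ref
  out[!metric$valid] <- 0
  metric_image(out, metric$valid, kind, reference_value = ref)
}
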