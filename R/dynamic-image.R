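#' Dynamic PET image container
#'
#' Couples a 4D activity-concentration volume (kBq/mL, decay-corrected to
#' scan start) with its [frame_schedule()] and voxel geometry.  The fourth
#' array dimension indexes frames and must match the schedule length.
#'
#' @param img 4D numeric array (x, y, z, frame).
#' @param schedule a [frame_schedule()].
#' @param voxel_mm voxel edge lengths in mm (length 3).
#' @return A `dynamic_image` list with elements `img`, `schedule`,
#'   `voxel_mm`.
#' @export
dynamic_image <- function(img, schedule, voxel_mm = c(2, 2, 2.76)) {
  stopifnot(inherits(schedule, "frame_schedule"))
  d <- dim(img)
  if (length(d) != 4L)
    stop("img must be a 4D array (x, y, z, frame)")
  if (d[4] != nrow(schedule))
    stop(sprintf("frame-count mismatch: image has %d frames, schedule has %d",
                 d[4], nrow(schedule)))
  if (length(voxel_mm) != 3L || any(voxel_mm <= 0))
    stop("voxel_mm must be three positive lengths")
  structure(list(img = img, schedule = schedule, voxel_mm = voxel_mm),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$img)
  cat(sprintf(
    "Dynamic PET image: %d x %d x %d voxels (%.2g x %.2g x %.2g mm), %d frames over %.0f min\n",
    d[1], d[2], d[3], x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3],
    d[4], sum(x$schedule$duration_s) / 60))
  invisible(x)
}

# check that a 3D label volume shares the dynamic image's grid
check_labels <- function(dyn, labels) {
  d <- dim(dyn$img)[1:3]
  if (!identical(as.integer(dim(labels)), as.integer(d)))
    stop(sprintf(
      "label grid (%s) does not match the image grid (%s)",
      paste(dim(labels), collapse = "x"), paste(d, collapse = "x")))
  invisible(TRUE)
}

# mean TAC over a labelled region
#' Regional mean time-activity curve
#'
#' @param dyn a [dynamic_image()].
#' @param labels integer 3D label volume on the same grid.
#' @param label_id region label whose voxel-mean TAC is wanted.
#' @return A [tac()].
#' @export
region_mean_tac <- function(dyn, labels, label_id) {
  stopifnot(inherits(dyn, "dynamic_image"))
  check_labels(dyn, labels)
  sel <- which(labels == label_id)
  if (length(sel) == 0L) stop("region ", label_id, " is empty")
  V <- matrix(dyn$img, prod(dim(dyn$img)[1:3]), dim(dyn$img)[4])
  tac(dyn$schedule$mid_min, colMeans(V[sel, , drop = FALSE]),
      dyn$schedule$duration_min)
}
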