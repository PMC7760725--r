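#' Early-phase average image
#'
#' Duration-weighted average of the dynamic frames overlapping a short early
#' window (default 10-40 s after injection), used to locate the internal
#' carotid artery while the bolus is still intravascular.  Frames partially
#' covered by the window contribute with weight equal to their overlap in
#' seconds, so the average is exact for constant activity regardless of the
#' schedule.
#'
#' @param dyn a [dynamic_image()].
#' @param window_s two-element window `[start, end]` in seconds.
#' @return A 3D array.
#' @export
early_average_image <- function(dyn, window_s = c(10, 40)) {
  stopifnot(inherits(dyn, "dynamic_image"))
  w <- frame_overlap_s(dyn$schedule, window_s)
  if (all(w == 0))
    stop("no frame overlaps the window [", window_s[1], ", ", window_s[2], "] s")
  d <- dim(dyn$img)
  V <- matrix(dyn$img, prod(d[1:3]), d[4])
  array(as.vector(V %*% w) / sum(w), d[1:3])
}

#' Select the hottest voxels inside a search region
#'
#' Picks the `n` most intense voxels of an early-phase image within a search
#' mask — the carotid VOI of the image-derived input function.  Ties are
#' broken by ascending flattened (column-major) voxel index so the selection
#' is deterministic; it is also invariant to any positive affine rescaling of
#' the image.
#'
#' @param early 3D image (e.g. from [early_average_image()]).
#' @param mask logical 3D array, or an integer label volume combined with
#'   `label_id`.
#' @param n number of voxels to select (default 30).
#' @param label_id region label to use when `mask` is a label volume.
#' @return A `voi_mask`: integer matrix of 1-based voxel coordinates
#'   (columns `i`, `j`, `k`, one row per voxel) with attributes `dim` and
#'   `slice_counts` (voxels per axial slice `k`).
#' @export
select_hottest_voxels <- function(early, mask, n = 30L, label_id = NULL) {
  stopifnot(length(dim(early)) == 3L)
  if (!is.logical(mask)) {
    if (is.null(label_id)) stop("label_id is required when mask is a label volume")
    mask <- mask == label_id
  }
  if (!identical(dim(mask), dim(early)))
    stop("mask grid does not match the image grid")
  idx <- which(mask)
  if (length(idx) < n)
    stop(sprintf("search region has %d voxels but %d were requested",
                 length(idx), n))
  ord <- idx[order(-early[idx], idx)][seq_len(n)]
  co <- arrayInd(ord, dim(early))
  colnames(co) <- c("i", "j", "k")
  sc <- table(factor(co[, "k"], levels = sort(unique(co[, "k"]))))
  structure(co, dim_img = dim(early),
            slice_counts = setNames(as.integer(sc), names(sc)),
            class = c("voi_mask", class(co)))
}

#' Extract the image-derived input function from a carotid VOI
#'
#' Builds the whole-blood IDIF TAC in two phases.  In the bolus phase (frame
#' midpoints up to `phase_switch_s`) the value is the mean, over the
#' `slices_phase1` axial VOI slices holding the most VOI voxels (ties broken
#' by ascending slice index), of each slice's *maximum* voxel value — robust
#' to partial-volume dilution while counts change fast.  After the switch the
#' value is the maximum over all VOI slices of each slice's *mean*, which is
#' stabler at low late-phase counts.  The two phases are combined into one
#' continuous TAC.
#'
#' @param dyn a [dynamic_image()].
#' @param voi a `voi_mask` from [select_hottest_voxels()].
#' @param phase_switch_s time (seconds) separating the two phases; frames
#'   with midpoint at or before this time use the bolus-phase rule.
#' @param slices_phase1 number of slices averaged in the bolus phase.
#' @return A [tac()] of whole-blood activity.
#' @export
extract_idif <- function(dyn, voi, phase_switch_s = 45, slices_phase1 = 4L) {
  stopifnot(inherits(dyn, "dynamic_image"), inherits(voi, "voi_mask"))
  d <- dim(dyn$img)
  if (!identical(attr(voi, "dim_img"), d[1:3]))
    stop("VOI was selected on a different image grid")
  slices <- sort(unique(voi[, "k"]))
  if (length(slices) < slices_phase1)
    stop(sprintf("VOI spans %d slices; at least %d are required",
                 length(slices), slices_phase1))
  counts <- attr(voi, "slice_counts")
  # phase-1 slices: the slices_phase1 slices with most VOI voxels, ties by
  # ascending slice index
  ord <- order(-counts, as.integer(names(counts)))
  p1_slices <- as.integer(names(counts))[ord][seq_len(slices_phase1)]

  V <- matrix(dyn$img, prod(d[1:3]), d[4])
  flat <- voi[, "i"] + (voi[, "j"] - 1L) * d[1] +
    (voi[, "k"] - 1L) * d[1] * d[2]
  vals <- V[flat, , drop = FALSE]          # voi voxels x frames
  by_slice <- split(seq_len(nrow(voi)), voi[, "k"])

  slice_max <- vapply(by_slice, function(r)
    apply(vals[r, , drop = FALSE], 2, max), numeric(d[4]))
  slice_mean <- vapply(by_slice, function(r)
    colMeans(vals[r, , drop = FALSE]), numeric(d[4]))
  # columns of slice_* are slices in ascending k order
  k_order <- as.integer(names(by_slice))
  p1 <- rowMeans(slice_max[, match(p1_slices, k_order), drop = FALSE])
  p2 <- apply(slice_mean, 1, max)

  early <- dyn$schedule$mid_s <= phase_switch_s
  tac(dyn$schedule$mid_min, ifelse(early, p1, p2), dyn$schedule$duration_min)
}
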