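#' Late static image
#'
#' Frame-duration-weighted mean of the dynamic data over a late window
#' (default 50-70 min), the static accumulation image from which SUV is
#' computed.  Frames partially inside the window contribute with weight equal
#' to their overlap.
#'
#' @param dyn a [dynamic_image()].
#' @param window_min two-element window in minutes.
#' @return A 3D array (kBq/mL).
#' @export
static_image <- function(dyn, window_min = c(50, 70)) {
  stopifnot(inherits(dyn, "dynamic_image"))
  w <- frame_overlap_s(dyn$schedule, window_min * 60)
  if (all(w == 0))
    stop("no frame overlaps the window [", window_min[1], ", ",
         window_min[2], "] min")
  d <- dim(dyn$img)
  V <- matrix(dyn$img, prod(d[1:3]), d[4])
  array(as.vector(V %*% w) / sum(w), d[1:3])
}

#' Standardized uptake value image
#'
#' `SUV = concentration (kBq/mL) / (injected dose (MBq) / body weight (kg))`.
#'
#' @param static 3D activity image in kBq/mL (see [static_image()]).
#' @param dose_mbq injected dose in MBq (> 0).
#' @param weight_kg body weight in kg (> 0).
#' @return A `metric_image` of kind `"SUV"` (all voxels valid).
#' @export
suv_image <- function(static, dose_mbq, weight_kg) {
  if (!is.finite(dose_mbq) || dose_mbq <= 0) stop("dose_mbq must be positive")
  if (!is.finite(weight_kg) || weight_kg <= 0) stop("weight_kg must be positive")
  metric_image(static / (dose_mbq / weight_kg),
               array(TRUE, dim(static)), "SUV")
}

#' SUV ratio image
#'
#' Normalizes an SUV image by the mean SUV of the reference region (the
#' cerebellar cortex), yielding the SUVR image.
#'
#' @inheritParams normalize_to_reference
#' @param suv a `metric_image` of kind `"SUV"`.
#' @return A `metric_image` of kind `"SUVR"`.
#' @export
suvr_image <- function(suv, labels, label_id) {
  normalize_to_reference(suv, labels, label_id, kind = "SUVR")
}

#' Regional means of a metric image
#'
#' Arithmetic mean of the metric over the valid voxels of each named region.
#' Regions with no valid voxels are dropped from the result.
#'
#' @param metric a `metric_image`.
#' @param labels integer 3D label volume on the metric's grid.
#' @param region_ids named integer vector mapping region names to labels
#'   (default [pib_region_ids()] without the carotid search region).
#' @return A data frame with columns `region`, `metric`, `value`,
#'   `n_voxels`.
#' @export
regional_means <- function(metric, labels, region_ids = NULL) {
  stopifnot(inherits(metric, "metric_image"))
  if (!identical(dim(labels), dim(metric$values)))
    stop("label grid does not match the metric image grid")
  if (is.null(region_ids)) {
    region_ids <- pib_region_ids()
    region_ids <- region_ids[names(region_ids) != "ica"]
  }
  rows <- lapply(names(region_ids), function(nm) {
    sel <- labels == region_ids[[nm]] & metric$valid
    if (!any(sel)) return(NULL)
    data.frame(region = nm, metric = metric$kind,
               value = mean(metric$values[sel]), n_voxels = sum(sel))
  })
  do.call(rbind, rows)
}

#' Cortical maximum and posterior cingulate value
#'
#' From one subject's regional means of a single metric, returns the cortical
#' maximum (the largest mean among the eight lobar regions: frontal,
#' temporal, parietal, occipital, left and right) together with the posterior
#' cingulate cortex (PCC) value.
#'
#' @param regional data frame with columns `region` and `value` for one
#'   subject and one metric (as from [regional_means()]).
#' @return Named numeric vector `c(cortical_max = , pcc = )`.
#' @export
cortical_summary <- function(regional) {
  need <- c(pib_cortical_regions(), "pcc")
  miss <- setdiff(need, regional$region)
  if (length(miss) > 0)
    stop("missing regions: ", paste(miss, collapse = ", "))
  lob <- regional$value[match(pib_cortical_regions(), regional$region)]
  c(cortical_max = max(lob),
    pcc = regional$value[match("pcc", regional$region)])
}
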