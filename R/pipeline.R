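#' Analysis configuration
#'
#' Collects every tunable of the quantification pipeline with its default:
#' the Logan linear-phase start `t_star_min` (50 min, i.e. the last 50-70 min
#' of the scan), the static SUV window (50-70 min), the reference region
#' (cerebellar cortex), the carotid VOI size (30 hottest voxels from the
#' 10-40 s early image), the IDIF phase switch (45 s, the midpoint of the
#' 40-50 s range) and slice count (4, within the 3-5 range), the Hill
#' metabolite-correction constants, the plasma-to-whole-blood ratio (1) and
#' an optional reference-tissue `k2_ref` for the reference Logan (NULL:
#' two-integral form).
#'
#' @param t_star_min Logan linear-phase start (minutes).
#' @param static_window_min late static window (minutes).
#' @param reference_region name of the reference region.
#' @param search_region name of the carotid IDIF search region.
#' @param n_voi_voxels hottest-voxel count of the carotid VOI.
#' @param early_window_s early-average window (seconds).
#' @param phase_switch_s IDIF phase switch (seconds).
#' @param slices_phase1 slices used by the bolus-phase IDIF rule.
#' @param hill [hill_params()] for metabolite correction.
#' @param pb_ratio plasma-to-whole-blood ratio.
#' @param k2_ref optional reference-tissue efflux constant (1/min).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(t_star_min = 50, static_window_min = c(50, 70),
                            reference_region = "cerebellum",
                            search_region = "ica",
                            n_voi_voxels = 30L, early_window_s = c(10, 40),
                            phase_switch_s = 45, slices_phase1 = 4L,
                            hill = hill_params(), pb_ratio = 1,
                            k2_ref = NULL) {
  structure(list(t_star_min = t_star_min,
                 static_window_min = static_window_min,
                 reference_region = reference_region,
                 search_region = search_region,
                 n_voi_voxels = as.integer(n_voi_voxels),
                 early_window_s = early_window_s,
                 phase_switch_s = phase_switch_s,
                 slices_phase1 = as.integer(slices_phase1),
                 hill = hill, pb_ratio = pb_ratio, k2_ref = k2_ref),
            class = "analysis_config")
}

#' Quantify one dynamic PiB study
#'
#' Runs the whole noninvasive quantification chain on a study (a
#' [build_phantom()] result or a bundle from [read_study()]):
#' \enumerate{
#'   \item early-phase average image and hottest-voxel carotid VOI;
#'   \item two-phase IDIF extraction and Hill metabolite correction to the
#'     plasma input Cp;
#'   \item voxel-wise plasma-input Logan DV image, normalized to the
#'     cerebellar mean to give the DVR_L image;
#'   \item voxel-wise reference-tissue Logan DVR_r image using the
#'     cerebellar mean TAC;
#'   \item late static image, SUV (dose/weight) and SUVR;
#'   \item regional means of DVR_L, DVR_r and SUVR, and a QC record.
#' }
#'
#' @param study list with elements `dyn` ([dynamic_image()]), `labels` and
#'   `subject` (list with `dose_mbq`, `weight_kg`).
#' @param config an [analysis_config()].
#' @return An object of class `pib_quant`: list with `input` (the
#'   [plasma_input()] result), `voi`, `images` (named `metric_image`s `dv`,
#'   `dvr_l`, `dvr_r`, `suv`, `suvr`), `regional` (long data frame), and
#'   `qc`.
#' @export
quantify_study <- function(study, config = analysis_config()) {
  stopifnot(inherits(study$dyn, "dynamic_image"))
  check_labels(study$dyn, study$labels)
  ids <- pib_region_ids()
  ref_id <- ids[[config$reference_region]]
  search_id <- ids[[config$search_region]]

  early <- early_average_image(study$dyn, config$early_window_s)
  voi <- select_hottest_voxels(early, study$labels, n = config$n_voi_voxels,
                               label_id = search_id)
  idif <- extract_idif(study$dyn, voi,
                       phase_switch_s = config$phase_switch_s,
                       slices_phase1 = config$slices_phase1)
  input <- plasma_input(idif, config$hill, ratio = config$pb_ratio)

  dv <- logan_image(study$dyn, input$cp, t_star = config$t_star_min,
                    kind = "DV")
  dvr_l <- normalize_to_reference(dv, study$labels, ref_id, kind = "DVR_L")
  cref <- region_mean_tac(study$dyn, study$labels, ref_id)
  dvr_r <- logan_image(study$dyn, cref, t_star = config$t_star_min,
                       kind = "DVR_r", k2_ref = config$k2_ref)

  if (is.null(study$subject$dose_mbq) || is.null(study$subject$weight_kg))
    stop("subject metadata must provide dose_mbq and weight_kg for SUV")
  stat <- static_image(study$dyn, config$static_window_min)
  suv <- suv_image(stat, study$subject$dose_mbq, study$subject$weight_kg)
  suvr <- suvr_image(suv, study$labels, ref_id)

  regional <- rbind(regional_means(dvr_l, study$labels),
                    regional_means(dvr_r, study$labels),
                    regional_means(suvr, study$labels))

  qc <- list(
    reference_dv_mean = dvr_l$reference_value,
    reference_suv_mean = suvr$reference_value,
    n_invalid_dv = dv$n_invalid,
    n_invalid_dvr_r = dvr_r$n_invalid,
    n_clipped_parent_fraction = input$n_clipped,
    regional_logan_r2 = regional_logan_r2(study, input$cp, config)
  )
  structure(list(input = input, voi = voi,
                 images = list(dv = dv, dvr_l = dvr_l, dvr_r = dvr_r,
                               suv = suv, suvr = suvr),
                 regional = regional, qc = qc, config = config),
            class = "pib_quant")
}

# per-region Logan plot r^2 on region-mean TACs, for QC reporting
regional_logan_r2 <- function(study, cp, config) {
  ids <- pib_region_ids()
  ids <- ids[names(ids) != "ica"]
  vapply(names(ids), function(nm) {
    ct <- region_mean_tac(study$dyn, study$labels, ids[[nm]])
    out <- tryCatch(logan_fit(ct, cp, t_star = config$t_star_min)$r.squared,
                    error = function(e) NA_real_)
    out
  }, numeric(1))
}

#' @export
print.pib_quant <- function(x, ...) {
  cat("PiB quantification result\n")
  print(x$input)
  cat(sprintf("  cerebellar DV %.3f mL/g; invalid voxels: DV %d, DVR_r %d\n",
              x$qc$reference_dv_mean, x$qc$n_invalid_dv, x$qc$n_invalid_dvr_r))
  invisible(x)
}

#' @export
summary.pib_quant <- function(object, ...) {
  wide <- stats::reshape(object$regional[, c("region", "metric", "value")],
                         direction = "wide", idvar = "region",
                         timevar = "metric")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide
}

#' Run the pipeline on a study directory
#'
#' Reads a study bundle from `dir` (see [read_study()]), quantifies it, and
#' (optionally) writes the DV/DVR_L/DVR_r/SUVR volumes, the IDIF/Cp curves,
#' the regional table and a QC record to `out_dir`.
#'
#' @param dir study directory (as written by [write_study()]).
#' @param config an [analysis_config()].
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return The [quantify_study()] result, invisibly when writing.
#' @export
run_pipeline <- function(dir, config = analysis_config(), out_dir = NULL) {
  study <- read_study(dir)
  q <- quantify_study(study, config)
  if (is.null(out_dir)) return(q)
  write_quant(q, out_dir)
  invisible(q)
}
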