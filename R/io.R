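#' Read a dynamic PET image with its frame schedule
#'
#' Loads a 4D NIfTI-1 volume (activity in kBq/mL, decay-corrected to scan
#' start by convention) and its frame-timing JSON, validating that the
#' fourth image dimension matches the schedule length.
#'
#' @param path 4D NIfTI file (.nii or .nii.gz).
#' @param frames_path frame-schedule JSON (see [read_frame_schedule()]).
#' @return A [dynamic_image()].
#' @export
read_dynamic <- function(path, frames_path) {
  nii <- RNifti::readNifti(path)
  schedule <- read_frame_schedule(frames_path)
  d <- dim(nii)
  if (length(d) != 4L)
    stop("expected a 4D dynamic volume, got ", length(d), " dimensions")
  if (d[4] != nrow(schedule))
    stop(sprintf("frame-count mismatch: image has %d frames, schedule has %d",
                 d[4], nrow(schedule)))
  vox <- RNifti::pixdim(nii)[1:3]
  if (any(!is.finite(vox)) || any(vox <= 0)) vox <- c(2, 2, 2.76)
  dynamic_image(array(as.numeric(nii), d), schedule, vox)
}

#' Write / read a synthetic study bundle
#'
#' `write_study` writes one phantom to a directory as the pipeline's
#' interchange formats: `dynamic.nii.gz` (4D), `labels.nii.gz` (3D integer),
#' `frames.json`, `truth.csv` (region, K1, k2, k3, k4, DV, DVR) and
#' `subject.csv` (id, group, dose_MBq, weight_kg, seed).  `read_study` loads
#' such a directory (the truth table only if present) into the bundle
#' structure accepted by [quantify_study()].
#'
#' @param phantom a [build_phantom()] result.
#' @param dir target directory (created if missing).
#' @return `write_study` returns `dir` invisibly; `read_study` returns a
#'   list with `dyn`, `labels`, `subject` and (if available) `truth`.
#' @export
write_study <- function(phantom, dir) {
  stopifnot(inherits(phantom, "pib_phantom"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vox <- phantom$dyn$voxel_mm
  dyn_nii <- RNifti::asNifti(phantom$dyn$img,
                             pixdim = c(vox, sum(phantom$dyn$schedule$duration_s)))
  RNifti::writeNifti(dyn_nii, file.path(dir, "dynamic.nii.gz"))
  lab_nii <- RNifti::asNifti(phantom$labels, pixdim = vox)
  RNifti::writeNifti(lab_nii, file.path(dir, "labels.nii.gz"))
  write_frame_schedule(phantom$dyn$schedule, file.path(dir, "frames.json"))
  write.csv(phantom$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  subj <- data.frame(id = phantom$id %||% "S01",
                     group = phantom$subject$group,
                     dose_MBq = phantom$subject$dose_mbq,
                     weight_kg = phantom$subject$weight_kg,
                     seed = phantom$spec$seed)
  write.csv(subj, file.path(dir, "subject.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  dyn <- read_dynamic(file.path(dir, "dynamic.nii.gz"),
                      file.path(dir, "frames.json"))
  labels <- RNifti::readNifti(file.path(dir, "labels.nii.gz"))
  labels <- array(as.integer(labels), dim(labels))
  if (!identical(dim(labels), dim(dyn$img)[1:3]))
    stop("label grid does not match the dynamic image grid")
  subj_df <- read.csv(file.path(dir, "subject.csv"))
  study <- list(
    dyn = dyn, labels = labels,
    subject = list(dose_mbq = subj_df$dose_MBq[1],
                   weight_kg = subj_df$weight_kg[1],
                   group = as.character(subj_df$group[1])),
    id = as.character(subj_df$id[1]))
  truth_path <- file.path(dir, "truth.csv")
  if (file.exists(truth_path)) study$truth <- read.csv(truth_path)
  study
}

#' Write quantification outputs
#'
#' Writes the metric volumes (`dv.nii.gz`, `dvr_l.nii.gz`, `dvr_r.nii.gz`,
#' `suvr.nii.gz`), the input curves (`input.csv`: time_min,
#' idif_kBq_per_mL, parent_fraction, cp_kBq_per_mL), the regional table
#' (`regional.csv`) and a QC JSON (`qc.json`).
#'
#' @param q a [quantify_study()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_quant <- function(q, dir) {
  stopifnot(inherits(q, "pib_quant"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("dv", "dvr_l", "dvr_r", "suvr")) {
    img <- q$images[[nm]]$values
    RNifti::writeNifti(RNifti::asNifti(img), file.path(dir, paste0(nm, ".nii.gz")))
  }
  inp <- data.frame(time_min = q$input$idif$time_min,
                    idif_kBq_per_mL = q$input$idif$activity,
                    parent_fraction = q$input$parent_fraction,
                    cp_kBq_per_mL = q$input$cp$activity)
  write.csv(inp, file.path(dir, "input.csv"), row.names = FALSE)
  write.csv(q$regional, file.path(dir, "regional.csv"), row.names = FALSE)
  jsonlite::write_json(q$qc, file.path(dir, "qc.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
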