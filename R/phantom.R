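#' Region labels of the synthetic brain phantom
#'
#' The phantom reduces a full anatomical parcellation to the named regions
#' the analysis actually aggregates to: the internal-carotid search region
#' (for the IDIF), the cerebellar cortex (the reference), the eight lobar
#' cortices (frontal/temporal/parietal/occipital, left and right), the
#' posterior cingulate cortex and white matter.
#'
#' @return `pib_region_ids()`: named integer vector of label values;
#'   `pib_cortical_regions()`: the eight lobar region names entering the
#'   cortical maximum.
#' @export
pib_region_ids <- function() {
  c(ica = 1L, cerebellum = 2L,
    frontal_l = 3L, frontal_r = 4L, temporal_l = 5L, temporal_r = 6L,
    parietal_l = 7L, parietal_r = 8L, occipital_l = 9L, occipital_r = 10L,
    pcc = 11L, white_matter = 12L)
}

#' @rdname pib_region_ids
#' @export
pib_cortical_regions <- function() {
  c("frontal_l", "frontal_r", "temporal_l", "temporal_r",
    "parietal_l", "parietal_r", "occipital_l", "occipital_r")
}

#' Schematic label volume for the phantom
#'
#' Paints the named regions as axis-aligned blocks in a 3D grid (z is the
#' axial/slice direction, y anterior-to-posterior): cerebellum in the lowest
#' slices, temporal lobes laterally above it, the remaining lobes in the
#' upper slices split left/right, a central white-matter core, a small
#' midline PCC block, and a carotid column of at least 30 voxels spread over
#' at least 5 slices.  Later paints overwrite earlier ones, so regions are
#' disjoint by construction; emptiness is checked before returning.
#'
#' @param dim integer grid dimensions, each at least `c(16, 16, 12)`.
#' @return Integer 3D array of labels (0 = background).
#' @export
phantom_labels <- function(dim = c(32, 32, 32)) {
  nx <- dim[1]; ny <- dim[2]; nz <- dim[3]
  if (nx < 16 || ny < 16 || nz < 12)
    stop("phantom grid must be at least 16 x 16 x 12")
  lab <- array(0L, dim)
  fr <- function(n, a, b) max(1L, ceiling(a * n)):min(n, floor(b * n))
  ids <- pib_region_ids()
  xl <- fr(nx, 0.10, 0.45); xr <- fr(nx, 0.55, 0.90); xc <- fr(nx, 0.35, 0.65)
  z_top <- fr(nz, 0.55, 0.90)

  lab[xc, fr(ny, 0.30, 0.60), fr(nz, 0.30, 0.75)] <- ids[["white_matter"]]
  lab[xl, fr(ny, 0.30, 0.70), fr(nz, 0.30, 0.50)] <- ids[["temporal_l"]]
  lab[xr, fr(ny, 0.30, 0.70), fr(nz, 0.30, 0.50)] <- ids[["temporal_r"]]
  lab[xl, fr(ny, 0.10, 0.40), z_top] <- ids[["frontal_l"]]
  lab[xr, fr(ny, 0.10, 0.40), z_top] <- ids[["frontal_r"]]
  lab[xl, fr(ny, 0.42, 0.65), z_top] <- ids[["parietal_l"]]
  lab[xr, fr(ny, 0.42, 0.65), z_top] <- ids[["parietal_r"]]
  lab[xl, fr(ny, 0.70, 0.90), z_top] <- ids[["occipital_l"]]
  lab[xr, fr(ny, 0.70, 0.90), z_top] <- ids[["occipital_r"]]
  lab[fr(nx, 0.20, 0.80), fr(ny, 0.50, 0.90), fr(nz, 0.05, 0.25)] <-
    ids[["cerebellum"]]
  lab[fr(nx, 0.40, 0.60), fr(ny, 0.60, 0.78), fr(nz, 0.45, 0.62)] <-
    ids[["pcc"]]

  # carotid column: 2 x 3 cross-section over >= 5 slices near the skull base
  cx <- max(2L, round(nx / 2)); cy <- max(1L, floor(0.35 * ny))
  n_sl <- max(5L, round(0.2 * nz))
  z0 <- max(1L, floor(0.25 * nz)); z1 <- min(nz, z0 + n_sl - 1L)
  lab[(cx - 1L):cx, cy:(cy + 2L), z0:z1] <- ids[["ica"]]

  counts <- vapply(ids, function(id) sum(lab == id), integer(1))
  if (any(counts == 0L))
    stop("empty phantom region(s): ",
         paste(names(ids)[counts == 0L], collapse = ", "))
  ica_slices <- length(unique(which(lab == ids[["ica"]], arr.ind = TRUE)[, 3]))
  if (counts[["ica"]] < 30L || ica_slices < 5L)
    stop("carotid region must have >= 30 voxels over >= 5 slices")
  lab
}

#' Regional 2TC kinetics hitting prescribed DVR targets
#'
#' Builds the per-region kinetic table from target distribution-volume ratios
#' (relative to the cerebellar reference).  The cerebellum is a 1TC region
#' with `DV = K1/k2`; each target region shares the cerebellar `K1` and `k2`
#' (delivery is not amyloid-dependent) and obtains its excess DV through the
#' binding compartment, `k3 = k4 * (DVR - 1)` (clamped at 0 when a sampled
#' target falls below 1).  White matter keeps `DVR = 1` by construction but
#' with halved delivery and slower efflux, reproducing its slow kinetics.
#'
#' @param dvr named vector of target DVRs covering the eight lobar regions
#'   and `pcc` (a `white_matter` entry is optional, default 1).
#' @param K1 cerebellar/cortical delivery (mL/min/g).
#' @param k2 cerebellar/cortical efflux (1/min); the reference DV is `K1/k2`.
#' @param k4 release constant of the binding compartment (1/min).
#' @return Data frame with columns `region`, `K1`, `k2`, `k3`, `k4`, `DV`,
#'   `DVR`.
#' @export
region_kinetics <- function(dvr, K1 = 0.3, k2 = 0.2, k4 = 0.25) {
  need <- c(pib_cortical_regions(), "pcc")
  miss <- setdiff(need, names(dvr))
  if (length(miss) > 0)
    stop("dvr is missing regions: ", paste(miss, collapse = ", "))
  dv_ref <- K1 / k2
  rows <- list(data.frame(region = "cerebellum", K1 = K1, k2 = k2,
                          k3 = 0, k4 = 0))
  for (nm in need) {
    k3 <- max(0, k4 * (dvr[[nm]] - 1))
    rows[[length(rows) + 1L]] <-
      data.frame(region = nm, K1 = K1, k2 = k2, k3 = k3, k4 = k4)
  }
  dvr_wm <- if ("white_matter" %in% names(dvr)) dvr[["white_matter"]] else 1
  K1w <- K1 / 2
  rows[[length(rows) + 1L]] <-
    data.frame(region = "white_matter", K1 = K1w,
               k2 = K1w / (dv_ref * dvr_wm), k3 = 0, k4 = 0)
  out <- do.call(rbind, rows)
  out$DV <- vapply(seq_len(nrow(out)), function(i)
    total_dv(kinetic_params(out$K1[i], out$k2[i], out$k3[i], out$k4[i])),
    numeric(1))
  out$DVR <- out$DV / out$DV[out$region == "cerebellum"]
  out
}

#' Specification of a synthetic dynamic PiB study
#'
#' Collects everything that determines one phantom subject: grid geometry,
#' per-region kinetics (or the group/DVR targets they are derived from), the
#' arterial input parameters, the Hill metabolism model, the noise scale and
#' the subject metadata.  The seed fully determines the generated study.
#'
#' @param group `"CTL"` or `"eAD"`; when `dvr` and `kinetics` are absent the
#'   group's mean DVR targets ([pib_group_targets()]) are used.
#' @param dvr optional named DVR targets passed to [region_kinetics()].
#' @param kinetics optional kinetic table overriding `dvr` (columns `region`,
#'   `K1`, `k2`, `k3`, `k4`).
#' @param dim,voxel_mm grid dimensions and voxel size (mm).
#' @param input [blood_input_params()].
#' @param hill [hill_params()] of the simulated metabolism.
#' @param noise_scale Gaussian noise scale: each frame value is perturbed
#'   with SD `noise_scale * sqrt(activity / duration_min)`, mimicking
#'   count statistics; 0 gives a noise-free study.
#' @param dose_mbq,weight_kg subject metadata for SUV.
#' @param ica_gradient linear intensity fall-off (0-1) across the carotid
#'   column from its hottest central voxels outward; 0 (default) makes every
#'   carotid voxel carry the whole-blood curve exactly.
#' @param seed integer random seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(group = c("CTL", "eAD"), dvr = NULL, kinetics = NULL,
                         dim = c(32, 32, 32), voxel_mm = c(2, 2, 2.76),
                         input = blood_input_params(), hill = hill_params(),
                         noise_scale = 0.15, dose_mbq = 740, weight_kg = 60,
                         ica_gradient = 0, seed = 1L) {
  group <- match.arg(group)
  if (is.null(kinetics)) {
    if (is.null(dvr)) {
      tg <- pib_group_targets(group)
      dvr <- setNames(tg$mean, tg$region)
    }
    kinetics <- region_kinetics(dvr)
  }
  if (!is.finite(dose_mbq) || dose_mbq <= 0 ||
      !is.finite(weight_kg) || weight_kg <= 0)
    stop("dose_mbq and weight_kg must be positive")
  if (noise_scale < 0) stop("noise_scale must be nonnegative")
  if (ica_gradient < 0 || ica_gradient >= 1)
    stop("ica_gradient must be in [0, 1)")
  structure(list(group = group, kinetics = kinetics, dim = dim,
                 voxel_mm = voxel_mm, input = input, hill = hill,
                 noise_scale = noise_scale, dose_mbq = dose_mbq,
                 weight_kg = weight_kg, ica_gradient = ica_gradient,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# frame-duration averages of a curve sampled on the 1-s fine grid
frame_average <- function(schedule, t_s, y) {
  Fint <- cumtrapz_grid(t_s, y)
  i0 <- match(schedule$start_s, t_s)
  i1 <- match(schedule$end_s, t_s)
  if (anyNA(i0) || anyNA(i1))
    stop("frame boundaries must lie on the fine simulation grid")
  (Fint[i1] - Fint[i0]) / schedule$duration_s
}

#' Build a synthetic dynamic PiB PET study
#'
#' Generates the 4D dynamic image, label volume, ground-truth table and true
#' input curves for one subject.  Tissue TACs are the 2TC response to the
#' metabolite-corrected plasma input (the whole-blood curve times the clipped
#' Hill parent fraction), computed on a 1-s grid and then averaged over each
#' frame's duration — every voxel of a region carries the region's exact
#' frame-averaged TAC before noise.  Carotid voxels carry the frame-averaged
#' whole-blood curve.  Noise is zero-mean Gaussian with SD
#' `noise_scale * sqrt(activity / duration_min)` per voxel and frame, and the
#' whole study is reproducible from the seed.
#'
#' @param spec a [phantom_spec()].
#' @param schedule frame schedule (default [pib_frame_schedule()]).
#' @return A `pib_phantom` list: `dyn` ([dynamic_image()]), `labels`,
#'   `truth` (region kinetics with ground-truth `DV`/`DVR`), `input_truth`
#'   (list with the true whole-blood and plasma [tac()]s at frame midpoints
#'   and the generating parameters), `subject`, `spec`.
#' @export
build_phantom <- function(spec, schedule = pib_frame_schedule()) {
  stopifnot(inherits(spec, "phantom_spec"))
  labels <- phantom_labels(spec$dim)
  total_s <- sum(schedule$duration_s)
  t_s <- seq(0, total_s, by = 1)
  t_min <- t_s / 60
  cb <- blood_input(t_min, spec$input)
  cp <- hill_fraction(t_min, spec$hill, clip = TRUE) * cb

  kin <- spec$kinetics
  reg_tac <- lapply(seq_len(nrow(kin)), function(i) {
    kp <- kinetic_params(kin$K1[i], kin$k2[i], kin$k3[i], kin$k4[i])
    frame_average(schedule, t_s, tissue_tac(kp, cp, t_min))
  })
  names(reg_tac) <- kin$region
  cb_frames <- frame_average(schedule, t_s, cb)
  cp_frames <- frame_average(schedule, t_s, cp)

  ids <- pib_region_ids()
  d <- spec$dim
  nf <- nrow(schedule)
  V <- matrix(0, prod(d), nf)
  for (nm in names(reg_tac))
    V[labels == ids[[nm]], ] <- rep(reg_tac[[nm]], each = sum(labels == ids[[nm]]))
  ica_idx <- which(labels == ids[["ica"]])
  if (spec$ica_gradient > 0) {
    co <- arrayInd(ica_idx, d)
    ctr <- colMeans(co)
    dist <- sqrt(rowSums(sweep(co, 2, ctr)^2))
    gain <- 1 - spec$ica_gradient * dist / max(dist)
    V[ica_idx, ] <- gain %o% cb_frames
  } else {
    V[ica_idx, ] <- rep(cb_frames, each = length(ica_idx))
  }

  if (spec$noise_scale > 0) {
    sdm <- spec$noise_scale *
      sqrt(pmax(V, 0) / rep(schedule$duration_min, each = prod(d)))
    V <- with_seed(spec$seed, V + rnorm(length(V), sd = sdm))
  }

  truth <- kin
  truth$DV <- vapply(seq_len(nrow(kin)), function(i)
    total_dv(kinetic_params(kin$K1[i], kin$k2[i], kin$k3[i], kin$k4[i])),
    numeric(1))
  truth$DVR <- truth$DV / truth$DV[truth$region == "cerebellum"]

  structure(list(
    dyn = dynamic_image(array(V, c(d, nf)), schedule, spec$voxel_mm),
    labels = labels,
    truth = truth,
    input_truth = list(
      blood = tac(schedule$mid_min, cb_frames, schedule$duration_min),
      cp = tac(schedule$mid_min, cp_frames, schedule$duration_min),
      input = spec$input, hill = spec$hill),
    subject = list(dose_mbq = spec$dose_mbq, weight_kg = spec$weight_kg,
                   group = spec$group),
    spec = spec),
    class = "pib_phantom")
}

#' @export
print.pib_phantom <- function(x, ...) {
  cat(sprintf("Synthetic PiB study (%s-like, seed %d, noise %.2g)\n",
              x$subject$group, x$spec$seed, x$spec$noise_scale))
  print(x$dyn)
  cat("Ground-truth DVR: ",
      paste(sprintf("%s=%.2f", x$truth$region, x$truth$DVR), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
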