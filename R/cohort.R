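#' Group-level DVR targets for cohort simulation
#'
#' Per-region ground-truth DVR means and standard deviations used as the
#' between-subject distribution when simulating a cohort.  The defaults are
#' the regional plasma-input Logan DVR values reported for healthy controls
#' and early-AD patients in a 35-subject \[11C\]PiB PET/MRI population
#' (frontal/temporal/parietal/occipital left and right, and the posterior
#' cingulate), so a simulated cohort carries the same group contrast as that
#' study.
#'
#' @param group `"CTL"` or `"eAD"`.
#' @return Data frame with columns `region`, `mean`, `sd`.
#' @export
pib_group_targets <- function(group = c("CTL", "eAD")) {
  group <- match.arg(group)
  regions <- c(pib_cortical_regions(), "pcc")
  if (group == "CTL") {
    m <- c(1.22, 1.24, 1.13, 1.13, 1.18, 1.19, 1.16, 1.16, 1.30)
    s <- c(0.14, 0.13, 0.06, 0.06, 0.12, 0.13, 0.07, 0.08, 0.16)
  } else {
    m <- c(2.14, 2.17, 1.72, 1.74, 2.11, 2.19, 1.73, 1.78, 2.43)
    s <- c(0.32, 0.38, 0.22, 0.23, 0.31, 0.38, 0.25, 0.24, 0.42)
  }
  data.frame(region = regions, mean = m, sd = s)
}

#' Simulate a two-group cohort of synthetic PiB studies
#'
#' Draws per-subject regional DVR targets from the configured group
#' distributions and builds one phantom per subject.  Regional draws within
#' a subject are correlated (a common amyloid-burden factor with loading
#' `region_cor`, plus independent regional variation), reflecting that an
#' amyloid-positive subject is elevated across cortex.  Between-subject
#' physiological variability is added on top: log-normal delivery (`K1`) and
#' efflux (`k2`) variation shared by all of a subject's regions, a variable
#' injected-peak amplitude, and uniform dose (700-750 MBq) and normal body
#' weight (60 +/- 8 kg).  Sampled DVRs below 1 are realised as `k3 = 0`
#' (no binding), so the realised ground truth is floored at 1.
#'
#' Subject seeds are derived deterministically from `seed`, so the whole
#' cohort is reproducible and individual subjects can be rebuilt in
#' isolation.
#'
#' @param n_ctl,n_ad subjects per group (>= 1).
#' @param targets_ctl,targets_ad group target tables as
#'   [pib_group_targets()] (columns `region`, `mean`, `sd`; `sd` may be 0).
#' @param dim phantom grid (default `c(20, 20, 16)`, sized for cohort work).
#' @param noise_scale voxel noise scale per [phantom_spec()].
#' @param region_cor loading (0-1) of the shared per-subject burden factor.
#' @param k1_cv,k2_cv coefficients of variation of the subject-level
#'   delivery and efflux constants.
#' @param amp_cv coefficient of variation of the arterial peak amplitude.
#' @param seed integer seed for the whole cohort.
#' @return A list of [build_phantom()] results with per-subject `id` fields;
#'   attribute `subjects` holds the subject table (id, group, dose, weight,
#'   seed).
#' @export
simulate_cohort <- function(n_ctl = 16L, n_ad = 19L,
                            targets_ctl = pib_group_targets("CTL"),
                            targets_ad = pib_group_targets("eAD"),
                            dim = c(20, 20, 16), noise_scale = 0.15,
                            region_cor = 0.7, k1_cv = 0.1, k2_cv = 0.1,
                            amp_cv = 0.15, seed = 1L) {
  if (n_ctl < 1L || n_ad < 1L) stop("each group needs at least one subject")
  for (tg in list(targets_ctl, targets_ad)) {
    if (!all(c("region", "mean", "sd") %in% names(tg)))
      stop("group targets need columns region, mean, sd")
    if (any(tg$sd < 0)) stop("target SDs must be nonnegative")
  }
  groups <- c(rep("CTL", n_ctl), rep("eAD", n_ad))
  n <- length(groups)
  out <- vector("list", n)
  subjects <- data.frame(id = sprintf("S%02d", seq_len(n)), group = groups,
                         dose_mbq = NA_real_, weight_kg = NA_real_,
                         seed = NA_integer_)
  base_input <- blood_input_params()
  with_seed(seed, {
    for (i in seq_len(n)) {
      tg <- if (groups[i] == "CTL") targets_ctl else targets_ad
      z_subj <- rnorm(1)
      z_reg <- rnorm(nrow(tg))
      z <- region_cor * z_subj + sqrt(1 - region_cor^2) * z_reg
      dvr <- setNames(pmax(tg$mean + tg$sd * z, 0.2), tg$region)
      K1 <- 0.3 * exp(rnorm(1, sd = k1_cv) - k1_cv^2 / 2)
      k2 <- 0.2 * exp(rnorm(1, sd = k2_cv) - k2_cv^2 / 2)
      kin <- region_kinetics(dvr, K1 = K1, k2 = k2)
      amp <- base_input$amplitudes_kbq *
        exp(rnorm(1, sd = amp_cv) - amp_cv^2 / 2)
      input <- blood_input_params(base_input$peak_time_min, amp,
                                  base_input$decay_per_min)
      dose <- runif(1, 700, 750)
      weight <- max(35, rnorm(1, 60, 8))
      sseed <- (seed %% 100000L) * 10000L + i
      sp <- phantom_spec(group = groups[i], kinetics = kin, dim = dim,
                         input = input, noise_scale = noise_scale,
                         dose_mbq = dose, weight_kg = weight, seed = sseed)
      ph <- build_phantom(sp)
      ph$id <- subjects$id[i]
      out[[i]] <- ph
      subjects$dose_mbq[i] <- dose
      subjects$weight_kg[i] <- weight
      subjects$seed[i] <- sseed
    }
  })
  attr(out, "subjects") <- subjects
  out
}

#' Quantify every subject of a simulated cohort
#'
#' Runs the full quantification pipeline ([quantify_study()]) on each
#' phantom and stacks the regional results into one long table.
#'
#' @param cohort list of phantoms from [simulate_cohort()].
#' @param config an [analysis_config()].
#' @return Data frame with columns `subject`, `group`, `region`, `metric`,
#'   `value`, `n_voxels`, plus `truth_dvr` where ground truth is known.
#' @export
quantify_cohort <- function(cohort, config = analysis_config()) {
  rows <- lapply(cohort, function(ph) {
    q <- quantify_study(ph, config)
    reg <- q$regional
    reg$subject <- ph$id %||% "S01"
    reg$group <- ph$subject$group
    reg$truth_dvr <- ph$truth$DVR[match(reg$region, ph$truth$region)]
    reg
  })
  do.call(rbind, rows)
}

#' Regional agreement between two metrics across a cohort
#'
#' Pools the per-subject regional values of two metrics (lobar regions plus
#' PCC by default), regresses the first on the second by ordinary least
#' squares with Pearson r-squared, and computes the Bland-Altman agreement
#' of the pair after regression correction.
#'
#' @param table long table from [quantify_cohort()].
#' @param metric_y,metric_x metric names, e.g. `"DVR_L"` and `"DVR_r"`.
#' @param regions regions to pool (default lobes + PCC).
#' @return List with `regression` ([pearson_regression()] result),
#'   `bland_altman` ([bland_altman()] result) and the paired data frame.
#' @export
metric_agreement <- function(table, metric_y, metric_x,
                             regions = c(pib_cortical_regions(), "pcc")) {
  sub <- table[table$region %in% regions &
                 table$metric %in% c(metric_x, metric_y), ]
  wide <- merge(
    sub[sub$metric == metric_x, c("subject", "region", "value")],
    sub[sub$metric == metric_y, c("subject", "region", "value")],
    by = c("subject", "region"), suffixes = c("_x", "_y"))
  reg <- pearson_regression(wide$value_x, wide$value_y)
  ba <- bland_altman(wide$value_x, wide$value_y, regression_correct = TRUE)
  list(regression = reg, bland_altman = ba, data = wide)
}
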