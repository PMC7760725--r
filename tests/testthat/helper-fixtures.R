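# Shared test fixtures, built in code.

# test-local trapezoidal frame averaging of a continuous curve sampled on a
# 1-s grid (independent of the package's internal helper)
tt_frame_avg <- function(schedule, t_s, y) {
  vapply(seq_len(nrow(schedule)), function(i) {
    sel <- t_s >= schedule$start_s[i] & t_s <= schedule$end_s[i]
    ts <- t_s[sel]; ys <- y[sel]
    sum(0.5 * (ys[-1] + ys[-length(ys)]) * diff(ts)) / schedule$duration_s[i]
  }, numeric(1))
}

# analytic plasma input on a fine grid plus its frame-averaged tac
tt_cp_fixture <- function(schedule = pib_frame_schedule(), by_s = 1) {
  t_s <- seq(0, sum(schedule$duration_s), by = by_s)
  t_min <- t_s / 60
  cp_fine <- blood_input(t_min) * hill_fraction(t_min)
  list(t_s = t_s, t_min = t_min, cp_fine = cp_fine,
       cp = tac(schedule$mid_min, tt_frame_avg(schedule, t_s, cp_fine),
                schedule$duration_min))
}

# frame-averaged tissue tac for given kinetics, on the same fixture grid
tt_ct_frames <- function(kp, fx, schedule = pib_frame_schedule()) {
  ct_fine <- tissue_tac(kp, fx$cp_fine, fx$t_min)
  tac(schedule$mid_min, tt_frame_avg(schedule, fx$t_s, ct_fine),
      schedule$duration_min)
}

# a tiny noise-free phantom with three distinct DVR levels {1, 1.5, 2}
tt_three_level_dvr <- function() {
  setNames(c(1.5, 1.5, 1, 1, 2, 2, 1, 1, 2),
           c(pib_cortical_regions(), "pcc"))
}

# brute-force all-pairs concordance AUC: P(pos > neg) + 0.5 P(tie)
tt_concordance_auc <- function(values, groups, positive = "eAD") {
  pos <- values[groups == positive]
  neg <- values[groups != positive]
  g <- expand.grid(p = pos, n = neg)
  mean((g$p > g$n) + 0.5 * (g$p == g$n))
}

# cortical-max table per subject and metric from a cohort table
tt_cortical_table <- function(tab) {
  do.call(rbind, lapply(split(tab, list(tab$subject, tab$metric)), function(s)
    data.frame(subject = s$subject[1], group = s$group[1],
               metric = s$metric[1], t(cortical_summary(s)))))
}
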