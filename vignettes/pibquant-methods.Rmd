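---
title: "Noninvasive PiB PET quantification: models, assumptions and design choices"
author: "pibquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noninvasive PiB PET quantification: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pibquant)
```

# The problem

Quantitative amyloid PET with [^11^C]PiB rests on the total distribution
volume (DV, mL/g) of the reversibly bound tracer, estimated voxel-wise from a
dynamic scan and an arterial plasma input function. Arterial cannulation is
impractical in routine imaging, so this package implements the noninvasive
alternative: an image-derived input function (IDIF) read off the internal
carotid artery in the dynamic images themselves, corrected for radiolabelled
metabolites with a Hill-type parent-fraction model, and fed to Logan graphical
analysis. Three metrics come out of a single 70-min acquisition:

* **DVR~L~** — the plasma-input Logan DV image normalized by the cerebellar
  cortical mean;
* **DVR~r~** — the reference-tissue Logan slope computed directly against the
  cerebellar TAC;
* **SUVR** — the 50–70 min static uptake normalized by the cerebellar mean.

The package also ships a synthetic dynamic-PET phantom with known kinetics so
that every stage — VOI selection, IDIF, metabolite correction, Logan slopes,
normalization, cohort statistics — can be validated by parameter recovery
rather than by eyeballing patient data.

# Acquisition model

All analyses assume activity concentrations in kBq/mL, decay-corrected to
scan start, on the 38-frame reconstruction schedule
(12 × 5 s, 6 × 10 s, 3 × 20 s, 4 × 30 s, 5 × 60 s, 4 × 5 min, 4 × 10 min;
4200 s in total). Protocol descriptions sometimes quote this listing as "39
frames", but the multiplicities sum to 38 and the package treats the listed
schedule as authoritative. Frame values are modelled as duration averages of
the continuous activity curve — that is how reconstructed frames behave —
and frame midpoints serve as the nominal sample times of every TAC.

# Input-function chain

**Early image and VOI.** The 10–40 s average image (overlap-weighted, so
partially covered frames count by their overlap seconds) localizes the
intravascular bolus; the 30 most intense voxels inside the carotid search
region form the VOI. Ties are broken by ascending flattened voxel index,
making the selection deterministic and invariant to positive affine
rescaling of the image.

**Two-phase IDIF.** While counts change rapidly (frame midpoints up to the
phase switch, default 45 s — the midpoint of the defensible 40–50 s range)
the IDIF takes the mean over the four VOI slices richest in VOI voxels of
each slice's maximum; afterwards it takes the maximum over slices of each
slice's mean, which is stabler at late, low-count frames. Four slices sits
inside the plausible 3–5 range and is fixed for determinism; both the switch
time and the slice count are exposed in `analysis_config()`.

**Metabolite correction.** The unmetabolized fraction follows the Hill form
$$R(t) = \frac{\alpha\,t^{\beta}}{t^{\beta} + \gamma},$$
with defaults $\alpha = 1.62$, $\beta = -0.92$, $\gamma = 0.47$ (nonlinear
least-squares estimates from published PiB parent-fraction assays, shipped
as constants rather than re-derived). With $\beta < 0$ the raw model tends
to $\alpha > 1$ at early times; since a parent fraction cannot exceed unity
the applied correction is clipped to $[0, 1]$ and every clipped frame is
counted in the QC record. The plasma-to-whole-blood ratio is taken as 1 —
the correction is applied directly to the whole-blood IDIF, any residual
scale being absorbed by scanner calibration — and is configurable.
`fit_hill()` estimates the three constants from measured fractions by
Levenberg–Marquardt least squares over a 64-point multi-start grid; the
$(\alpha, \gamma)$ pair is not identifiable when the data are flat in time
(only $\alpha/(1+\gamma)$ is), which the documentation flags.

# Graphical analysis

For a tissue curve $C_T$ and input $C_{in}$ (plasma $C_p$, or the cerebellar
TAC for the reference form) the Logan transform is
$$y(T) = \frac{\int_0^T C_T}{C_T(T)}, \qquad
  x(T) = \frac{\int_0^T C_{in}}{C_T(T)},$$
and the ordinary least-squares slope of $y$ on $x$ over frames with midpoint
$\ge t^\*$ estimates DV (plasma input) or DVR (reference input). Choices and
their rationale:

* **Integration.** Running integrals use the trapezoid rule from an implied
  $(0, 0)$ sample at injection; this is exact for piecewise-linear TACs and
  matches frame-averaged data.
* **$t^\*$ = 50 min**, i.e. the last 50–70 min of the scan — on this schedule
  the two 10-min frames with midpoints 55 and 65 min. Noise-free slopes move
  by well under 2% when $t^\*$ is shifted to 40 min.
* **Sample times.** Frame midpoints are used as $T$; frame end-times are the
  undocumented alternative and would change slopes by a fraction of a
  percent at these frame durations.
* **OLS, unweighted.** The classic formulation; its known noise-induced
  downward bias at low counts is accepted and documented rather than
  replaced by perpendicular or weighted variants.
* **Reference form without $k_2'$.** The pure two-integral reference Logan
  is used; an optional `k2_ref` argument restores the $C_{ref}/k_2'$ term.
  With the fast-equilibrating reference adopted in the phantom the two DVR
  routes agree within ~0.5% noise-free, and the sign of the residual
  difference is below that resolution (patient data show DVR~r~ slightly
  below DVR~L~; the phantom does not resolve that ordering).
* **Voxel validity.** A voxel's slope is kept only if (i) $C_T > 0$ at every
  used frame, (ii) the observed abscissa is strictly increasing — it is
  strictly increasing in continuous time whenever both curves are positive,
  so a violation marks a noise-dominated voxel — and (iii) the relative
  abscissa span $(x_{max} - x_{min})/\bar{x}$ is at least 0.05. The expected
  relative span is input-driven (about 0.15–0.2 here, nearly independent of
  voxel kinetics), while a span collapsing toward zero makes the two-point
  slope unbounded; masking below 0.05 removes exactly those non-identifiable
  voxels. Masked voxels are set to 0, excluded from regional means and
  counted in QC.

SUV follows the printed convention
$\mathrm{SUV} = C\,[\mathrm{kBq/mL}] / (\mathrm{ID}\,[\mathrm{MBq}] /
\mathrm{BW}\,[\mathrm{kg}])$ on the 50–70 min overlap-weighted static image,
and SUVR divides by the cerebellar SUV mean.

# Statistics

Regional values are arithmetic means of valid voxels per named region.
Group contrasts use Welch's two-sample test; region-vs-PCC contrasts use the
within-subject paired test. Metric agreement uses OLS regression with
Pearson $r^2$, and Bland–Altman analysis after regression correction: the
second metric is mapped onto the first's scale through the inverse of the
fitted line, so a purely linear relationship leaves zero mean difference.
Difference variances of two method pairs are compared with the
Pitman–Morgan test (equality of correlated variances via
$\mathrm{cor}(a+b,\,a-b)$), a deliberate concrete choice where the source
analyses report only a p-value. ROC analysis is empirical over all observed
thresholds with trapezoid AUC — provably identical to the all-pairs
concordance probability, which the tests verify — and the operating
threshold maximizes Youden's J, ties resolved toward the lower threshold.
"Optimal cutoff" criteria other than Youden's J would be equally defensible;
Youden is standard and deterministic. Box-plot outliers in figures follow
the usual 1.5·IQR rule; it affects plotting only.

# The synthetic phantom

The analysis pipeline above never sees ground truth in patients, so the
phantom supplies it. Design:

* **Forward model.** Each tissue region follows the reversible
  two-tissue-compartment model; the tissue curve is the plasma input
  convolved with the model's bi-exponential impulse response. The
  convolution uses an exact exponential-update recursion for
  piecewise-linear inputs on a 1-s grid, so generator accuracy is set by the
  sampling of the input curve, not by an ODE solver tolerance (an
  independent `deSolve` integration is the test oracle). A vanishing
  eigenvalue discriminant is regularised by an O(1e-8) nudge of $k_4$.
* **Arterial input.** A linear rise to a peak at 0.75 min (peak
  $\sum A_i = 50$ kBq/mL, emulating a 700–750 MBq bolus seen in a carotid
  VOI) followed by three decaying exponentials
  ($A = 35, 10, 5$ kBq/mL; $\lambda = 4, 0.6, 0.008$ min^-1^). Carotid
  voxels carry this whole-blood curve; tissue is driven by
  $C_p(t) = \min(R(t), 1)\,C_b(t)$ with the Hill defaults, so the phantom
  and the analysis share one metabolism model.
* **Kinetic defaults.** $K_1 = 0.3$ mL/min/g and $k_2 = 0.2$ min^-1^ for
  cortex and cerebellum (reference DV $= 1.5$ mL/g, one-tissue), binding
  via $k_3 = k_4(\mathrm{DVR} - 1)$ with $k_4 = 0.25$ min^-1^ at the fast
  end of published PiB estimates — chosen so the 50–70 min window sits near
  transient equilibrium, as the patient comparisons of SUVR against DVR
  require. White matter has halved delivery and proportionally slower
  efflux (DVR 1, slow kinetics). Ground-truth DVR is exactly
  $1 + k_3/k_4$ because delivery is shared within a subject.
* **Noise.** Zero-mean Gaussian per voxel and frame with
  $\mathrm{SD} = s\sqrt{C/\Delta t}$ ($\Delta t$ the frame duration in
  minutes), mimicking count statistics. The default $s = 0.15$ realises
  late-frame (10 min) voxel CVs of roughly 7–10% at the phantom's
  0.5–2 kBq/mL late tissue activities, in line with smoothed OSEM
  reconstructions; noise is spatially independent, which is slightly harsher
  on voxel-wise Logan than the correlated noise of real reconstructions.
* **Geometry.** Eleven named regions painted as blocks (eight lobar
  cortices, PCC, cerebellum, white matter) plus a carotid column of ≥ 30
  voxels across ≥ 5 slices; a deliberate reduction of the 78-region
  anatomical parcellation to the level at which the analyses aggregate
  anyway. Default grids: 32³ voxels for single-study work, 20 × 20 × 16 for
  cohorts (tests and the acceptance script use these sizes).
* **Cohorts.** Per-subject regional DVR targets are drawn from the group
  tables in `pib_group_targets()` — the regional DVR~L~ means ± SD of a
  35-subject CTL/eAD population — with a shared amyloid-burden factor
  (loading 0.7) plus independent regional variation; subject-level
  physiology varies as 10% CVs on $K_1$ and $k_2$, 15% on the injected peak,
  700–750 MBq doses and 60 ± 8 kg weights. Draws below DVR 1 are realised
  as $k_3 = 0$; the resulting truncation bias is a few thousandths of a DVR
  unit, far below the sampling error at cohort sizes. Subject seeds derive
  deterministically from the cohort seed.

# What passing tests do and do not show

The phantom omits partial-volume and spillover effects, dispersion and
delay of the input, head motion, attenuation/scatter residuals and
reconstruction noise correlations. Consequences worth knowing:

* SUVR magnitudes overshoot equilibrium DVR at high burden (the late window
  retains a kinetic transient that partial-volume effects damp in patients),
  so simulated SUVR thresholds sit above the patient values even though
  orderings, linearity and group separation reproduce.
* The DVR~L~–DVR~r~ agreement is tighter than in patients because both
  estimators share the same voxel noise and nothing else perturbs them;
  the package demonstrates the *ordering* (DVR pairs agree better than
  SUVR pairs, and the SUVR pair carries the larger Bland–Altman variance),
  not the patient scatter magnitudes.
* IDIF recovery is exact by construction in the noise-free phantom; it
  validates the extraction arithmetic, not vascular delineation on real
  anatomy.

# Degenerate inputs and edge behaviour

Empty or overlapping phantom regions, sub-minimum grids, non-contiguous
frame schedules, VOIs spanning too few slices, windows outside the scan,
nonpositive doses/weights and single-class ROC inputs all raise immediate
errors with the offending quantity named. Voxels that fail Logan validity
are masked, zero-valued and counted, never silently imputed. The Hill fit
reports failure only after all 64 starts diverge.
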