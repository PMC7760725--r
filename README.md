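# pibquant

Noninvasive quantification of dynamic [¹¹C]PiB amyloid PET without arterial
blood sampling, for PET methodologists and analysts working with 70-min
dynamic acquisitions. The package implements the full chain from dynamic
image to diagnostic metric:

1. **Image-derived input function (IDIF):** the 30 hottest voxels of the
   10–40 s early image inside the internal carotid artery define a VOI; a
   two-phase rule (mean of per-slice maxima while the bolus passes, maximum
   of per-slice means afterwards) yields the whole-blood curve.
2. **Metabolite correction:** the unmetabolized fraction follows the Hill
   form *R*(*t*) = α·*t*^β / (*t*^β + γ) (defaults α = 1.62, β = −0.92,
   γ = 0.47), clipped to [0, 1]; the plasma input is
   *C*ₚ(*t*) = *R*(*t*) · IDIF(*t*).
3. **Logan graphical analysis:** with *y*(*T*) = ∫₀ᵀ*C*ₜ / *C*ₜ(*T*) and
   *x*(*T*) = ∫₀ᵀ*C*ᵢₙ / *C*ₜ(*T*), the OLS slope over the last 50–70 min
   estimates the distribution volume DV (plasma input, → **DVR_L** after
   cerebellar normalization) or the distribution volume ratio directly
   (cerebellar TAC as input, → **DVR_r**).
4. **SUVR:** the 50–70 min static image divided by injected dose per body
   weight and by the cerebellar mean.
5. **Statistics:** regional tables, Welch and paired group tests, Pearson
   regression between metrics, regression-corrected Bland–Altman agreement
   with a Pitman–Morgan variance comparison, and empirical ROC analysis
   with Youden-optimal thresholds.

Because no patient data ship with the package, a **synthetic dynamic-PET
phantom** (two-tissue-compartment kinetics, parametric arterial input,
count-statistics noise, carotid column, 11 named brain regions) provides
ground truth for every stage; cohort simulation draws per-subject regional
DVR targets from configurable CTL/eAD group distributions.

## Worked example

```r
library(pibquant)

spec  <- phantom_spec(group = "eAD", dim = c(20, 20, 16),
                      noise_scale = 0.15, seed = 42)
study <- build_phantom(spec)
study
#> Synthetic PiB study (eAD-like, seed 42, noise 0.15)
#> Dynamic PET image: 20 x 20 x 16 voxels (2 x 2 x 2.8 mm), 38 frames over 70 min
#> Ground-truth DVR: cerebellum=1.00, frontal_l=2.14, frontal_r=2.17,
#>   temporal_l=1.72, temporal_r=1.74, parietal_l=2.11, parietal_r=2.19,
#>   occipital_l=1.73, occipital_r=1.78, pcc=2.43, white_matter=1.00

q <- quantify_study(study)
q
#> PiB quantification result
#> Input function: 38 frames, IDIF peak 52.8 kBq/mL, Cp/IDIF at end 0.071
#>   parent fraction clipped to 1 in 14 early frame(s)
#>   cerebellar DV 1.441 mL/g; invalid voxels: DV 3661, DVR_r 3660

summary(q)
#>          region    DVR_L     DVR_r     SUVR
#> 1    cerebellum 1.000000 0.9999993 1.000000
#> 2     frontal_l 2.131139 2.1421496 3.212274
#> 5    temporal_r 1.737459 1.7453996 2.279319
#> 10          pcc 2.424983 2.4375249 4.002123
#> 11 white_matter 1.003101 1.0056644 1.263220
```

The recovered DVR_L and DVR_r track the ground-truth DVR within about 1%
(PCC: 2.42/2.44 against a truth of 2.43). The invalid-voxel counts are
dominated by the empty background outside the labelled brain; masked
in-brain voxels are reported in `q$qc`. SUVR exceeds DVR at high binding —
the late static window retains a kinetic transient — which is why
thresholds are metric-specific.

Cohort-level comparisons mirror the patient analyses:

```r
cohort <- simulate_cohort(n_ctl = 20, n_ad = 20, seed = 1)
tab    <- quantify_cohort(cohort)
metric_agreement(tab, "DVR_L", "DVR_r")$regression$r.squared  # 0.9999
metric_agreement(tab, "SUVR",  "DVR_r")$regression$r.squared  # 0.978
```

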