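# gaitpromis

Tools for analysing recovery after surgically treated tibial and malleolar
fractures by combining two longitudinal data streams: objective gait
parameters extracted from instrumented-insole recordings (16 plantar
pressure sensors plus a gyroscope, sampled at 100 Hz) and subjective
patient-reported outcomes on the PROMIS T-score metric (Global Physical
Health, Global Mental Health, Pain Interference). It is aimed at
biostatisticians and movement scientists who monitor musculoskeletal
rehabilitation with wearables and questionnaires.

## What the package computes

**Gait extraction.** Every channel is low-pass filtered (4th-order
Butterworth, 6 Hz cutoff, zero-phase by default). Initial contact (IC) of a
stride is the first sample at which the total vertical force F(t) exceeds
30 N and stays above it for at least 300 ms; final contact (FC) is the
first later sample with F(t) < 30 N. Forces are expressed in percent body
weight (100·F/BW), regional pressures as the per-sensor normalized mean over
configurable forefoot/hindfoot/lateral/medial sensor sets, and each walk is
summarized by the mean per-stride maxima of the five middle strides.

**Longitudinal analysis.** Visits are binned into six post-surgery
intervals (0–15, 16–55, 56–110, 111–200, 201–300, >300 days), keeping the
last visit per patient and interval. PROMIS trajectories are modelled with
random-intercept linear mixed models

> T_ij = β₀ + β_interval + β_sex + β_hypertension + b_i + ε_ij,  b_i ~ N(0, σ_b²)

fitted by REML with Satterthwaite degrees of freedom, and PROMIS–gait
associations are summarized by pairwise-complete Spearman correlations per
interval. Demographic comparisons use the Pearson chi-square statistic
Σ(O−E)²/E (no continuity correction) and Wilcoxon rank-sum / one-way ANOVA
for continuous variables.

**Location–scale–shape model.** The conditional distribution of a positive
gait parameter y given the PROMIS scores is modelled with a GAMLSS using
the Box-Cox Cole-Green (BCCG) response — location μ (median-type), scale σ
(coefficient of variation), Box-Cox power ν:

> μ = a_μ + pb(PH) + pb(MH) + pb(PI)    (identity link)
> log σ = a_σ + pb(PI)
> ν = a_ν

where pb() are penalized B-spline smooths. The fitter (written in this
package) maximizes the penalized likelihood by outer cycling over (μ, σ, ν)
with iteratively reweighted penalized least squares, deviance-gated step
halving, and per-smooth local maximum-likelihood smoothing-parameter
selection; predicted (μ, σ, ν) yield full conditional centile curves.

**Synthetic data.** `generate_insole_recording()` produces walks with a
double-hump stance force curve, a hindfoot-to-forefoot sensor roll-over and
known ground-truth contact events; `generate_cohort()` produces a
patient-by-visit table with interval-shaped PROMIS trajectories,
saturating-exponential gait recovery, random intercepts and MCAR dropout —
so every downstream stage is testable against known generating values.

## Worked example

```r
library(gaitpromis)

# one synthetic walk -> per-visit gait summary
sim <- generate_insole_recording(
  gait_signal_config(n_strides = 9, sensor_noise_sd = 2, seed = 42))
extract_gait(sim$recording)
#>   max_total_force_pbw max_forefoot_p max_hindfoot_p max_lateral_p max_medial_p
#> 1              112.32          12.14          12.17          7.04         7.02
#>   max_angular_velocity_ml n_strides_used
#> 1                  200.63              5
```

The walk was generated at 115 %BW peak force; the 6 Hz filter shaves the
peak slightly (112.3 %BW). Averages are over the five middle strides.

```r
cohort <- generate_cohort(cohort_sim_config(seed = 42))$cohort
tab <- cohort |> add_intervals() |> dedupe_last_per_interval()
fit_lmm(tab, "ph_t")
#> Random-intercept LMM for ph_t
#> 281 observations, 85 patients
#>   term             estimate std.error    df statistic  p.value
#> 1 (Intercept)        49.8       1.17   97.5    42.7   6.11e-65
#> 2 interval6-weeks   -12.7       0.733 198.    -17.3   1.35e-41
#> 3 interval3-months  -11.4       0.836 202.    -13.7   1.61e-30
#> 4 interval6-months   -7.00      0.956 203.     -7.32  5.69e-12
#> 5 interval9-months   -2.91      1.13  202.     -2.58  1.07e- 2
#> 6 interval1-year     -3.13      1.28  200.     -2.46  1.49e- 2
#> 7 sexmale             3.33      1.50   78.6     2.22  2.90e- 2
#> 8 hypertensionTRUE    0.516     2.09   79.6     0.247 8.06e- 1
```

Physical Health drops ~13 T-score points by 6 weeks and recovers towards
the preinjury level (intercept ≈ 50) by one year; the male advantage
configured in the generator (+2 points) is recovered within sampling error.

```r
# demographic contingency test (counts: 3/35 female vs 16/30 male smokers)
pearson_chi_square(matrix(c(3, 16, 35, 30), 2))
#>   statistic    df p.value
#> 1      8.60     1 0.00337

# GAMLSS of a gait parameter at the 3-month interval
sub <- dplyr::filter(tab, interval == "3-months")
fit <- fit_gamlss_bccg(sub, "max_force_pbw")
tidy(fit)          # intercepts and linearized smooth slopes
predict_centile(fit, sub[1:3, ], p = 0.1)   # 10th-centile gait values
```

An end-to-end run (simulate → extract → analyse → GAMLSS → report CSVs with
a manifest) is one call: `run_pipeline(list(seed = 1, out_dir = "out",
simulate = list(n_patients = 85)))`.

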