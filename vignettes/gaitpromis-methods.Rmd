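---
title: "Methods: gait extraction, PROMIS handling and location-scale-shape modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gait extraction, PROMIS handling and location-scale-shape modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitpromis)
```

This vignette documents the statistical and numerical choices behind the
package: the signal-processing pipeline for instrumented-insole walks, the
PROMIS score handling, the longitudinal models, the Box-Cox Cole-Green
(BCCG) GAMLSS, and the synthetic-data generators that make all of it
testable. It states design rationale, not results; every empirical claim
about behaviour is encoded as a test in `tests/testthat/`.

## Gait extraction

**Filtering.** All channels pass through a fourth-order Butterworth
low-pass at 6 Hz (`lowpass_filter()`), the conventional smoothing choice
for walking-speed plantar-force data where the locomotor signal lives well
below ~10 Hz. The default mode is zero phase (forward–backward), because
gait-event *timing* is the quantity of interest and a causal pass would lag
every event by the filter's group delay; the cost is that the effective
magnitude response is squared (attenuation doubled in dB), which we judged
preferable to biased event times. A `causal` mode is kept for users who
want the single-pass behaviour. Zero-phase filtering uses odd-reflection
padding so start-up transients decay outside the data window; the padding
length (15 cycles of the cutoff frequency, capped at the series length) is
generous rather than minimal. The analytic reference response
(`butterworth_gain()`) is that of the *digital* design — the analog
Butterworth magnitude evaluated at bilinear-prewarped frequencies
`tan(pi f/fs)`. Below about a quarter of the Nyquist frequency this
coincides with the textbook analog formula; near Nyquist (e.g. a 30 Hz
tone at 100 Hz sampling) only the prewarped form describes the implemented
filter.

**Event detection.** Initial contact is the first sample where the
filtered total force exceeds 30 N and remains above it for at least
300 ms; final contact is the first later sample below 30 N. Both
comparisons are strict (`> 30`, `< 30`), applied to the *filtered* force —
the filter precedes detection for all channels. Above-threshold episodes
shorter than 300 ms (spurious spikes, partial weight shifts) are rejected;
episodes that never release before the recording ends are discarded as
incomplete. After a final contact, detection simply resumes at the next
threshold crossing; no extra debounce interval is imposed beyond the
persistence rule, which is the simplest reading of the detection rule and
is exercised by the sub-threshold-noise invariance test.

**Normalization and regions.** Forces are reported in percent body weight,
`100 * F / BW` with BW in Newtons. A regional pressure is the sum of its
member sensor channels, normalized to %BW, divided by the number of
sensors combined — so regions of different size are comparable per sensor.
The default 4x4 sensor-to-region map (rows 1–2 hindfoot, rows 3–4
forefoot; columns split medial/lateral, mirrored by side) is a
configuration default, not a claim about any particular commercial layout:
real insoles number their sensors differently, and `sensor_layout()`
accepts arbitrary disjoint index sets.

**Stride selection and summary.** To exclude gait initiation and
termination on a short walkway, only the five strides centred on the
midpoint of the detected sequence are kept. "Centred" is operationalized
as a window of length k whose start is `floor((n-k)/2) + 1`, which shifts
toward the *earlier* stride when centring is ambiguous (a deterministic
tie-break). With fewer than k+2 strides all interior strides are used and
a warning raised; fewer than three strides is an error because no interior
stride exists. The per-visit summary is the arithmetic mean of per-stride
maxima of: total force (%BW), the four regional pressures (%BW/sensor),
and the mediolateral angular velocity.

**Mediolateral axis and sign.** The gyroscope channel taken as
mediolateral defaults to the second axis of the recording schema
(`gyro_y_dps`) and is configurable. Maxima are taken on the *signed*
series, not the absolute value; with the package's sign convention
(positive = plantarflexion-direction rotation) the per-stride maximum is
the peak plantarflexion-direction velocity. Both the axis mapping and this
convention are stated here because device conventions differ.

## PROMIS scoring

Raw construct scores are sums of recoded item responses; T scores come
from an exact raw-to-T lookup with no interpolation — published conversion
tables are defined per integer raw score, and interpolating would
fabricate precision. The conversion tables themselves are licensed
instrument property, so the package treats the entire score map (item
groupings, recodes, lookup tables) as replaceable JSON configuration. The
shipped default uses the standard structure of Global Health v1.2 (four
items per component, symptom items reverse-coded) and Pain Interference 8a
(eight items), but its numeric tables are *synthetic*, clearly labelled as
such in the file and documentation; real scoring requires the licensed
tables via `read_score_map()`.

Missingness follows a per-construct exclusion rule: a visit missing any
contributing item loses that construct only, never the whole visit. No
prorating of half-complete constructs is attempted. A change of at least
5 T-score points between visits — half a population SD, a conventional
moderate effect size in orthopaedic populations — is flagged as clinically
meaningful, with the boundary inclusive.

## Longitudinal analysis set and models

Visits are assigned to six disjoint day intervals (0–15, 16–55, 56–110,
111–200, 201–300, >300 days post-surgery); when a patient has several
visits in one interval only the last (largest day; later file row on ties)
is analysed, so each patient contributes at most one observation per
interval. Interval is entered as a categorical fixed effect with the
0–15-day bin as reference — recovery trajectories are not forced through
any parametric time curve.

The mixed models are random-intercept LMMs fitted by REML through
`lmerTest`, so fixed-effect tests use Satterthwaite degrees of freedom.
Covariates default to sex and hypertension; the full-to-final reduction
rule (keep covariates with |coefficient| above a threshold, default 1
T-score point) is exposed as `select_covariates()` with the threshold as a
parameter, since the constant is a judgement call. Rows missing the
outcome or any covariate are dropped per model (complete case) — no
imputation, matching the per-variable n reporting convention of
demographic tables. No multiple-testing correction is applied anywhere.

Demographic comparisons: Pearson chi-square without continuity correction
(the uncorrected statistic is what published demographic tables
conventionally print), and for continuous variables both the Wilcoxon
rank-sum test (normal approximation, tie correction, no continuity
correction) and the one-way ANOVA F — published tables sometimes label one
with the other's name, so `rank_sum_test()` reports both rather than
guessing. Spearman correlations between the three PROMIS scores and six
gait parameters are computed pairwise-complete with average-rank ties,
per interval, with the per-pair n reported; fewer than three complete
pairs yields `NA` rather than a meaningless coefficient.

## The BCCG GAMLSS

The conditional distribution of a positive gait parameter given the PROMIS
scores is modelled as BCCG(μ, σ, ν): `z = ((y/μ)^ν − 1)/(νσ)` (log form at
ν = 0) is truncated standard normal, giving a median-type location, a
coefficient-of-variation-type scale, and a skewness power. The density
includes the exact truncation normalizer `Φ(1/(σ|ν|))` — it is not
approximated away — and the implementation evaluates the power transform
via `expm1`/`log1p` so density, CDF, quantile and sampler are continuous
through ν = 0 (the lognormal).

The model structure is fixed: μ gets an intercept plus penalized B-spline
smooths of all three PROMIS T scores (identity link), log σ an intercept
plus a smooth of Pain Interference, and ν a lone intercept. The identity
link for μ is retained — it is the natural reporting scale for %BW-valued
parameters — with a positivity screen: nonpositive fitted medians trigger
a warning rather than silently moving to a different link. ν carries no
covariates; skewness is assumed constant across the score range, which at
the sample sizes involved (tens of observations per interval in practice)
is as much as the data can support.

**Smooths.** Each `pb()` term is a cubic B-spline basis over 20 equally
spaced interior knots spanning the covariate range, with a second-order
difference penalty on the coefficients. The penalty null space is the
linear functions, so infinite smoothing degenerates the term to a straight
line; the implementation takes that limit *exactly* (the term's design
collapses to a centered linear column with zero penalty) instead of using
a numerically hazardous huge λ. Smoothing weights are selected by default
with a Schall-type local maximum-likelihood update per smooth each outer
cycle (`λ = σ̂e²/σ̂b²`, damped to at most a factor 10 per cycle and clamped
to [1e-4, 1e9]); a fixed-effective-degrees-of-freedom mode (`edf_target`,
e.g. 3) is available as the simpler, more predictable alternative.

**Fitting.** Penalized maximum likelihood by outer cycling μ → σ → ν; for
each parameter one iteratively reweighted penalized least-squares step on
the working response `z = η + u/w`, where the score `u = ∂ℓ/∂η` and
curvature `w = −∂²ℓ/∂η²` come from central finite differences of the
per-observation log-likelihood (relative step 1e-5). Numeric
differentiation was chosen over hand-derived score functions for
robustness across the ν-branches; it is validated against quadrature and a
direct-optimization oracle in the tests. Non-positive curvatures fall back
to the squared score (a Fisher-scoring-like safeguard). Every update is
accepted only through step halving against the global deviance
(−2 log-likelihood), so the reported deviance trace is non-increasing *by
construction*; a proposal that cannot avoid increasing the deviance after
ten halvings is rejected and the parameter kept. A consequence worth
stating: because acceptance is gated on the unpenalized deviance, an
auto-λ increase mid-fit cannot push the fit toward a smoother (higher
deviance) solution once converged, so fits err on the side of slight
under-smoothing rather than oscillation. Convergence is declared when the
deviance changes by less than 1e-4 between outer cycles; failure to
converge within `max_outer` (default 100) is an error carrying the
deviance trace. Initial values are deliberately bland: μ flat at the
sample mean, σ at the sample coefficient of variation (floored at 1e-3),
ν at 0.

**Reporting.** Intercept standard errors come from the *joint* observed
information across the three predictors — the full Hessian over
(μ-coefficients, σ-coefficients, ν), with the cross-parameter blocks
computed by finite differences — because the conditional per-block matrix
`(XᵀWX + S)⁻¹` understates the uncertainty when σ and ν are correlated, as
they are in Box-Cox families. Smooth-slope standard errors remain
conditional on their block and on the selected λ; p-values use the normal
approximation.
Because a smooth term has no single coefficient, the per-covariate rows of
the report table are *linearized slopes*: the unweighted least-squares
projection of the fitted smooth onto {1, x}, with a delta-method standard
error from the smooth's coefficient covariance. This is an interpretable
summary of a possibly nonlinear effect, and it is labelled as such — it is
not a claim that the smooth is linear. `predict()` inverts the links to
return full conditional (μ, σ, ν) triples, from which `predict_centile()`
draws centile curves; covariate values more than 5% of the training span
outside the training range are refused rather than extrapolated.

## Synthetic data: what it emulates, what it does not

**Walks.** The stance-phase force curve is a sharp-onset arc carrying two
Gaussian bumps (loading and push-off peaks) with a configurable midstance
valley; it is scaled so the noiseless peak equals exactly
`peak_force_pct_bw/100 * body_weight`, and is exactly zero during swing.
The arc component exists for a specific reason: ground truth is defined as
the support edges of the stance interval, and the signal must rise from 0
past any realistic detection threshold within about one sample of the true
initial contact for threshold-detected events to coincide with ground
truth at any stance duration — a pure sum of slow Gaussian bumps cannot do
that. Stance durations below 0.3 s are rejected at configuration time
because they would make the ground truth undetectable under the 300-ms
persistence rule. The 16 sensor channels share the total force through a
hindfoot-to-forefoot activation wave on a 4x4 grid, renormalized per
sample so the channels sum exactly to the total force (unit sensor area
factor). The mediolateral gyroscope channel is a stride-periodic
oscillation. Not emulated: accelerometer channels, left/right asymmetry,
stride-to-stride timing variability, device drift, or any musculoskeletal
realism — the generator exists to give the *detector and feature
extractor* known answers, and passing its tests says nothing about
biomechanical validity on real insole data.

**Cohorts.** PROMIS T scores are generated as interval means (piecewise —
matching the categorical-interval structure of the analysis model, not a
smooth curve) plus additive sex and hypertension shifts, a patient random
intercept, and i.i.d. residuals; the pain-interference construct receives
the shifts and intercept with opposite sign, since higher pain
interference is worse while higher health scores are better. Default
interval means trace the recovery shape of such cohorts: a sharp
worsening to an extremum around 6 weeks–3 months and a return toward
preinjury levels by one year. Gait parameters follow a
saturating-exponential recovery `plateau − (plateau − baseline)·exp(−rate·day)`
(default rate 0.02/day, i.e. ~80% of the recovery inside the first three
months) with a per-patient multiplicative level and lognormal noise, which
keeps them strictly positive — the support the BCCG stage requires.
Dropout is permanent and missing-completely-at-random with a per-visit
hazard (default 0.25, calibrated loosely to the declining per-visit sample
sizes typical of one-year fracture follow-up, e.g. roughly 85 → ~35 → ~15
across a year). Real attrition is plainly not MCAR (patients who feel
recovered stop returning); the generator makes the MCAR simplification
because the analysis stack under test makes the same implicit assumption,
and modelling informative dropout is out of scope.

## Problem sizes and tolerances used in the tests

Stride-detection properties run on 200 generated walks with stance
durations 0.4–0.9 s; filter contracts compare measured tone gains to the
analytic response within 2% at f/fc of 0.17, 1 and 5; BCCG normalization
is checked to 1e-6 by adaptive quadrature over a (μ, σ, ν) grid including
ν in {−1, 0, 1}; GAMLSS recovery uses n = 1000 simulated rows (intercepts
within 3 standard errors, smooth-recovery grid correlation above 0.95);
LMM recovery uses cohorts of 2000 patients, with 95% CI coverage measured
over 200 replicate cohorts of 150 patients; Spearman nulls use n = 10⁴.
These sizes were chosen to make Monte-Carlo assertions stable at the
stated tolerances while keeping the default test run fast.

## Known limitations

- The GAMLSS fitter supports the fixed structure above (smooths in μ, one
  smooth in log σ, intercept ν) — not arbitrary formulas, other response
  families, or random effects inside the GAMLSS.
- Standard errors for smooth terms are conditional on the selected λ;
  smoothing-parameter uncertainty is not propagated.
- Temporal gait parameters (cadence, stance time, asymmetry indices) are
  not extracted; only per-stride maxima of force, regional pressures and
  mediolateral angular velocity.
- The shipped score map's raw-to-T tables are synthetic placeholders; all
  real use requires the licensed conversion tables.
- IRT-based (pattern) PROMIS scoring is not implemented; scoring is
  sum-plus-lookup only.
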