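---
title: "Methods: smartphone transcutaneous bilirubinometry from adapter physics to gamma regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smartphone transcutaneous bilirubinometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The measurement problem

Transcutaneous bilirubinometry (TcB) estimates total serum bilirubin
(TSB, mg/dL) in newborns from the diffuse reflectance of skin. Bilirubin
absorbs strongly in a band around 460 nm, so jaundiced skin darkens in
the blue while longer wavelengths are nearly unaffected; measuring blue
reflectance against green/red references, at one or more lateral
source-detector offsets, normalizes away pigmentation, perfusion and
scattering differences. `biliphone` implements the computational stack
of a phone-based TcB device: a snap-on adapter redirects the flash to a
small illumination spot next to the camera field of view (FOV), a
triple-band filter isolates blue (474 ± 10 nm), green (554 ± 10 nm) and
red (635 ± 10 nm) passbands, and the camera records a spatially resolved
map of diffuse reflectance from which arc-shaped regions of interest
(ROIs) feed a gamma regression of TSB.

The package has five connected parts: photon-transport simulation for
adapter design, the raw-capture calibration pipeline, the two-stage
arc-ROI + gamma-GLM estimator (`tcb_fit()`), agreement statistics, and a
synthetic-cohort generator that stands in for clinical captures, which
are not publicly deposited.

# Photon transport in layered skin

`simulate_reflectance()` is an MCML-style weighted-photon kernel
(compiled C++): exponential step sampling, Henyey–Greenstein scattering,
absorption by weight decay, unpolarized Fresnel reflection/refraction at
every refractive-index mismatch, and Russian roulette below a weight of
1e-4 with survival probability 0.1. The skin is laterally homogeneous,
so a layered slab is sufficient; voxelized heterogeneity, polarization,
fluorescence and time resolution are out of scope.

Assumptions and numerical choices:

* **Beam**: uniform (top-hat) disk of radius 1.5 mm at 30° incidence,
  tilted toward the FOV. The spot radius is back-derived from the
  adapter's 7.5/9.1 mm source-to-FOV-centre offsets and the 12 mm FOV
  width, not a measured device value; the true beam profile is unknown.
* **Collection**: exit weight is binned into 0.25 mm squares over the
  9 × 12 mm FOV only when the refracted exit direction lies within the
  acceptance cone (default half-angle 21°, matching the illumination
  channel; the true collection NA is unknown and user-overridable). An
  azimuthal radial tally of *all* reflected weight is kept for
  diffusion-theory comparisons.
* **Bookkeeping**: specular, reflected, transmitted and absorbed tallies
  sum to the launched weight exactly (roulette boosts are debited from
  the absorbed tally), so conservation is checked to 1e-6 as arithmetic,
  not sampling error.
* **Step cap**: photons exceeding 1e6 interactions — reachable only in
  near-lossless media, where escape-time tails are heavy — are credited
  to total reflectance without a spatial bin. With any absorption the
  roulette terminates photons long before the cap.
* **Determinism**: a self-contained xoshiro256++ generator, seeded per
  wavelength from the user seed, makes runs bit-identical and
  independent of R's RNG state.

Optical properties come from `build_default_skin()`: epidermis
(0.06 mm), dermis (1.2 mm) and semi-infinite subcutis, with absorption
assembled from the packaged chromophore table
(`inst/extdata/chromophores.csv`) — melanosome power-law decay,
oxy/deoxy-hemoglobin with Soret and Q bands, a bilirubin band at 460 nm
that is numerically zero in the red passband, and a flat baseline — and
reduced scattering following `musp(500 nm) * (lambda/500)^-b`. These are
smooth, documented package defaults with the right qualitative shape;
no numeric equality with any particular device's internal model is
claimed, and every layer property can be overridden through
`layered_skin()`.

`diffusion_reflectance()` is the independent cross-check: the standard
two-term dipole with `mueff = sqrt(3 mua (mua + mus'))` and an
extrapolated boundary via the Groenhuis internal-reflection polynomial.
The test suite verifies the Monte-Carlo radial profile against it within
15% for 2–8 mm at `mua/mus' <= 0.05` (1e6 photons), flags sub-transport-
length distances as near-field, and checks the lossless semi-infinite
limit (total reflectance = 1).

## The geometry comparison and its "percent increase"

`compare_geometries()` contrasts the 1.6 mm and 0 mm beam-edge-to-FOV
offsets with paired seeds and reports channel totals normalized by the
global maximum across both configurations. Two increase measures are
reported deliberately. On the *channel-relative* scale
`100 (R_0 - R_1.6)/R_1.6`, the steeply attenuated blue channel always
gains the most — the gain grows like `exp(mueff * 1.6 mm)`, and this is
a structural property of radially decaying reflectance, not a modelling
choice. On the *normalized-reflectance* scale `100 (R_0 - R_1.6)` (points
of full scale), the red channel, which carries the largest absolute
signal, gains the most. The device-design observation that shrinking the
offset benefits red slightly more than blue is a statement on the second
scale, so `percent_increase` reports it and
`percent_increase_relative` carries the channel-relative figure.

# Capture calibration pipeline

`process_capture_set()` turns a burst of three flash-on and three
flash-off 16-bit frames of tissue, plus a paired burst of an HDPE-like
white reflectance standard, into one calibrated image:

1. **Demosaic** (`demosaic()`): bilinear interpolation per colour plane
   of an RGGB mosaic (layout configurable; already-decoded planar
   frames pass through). Vendor DNG decoding is out of scope — the
   package ingests decoded 16-bit arrays.
2. **Quarter resize** (`quarter_downsample()`): 2 × 2 block averaging,
   i.e. quarter *area*; the block factor is configurable.
3. **Outlier frames** (`flag_outlier_frames()`): each frame is
   summarized by per-channel mean and standard deviation; a frame is
   dropped when its mean distance to its `k = 1` nearest neighbours
   exceeds the median + 3 scaled MADs of all such distances. The
   reference algorithm is under-specified in the source literature, so
   operating on summary features is a documented assumption; the
   minimum-distance frame is always retained.
4. **Averaging and calibration** (`calibrate_reflectance()`):
   `R = (tissue_on - tissue_off) / (cal_on - cal_off)` per pixel and
   channel. Pixels whose calibration denominator falls below 1e-6 of
   full scale are masked, not clipped. Saturation (raw value at or above
   98% of full scale in any flash-on frame) is masked with a one-pixel
   guard band for demosaic spill, then AND-reduced through the
   downsampling blocks.

The pixel-to-mm mapping divides the 12 mm FOV width by the image width
after downsampling; the empirical grid calibration of the physical
device is replaced by this declared scale. Identities the tests enforce:
self-calibration gives reflectance 1, common gain and dark offset cancel
exactly, and frame order is irrelevant under a consistently permuted
keep-mask.

# The two-stage estimator

`tcb_fit()` is the package's central fitting function.

**Features.** An arc ROI is an annular segment around the
illumination-spot centre, parameterized by mid-arc radius, radial width
and angular centre (span fixed at 90° by default; arc "position" is
read as the angular centre, with the arc origin fixed at the
illumination-spot centre). One feature per arc: the mean of its channel over valid pixels.
The composition — 4 blue, 3 green, 2 red — follows the relative amount
of unsaturated area per channel and is configuration, not code.
Defaults start the arcs at evenly spaced radii per channel, blue nearest
the source where bilirubin contrast is strongest.

**Stage 1** (`optimize_rois_stage1()`): for each resample, 2 training
patients per TSB bin (0–5, 5–10, 10–15, 15–25 mg/dL; 8 in total) and
2/2/2/1 test patients are drawn; a bounded generalized pattern search
(deterministic polling, first-improvement acceptance, mesh ×2 on
success, ×0.5 on a failed poll, candidates clipped to the box) moves the
27 arc parameters to minimize the sum of squared prediction errors of a
gamma GLM fitted on the training patients and evaluated on the test
patients. Degenerate arcs (outside the image or fully saturated) return
`Inf`, acting as a barrier. Evaluating the objective on the held-out set (rather than the training
set) is a deliberate choice: the test resample otherwise has no role,
and held-out error is what the arcs should generalize to. Per-resample
optima are aggregated by the parameter-wise median (lower-median on
even counts — a documented tie-break). The search is budgeted by
evaluation count (default 500) rather than wall-clock time, for
reproducibility across hardware.

Eight training rows cannot identify ten coefficients: stage-1 fits are
intentionally underdetermined, computed on the pivoted column basis and
flagged as such. They interpolate their training data and are meaningful
only through held-out predictions — which is exactly how the objective
uses them. The linear predictor is clamped to ±30 on the log scale so
interpolating fits cannot overflow.

**Stage 2** (`cross_validate_stage2()`): with the stage-1 median arcs
frozen, each iteration draws one test patient per bin of a finer 5-bin
stratification (0–3.5, 3.5–6.5, 6.5–10, 10–15, 15–25 mg/dL), fits the
gamma GLM on all remaining patients, and records test predictions; after
all iterations each patient's median prediction is taken. Defaults are
the full-scale 3000 resamples and 10000 cross-validations; the test
suite exercises the same code at 50 resamples / budget 100 / 500
iterations, which preserves every structural property while keeping the
suite inside a desk-scale run.

**Why a gamma GLM with a log link.** TSB is positive and right-skewed;
the gamma family respects the non-negativity constraint and the log link
(the default; inverse selectable) guarantees strictly positive
predictions. Fitting is IRLS via `stats::glm`, convergence declared at a
relative deviance change below 1e-8.

# Agreement statistics

`agreement_report()` computes the squared Pearson correlation with its
t-statistic p-value; Bland–Altman bias and 95% limits of agreement
`bias ± 1.96 sd` with the sample (n−1) standard deviation; RMSE by TSB
range (default 0–10 / 10–25 mg/dL); and RMSE by skin group with a Welch
two-sided t-test on absolute errors between the two largest groups
(groups under two members are excluded with a warning). Differences are
**prediction − TSB** throughout — documented prominently because the
sign convention changes the reported bias's sign: under this convention
an under-predicting device shows a negative bias.

# What the synthetic cohort does and does not emulate

`generate_cohort()` renders fully synthetic capture datasets with known
ground truth:

* **TSB**: gamma(shape 3.2, scale 2.6) truncated to (0, 25] mg/dL by
  exact inverse-CDF sampling — mode in the 5–10 mg/dL bulk, a tail
  reaching ≈ 24. The parameters are the generator's own documented
  fixture constants chosen to match the qualitative histogram of
  newborn TSB. When the cohort is large enough, draws are redistributed
  (re-drawn inside deficient bins, still from the same family) so every
  stratified-analysis bin is populated — the generator's job is to
  produce analyzable cohorts, mirroring the enrolment floors the
  clinical design implies.
* **Pigmentation**: two melanosome fractions (light 0.02, dark 0.10)
  sampled near-evenly, emulating a deliberately balanced multi-ethnic
  enrolment; the group label is recorded for the agreement statistics.
* **Physics**: each patient's noiseless field is the diffusion dipole
  evaluated at the band centres with the chromophore model homogenized
  over epidermis and dermis (epidermal path weight 0.15) — the fast
  closed form rather than per-patient Monte Carlo, keeping cohort
  generation to seconds while preserving the structure the estimator
  must exploit: blue-channel attenuation strictly increasing in TSB,
  all channels attenuated by melanin.
* **Sensor**: per-channel gains that place the calibration standard's
  proximal edge at ~60% of full scale, dark offset (800 counts),
  signal-proportional shot noise plus Gaussian read noise, 16-bit
  clipping, forced saturation inside a configurable radius around the
  source, occasional "non-contact" frames (dark frame substituted with
  recorded index), and optional Bayer mosaicking. The calibration
  frames image an HDPE-like diffuse standard through the same geometry
  — a literally flat unit-reflectance target could not share the tissue
  gain without saturating.
* **Exact-inversion mode**: `quantize = FALSE` disables integer
  rounding so a noiseless cohort round-trips through the full pipeline
  to machine precision; with quantization the round-trip is limited by
  the 16-bit ladder, which is the sensor's own physics.

Not emulated: skin texture and curvature, contact-pressure artifacts,
ambient-light leakage, lens shading, chromatic aberration, frame-to-
frame motion. Passing end-to-end tests on this generator therefore
demonstrates that the estimator recovers the *encoded* physics
(monotone spectral attenuation with TSB under pigmentation confounding
and sensor noise) — not clinical performance on real skin.

# Problem sizes and reproducibility

The test suite runs the full pipeline at documented desk scales: 2e4
photons per wavelength for qualitative transport checks and 1e6 for the
quantitative physics suite; a 60-patient low-noise cohort with stage 1
at 50 resamples × 100 evaluations and stage 2 at 500 iterations for
end-to-end recovery (the suite requires cross-validated median
predictions with R² ≥ 0.8 and |bias| ≤ 0.5 mg/dL against ground truth);
and a 20-patient chain run twice through the command-line interface
(`synth → preprocess → optimize-rois → crossval → report`) compared
byte-for-byte. Every stochastic component takes an explicit integer
seed: splits, resamples and captures derive per-unit seeds from it, the
transport kernel seeds one stream per wavelength, and none of it
disturbs R's global RNG state.

# Known limitations

* The chromophore table and layer geometry are plausible defaults, not
  fitted constants; absolute spectra and absolute channel differences
  are not reproduced and not claimed — only the qualitative orderings
  and monotonicities the tests assert.
* The layered model cannot represent lateral heterogeneity (vessels,
  naevi, curvature shadowing).
* Underdetermined stage-1 fits make the objective surface noisy;
  the resample-median aggregation is what stabilizes the arcs, and
  small resample counts should be read accordingly.
* The kNN outlier screen sees only global frame statistics; localized
  corruption that preserves means and SDs would pass.
* With 16-bit quantization and realistic gains, reflectance beyond
  ~8 mm in the blue channel drops below the quantization floor; arcs
  placed there carry noise, which the bounded search and the saturation
  mask mitigate but do not eliminate.
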