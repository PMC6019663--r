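---
title: "Quantifying hemidiaphragm movement from ultrasound cine loops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hemidiaphragm movement from ultrasound cine loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diamus)
```

## The measurement problem

The diaphragm is the primary respiratory muscle; its contraction moves the
central fibrous dome caudally, and reduced motion accompanies phrenic nerve
injury, neuromuscular disease, COPD, and prolonged weaning from mechanical
ventilation. Ultrasound is the bedside tool of choice for assessing that
motion, but the two established measurements sample it at a single point:

* **M-mode excursion** follows one scan line through the posterior diaphragm
  (subcostal, mid-clavicular view) and reads the wave amplitude of the bright
  interface — easy on the right through the liver window, frequently
  impossible on the left, where stomach gas and the posterior spleen block
  the view.
* **B-mode apex displacement** tracks the most cranial point of the dome in a
  lateral mid-axillary view with the caliper, capturing only the
  cranio-caudal motion of one landmark.

The **Area method** instead traces the entire visible hemidiaphragm in the
frames of maximal and minimal contraction. With the transducer held fixed,
the image borders do not move during the breath, so each trace can be closed
with the borders of the ultrasound sector and the enclosed
supradiaphragmatic ("intra-thoracic") area computed. The measurement is the
difference

$$\Delta A = A_{\text{max contraction}} - A_{\text{min contraction}},$$

where maximal contraction (end-inspiration) is the frame in which the
diaphragm sits most caudally — equivalently, the frame of largest enclosed
area. $\Delta A$ has no anatomic meaning as an absolute area; what matters
is that it integrates motion over the whole dome, in two dimensions, and is
obtainable from the same lateral view on both sides.

## What the package computes

`diamus` implements all three measurements on calibrated cine clips
(`cine_clip`: frame stack + cm-per-pixel spacing + frame period; calibration
is mandatory and never guessed):

* `area_above_contour()` closes a traced contour with the image borders
  (contour, up the right border, across the top, down the left border) and
  applies the shoelace formula in physical cm. `select_extreme_frames()` and
  `delta_area()` pick the extreme frames *with the same area functional that
  is being measured*, so frame selection and measurement cannot disagree;
  ties go to the earliest frame.
* `extrapolate_contour()` continues a partially visible trace to the lateral
  borders, as an operator does when lung artifact hides part of the dome: a
  weighted quadratic is fitted to the outermost 25% of visible points on the
  gap side (tricube weights with bandwidth at half that segment, so the
  points nearest the gap dominate) and evaluated to the border, clamped to
  the image depth. On a circular arc truncated to 70% of the window the
  extension stays within 2% of the true radius. Extrapolated points carry a
  per-point flag end to end, including in the contour JSON files.
* `m_mode_excursion()` resamples intensity along a `scan_line`, localizes
  the dominant bright interface per frame (Gaussian-smoothed profile,
  sigma = 2 samples, parabolic sub-sample refinement) and follows it with
  temporal coherence: the highest-contrast frame anchors the track and each
  neighboring frame is searched within ±3 cm of the previous depth, the way
  a continuous M-mode trace is read. The excursion is the range of the
  tracked depth.
* `b_mode_apex_displacement()` takes the per-frame contour point of minimal
  depth and reports the range of its depth, warning when the apex comes
  within a pixel of the top border (clipped dome top).

For a pure piston motion all three numbers coincide: $\Delta A$ / window
width = M-mode excursion = apex displacement. That identity is one of the
package's standing tests.

### Deciding that the diaphragm is *not* visualized

A line or column with no diaphragm echo must be recognized, because the
failure mode matters clinically (the left mid-clavicular M-mode view). A
median + 3 MAD threshold on the intensity profile — the obvious choice — is
unusable here: the profile background is two-level (echo-poor thorax above,
echogenic organ below), and when the two levels split near 50/50 the MAD
jumps to the level gap itself, pushing the threshold above any real echo.
Instead the peak must exceed the maximum of the background (the profile with
a ±10-sample guard band around the peak excised) by a 10% contrast margin.
Visibility is judged on a nearly raw profile (sigma = 0.5 px), where the
specular diaphragm echo keeps its full amplitude, while localization uses
the sigma = 2 px profile. On phantom clips this classifies every frame of 15
speckled clips with a visible diaphragm as visible and rejects 10/10 clips
rendered without the bright band. A clip is rejected when at least 20% of
frames fail, mirroring how a study reader abandons a view. The
classification is statistical: a band-free clip whose static speckle happens
to contain one dominant blob can rarely slip through.

## The phantom and what it does (not) emulate

`dome_model()` is a circular-arc dome (chord, sagitta, insertion depth)
translating caudally by an `amplitude` per breath inside a fixed window,
with a flat diaphragm continuation to the window edges and an optional
`flattening` factor that reduces the sagitta as the dome descends
(emphysema-like). `breath_cycle()` maps frames to excursion fraction
(default: raised-cosine slow breath that attains both extremes exactly on
the frame grid). Analytic ground truth comes from `true_delta_area()`
(trapezoid integral at 0.005 cm steps between the extreme contours — equal
to width × amplitude for any rigid translation) and `true_volume()` (swept
solid of revolution of the dome about the apex axis, scaled by effort).

`render_cine()` rasterizes this into B-mode-like frames: echo-poor thorax,
bright specular diaphragm band (5 px ≈ 2.5 mm interface complex), textured
organ below, multiplicative speckle on the diffuse tissue. Defaults are
display-scale: after log compression, fully developed speckle has a standard
deviation of roughly 5–6 dB on a ~50 dB display range, hence
`speckle_sd = 0.12`; the specular diaphragm echo is coherent and composited
with stable amplitude. Texture and speckle are drawn once per clip — the
organs are static while the diaphragm sweeps across them — so a
zero-amplitude clip renders bit-identical frames under a fixed seed.

What the phantom deliberately does **not** emulate: wave propagation and the
transducer point-spread function, frame-to-frame speckle decorrelation,
rib shadows, sector (polar) geometry, posture and ventilation effects, and
real anatomic variation of the dome shape beyond the circular arc. Passing
the round-trip tests therefore shows that the measurement chain is unbiased
and sub-pixel accurate *on images whose degradations are speckle, texture,
and apex obscuration* — it does not certify performance on clinical images.

## The cohort simulator

`simulate_cohort()` emulates a validation study: subjects breathe at
self-chosen depths (amplitude uniform on 0.5–9 cm, spanning shallow breaths
to maximal inspiration) while each breath is measured by all three methods
and paired with an exhaled-volume analog. Choices that shape the statistics:

* **Geometry.** Dome height (2–3.5 cm) and insertion depth (4.5–5.5 cm) vary
  per subject; the chord is fixed at 10 cm. A common footprint makes exhaled
  volume a strictly monotone map of excursion in the noise-free,
  no-accessory limit — the regime in which the rank correlation must be
  exactly 1 — while leaving all realistic variability in amplitude, tracing
  noise and accessory recruitment.
* **Tracing noise.** Each observed contour is the truth plus a smooth
  perturbation field (sd `sigma_contour` = 0.15 cm, correlation length 1 cm),
  emulating hand tracing. Rater sets (for agreement studies) are two
  independent such fields at `sigma_rater`.
* **Accessory muscles.** Above 80% of maximal effort, secondary respiratory
  muscles add `accessory_gain` liters per unit effort, scaled by a per-breath
  engagement factor uniform on [0, 1]: how much a subject recruits them
  varies breath to breath. This extra volume is invisible to the diaphragm,
  which is exactly why measurement–volume correlations degrade in the
  high-volume stratum; with deterministic engagement the ranks would be
  untouched and no degradation could occur. The 80% threshold and the
  engagement law are simulator knobs, not estimates.

With tracing noise only, the Spearman correlation between measured
$\Delta A$ and volume stays above 0.99 on a 20-subject × 4-breath cohort;
with `accessory_gain = 1.5` L the high-volume stratum correlates worse than
the low-volume stratum in ~99% of replicates — the qualitative pattern the
mean-split analysis (`split_by_mean()`) is designed to expose. The cohort's
human counterpart values are not reproducible from a simulator and are not
targets.

## Statistics

* `spearman_ci()`: midranks for ties; 95% CI by Fisher z with variance
  $1/(n-3)$ — the construction is stated because published Spearman CIs are
  often not reproducible otherwise; p two-sided, by full permutation
  enumeration for n ≤ 8 without ties (cross-checked against the exact
  distribution in `stats::cor.test`) and by the t approximation
  $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df otherwise.
* `icc_oneway()`: one-way random-effects, single-rater ICC(1,1) =
  $(MS_B - MS_W)/(MS_B + (k-1)MS_W)$, with p from the F test — the
  agreement statistic for raters who each re-measure every clip once, when
  no rater effect is separable. Identical raters give exactly 1. Its
  calibration is checked two ways: against `stats::aov` mean squares, and on
  moment-standardized simulated components (exact between/within variances,
  zero cross-covariance), where the estimate equals
  $\sigma_b^2/(\sigma_b^2+\sigma_w^2)$ to machine precision — a plain
  simulation at n = 2000, k = 2 carries sampling noise of the same order as
  a 0.02 tolerance and would confound calibration with chance.
* `clopper_pearson()`: exact two-sided binomial CI from Beta quantiles,
  with the k = 0 / k = n endpoints closed at 0 and 1. Coverage is at least
  nominal for every p by construction; the suite verifies it empirically.
* `study_report()` assembles the descriptive summary (mean, SD, range, n per
  method — reported at 0.1 cm² / 1 mm granularity in the CLI), correlation,
  mean-split, ICC and feasibility tables as CSV plus a text report. Records
  with volume equal to the mean go to the low stratum (a convention; the
  boundary is measure-zero under the simulator).

## Numerical conventions and degenerate inputs

All geometry is computed in physical cm (origin top-left, depth increasing
caudally), converted once at ingest; pixel units never reach the
measurement code. Contours must be strictly monotone in x, reach both
lateral borders to within half a pixel (otherwise: "open contour"), and
carry at least 3 points; extrapolation needs 4. A constant clip yields
$\Delta A = 0$ with extreme frames (1, 1) and a warning rather than an
error. Scan lines are normalized; a line missing the image or crossing
fewer than 5 samples is rejected. Ratings matrices must be complete with at
least 5 targets and 2 raters; a matrix with no variance at all is
degenerate. The whole pipeline is seed-deterministic: identical seeds give
byte-identical study tables, clips, and report files.

Problem sizes in the tests are chosen to keep the full suite within a few
minutes: 9–11 frames per clip at 0.05 cm/px (240 × 300 px), 20 renders
spanning the amplitude range for round-trip checks, 100–200 cohort
replicates for the stratified-correlation pattern, and 2000 targets for ICC
calibration.

## Known limitations

* The phantom's kinematics are a rigid (or flattening) arc translation; real
  hemidiaphragms tilt and deform regionally.
* Whether human operators trace through lung artifact near the apex, or
  stop at it, is unknown; the package extrapolates through and flags the
  points, so the convention is at least explicit and auditable.
* The volume analog is the dome-swept solid of revolution, not a thorax
  model; only rank relations with measurements are meaningful.
* DICOM input is not supported in this build; cine clips travel as TIFF/PNG
  stacks with a mandatory YAML calibration sidecar.
* The visibility classifier is tuned to the phantom's contrast regime; on
  clinical images its margin would need re-estimation.
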