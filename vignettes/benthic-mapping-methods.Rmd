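---
title: "Methods: from underwater hyperspectral transects to benthic maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from underwater hyperspectral transects to benthic maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, assumptions and numerical choices behind
`benthoscan`, in the order the data flows: cube geometry, reflectance
correction, derivative spectrometry, topography, classification, and the
synthetic scene model that underpins the test suite.

## Data model and geometry

A push-broom imager resolves one spatially-resolved spectral line per frame;
successive lines during the swim are compiled into a transect cube. The
package stores cubes as `values[line, sample, band]` with a strictly
increasing wavelength axis in nm and 0-based `(line, sample)` image
coordinates. On disk the cube is a standard ENVI header/binary pair
(interleaves `bil`/`bsq`/`bip`; sample encodings int16/uint16/float32/
float64; `bil` + float32 written by default, matching line-at-a-time
acquisition). Transect pixels are strongly anisotropic — at the reference
operating point (1 m altitude, 1.28 m swath over 640 pixels, 20 m/min, 2 cm
frame spacing) they are 0.2 × 2 cm — so `rectify_aspect()` resamples for
display only; analysis always runs on the raw grid.

Nearest-band lookup resolves ties toward the lower wavelength. This is
arbitrary but deterministic, and it matters only when a query sits exactly
between two band centres.

## Reflectance correction

The in-scene gray board samples the product of downwelling illumination and
water-column attenuation along the instrument–bottom path. Dividing every
pixel spectrum by the per-band board mean and multiplying by the board
albedo yields board-relative reflectance. Assumptions, in decreasing order
of importance:

* the average light field is stable over the transect (1–2 min);
* the board and the surveyed bottom sit at comparable optical path lengths —
  the correction applies one transect-wide reference, with no per-pixel
  path-length adjustment for local altitude;
* the board is spectrally flat. Its true albedo is rarely known, so
  `board_albedo` defaults to 1 and the output is reflectance *relative to
  the board*; supply the albedo when absolute levels matter.

Out-of-gamut values (below 0 or above 1, from noise, shadow or specular
targets) are deliberately retained and flagged in a QC mask: clipping would
bias spectral derivatives right at the features of interest. The per-band
coefficient of variation of the board region is returned as a quality
check; it uses the population SD, so a two-pixel region with values 1 and 3
has CV = 0.5 exactly.

When several `"Reference"` polygons are annotated (a board at each transect
end), their pixels are pooled into one spectrum.

## Colour rendering

`to_rgb()` extracts the bands nearest 640/540/460 nm and applies a 2–98
percentile stretch. The default stretch is *joint*: percentiles are computed
over the three planes pooled and one affine map is applied to all channels,
which preserves relative band brightness — uncorrected radiance renders with
its blue-green water tint, and the tint disappears after reflectance
correction (the board then renders neutral to within ~2%). A `per_channel`
mode maximises contrast instead, but note that it normalises each band
independently and therefore cancels *any* per-band gain, tint included; it
cannot visualise the effect of the correction.

## Derivative spectrometry

Narrow absorption features are quantified by local-polynomial
(Savitzky–Golay) derivatives: a reflectance dip is convex at its minimum, so
the second derivative at the absorption wavelength is positive when the
pigment is present, and (for a fixed feature width) proportional to the
feature depth. Defaults, all configurable:

* **window: 7 bands** (~7 nm on a 480-band, 400–900 nm axis) — wide enough
  to suppress band-to-band noise, narrow relative to the ~10 nm-sigma
  pigment features being measured;
* **polynomial degree 2 for first derivatives, 4 for second derivatives.**
  Even-order derivatives of curved features carry a smoothing bias at
  cubic degree: for a Gaussian dip of sigma 10 nm a degree-3/window-7 filter
  underestimates the centre curvature d/sigma² by about 3%, while a quartic
  fit cancels the leading bias term and is exact to ~0.2%. First derivatives
  do not suffer this at the feature shoulders, so degree 2 suffices;
* derivatives are in physical units (per nm, per nm²); edge bands use the
  one-sided fits of the same window;
* the wavelength grid must be even to within 1% of the mean spacing;
  `resample_wavelengths()` linearly interpolates to the median spacing
  otherwise.

The built-in index registry maps four named features: `chl_670` (2nd, 670
nm, chlorophyllic pigments), `coral_rededge_700` (1st, 700 nm, rectified to
positive values — only a positive red-edge slope is meaningful),
`chromo_580` (2nd, 580 nm; the chromoprotein identity is unconfirmed, so the
index is named by wavelength), and `phyco_605` (2nd, 605 nm, phycoerythrin
in sediment biofilms). Indices are computed on reflectance; computing on raw
radiance is supported for comparison but mixes the attenuation spectrum's
curvature into the result. These maps are semi-quantitative: converting them
to absolute pigment densities would require chemical calibration, which is
out of scope.

## Topography and rugosity

Bottom depth is instrument depth (pressure gauge, positive down) plus
acoustic altitude. The dominant approximation is the **constant-swim-speed
mapping** of time onto distance — the system has no positioning beyond
heading and acceleration — so `fuse_bottom_profile()` also accepts an
external distance series when one exists. Missing 1 Hz samples in gaps of at
most 5 s are linearly interpolated; longer gaps split the profile into
segments, and the whole-transect rugosity is then the chord-weighted
combination of per-segment values (reported individually as an attribute).
Arc-chord rugosity is contour length over chord length, exactly 1 for a flat
bottom; a windowed mode computes it over non-overlapping windows with the
final partial window dropped.

## Classification

* **Features.** `hsi` mode keeps the bands in 400–750 nm (the infrared end
  carries no usable signal underwater) and Z-norms each pixel spectrum
  across bands. The normalization axis is per *pixel*, not per band: under
  water, brightness varies strongly with altitude and terrain, and per-pixel
  Z-norming makes features invariant to per-pixel gain and offset.
  Per-band-across-pixels normalization is a reasonable alternative on land
  and is available for comparison in preprocessing configs. `rgb` mode uses
  the raw intensities of the bands nearest 640/540/460 nm, unnormalized —
  it deliberately emulates what a plain colour camera sees, brightness
  confound included. Pixels with zero spectral SD cannot be Z-normed; they
  are excluded from training sets (with a reported count) and assigned by a
  nearest-class-mean fallback in full-image prediction.
* **Split.** Stratified 75/25 per class (round(0.75·N_k) training rows),
  seeded. Stratification guarantees every class appears in validation.
* **Perceptron** — one hidden layer of 64 tanh units, softmax output,
  full-batch Adam (learning rate 0.01, weight decay 1e-4), at most 500
  epochs with early stopping after 25 epochs without loss improvement,
  seeded initialisation. The implementation is in-package and vectorized;
  at this problem size (~1800 × 324 features, 11 classes) a fit takes
  seconds.
* **Mahalanobis** — per-class mean and covariance with ridge shrinkage
  Σ_k + εI, ε = 1e-6·trace(Σ_k)/F (falling back to ε = 1e-6 when a class is
  exactly degenerate); prediction is the smallest Mahalanobis distance, ties
  to the lexicographically first class. With fewer training rows per class
  than features the covariance is rank-deficient and the shrinkage carries
  the null space; this is the textbook rule, kept deliberately simple
  because it also serves as a reference point against which the test suite's
  independent brute-force oracle is compared.
* **Linear SVM** — binary linear-kernel SVMs (cost 1.0) in one-vs-rest
  arrangement, prediction by largest decision value.
* **Metrics.** Confusion matrix with true classes in rows; accuracy =
  trace/total; precision (producer accuracy) = diagonal over column sums;
  recall (user accuracy) = diagonal over row sums. Classes absent from a
  validation set keep NA metrics rather than vanishing.

Models record their preprocessing (mode, band range, normalization, feature
wavelengths, standardization constants) and apply it inside
`predict_map()`, so a fitted classifier is a self-contained object.
Features may come from radiance or reflectance cubes — per-pixel Z-norming
makes the two nearly equivalent in `hsi` mode — and the choice is recorded
in the model.

## The synthetic scene model

The simulator exists so that every claim above can be tested against known
ground truth. Per pixel of class c at line altitude h:

    I(λ) = E(λ) · exp(−2·K_d(λ)·h) · R_c(λ) · (1 + ε),  ε ~ N(0, 1/SNR)

* Endmembers are a baseline minus Gaussian absorption features plus a
  red-edge ramp above 690 nm, clipped to ≥ 0.001.
* The factor 2 approximates the down-and-back path of bottom-reflected
  light with the board on the bottom; a simplification, not radiative
  transfer.
* K_d rises smoothly from 0.03 m⁻¹ at 400 nm through 0.5 m⁻¹ at 700 nm to
  2.5 m⁻¹ at 900 nm (monotone spline through fixed anchors) — a clear-water
  shape chosen as a fixture constant, not a claim about any site.
* Noise is multiplicative Gaussian (shot-noise-like proportionality),
  seeded; layouts are non-overlapping axis-aligned ellipses placed by
  rejection sampling, or explicit polygons.
* The sensor track is derived at 1 Hz from the prescribed seafloor function
  and altitude profile, so the topography stage can be checked against its
  own generating function.

The reference fixture `reef11_spec()` is a 200 × 640 × 480-band transect at
SNR 50 with 11 classes: seven coral genera sharing one broadband "chassis"
(baseline 0.28, a 440 nm Soret-band dip of 0.10) and differing only in
narrow features — 670 nm chlorophyll depth (0.10–0.16), a 580 nm
chromoprotein dip on the two massive-coral classes (0.06/0.08), red-edge
slopes (0.0008–0.0024 per nm) — plus a bright sediment background with a
605 nm phycoerythrin dip, dark turf algae, and a 0.5-albedo gray board. The
altitude profile undulates 1 m ± 0.15 m. This construction makes the coral
classes nearly indistinguishable to broadband colour features while leaving
them separable at full spectral resolution, which is exactly the contrast
the spectral-vs-colour comparison is designed to expose. Sparse annotations
are small rectangles inside class regions, an even pixel budget per class
(an annotator aiming for broad coverage), totalling ~1.8% of scene pixels.

The elevated-altitude twin doubles the altitude profile and compresses the
same layout laterally by 1.5× about the frame centre (a wider swath maps
the content onto fewer of the 640 samples), with a fresh noise seed: the
physical scene is unchanged, only the acquisition. Training on the normal
scene and predicting the elevated one probes transfer across acquisition
altitude; pooling the two annotation sets and retraining probes how much of
the lost accuracy returns.

**What the simulator does not emulate:** surface glint, inter-pixel
scattering, bidirectional reflectance, within-class endmember variability
beyond multiplicative noise, macro-optic structure of branching growth
forms, and georeferencing. Passing tests therefore demonstrate the
correctness and internal consistency of the pipeline, and qualitative
agreement with the field phenomena (spectral ≫ colour, altitude transfer
loss recovered by pooling) — not field-scale accuracy figures.

## Problem sizes and runtime

The test suite and the acceptance script run the full-size reference scene
(200 × 640 × 480 ≈ 61 M samples) once each — generation ~30 s, each
perceptron fit 5–15 s, the whole acceptance script ~2 min on one CPU.
Smaller 60 × 160 scenes with the same structure back the per-module tests.

## Known limitations

* The constant-speed distance mapping distorts profiles whenever the diver's
  speed varies; rugosity inherits that distortion.
* One transect-wide reference spectrum leaves altitude-dependent residuals
  in reflectance when the altitude varies along the transect (visible in the
  reference fixture, where the profile undulates by ±15%).
* The Mahalanobis rule with tiny ridge shrinkage is noise-sensitive when
  classes have fewer training pixels than features; it is kept in its
  textbook form on purpose.
* Classification is purely per-pixel; spatial-spectral and object-based
  methods are out of scope.
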