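# benthoscan

Analysis of diver-operated, push-broom **underwater hyperspectral transect
surveys** of shallow benthic habitats such as coral reefs. A single transect
with such a system yields a hyperspectral image cube (hundreds of contiguous
bands per pixel), a 1 Hz log of diver depth and acoustic altitude, and
water-column PAR/O2/pH — and from these one can derive colour-accurate
imagery, photopigment abundance maps, seafloor rugosity, and centimetre-scale
benthic composition maps with very little manual annotation. `benthoscan`
implements that full analysis chain for R, together with a parametric
synthetic reef-scene simulator so every stage can be exercised and validated
without field data.

Intended users: reef ecologists and remote-sensing practitioners processing
underwater hyperspectral transects, and method developers who need a
reproducible, fully synthetic test bed for benthic-classification pipelines.

## What it computes

**Reflectance correction.** An in-scene gray board of albedo ρ_b samples the
full optical path (downwelling illumination × water-column attenuation at
survey altitude). With I_board(λ) the mean board radiance, every pixel
spectrum is converted to board-relative reflectance

    R(l, s, λ) = ρ_b · I(l, s, λ) / I_board(λ),

valid while the average light field is stable over the 1–2 min transect.

**Derivative index maps.** Narrow pigment absorptions are quantified with
Savitzky–Golay local-polynomial derivatives of the reflectance spectra
(window 7 bands; degree 2 for first, 4 for second derivatives). Built-in
indices: `chl_670` (2nd derivative at the 670 nm chlorophyll absorption
maximum), `coral_rededge_700` (positive first derivative at 700 nm, the coral
red edge), `chromo_580` (2nd derivative at a coral chromoprotein feature),
`phyco_605` (2nd derivative at the phycoerythrin feature of sediment
microalgae).

**Topography.** Bottom depth is diver depth + acoustic altitude; distance is
mapped by a constant-swim-speed assumption, and the arc-chord rugosity index
is the contoured profile length over its chord:

    R_ac = Σ √(Δd² + Δz²) / (d_N − d_0)  ≥ 1.

**Classification.** Sparse polygon annotations are rasterized to pixels;
features are either per-pixel Z-normed spectra restricted to 400–750 nm
("hsi") or raw intensities at the 640/540/460 nm bands ("rgb"). Three
classifiers — a single-hidden-layer perceptron, a per-class Mahalanobis
distance rule argmin_k (x−μ_k)ᵀ(Σ_k+εI)⁻¹(x−μ_k), and a one-vs-rest linear
SVM — are trained on a stratified 75/25 split and reported with a confusion
matrix, overall accuracy, and per-class precision (TP/(TP+FP)) and recall
(TP/(TP+FN)).

**Survey planning.** Deterministic arithmetic linking altitude, swath, swim
speed and frame spacing to pixel size, areal coverage, data rate and transect
data volume (e.g. 1.28 m swath / 640 pixels → 0.2 cm lateral pixels; 50 m at
2 cm frame spacing → 1.536 GB).

**Simulator.** Scenes are composed from class endmember spectra
R_c(λ) = baseline − Σ depth·exp(−(λ−center)²/2width²) + slope·max(0, λ−690),
imaged through the forward model
I = E(λ)·exp(−2·K_d(λ)·h)·R_c(λ)·(1+ε), ε ~ N(0, 1/SNR), with a gray board,
blob class layouts, an altitude profile, a seafloor function and a matching
1 Hz sensor track. `reef11_spec()` is the reference fixture: a
200 × 640 × 480-band transect with 11 classes whose seven coral genera share
one broadband envelope and differ only in narrow spectral features.

## Worked example

```r
library(benthoscan)

spec  <- reef11_spec()                 # the reference synthetic reef transect
scene <- generate_scene(spec)
scene$cube
#> <spectral_cube> 200 lines x 640 samples x 480 bands, 400.0-900.0 nm
#>   line period: 0.06 s

ann    <- sparse_annotations(scene$truth, 0.018, seed = 0)
labels <- rasterize_annotations(ann, dim(scene$cube$values)[1:2])
labels
#> <label_map> 200 x 640, 11 classes, 1.9% labelled

ds    <- extract_dataset(scene$cube, labels, mode = "hsi")
split <- split_dataset(ds, 0.75, seed = 0)
model <- train_classifier(split$train, "perceptron", seed = 0)
model
#> <benthic_classifier> perceptron on hsi features (336 bands), 11 classes
#>   trained on 1805 pixels (seed 0)

evaluate(model, split$validation)
#> <metrics_report> accuracy 0.998 over 601 pixels, 11 classes

prof <- fuse_bottom_profile(scene$track, spec$transect_length)
rugosity(prof)
#> [1] 1.239337
```

So from under 2% of pixels annotated, the spectral classifier recovers the
benthic map at 99.8% validation accuracy, and the fused depth + altitude
track gives an arc-chord rugosity of 1.24 for the simulated terrain. Colour
(rgb-mode) features on the same scene reach only ~40–53% — the coral classes
are deliberately near-identical in broadband colour — which is the core
argument for spectral over colour survey imagery.

A full pipeline run (colour renders, reflectance cube, four index maps,
topography, classification for each algorithm × feature mode, manifest with
checksums) is one call:

```r
run_transect(run_config(cube = "scene.dat.hdr", annotations = "annotations.json",
                        track = "track.csv", board_albedo = 0.5, seed = 0,
                        outdir = "out"))
```

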