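---
title: "Velocimetry from OCT speckle time series: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Velocimetry from OCT speckle time series: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Optical coherence tomography acquires depth-resolved complex reflectance
profiles (A-scans) at a high line rate. When the beam is parked on one
lateral location and A-scans are repeated, flowing scatterers (red blood
cells) sweep through the focal volume and modulate the speckle intensity,
while static tissue yields a constant signal. A *stepped M-scan* B-scan
parks the beam for 128 A-scans (10 µs apart at 100 kHz) at each of ~100
lateral locations, producing one 128-sample intensity time series per pixel.
The task is to turn those short, stochastic records into absolute blood flow
rates per vessel — including at Doppler angles near 90°, where phase-based
(Doppler) velocimetry diverges because the axial velocity component
vanishes.

octflow implements a complete analysis chain for this measurement:

1. a **forward speckle simulator** that generates training data with known
   velocity labels;
2. an **SNR-stratified bank of 1D convolutional classifiers** that maps a
   normalized 128-sample intensity record to a likelihood over 64 (or, in
   scaled configurations, fewer) log-spaced velocity classes;
3. a **Doppler phase-difference reference analysis** used as ground truth
   where the geometry permits;
4. a **flow-rate quantification layer** (pixel geometry, aperture masking,
   paraboloid extrapolation, calibration);
5. a **synthetic phantom generator** that emulates the tube-phantom and
   bifurcation experiments and provides every test fixture.

## Forward model of transverse flow speckle

The simulator models a 1D strip of point scatterers translating at speed
`v` through a Gaussian beam. The complex field at sample time `t` is

    a(t) = sum_k A_k exp(i phi_k) g(x_k - v t),   g(x) = exp(-x^2 / w0^2)

with unit amplitudes `A_k = 1`, phases `phi_k ~ U[0, 2pi)`, and
`w0 = 9 µm`, half the 18 µm e⁻² intensity diameter of the beam, so that
`|g|^2` falls to e⁻² at radius `w0`. Fully developed (Rayleigh) speckle
emerges from the coherent sum; the intensity is `|a(t)|^2`. Each
realization redraws positions and phases.

Choices the underlying physics leaves open, fixed here once:

* **Scatterer density** defaults to 2 per e⁻² radius (0.222 µm⁻¹). It acts
  as a crude scatterer-concentration (hematocrit) proxy; the speckle
  statistics are insensitive to it once speckle is fully developed.
* **Strip support** is the beam support truncated at ±3 w0 plus the total
  travel distance `v (n-1) tau`; the scatterer count is Poisson with the
  matching mean, so edge effects are absent by construction.
* **Shot noise** is complex circular Gaussian added to the field with
  variance `sigma^2 = Ibar / 10^(SNR/10)`, where `Ibar = rho w0 sqrt(pi/2)`
  is the *ensemble-mean* signal intensity (closed form). Defining SNR
  against the ensemble mean rather than each record's own mean models a
  fixed-brightness target with a fixed detection noise floor.
* **Axial displacement is ignored** (pure transverse model). The axial
  Doppler phase ramp is added only by the phantom generator, where it is a
  deterministic multiplier that leaves the intensity untouched.

Every record is **self-normalized** to unit mean over its own 128 samples
before classification; no information crosses records.

## The classifier bank

Architecture (fixed): a single 1D convolution layer with 128 kernels of
length 32, *valid* (no padding) so a 128-sample input yields 97 positions;
ReLU; max pooling of length 4, stride 4 (24 positions; the 97th is dead);
flatten to 3072; fully connected 1024 → 256 → n_classes; softmax. With 64
output classes this is 3,429,824 trainable parameters; the count is checked
in the tests against an independent hand count of the layer shapes.

Training is plain SGD with momentum 0.9, learning rate 0.01, batch 128 and
cross-entropy loss. Velocity classes are geometric between the grid
endpoints (0.001 mm/s to 2000 mm/s, 64 classes, at full scale). Because
speckle decorrelation depends on the ratio of noise to signal power, one
network is trained per SNR level (5–35 dB in 1 dB steps at full scale) and
inference selects the network nearest the pixel's estimated SNR, ties
toward the lower SNR, clamped at the trained range; estimates below 4 dB
are flagged unreliable rather than refused.

### Scaled study conditions

The full-scale library (49.6 million records) is not a practical test
fixture. All in-package validation runs a scaled configuration, chosen once:

* 12 classes, 2–400 mm/s (same geometric spacing philosophy; covers the
  phantom's speeds with the mushy near-static classes at the bottom and
  saturated fast classes at the top deliberately included);
* SNR levels {10, 15, 20} dB;
* 1000 realizations per cell, split 880 train / 120 validation;
* at most 20 epochs with early stopping (patience 4 epochs on validation
  accuracy, minimum improvement 0.002). Validation accuracy plateaus by
  epoch 12–15 under these conditions; the cap only bounds runtime.

"Mid-range" in the tests means classes 5–9 (≈14–94 mm/s), where the decay
of the intensity autocorrelation is well sampled by the 1.27 ms record.
The bottom classes decorrelate slower than the record length and are
intrinsically confusable; the top classes decorrelate within a sample or
two. This mirrors the full-scale configuration, whose 64 classes also
bracket the measurable range on both sides.

The training passes are implemented in compiled code (im2col + BLAS matrix
products, in-place momentum updates); a pure-R reference implementation of
the same forward/backward math ships in the package and the test suite
asserts agreement to machine precision — the compiled path is the
production path, the R path its independent check.

## Per-pixel inference and spatial filtering

A B-scan is classified pixel by pixel: normalize the pixel's series, pick
the SNR-matched network, store the softmax likelihood curve. No
neighborhood information enters this stage (purity is asserted in tests).
A 3×3 kernel then multiplies likelihood curves elementwise around each
pixel (product over available neighbors at the edges, no padding); the
argmax of the filtered curve is the velocity class. Argmax ties break
toward the lower velocity and are flagged. The product is computed in log
space for numerical stability and left unnormalized, which does not affect
the argmax.

Pixel SNR is `10 log10(mean intensity / noise floor)` with the noise floor
taken from a designated signal-free region (deepest 10% of the image by
default). The angiography mask uses the temporal variance of the
self-normalized intensity, thresholded at 5× its median over usable
(SNR > 3 dB) pixels, cleaned to the largest 4-connected component. Pixels
at the noise floor decorrelate like flow, so the SNR gate is part of the
statistic's definition here; the minimum accepted component scales with
the image (0.5%, at least 9 pixels) because the variance statistic of
static speckle plus noise has a long tail of isolated false positives.

## Doppler reference analysis

For complex-valued scans, phase differences between A-scans separated by
delay `d` give the axial velocity. The chain, per B-scan:

1. **Lag products** `a(t+d) conj(a(t))` for delays 1–40 A-scans: 127 images
   at delay 1 down to 88 at delay 40 (4300 total) for 128 samples.
2. **Bulk-motion correction**: per phase-difference image and per A-scan
   pair, the circular-mean phase over static pixels with SNR > 3 dB is
   subtracted (columns without usable static pixels are flagged and left
   uncorrected).
3. **Per-delay circular averaging** of the lag products (Kasai-style);
   phases are never averaged linearly while wrapped.
4. **2D phase unwrapping** of each per-delay average with a quality-guided
   flood fill (quality = mean lag-product magnitude; compiled priority-queue
   implementation). The surface is anchored by forcing the static
   background's median unwrapped phase to the nearest multiple of 2π.
5. **Corrupted-image rejection**: images whose residual fraction of
   adjacent-pixel jumps above π exceeds 1% are dropped (they indicate
   noise, decorrelation, or unwrap failure). Delays whose phase gradient
   exceeds π per pixel — fast flow at large delay — eliminate themselves
   here.
6. **Scale and average**: each surviving image is divided by its delay and
   the results averaged, exactly recovering the per-A-scan phase difference
   for constant-velocity input regardless of the delay subset.
7. **Velocity conversion**: `v = dphi λ0 / (4π n τ cos α)` with λ0 =
   1040 nm, n = 1.36, τ = 10 µs. Doppler angles in [88°, 92°] are rejected
   (cos α ≈ 0 makes the total-flow conversion unstable).

The Doppler angle of a vessel can be estimated from the shift in its depth
position between two B-scans spaced 200 µm along the vessel:
`α = 90° + atan(Δz/Δx)`, with depths optical-path-corrected (divided by the
tissue group index).

**Closure accuracy.** On a noise-free phantom, the per-pixel phase error of
a single B-scan is limited by speckle decorrelation of the lag products, at
roughly 2% of the local velocity (median); it falls as the square root of
the number of repeated B-scans. Spatially averaged summaries — the fitted
peak velocity and the lumen-mean velocity — agree with ground truth to a
few tenths of a percent from a single B-scan, and the integrated rate to
well under 1%. The acceptance suite asserts closure at that
spatially-averaged level, which matches how the framework is used (flow is
always reported per vessel, never per pixel).

## Flow-rate quantification

Pixel rate is `v · A_pix` with `A_pix` = lateral step × axial pixel size /
n_blood (refractive-index-corrected). Vessel rate is either the direct sum
over the lumen or, preferably, an **aperture-masked paraboloid fit**: pixels
within `Ra × R` of the center (working in physical µm to respect the
lateral/axial anisotropy) are fit by least squares to
`v(r) = vmax (1 − r²/R²)`, forced to zero at the wall, and the fitted
surface is integrated analytically (`vmax π R² / 2`). The default aperture
`Ra = 0.67` trades off two effects, both reproduced on synthetic maps with
injected wall artifacts: a smaller aperture suppresses the quadratic growth
of the rate with |α − 90°| caused by lumen-edge artifacts (the C2/C0
coefficient of a parabola fit across angles), while apertures below ~0.5
amplify measurement variability because fewer pixels support the fit.

Vessel center and radius default to the mask centroid and equivalent-area
radius; both can be supplied exactly when known (the synthetic truth does),
in which case the fit recovers exact paraboloid input to machine precision
and is aperture-invariant.

The **calibration constant** (3.18, network-to-reference) is stored
configuration, applied once at reporting time and flagged; it is never
baked into velocity maps, and a paired-rate estimator (zero-intercept
least squares) is provided to re-derive it from data. In the synthetic
world the simulator and the classifier share one forward model, so no such
factor arises; the constant is exercised as stored configuration only —
its physical value is an instrument-level measurement outside the
simulator's claims. For oblique vessels the fit and integration stay in
the B-scan plane and report plane-normal flow; no cosine correction is
applied to the network path.

Conservation across bifurcations is summarized as `|A − (B+C)| / A`, and
the diameter dependence of rates as an ordinary least-squares fit of
log(Q) on log(D).

## The phantom generator

`synth_stepped_mscan()` builds a complex stepped M-scan of a tube
cross-section with known ground truth:

* **static slab**: one circular-Gaussian speckle draw per pixel, constant
  in time, at the lumen's mean brightness by default;
* **noise-floor rows**: the deepest 10% of rows carry no sample signal,
  providing the noise region that SNR estimation and angiography masking
  assume exists below the sample;
* **lumen**: per-pixel forward-model speckle at the local Poiseuille speed
  `v(r) = vmax (1 − r²/R²)`, `vmax = 2Q/(πR²)`, multiplied by the
  deterministic axial phase ramp `exp(i t · 4π n v cos α τ / λ0)`;
* **shot noise** at the configured SNR; optional per-A-scan global phase
  jitter to exercise bulk-motion correction; optional raised-cosine
  pulsatility across repeated B-scans.

Decorrelation in the lumen is driven by the **total** speed. This matches
the near-perpendicular regime (α within ~10° of 90°) that the method
targets; at steep angles the transverse-only training model and the
phantom would diverge.

`synth_bifurcation()` derives daughter diameters from a branching power
law (`D_p^k = D_b^k + D_c^k`, default exponent 3) and encodes each
segment's Doppler angle as a depth shift between paired imaging locations
200 µm apart. `synth_vessel_series()` produces exact `Q = c D^k` datasets.
`synth_edge_artifact_map()` adds a one-pixel rim of elevated apparent
velocity growing as 0.1 per degree of |α − 90°| times the peak speed — the
synthetic stand-in for lumen-edge artifacts — plus optional multiplicative
pixel noise for variability studies.

**What the phantom does not model**: blood rheology and hematocrit-dependent
optics, Brownian motion, multiple scattering below the lumen, intravoxel
velocity gradients, and instrument specifics. Consequently, passing the
synthetic suite demonstrates *algorithmic* closure — each analysis stage
inverts the generative model it assumes — not optical realism. In
particular, the empirical network-to-Doppler scale factor observed on real
blood (attributed to exactly those unmodeled effects) cannot arise here,
which is why the calibration constant enters only as stored configuration.

## Numerical and degenerate-input conventions

* Circular means everywhere phases are averaged while possibly wrapped;
  linear averaging only after unwrapping.
* Likelihood products in log space; argmax ties toward the lower class,
  flagged.
* Self-normalization of an all-zero record is an error, as is noising an
  already-noisy series, re-filtering a filtered likelihood map, and
  applying a calibration twice.
* The paraboloid fit requires ≥ 6 pixels in the aperture; angle fits ≥ 3
  points; power-law fits ≥ 2 positive pairs.
* All generators are seeded; identical spec + seed reproduces libraries,
  phantoms and training bit-for-bit (training is serial by construction).
* Weights are double precision; the library stores records as doubles in
  memory and the container schema versions all on-disk formats.

## Problem sizes used by the shipped validation

Tests and the acceptance script run: the scaled bank above (three
networks); one 100×60-pixel noise-free phantom for Doppler closure; nine
edge-artifact maps for the angle sweep plus 12 noisy repeats per aperture
for variability; one bifurcation (three segments) classified end-to-end;
and assorted small fixtures. These sizes were chosen as the smallest at
which each qualitative effect is unambiguous; they are package choices,
not physical constants, and scale up cleanly through the same
configuration objects.

## Known limitations

* The classifier quantizes velocity to its grid; with the scaled 12-class
  grid adjacent classes are a factor 1.62 apart, so single-pixel estimates
  carry up to ±27% quantization error. Vessel-level fits dither this
  substantially but grid resolution, not physics, sets the floor there.
* The SNR-stratified bank interpolates between trained levels by nearest
  selection, not by blending.
* Quality-guided unwrapping has no residue balancing; pathological phase
  topologies are meant to be caught by the discontinuity rejection rather
  than repaired.
* The angiography mask assumes a single dominant vessel per B-scan (largest
  component); multi-vessel scans need external segmentation.
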