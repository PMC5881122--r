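---
title: "A spatio-chromatic model of parvocellular cone-tuning optimisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spatio-chromatic model of parvocellular cone-tuning optimisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Catarrhine primates carry three cone classes peaking near 440 (S), 535 (M)
and 562 nm (L). Purely spectral ideal-observer analyses of fruit-foraging
predict an optimal M peak 10–20 nm *shorter* than the observed 535 nm.
`parvocone` implements a spatio-chromatic alternative: it models the foveal
parvocellular pathway as an image-processing system and asks which pair of
peak sensitivities (λmaxM, λmaxL) best preserves a chromatic spatial
pattern — a sinusoidal grating whose two phases carry fruit and leaf
radiance spectra — at the stage of the cortical inputs.

## The model

A stimulus is an Nx × Ny × Nλ radiance stack on Λ = {400, 404, …, 700} nm
(Nλ = 76). For a reference grating P̄ ∈ [0,1] (two full cycles, Ny = 30, one
pixel = one cone = 1/120°), a target spectrum s_t, a background spectrum
s_b and an illuminant i, the image pipeline is:

1. illuminate: s = i ⊙ s′ for both spectra;
2. mix per pixel: p̄·s_t + (1 − p̄)·s_b;
3. multiply each pixel's spectrum by a 1/f luminance coefficient
   (shadow/shading noise), mean 1;
4. blur each wavelength plane with its diffraction-limited Airy disk
   (5 mm pupil, 1.22 λ/d first zero; long wavelengths blur more).

The retina is a square cone mosaic with i.i.d. labels (L with probability
0.5). Each cone's sensitivity is `10^(−Δ(λ)) · (1 − 10^(−D·ψ(λ, λmax)))`:
a Govardovskii-type A1 pigment template ψ (peak-normalised absorbance,
alpha plus beta band) converted to absorptance with peak optical density
D = 0.5, filtered by the combined lens + macular density Δ(λ) (a smooth
parametric approximation to standard human values; a Δ = 0 mode exists).
Quantal catch is the per-pixel inner product of image and sensitivity
(no photon noise). Midget-cell opponency is a difference-of-Gaussians with
a single-cone centre (σc = 0.25 cones), surround σs = 1.66 cones and a
9-cone window; `W_OFF = −W_ON`; convolution is "valid", discarding the 4
border pixels on each side, and masks and reference are trimmed
identically. Channel integration uses the cone-identifier masks:
red-green `O = L∘G_ON + M∘G_OFF`, luminance `O′ = G_ON`.

Performance of a peak pair is the mean, over all images, of
`PSNR(normalise(O), P̄)` (min–max normalisation to [0,1], peakval 1, MSE = 0
capped at 120 dB). `exhaustive_search()` scores every pair of a constrained
grid (λmaxL ≥ λmaxM) across replicate mosaics and returns a classed surface
with `print`/`summary`/`coef`/`plot` methods.

## The kernel normalisation choice

The surround weight of primate P cells is usually quoted as an *integrated*
surround:centre sensitivity ratio of ≈ 0.55. Writing the DoG with raw
peak-1 Gaussians and a surround amplitude of 0.55 instead makes the
surround integral ≈ 9.4 × the centre's, so the kernel's response to a
uniform field is strongly negative; the red-green combination then rides on
a ±(mask) pedestal proportional to local mean catch that buries the
opponent signal (outputs essentially decorrelate from the pattern). For the
red-green channel to behave as an opponent map at all — positive where the
centre cone is locally "redder", negative where "greener", with full scene
coverage — the kernel must integrate to zero. `make_receptive_fields()`
therefore defaults to the balanced form (both Gaussians normalised to unit
integral and differenced), and also exposes:

* `normalization = "integral"` — unit-integral Gaussians with the surround
  scaled by ω = 0.55 (the physiological integrated ratio; DC response
  1 − ω);
* `normalization = "none"` — the raw peak-amplitude form (centre value
  1 − ω = 0.45).

All three are tested; the balanced kernel is the one under which the model
reproduces the qualitative optima described below, and is used throughout.

## Synthetic spectra: what they emulate, and what they do not

No reflectance data are bundled; `synth_spectra()` generates four families
on Λ, bit-reproducible per seed:

* **fruit** — 80% logistic long-pass edges (inflection ~U(500, 640) nm,
  slope 8–25 nm), the rest green-peaked or dark/flat fruits. Because the
  model's task should not be solvable by brightness alone,
  `match_intensity()` rescales each fruit so its broadband radiance under
  the scene illuminant matches the mean-leaf background up to a log-normal
  scatter of sd 0.08 — fruit and leaf stimuli are then "highly similar in
  intensity", which is characteristic of measured fruit/leaf sets and
  forces discrimination through chromatic structure.
* **leaf** — chlorophyll-type curves: low pedestal (~0.04), green bump at
  548 ± 6 nm (height ~0.10, width ~32 nm), small red-edge rise near
  700 nm; small between-leaf variance. The background is always the
  pointwise mean of the leaf library.
* **munsell** — hue-diverse chips: short-pass (blues), band-pass
  (greens/yellows) and long-pass (oranges/reds) features at base
  0.04–0.12 and amplitude 0.30–0.60, emulating a hue circle at medium
  value. In image building, two chips are drawn per image randomly and
  without replacement; the *redder* chip (longer reflectance centroid)
  fills the grating crests. The orientation rule matters: with random
  orientation, half the outputs would be inverted patterns, and the PSNR
  comparison would penalise chromatic structure by construction.
* **illuminant** — a broad, smooth, green-biased curve (forest shade),
  mean 1.

These families capture reflectance smoothness, the long-pass structure of
ripe fruit, leaf/background similarity, and hue diversity. They do **not**
capture the short-wavelength (blue/purple fruit) reflectance present in
measured fruit databases, within-class covariances of real spectra, or
measured illuminant fine structure. Passing tests therefore demonstrate the
model's mechanics and directionally correct optima under these stylised
conditions, not quantitative agreement with any measured spectral library;
`run_experiment()` accepts external delimited spectra files for that
purpose.

## Luminance variation

`synth_luminance_field()` builds random-phase fields with 1/f amplitude
spectra (slope ≈ −1 on the radially averaged amplitude spectrum),
standardised to RMS contrast 0.3, floored at 0.05 and renormalised to mean
exactly 1. The moderate-contrast Gaussian form emulates *greyscale pixel
values* of photographs of leafy scenes — camera pixel values are
gamma-compressed luminance, hence roughly symmetric with mild contrast. A
heavy-tailed multiplicative (log-normal) variant was evaluated and drives
every optimum to full M/L overlap; it is not used. Fields are regenerated
per image from a dedicated RNG stream.

## Numerical choices

* Resampling of external spectra: linear interpolation onto Λ, truncation
  to 400–700 nm, negatives clipped to 0.
* Constant channel outputs normalise to all-0.5 (finite scores mid-search);
  PSNR is capped at 120 dB.
* Argmax ties break toward the shortest wavelength and are flagged.
* Confidence intervals are normal-theory mean ± 1.96 sd/√n; the
  two-condition comparison is a Welch t-test by default (pooled optional).
* Seeds: every source of randomness (mosaic, luminance fields, spectrum
  draws, replicates) is a named stream derived from one master seed
  (`derive_seed()`), so ablations change one factor at a time and runs are
  bit-reproducible.
* PSF convolution wraps around (the stimulus is periodic in x), so each
  wavelength plane's sum is conserved; the DoG convolution is "valid" and
  border effects are removed before scoring.

## Behaviour of the metric, and a known limitation

A constant 0.5 output scores ≈ 9.03 dB against the sinusoidal reference;
informative outputs must clear this. Under the balanced kernel the
searches sit in the sane regime, and at reduced scale (60–100 images,
5 replicate mosaics, 4 cpd — the problem sizes used by the test suite and
`scripts/acceptance.R`, chosen to keep a full run in minutes) the package
computes: an optimal λmaxM near 526 nm with replicate sd ≈ 1 nm when
luminance variation is on; a free λmaxL that always occupies the longest
wavelength in the grid; a red-green score above the luminance-channel
score; and diverse-hue performance that increases monotonically with peak
separation.

Two qualitative expectations are *not* met under the synthetic conditions,
and the acceptance tests that encode them fail honestly. First, the
per-replicate diverse-hue optimum usually sits one to three 10-nm grid
steps inside the maximal-separation corner (the gradient along the
diagonal is shallow relative to replicate noise, though the mean surface
does peak at the corner). Second, *removing* luminance variation moves the
optimal λmaxM longer (toward λmaxL), not shorter: without short-wavelength
fruit–leaf contrast in the synthetic fruit family, the no-noise condition
favours the cleanest near-diagonal configurations. With measured fruit
databases — which include blue/purple fruits and richer short-wave
structure — the expected direction is a shift toward shorter wavelengths;
testing that requires external spectra via `run_experiment()`.

## Scope

S cones, rods, photon noise, cone coupling, non-1:1 L:M ratios, hexagonal
mosaics, eccentricity-dependent receptive fields, cortical spatial
integration and colorimetric transforms are out of scope by design.
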