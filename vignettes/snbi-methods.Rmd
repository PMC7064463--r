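---
title: "Methods: the snapshot narrow-band imaging pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the snapshot narrow-band imaging pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snbi)
```

## The measurement model

A snapshot narrow-band camera bonds a 2×2 periodic filter mosaic to a
monochrome sensor. One period — a *spectral pixel* — contains four
sub-spectral pixels, each passing one narrow band: 415, 450, 525 and 620 nm.
The physiological basis is hemoglobin: lesions of increasing grade (normal →
inflammation → CIN1 → CIN2 → CIN3 → carcinoma in situ) carry increasing
hemoglobin load, which absorbs strongly near 415 nm, depresses reflectance
near 620 nm, and leaves a reflectance peak near 525 nm; 450 nm carries no
lesion signature and serves as a background band. Because all four bands are
captured in one exposure through one optical path, the band images are
co-registered by construction — there is deliberately no registration code in
this package.

The default `mosaic_layout()` encodes the reference geometry: 320 × 270
spectral pixels, each covering 8 × 8 sensor pixels (4 × 4 per band cell).
Which band occupies which 2×2 cell is hardware-specific and never uniquely
determined by the data, so it is explicit configuration; the default assigns
415/450/525/620 row-major.

## Demosaicing

`demosaic()` reduces each band cell to one value by averaging its interior
sensor pixels. The mean is the default statistic because, for a uniform
response within a cell, it minimizes the noise of the binned estimate; a
median option is provided for sensors with hot pixels. A `gap_margin`
parameter can exclude a border of sensor pixels around each cell for mosaics
whose inter-filter gap is comparable to the pixel pitch; the reference
hardware's gap (~1 µm against a 6.5 µm pitch) is sub-pixel, hence the default
of 0, at which `demosaic()` is the exact inverse of `mosaic_render()` — a
property the test suite exercises as a round-trip identity. Saturated pixels
are included in the statistic but counted and surfaced as a warning, since
silently averaging clipped values would bias the band estimate downward
without trace.

## Flat-field normalization

Band images are made comparable by

$$I(\lambda) = \frac{I(\lambda)_{sample} - \overline{I(\lambda)_{dark}}}
{\overline{I(\lambda)_{board}} - \overline{I(\lambda)_{dark}}}$$

where the overbars are per-band *scalar* means over dark-current frames and
white-reference-board frames. The scalar form is intentional: the correction
targets band-to-band differences (illumination spectrum, quantum efficiency,
filter transmittance), not pixel-to-pixel ones. A consequence worth knowing:
spatial illumination non-uniformity is *not* removed — a normalized pixel
equals its reflectance times the ratio of local to mean illumination. The
synthetic experiments below keep that effect in play on purpose.

Two policy choices are this module's own. Negative normalized values (sample
below the dark level, possible under noise) are clipped to 0, since
reflectance is physically non-negative. Values above 1 are kept — specular
highlights can legitimately exceed a matte Teflon board — but counted and
reported. Normalizing twice is refused outright rather than warned about,
because a doubly-normalized stack is silently meaningless downstream.

## Fusion

The four normalized bands collapse into one contrast image:

$$I_{fused} = \left(\frac{I_{620} - I_{450} + I_{415} - I_{525}}{\alpha}\right)^2$$

The inner difference $d$ pairs the two hemoglobin-dark bands (415, 620)
against the background and hemoglobin-bright bands (450, 525), so $|d|$ grows
with hemoglobin content; squaring makes the output respond to the magnitude
of the spectral contrast regardless of sign. The scale factor $\alpha$ is
defined only by its purpose — keeping the output within $[0, 255]$ — so the
package makes it operational: by default $\alpha = \max|d| / \sqrt{255}$ per
frame, which pins the brightest fused pixel at exactly 255
(`alpha_policy = "auto_per_frame"`). For video streams, a fixed $\alpha$
avoids frame-to-frame flicker at the cost of clipping at 255; both policies
are recorded in the result. Fusing unnormalized intensities is refused:
normalization precedes fusion in the pipeline, and raw counts would let
exposure differences masquerade as contrast.

## Seeded minimum-distance classification

Supervision is weak by design: the operator marks one or two small regions
per tissue type, without boundaries. For a pixel of intensity $I$ (scalar on
the fused image; a vector on a multi-channel image) and the $p$ seed pixels
$S_i^x$ of type $x$,

$$D_{Ex} = \sqrt{\sum_{i=1}^{p} (I - S_i^x)^2}, \qquad C_x = \min_x D_{Ex}$$

`classify_pixels()` computes this with the expanded quadratic form
($\sum_i \|I - S_i\|^2 = p\|I\|^2 - 2 I \cdot \sum_i S_i + \sum_i \|S_i\|^2$),
vectorized over pixels; an independent per-pixel, per-seed double loop serves
as the oracle in the tests, and the two agree exactly on randomized
instances.

The summed form grows with $p$, which biases against classes with more
seeds. `mode = "sum"` keeps the summed definition as the default;
`mode = "rms"` divides by $p$ inside the root and is the statistically sane
choice for unequal seed counts. The package's own experiments use equal-size
seed patches per class, where the two modes provably coincide (a tested
property). Ties break toward the first class in declared order —
deterministic by construction — and seed pixels always retain their own
class. No spatial regularization is applied; contours derive solely from the
label map.

`extract_contours()` defaults to `label_boundary`, which marks exactly the
pixels whose 4-neighborhood contains a different label: parameter-free and
exact on a label map. A classical Canny operator (Gaussian blur, Sobel
gradients, non-maximum suppression, hysteresis) is available for rendering
smoother boundary overlays; its defaults (σ = 1, hysteresis at 0.10/0.20 of
the maximum gradient) are ordinary textbook settings, configurable because
no principled values exist for a label raster.

`evaluate_regions()` scores accuracy at *region* level: each ground-truth
region's predicted class is the majority label over its pixels, and accuracy
is correct regions / total regions. Region-level majority voting is what
matches per-sample integer accounting against a histopathological gold
standard; pixel-level accuracy is deliberately not reported, as no pixel-level
truth exists in that setting.

## The synthetic phantom

The phantom exists to make every stage testable, end to end, without
clinical data. `make_scene()` builds a class map at spectral-pixel
resolution plus per-class band reflectance:

* **Reflectance** (`phantom_reflectance()`): for severity rank
  $k = 0..5$ and contrast level $c \in (0, 1]$, reflectance is
  $0.50 - 0.05ck$ at 415 nm, $0.60 - 0.05ck$ at 620 nm, $0.50 + 0.01ck$ at
  525 nm, and a constant $0.65$ at 450 nm. These are *stipulated,
  ordering-constrained stand-ins* — no per-class tissue reflectance is
  published to emulate — chosen so the band difference
  $|d| = 0.05 + 0.11ck$ is strictly increasing in grade with comfortably
  separated steps. The constructor enforces the ordering invariant
  (415/620 strictly decreasing, 525 non-decreasing with severity) and
  rejects degenerate identical vectors.
* **Scene geometry**: a `"lesion"` preset (carcinoma-in-situ core, CIN3
  ring, CIN2 ring on normal background — the concentric topology of an
  advancing lesion) and a `"table1"` preset: 24 disk regions in the
  composition 7 normal / 5 inflammation / 3 CIN1 / 3 CIN2 / 3 CIN3 / 3
  carcinoma in situ on a 6 × 4 grid with seeded jitter. Regions hold ≥ 100
  spectral pixels so majority voting is stable.
* **Rendering** (`render_frames()`): per band,
  `reflectance × illumination × exposure_scale + dark_offset + noise`,
  laid onto the sensor grid by `mosaic_render()`. Defaults:
  `exposure_scale = 40000` counts (mid-range for a 16-bit sensor),
  `dark_offset = 400` counts, `noise_sd = 200` counts — the shot-noise scale
  at 40 k counts ($\sqrt{40000} = 200$), i.e. realistic moderate noise — and
  a radial illumination vignette of amplitude 0.08, a gentle falloff typical
  of simple illumination optics. Board frames use reflectance 1; dark frames
  reflectance 0 with no illumination. Everything is deterministic given the
  scene seed. A Poisson noise mode was considered and dropped: at 40 k
  counts the Gaussian approximation is indistinguishable for every property
  tested here.

With flat illumination and zero noise, normalization inverts rendering
exactly, so the normalized bands recover the stipulated reflectance vectors
to machine precision — the pipeline's closed-form self-check. With noise,
recovery holds within the propagated bound $3\sigma/(board - dark)$ for at
least 95 % of pixels.

## The two-arm reference experiment

`run_reference_experiment()` mirrors a clinical comparison on the synthetic
stand-in: the `table1` scene is rendered, pushed through the full SNBI
pipeline, classified from one 5 × 5 seed patch per class, and scored at
region level; the same classifier with the same seed coordinates then runs
on a synthetic white-light color image of the same scene. The color arm maps
grades to closely spaced mucosa hues (≈ 2 % channel steps) with the same
vignette and *no* flat-field correction — conventional color imaging has
none — so the deterministic illumination shift (up to ≈ 6 % of brightness)
exceeds the inter-grade color spacing. That structural compression, not
noise, is what degrades the color arm; the experiment demonstrates the
*direction* (color accuracy below SNBI accuracy), not any particular
clinical figure, which would depend on unavailable clinical images.

Problem sizes are the package's chosen working scale: the experiment runs on
a 160 × 135 spectral-pixel canvas with 2 × 2 binning (a 540 × 640 sensor
frame), where the full two-arm experiment completes in well under a second
and the whole test suite in seconds. The full 320 × 270, 8 × 8-binned camera
geometry remains the `mosaic_layout()` default and runs through the same
code paths.

What passing these experiments shows: the pipeline's algebra is correct, the
fused statistic separates grades whose band reflectance is ordered as
hemoglobin physiology dictates, and it does so under sensor noise and
illumination non-uniformity that scalar normalization cannot remove. What it
does not show: performance on real tissue, where reflectance spacing is not
guaranteed, textures and specularities exist, seed placement is imperfect,
and grade boundaries are gradual rather than sharp. The phantom also renders
piecewise-constant regions — no within-class biological variability beyond
sensor noise — which flatters any classifier; conclusions about clinical
accuracy require clinical data.

## Numerical and degenerate-input choices

* Auto-α fusion computes $255 (d/\max|d|)^2$, algebraically identical to
  $(d/\alpha)^2$ but exact in floating point: the maximum lands on 255 and
  no value escapes $[0, 255]$.
* An all-zero band difference under auto α returns an all-zero image with
  α = 1 and a notice, rather than dividing by zero.
* Classifier distances are compared as squared distances; the guard
  `d2[d2 < 0] <- 0` absorbs negative round-off from the expanded quadratic.
* Classification ties break by declared class order; majority-vote ties in
  `evaluate_regions()` break the same way via `which.max`.
* Degenerate calibration (board mean ≤ dark mean) is an error naming the
  offending band, not a silent NaN.
* File formats are plain: 8/16-bit integer TIFF/PNG for frames, 32-bit float
  TIFF for the fused image (stored on a [0, 1] scale, rescaled by 255 on
  write), JSON/YAML for layout, references, seeds and the manifest. Seed
  coordinates are 0-based on disk (image convention) and 1-based in R.

## Known limitations

* The scalar flat-field model leaves spatial illumination structure in the
  normalized bands; a per-pixel flat-field variant would be the natural
  extension for optics with stronger vignetting.
* The classifier is purely spectral: no texture, shape or neighborhood
  features, and no probabilistic output. This is faithful to the method's
  real-time design point (simple arithmetic only), not a modeling judgment.
* Band-to-cell assignment must be supplied (or defaulted) as configuration;
  the package cannot infer it from a frame.
* The Canny operator works on the label raster rendered as intensity, so
  multi-class junctions can produce locally thick or broken edges;
  `label_boundary` is exact and preferred for quantitative use.
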