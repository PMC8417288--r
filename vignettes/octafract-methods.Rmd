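---
title: "Fractal-dimension quantification of OCTA angiograms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractal-dimension quantification of OCTA angiograms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octafract)
```

## The problem

Optical coherence tomography angiography (OCTA) produces en face maps of
retinal blood flow, segmented into a superficial (SCP) and a deep (DCP)
capillary plexus. In retinal vascular disease the clinically relevant
changes are capillary rarefaction (loss of flow signal between vessels),
alteration of the foveal avascular zone (FAZ), and — as a confounder —
projection artifacts, where flow in superficial vessels replicates their
pattern into the deep slab and inflates its apparent vasculature.

`octafract` quantifies these on single-channel en face angiograms. Its
central statistic is the *local box-counting fractal dimension*, used as a
per-pixel index of vessel presence, normalized per image and cut into three
bands: **vessel**, **spacing between small vessels**, and **spacing between
large vessels**. The two spacing percentages quantify capillary dropout;
the vessel percentage is the vessel density. Because no public image data
accompany these metrics, the package ships a synthetic phantom generator
with exact ground truth, and every claim the test suite makes is made
against that ground truth.

## Pipeline

For one eye (an SCP/DCP pair on the same scan geometry), `analyze_eye()`
runs, in fixed order:

1. **Projection estimation and removal** (`estimate_projection()`,
   `remove_projection()`) — DCP only, before any quantification.
2. **Binarization** (`binarize()`) — Otsu's between-class-variance
   threshold on the intensity histogram.
3. **Local fractal dimension** (`local_fractal_dimension()`) on the binary
   mask.
4. **Normalized ratio** (`normalized_ratio_map()`) — division by the
   image's own maximum dimension.
5. **Band classification** (`classify_pixels()`) and **band percentages**
   (`band_percentages()`) over the whole image and over the 1–2.5 mm
   parafoveal ring (`parafoveal_ring()`).
6. **FAZ measurement** (`measure_faz()`) on the binary mask.
7. **z-scores** against a normative reference (`compare_to_normative()`).

## The local fractal dimension

At every pixel a window of side `window_px` (default 33, odd) is centred;
within it, boxes of side $s \in \{16, 8, 4, 2\}$ px tile the window from
its top-left corner (complete boxes only; the partial strip beyond the
last complete box is ignored). The local dimension is the least-squares
slope of $\log N(s)$ against $\log(1/s)$, where $N(s)$ is the number of
boxes containing foreground. Conventions, all of which matter for
reproducibility:

* Windows are clipped, not padded, at image borders, and tiled over their
  clipped extent.
* Box sizes whose complete tiles capture no foreground are dropped from
  the regression; if fewer than two sizes remain the dimension is 0, as it
  is for a window with no foreground at all.
* The slope is clamped to $[0, 2]$, the meaningful range for planar sets.
* At least 3 box sizes are required; fewer make the slope unreliable.

Under this convention a filled window has $N(s) = (32/s)^2$ exactly and
dimension 2.0; a one-pixel straight line has $N(s) = 32/s$ and dimension
1.0. A capillary mesh sits between ~1.3 and ~1.9 depending on its local
density, which is precisely what makes the dimension usable as a
vessel-presence index. The 33 px default (~0.33 mm at 3 mm / 304 px) spans
several capillary spacings while remaining local; powers of two give
evenly spaced abscissae in the log-log regression. Window and box sizes
are exposed in `octa_config()` — published band percentages are only
comparable under the same convention.

The per-pixel computation is an integral-image kernel in C++ (each
box-occupancy query is O(1)), so a full 304 × 304 map takes well under a
tenth of a second. An independently coded brute-force oracle (submatrix
scans) is kept in the test suite and the two are required to agree to
1e-9.

## Normalization and bands

Each pixel's dimension is divided by the *maximum dimension observed in
the same image* (not the theoretical 2), so a vessel-bearing image always
attains ratio 1 somewhere and the band cut points keep their meaning
across window conventions. The bands are declared as an exact partition —
large spacing $[0, 0.3)$, small spacing $[0.3, 0.7)$, vessel $[0.7, 1]$ —
because prose interval statements ("between 0.3 and 0.7") overlap at the
cut points; the half-open convention resolves the boundary pixels
deterministically and is configurable via `class_bands()`.

Vessel density is the vessel-band pixel count divided by the pixel count
of the analysed region, times 100. Both the whole image (the convention
behind the shipped normative values) and the parafoveal ring are reported,
clearly labelled, since either denominator is defensible and published
sources are not always explicit about which was used.

## FAZ measurement

The FAZ is segmented as the connected avascular region containing the
fovea: the binarized vessel pattern is morphologically closed with a disc
of radius `faz_closing_radius_px` (default 5 px ≈ 0.05 mm, enough to
bridge normal intercapillary gaps of up to ~0.1 mm so that intercapillary
spaces do not merge with the FAZ), the non-vessel connected component
containing the fovea centre is selected, and its pixel count is converted
to mm². If the centre pixel falls on a vessel, the nearest avascular pixel
within 5 px seeds the search; if none exists the FAZ is reported *absent*
(`NA`), never zero — absence of a measurable FAZ is a clinically distinct
finding and propagates as a quality flag.

The measurement deliberately uses the binary mask rather than the
vessel-class map: the fractal window smears vessel evidence ~half a window
(16 px) into the FAZ, so a class-map FAZ is biased low by several tens of
percent, while the binary boundary is sharp. On phantoms with carved discs
of 0.20 / 0.42 / 0.80 mm² the measured areas are within 1–2% of truth.

## Projection-artifact removal

The model is a single global contamination scale $\alpha$: observed DCP
$= $ true DCP $ + \alpha \cdot$ SCP, top-coded at the detector ceiling 1.
Removal subtracts $\hat\alpha \cdot$ SCP and clips to $[0, 1]$. Two
departures from the naive least-squares recipe are load-bearing:

* **$\hat\alpha$ is a conditional-quantile regression slope**
  ($\tau = 0.25$, fitted by IRLS), not covariance over variance. Wherever
  intrinsic deep flow coincides with a projected superficial vessel the
  sum exceeds the ceiling and is recorded as 1; this one-sided censoring
  biases the OLS slope substantially (by up to −0.2 at strong
  contamination in phantom experiments) while the lower conditional
  quantiles of the deep signal are untouched as long as fewer than
  $1 - \tau$ of the pixels at any superficial intensity are saturated.
  The OLS slope is still reported (`slope_ls`) for comparison, and the
  zero-lag normalized cross-correlation `correlation_r` is reported as
  the contamination diagnostic.
* **Saturated pixels are exempt from subtraction.** A top-coded value
  carries no information about how much projected signal it contains, and
  since background plus projection cannot reach the ceiling, a saturated
  deep pixel almost surely overlies true deep flow. Subtracting there
  carves spurious vessel shadows — in phantom experiments this single rule
  is the difference between removal restoring the deep vessel density and
  removal making it worse than the contaminated measurement.

$\hat\alpha$ is clamped to $[0, 1.5]$ with a warning; mildly negative fits
occur by chance on genuinely uncontaminated pairs and clamp to 0, making
removal a no-op. One subtlety the phantom experiments exposed: weak
contamination (scale ~0.3) often does not move the thresholded metrics at
all, because the adaptive binarization threshold sits above the projected
intensities — removal then neither helps nor harms.

## The phantom generator

`generate_phantom()` produces SCP/DCP pairs with exact ground truth. The
model, chosen once as a realistic emulation of the structures the metrics
assume:

* **Capillary mesh** — the set of pixels where a Gaussian-smoothed random
  field (correlation length `capillary_scale_px`, default 3 px) is nearest
  its zero level. The level curves of a smooth field form closed,
  anastomosing loops with spacing set by the correlation length, which is
  the morphology of a capillary plexus at this resolution. The admission
  threshold is modulated by a coarser lognormal field
  (`capillary_heterogeneity` = 2.5, scale 40 px): real plexuses are not
  uniformly dense, and without this heterogeneity the fractal-ratio
  histogram collapses into the vessel band instead of spreading over all
  three. The overall threshold is set by rank so the mesh covers exactly
  `capillary_density_target` (default 0.35) of the non-FAZ area.
* **FAZ** — a carved central disc of exactly the requested area (default
  0.42 mm², the normal adult value), delimited by a *terminal capillary
  ring* (the synthetic counterpart of the perifoveal arcade). The ring is
  what makes the carved area recoverable to ~1%: without it the measured
  avascular zone extends to the first mesh line, overshooting by a
  mesh-spacing margin. `faz_irregularity` perturbs the outline smoothly to
  emulate the broken perifoveal network of disease (the area ground truth
  is then only approximate).
* **Large vessels** — `n_large_vessels` (default 6) smooth random paths
  steered around the FAZ, dilated to `large_vessel_width_px` (default
  7 px ≈ 70 µm).
* **Dropout** — discs of radius `dropout_patch_radius_px` (default 6 px ≈
  60 µm: fine-grained rarefaction rather than confluent nonperfusion)
  placed uniformly at random erase capillary pixels — never large-vessel
  pixels — until exactly the requested fraction of capillary pixels is
  gone (the last patch is trimmed). For a fixed seed the erasures are
  nested across dropout levels, so coverage decreases strictly.
* **Rendering** — vessel pixels 0.8, background 0.1, additive Gaussian
  noise (default sd 0.05), clipped to $[0, 1]$. Projection contamination
  adds `projection_scale` times the rendered SCP to the rendered DCP,
  clipped — the exact generative counterpart of the removal model.

All randomness derives from `spec$seed` through fixed per-stage offsets;
identical specs give bit-identical phantoms, and the caller's RNG stream
is left untouched.

### What the phantoms do and do not show

The phantoms emulate the *geometry* the metrics assume: two-scale
vasculature, an area-exact FAZ, patchy capillary loss, and linear
projection contamination with detector saturation. They do **not** emulate
OCT speckle, motion or blink artifacts, edema-induced shadowing,
segmentation errors, vessel-calibre variation within a class, or true
three-dimensional projection physics. Passing the phantom suite therefore
validates the computational pipeline — the box-counting estimator against
its oracle, area recovery, contamination-scale recovery, direction of the
disease response — not clinical accuracy on device images. The phantom
family's healthy band split (~65–72% vessel on the default spec) is denser
than real normative data (~48%), mostly because the synthetic large-vessel
tree is denser than a real arcade; direction checks, not level checks, are
what the suite asserts.

One documented wobble: under increasing dropout the vessel band falls and
the large-spacing band rises strictly (both are monotone per pixel once
the erasures are nested and the image maximum dimension is saturated at
2), but the small-spacing band is a net-flux band — it gains from above
and loses to below — and on a small fraction of seeds a single step can
dip by well under a percentage point. The suite asserts strict
monotonicity of all three bands at the generator's default-seed
conditions and the pairwise intact-versus-dropout direction on a
20-seed batch.

```{r dropout-direction}
intact <- generate_phantom(phantom_spec(seed = 1))
dropped <- generate_phantom(phantom_spec(dropout_fraction = 0.4, seed = 1))
rbind(
  intact = as.data.frame(band_percentages(classify_pixels(
    normalized_ratio_map(local_fractal_dimension(binarize(intact$scp)))),
    layer = "SCP"))[, 3:5],
  dropout_40 = as.data.frame(band_percentages(classify_pixels(
    normalized_ratio_map(local_fractal_dimension(binarize(dropped$scp)))),
    layer = "SCP"))[, 3:5]
)
```

## Normative comparison

`normative_reference()` ships per-layer means and standard deviations for
the four metrics (healthy adults, 3 × 3 mm scans, whole-image
denominator) as an editable YAML; `compare_to_normative()` reports
$z = (x - \mu)/\sigma$ and flags $|z| > 2$. The shipped spreads are used
as printed by their source; whether a published "±" is an SD or an SEM is
not always stated, so the file is a convention to be replaced by a
device- and population-matched cohort for any real use. Low signal
strength (SSI < 40) and absent FAZ are carried as quality flags, never
hard errors — they are acquisition facts, not analysis failures.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on generated
phantoms at the native 304 × 304 scan size: a 50-phantom partition batch,
a 30-run projection grid (scales 0.3/0.5/0.8 × 10 seeds), three FAZ
areas, a six-level dropout ladder, and ten 64 × 64 oracle masks — about a
minute in total, thanks to the compiled box-counting kernel. Every
stochastic step is seeded; the full pipeline serializes to byte-identical
JSON across repeated runs of the same spec, seed and configuration.
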