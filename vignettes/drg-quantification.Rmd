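---
title: "Automated quantification of immune signals in DRG fluorescence images"
author: "drgquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated quantification of immune signals in DRG fluorescence images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drgquant)
library(dplyr)
```

## The measurement problem

Dorsal root ganglion (DRG) sections are densely packed: sensory neuron
somata sit inside a satellite-glial envelope, surrounded by nerve fibers,
nuclei, and scattered immune cells whose MHCII staining runs more than five
times brighter than the faint MHCII on the neurons themselves. Asking "what
fraction of neurons express MHCII?" therefore requires a chain of masking
decisions — which pixels are a neuron, which belong to its glial rim, which
bright signal is a neighboring immune cell bleeding over the border — and
every manual answer to those questions imports observer bias. `drgquant`
implements that chain as a deterministic, parameterized pipeline, and pairs
it with a synthetic ground-truth generator so that every stage can be
checked by parameter recovery instead of by eye.

The pipeline quantifies, per section and pooled per mouse:

* the percent of MHCII⁺ DRG neurons (overall and within soma-size classes),
  classified against an isotype-control-derived threshold;
* MHCII puncta per neuron and the percent of neuron area they occupy;
* surface-MHCII (and OVA-peptide) polarization on cultured neurons;
* the percent of RFX1⁺ neuronal nuclei;
* CD3⁺CD4⁺ T cells per mm² of neuron-containing tissue;
* soma diameters, their small/intermediate/large classification, and a
  Gaussian fit to the pooled diameter distribution;
* thermal place preference (TPP) behavior scores from timed plate-occupancy
  logs.

## The section pipeline, step by step

1. **Tissue mask.** The pan-neuronal marker channel (PGP9.5) is smoothed
   (Gaussian, σ = 2 px), thresholded, and hole-filled. With the default
   `"otsu"` setting the class split is found on log intensity — on a linear
   scale the very bright somata dominate the between-class variance and
   Otsu separates somata from everything else, not tissue from glass — and
   the final cut is then refined to the midpoint of the two class medians
   in linear space. The midpoint rule places the mask edge at the 50% point
   of the smoothing ramp, i.e. at the true tissue boundary, which keeps the
   tissue area (the denominator of the T-cell density) unbiased.
2. **Neuron instances.** Supra-threshold marker components are filtered by
   area (default gate: 8–60 µm equivalent diameter) and marker MPI, and
   fiber-like components are removed. The fiber rule is moment-based:
   eccentricity > 0.97 or major/minor axis ratio > 5. (A skeleton
   length-to-width criterion would test the same property; image moments
   need no thinning pass and are already computed for every component.)
3. **Shrink.** Each soma mask is eroded by a Euclidean disc of radius 4 px,
   pulling the border inside the satellite-glia rim so perisomatic signal
   cannot contaminate the soma's MPI. The structuring element is a disc so
   that the border moves isotropically — "decrease the border by k pixels"
   then means the same thing in every direction.
4. **Non-neuronal MHCII mask, grown.** Components of MHCII signal at or
   above 25,000 AFU (the published immune-cell cutoff) within the
   immune-cell size gate are dilated by a 7-px disc to swallow their dim
   fringe. Where two grown cells meet, contested pixels go to the nearest
   original cell.
5. **Exclusion.** Grown non-neuronal pixels are subtracted from the
   shrunken somata. Somata losing every pixel are flagged unmeasurable and
   excluded from both numerator and denominator of positive fractions —
   they carry no intensity evidence either way.
6. **MPI and classification.** Per-soma MHCII MPI is the arithmetic mean
   over the surviving pixels. The MHCII⁺ threshold is the 99th percentile
   of the per-neuron MPI distribution measured on isotype-control sections
   (type-7 linear interpolation between order statistics, fixed for
   reproducibility). All positivity comparisons are strict `>` — the one
   comparator the method states explicitly is the nuclear RFX1 rule
   "MPI > 37.19", and the package applies the same strictness everywhere,
   so an object exactly at threshold is negative.
7. **Puncta.** Within each measurable soma, the local background is the
   median MHCII intensity over the soma's own pixels; puncta are
   8-connected components of pixels at or above background + 800 AFU with
   area ≥ 2 px (the "≥ 1.5 px" rule with integer component areas). Percent
   puncta area divides the summed puncta area by the measurable soma area.
8. **Nuclei and RFX1.** DAPI components are size/intensity-filtered; a
   nucleus is neuronal iff its centroid falls inside a neuron instance, in
   which case it inherits the neuron's id. Nuclear RFX1 MPI > 37.19 flags
   the neuron RFX1⁺; the denominator is neurons with a visible nucleus.
9. **T cells.** CD3 and CD4 components are detected independently; a CD3
   component is a CD4⁺ T cell when ≥ 50% of its pixels lie in CD4⁺
   components (tolerant to small channel registration error) and its
   centroid is inside the tissue mask. Density is the pooled ratio — total
   cells over total tissue area across a mouse's sections — which is
   unbiased when section areas differ, unlike the mean of per-section
   densities.

Cultured-neuron (ICC) scenes skip the tissue/shrink/grow machinery: somata
are segmented directly and surface polarization is scored as the percent of
soma area covered by 8-connected components (≥ 2 px) of signal at
≥ 1.7-fold the local background.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `shrink_px` | 4 | px | erosion radius excluding the glial rim |
| `grow_px` | 7 | px | dilation radius of the non-neuronal MHCII mask |
| `nonneuronal_mhcii_min` | 25,000 | AFU | immune-cell MHCII cutoff |
| `delta_afu` | 800 | AFU | per-pixel puncta offset above local background |
| `min_area_px` | 1.5 (→ 2) | px | minimum punctum area |
| `polar_fold` | 1.7 | — | polarization fold over background |
| `polar_min_area_px` | 2 | px | minimum polarized component |
| `rfx1_threshold` | 37.19 | AFU | nuclear RFX1 cutoff (fixed, strict `>`) |
| `pixel_area_um2` | 6.718 | µm²/px | area→diameter conversion constant |
| `small_max_um` / `large_min_um` | 25 / 30 | µm | soma size classes |

All intensity thresholds operate on raw stored AFU values; the package
never normalizes intensities, because the AFU-denominated cutoffs above are
defined on the instrument scale. Thresholds the method leaves symbolic
(tissue, PGP9.5, CD3, CD4, DAPI) default to Otsu on the relevant channel
and accept absolute AFU overrides. The stated 25–30 µm soma band is tracked
as an explicit `intermediate` class rather than forced into small or large,
because the small class is defined as ≤ 25 µm and the large class as
> 30 µm: the band belongs to neither, and hiding it would silently change
both class denominators.

The `"≥ 800 MPI above local background"` puncta rule is read as a
*per-pixel* offset (a punctum pixel must reach background + 800) rather
than a component-mean criterion; a `background_estimator = "annulus_median"`
switch is provided for sensitivity analysis of the background definition.
The median-in-soma default is used because puncta occupy a small fraction
of the soma, so the median sits on the diffuse level while a mean would be
dragged upward by the puncta being measured.

## The synthetic ground-truth generator

Raw study images are not deposited, so the package ships a generator whose
defaults define the verification conditions:

* a tissue band covering 50% of a 512-px frame, with faint neuropil
  autofluorescence (500 AFU) under bright somata (12,000 AFU);
* 35 small + 15 large somata per scene, rendered as rotated ellipses of
  axis ratio 0.8–1.0 whose semi-axes are scaled so the equal-area
  equivalent diameter is exactly the sampled truth diameter; small
  diameters are normal(18, 3) truncated to (8, 25] µm, large are
  normal(38, 4) truncated to (30, 60] µm, mirroring the bimodal
  small/large structure of DRG somata;
* 30% MHCII⁺ somata (the naïve-tissue scale) carrying a 4,000 AFU diffuse
  base plus 2–4 planted puncta of 3–6 px at base + 1,200 AFU; puncta are
  placed so every pixel survives a 5-px erosion of the soma, so the 4-px
  analysis shrink can never clip one;
* 6 immune cells at 30,000 AFU MHCII (> 5× the neuronal base, straddling
  the 25,000 cutoff from above), 12 CD3⁺CD4⁺ T cells and 5 CD3-only
  distractors, one nucleus per cell plus 10 satellite nuclei pressed
  against neuron borders;
* RFX1 on a separate low-AFU scale (positive nuclei 300, negative 10,
  noise sd 8) consistent with its 37.19 cutoff — the RFX1 acquisition is a
  12-bit confocal scale, distinct from the 14-bit widefield scale of the
  other channels;
* additive Gaussian read noise, sd 100 AFU (= `delta_afu`/8), rounded and
  clipped to the 16-bit container.

The scene pixel footprint defaults to 1 µm²/px. This is a deliberate
divergence from the 6.718 µm²/px *conversion constant* used for
area→diameter: at 2.59 µm pixel pitch a ≤ 25 µm soma is under 5 px in
radius, and the pixel-denominated mask operations (4-px shrink, 7-px grow,
2-px puncta) would be geometrically meaningless — the shrink alone would
erase every small soma. At 1 µm pitch those parameters span the 1–7 µm
structures (glial rim, sub-cellular spots) they are meant to capture. The
6.718 constant remains the default wherever a pixel area is not supplied
explicitly, and all pipeline size gates are specified in µm and converted
through whatever pixel area the image declares.

Rendering is binary (no point-spread function, no partial-volume edges), so
in the noiseless limit every planted object's rendered pixel area is exact
and the test suite can assert exact recovery of counts, areas, puncta pixel
sets, RFX1 calls and T-cell counts. That is also the generator's main
limitation: real images have blurred borders, intensity gradients within
somata, touching cells and autofluorescence texture. Passing recovery tests
here demonstrates that the *rules* are implemented exactly as stated and
are stable under additive noise — not that the default thresholds are
optimal on any particular microscope's output. Touching-soma splitting
(watershed) is deliberately out of scope: synthetic scenes guarantee a 2-px
separation, and the instance gates assume separated objects.

## Numerical conventions

* Coordinates are 1-based `(row, col)` with the origin at the top-left
  pixel, matching R's matrix indexing.
* Components are 8-connected everywhere (configurable to 4), with
  deterministic raster-order labeling.
* Shrink/grow use exact Euclidean-disc morphology: a pixel survives
  erosion by radius *k* iff every pixel within Euclidean distance ≤ *k* is
  foreground, with pixels outside the image counting as background. The
  test suite holds this to bitwise agreement with a brute-force
  distance-transform oracle.
* Percentiles use the type-7 convention (position 1 + p·(n−1)).
* Erosion-extinct or fully-excluded instances are dropped with a logged
  message, never silently.
* Somata under 25 measurable pixels are not puncta/polarization-scored:
  a median background over a handful of pixels is meaningless.
* A zero background with non-zero signal makes the polarization fold
  undefined; such cells are scored against a 1-AFU floor and flagged.

## What the tests compute

The suite (and `scripts/acceptance.R`) verifies, at these problem sizes:
morphology against the distance oracle on 200 random masks up to 40×40 px;
puncta against a library-free pixel-by-pixel reimplementation on 100 random
somata up to 50×50 px; exact noiseless recovery on two full default scenes;
noisy recovery over 20 default-SNR scenes (10 each at planted MHCII⁺
fractions 0.25 and 0.55, ~1,000 pooled neurons) of the MHCII⁺ fraction
(within 5 percentage points), pooled T-cell density (within 10% relative)
and pooled diameter-fit mean (within 0.3 µm); and isotype self-calibration
(~1% positives among ≥ 500 reference neurons, within the binomial 99%
interval). Group-level inferential statistics (ANOVA, mixed models) are out
of scope: the package emits tidy per-mouse tables shaped for those tools
and reports only mean ± SEM descriptives.

## A minimal run

```{r example, eval = FALSE}
iso <- generate_isotype_section(scene_spec(seed = 101))
model <- isotype_reference(iso$stack)

g <- generate_section(scene_spec(seed = 1))
sec <- quantify_section(g$stack, mhcii_model = model)

glance(sec)
fit <- fit_diameter_distribution(sec$neurons$diameter_um)
autoplot(fit)
plot_section(g$stack, "MHCII", labels = sec$masks$measurable,
             puncta = sec$puncta)
```
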