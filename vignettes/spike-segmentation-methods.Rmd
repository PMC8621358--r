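---
title: "Texture-based spike segmentation: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture-based spike segmentation: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Grain spikes (ears) in greenhouse side-view images are hard to separate
from the plant canopy precisely when they share its colour fingerprint:
green spikes in a green canopy (GSGC) and yellow spikes in a senescent
yellow canopy (YSYC). What distinguishes a spike from a leaf under these
regimes is not colour but *texture*: the grain lattice of a spike is a
high-frequency, high-contrast pattern, while leaves are smooth, elongated
surfaces. `spikeseg` implements a classical texture pipeline around this
observation: a shallow neural network labels every pixel from local Laws
texture-energy features computed on a Haar-smoothed image, and a
multiscale Frangi line filter then removes the typical failure mode of
texture classifiers — elongated false positives along leaf and tiller
edges.

## The segmentation model

The feature chain for a pixel is:

1. **Grayscale and Haar LL.** The RGB image is converted to luminance and
   reduced to the level-1 Haar approximation (LL) band: each value is the
   mean of a 2×2 block (`haar_ll()`, averaging normalisation, so constant
   images are fixed points). Working at half resolution suppresses sensor
   noise and doubles the effective spatial reach of every later window.
2. **Laws filtering.** The nine 3×3 Laws masks — outer products of
   L3 = (1,2,1), E3 = (−1,0,1), S3 = (−1,2,−1) — are applied to every
   pixel's neighbourhood (`laws_convolve()`; sliding-window filtering
   with edge replication). Every mask with an E3 or S3 factor has zero
   sum, so responses vanish on flat regions.
3. **Texture energy.** Each response is rectified and averaged over a
   (2n+1)×(2n+1) macro-window (`texture_energy()`). The window mean is
   normalised by the full window area (2n+1)²; a printed variant of this
   normalisation that divides by 2n+1 only would make the energy scale
   with the window height, contradicting its own description as a local
   mean deviation, so the package deliberately uses the area-normalised
   form. Energies are non-negative by construction.
4. **Feature stack.** The nine energies are upsampled back to image
   resolution (nearest neighbour) and, by default, the raw R, G, B
   channels scaled to [0, 1] are appended: 12 features per pixel
   (`assemble_pixel_features()`). Both the wavelet step and the colour
   channels can be switched off; whether the original ANN consumed raw
   wavelet coefficients or Laws energies of the LL band is not
   recoverable from its description, so the package fixes the
   energies-of-LL path as the default and exposes the alternative.
5. **Classifier.** A single-hidden-layer network (default 10 logistic
   hidden units, logistic output) maps the standardised feature vector to
   a spike probability (`train_pixel_classifier()`, built on `nnet`).
   Training samples are drawn class-balanced from the ground-truth masks
   (default 8000 pixels per class across the corpus). The loss is
   cross-entropy, optimised by BFGS; a quasi-Newton step needs no
   learning rate, so the trainer exposes an iteration cap instead. The
   default cap of 500 iterations was chosen because the loss plateaus
   there (0.61 at 500 vs 0.60 at 1000 on the synthetic corpus) while 200
   iterations leave it clearly unconverged (0.83). The decision threshold
   on the output probability is 0.5.

## The Frangi post-filter

Texture classifiers misfire along high-contrast linear structures — leaf
edges and thin tillers — because an edge is locally indistinguishable
from texture. These errors are geometrically distinctive: long, thin,
and ridge-like in the intensity image. `frangi_vesselness()` computes
the standard two-dimensional Frangi measure from the scale-normalised
Hessian eigenvalues λ₁, λ₂ (|λ₁| ≤ |λ₂|),

> V = exp(−R_B² / 2β²) · (1 − exp(−S² / 2γ²)),  R_B = λ₁/λ₂,  S = √(λ₁²+λ₂²),

zeroed where λ₂ > 0 (bright-ridge polarity), maximised over scales
σ ∈ {1, 2, 3, 4}. With γ = `"auto"` the structureness scale is set to
half the maximum S at each scale; a constant image yields an all-zero
map with no division by zero. The truncated second-derivative taps are
zero-centred so a constant image has an exactly zero Hessian.

`suppress_linear_false_positives()` then removes *connected components*
of the predicted mask — never individual pixels, so true spikes are not
perforated — when all three criteria hold: mean vesselness ≥ 0.15,
eccentricity ≥ 0.97 and major-axis length ≥ 50 px. Spikes are compact
(eccentricity ≈ 0.8–0.94 for the 2–3:1 aspect ratios typical of ears),
so the eccentricity gate alone protects them; requiring high vesselness
*and* length makes removal specific to image-supported linear
structures. Defaults β = 0.5, γ auto, and the three component
thresholds are package choices, exposed as arguments.

## The synthetic scene generator

`generate_scene()` renders the imaging conditions the pipeline targets:
a uniform blue background (default RGB (30, 60, 150)) with Gaussian
sensor noise (sd 3), thin near-vertical stem/tiller lines, a canopy of
smooth curved leaf strokes, and textured ellipse-plus-awn spikes whose
hue range overlaps the canopy's (green-on-green by default,
yellow-on-yellow for YSYC). Spikes belong to three categories with a
configurable mix, defaulting to 53 % / 30 % / 17 % — the proportions of
the 80 top, 45 inner and 27 occluded/emergent spikes in the reference
annotation counts:

* **top** — placed in the upper, leaf-free quartile of the canvas;
* **inner** — crossed by leaf strokes until ≥ 30 % of the spike is
  covered (covered pixels leave the ground-truth mask);
* **occluded_emergent** — ≥ 40 % of the ellipse erased behind a large
  occluding blob.

Boxes always cover the full pre-occlusion spike extent — a partially
hidden spike is still one annotated object — while the mask holds only
visible pixels. The default canvas is 512×595, the aspect ratio of the
full 2560×2976 frames, to keep simulation affordable; full-size
generation is a configuration choice. Everything derives from one
integer seed; scenes are byte-identical across runs.

What the generator does *not* emulate: perspective, specular pot and
frame structures, natural leaf venation and soft shadows, intra-spike
colour gradients of real senescence, or barley/rye morphology. Passing
the end-to-end benchmark therefore shows that the pipeline recovers
texture-defined objects under colour camouflage, occlusion and noise —
not that it reaches any particular accuracy on real greenhouse imagery.

## Dataset preparation choices

* `split_dataset()` rounds the train size half-up, reproducing the
  234/58 partition of 292 ids at 80:20.
* `extract_frames()` tiles without overlap and pads the right/bottom
  edges with the median border colour (the background, in these scenes);
  how the original frames were padded is not documented anywhere, so
  non-overlapping tiling is a package definition. A 2560×2976 image at
  256 gives 10×12 = 120 frames. A frame counts as "spike" when at least
  0.5 % of its pixels are spike — a single stray pixel should not flip a
  frame's label, and the threshold is exposed.
* `balance_frames()` keeps all spike frames, drops pure-background
  frames (per-channel sd below 10 on the 0–255 scale), and subsamples
  the rest to the requested 1:1 ratio, seeded.
* `augment_pair()` applies rotation uniform in [−30°, 30°] (bilinear for
  the image, nearest-neighbour for the mask so labels stay binary), an
  optional horizontal flip, and a brightness factor uniform in
  [0.5, 1.5] with clipping. Rotation corners are filled with the median
  border colour rather than black, matching the uniform backdrop.

## Evaluation stack

Boxes are 0-based half-open internally (areas are exact pixel counts);
VOC XML files keep their native 1-based inclusive convention on disk.
Matching is greedy in descending confidence with one-to-one assignment
(ties broken by higher IoU, then input order). Precision, recall,
accuracy and F1 come from the matched counts; the true-negative count
exists only at image level (a spike-free image with no detections),
because detection has no pixel-level negative unit. Undefined ratios are
reported as NaN with a warning, never silently as 0. `ap_11point()` is
the VOC 11-point interpolated AP; `ap_coco()` interpolates at 101 recall
points for each IoU threshold in 0.50:0.05:0.95 and averages the ten.
Mask scores (`mask_metrics()`) report spike-class Dice and Jaccard plus
their class-averaged variants (aDC, mean IoU); an empty-in-both class
scores 1 by convention. Category-stratified reports attribute true
positives and misses to their ground-truth category and false positives
to the nearest ground truth; the mean confidence of matched true
positives is reported as the probability column of such summaries.

## Trait registry

`compute_traits()` produces exactly 70 descriptors per spike region —
12 shape, 32 colour, 26 texture — under fixed names (`trait_registry()`)
so tables from different runs are column-compatible. Notable choices:
hue statistics are circular (resultant direction and circular sd) to
avoid the 0/360° wrap; the perimeter is a Cauchy–Crofton estimate
(exposed pixel-edge count × π/4), which is asymptotically exact for
smooth convex shapes, giving rasterised disks of radius ≥ 10 a
compactness within [0.9, 1.0] — the estimator overshoots for axis-aligned
rectangles, a known raster artifact; solidity uses the convex hull over
pixel corners so filled rectangles score exactly 1; co-occurrence
statistics use 8 grey levels at the two unit offsets. Single-pixel
regions fall back to degenerate texture values with a warning rather
than NaN.

## Problem sizes and numerical notes

The bundled benchmark trains on 50 generated scenes and evaluates on 10
held-out scenes at the default 512×595 canvas — large enough for ~5
spikes per scene at realistic relative size, small enough that the whole
experiment (generation, features, training, prediction, filtering) runs
in a few minutes on one core. Window sums use a summed-area table;
values a few ulp below zero after cancellation are clamped. IoU
threshold comparisons use a 10⁻⁹ tolerance so boxes constructed to sit
exactly at a sweep threshold match on every platform. All randomness —
scene content, pixel sampling, network initialisation, frame
subsampling, augmentation draws — flows from explicit integer seeds.

## Known limitations

* The pixel classifier blurs object boundaries by the macro-window
  radius; spikes densely covered by leaves can lose small visible
  fragments to the minimum-area filter.
* Detection boxes derived from mask components merge spikes that touch
  in the mask and fragment heavily occluded ones; the detection AP on
  synthetic scenes is therefore a conservative summary of a
  segmentation-first pipeline.
* The trait registry is a package definition. The original tool's trait
  list is unpublished, so column-for-column equivalence with it cannot
  be claimed.
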