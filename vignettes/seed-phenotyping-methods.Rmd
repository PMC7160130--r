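---
title: "Methods: synthetic scene generation, evaluation metrics and seed morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic scene generation, evaluation metrics and seed morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedpheno)
```

seedpheno implements the computational core of an image-based seed
phenotyping workflow built on synthetic training data: a sprite-based
scene compositor that manufactures instance-segmentation training sets by
domain randomization, the detection/segmentation metrics used to judge a
model trained on them, a post-processing filter cascade that isolates
analyzable seeds, and a morphometry layer (eight shape descriptors,
normalized elliptic Fourier descriptors, PCA shape spaces with
latent-axis contour reconstruction). The neural network itself is out of
scope: any instance-segmentation model can be trained on the COCO
datasets this package writes, and its predictions evaluated and measured
here.

## The compositor

Real training data for seed instance segmentation is expensive because
touching seeds must be delineated by hand. The alternative implemented
here composites *sprites* — background-free cutouts of single seeds —
onto background tiles at random poses, so pixel-perfect masks come for
free.

A sprite holds an RGB raster, a per-pixel opacity in [0, 1] and a
cultivar tag; pixels outside the opacity support are (0,0,0). Extraction
from scans (`extract_sprite()`) is by chroma distance against a sampled
background color (default threshold 60/255 in Euclidean RGB — scanning
backgrounds are chosen for separability, so the exact threshold is not
delicate), keeping the largest connected component and filling interior
holes. Opacity is binary at extraction; fractional opacity only arises
later from the compositor's perimeter blur.

Scene synthesis (`generate_scene()`) follows a rejection-sampling loop on
a square virtual canvas (default 1024 px, one randomly drawn background
tile):

1. Draw a sprite uniformly from the pool and a rotation angle uniformly
   from [0, 360); rotate with bilinear interpolation, expanding the
   raster.
2. Draw a position uniform over all placements that keep the rotated
   raster fully on the canvas.
3. Compute the overlap fraction: the share of the candidate's support
   already covered by previously pasted seeds. If it exceeds the
   threshold (default 0.25) the trial is consumed and the next trial
   redraws *only the position* for the same rotated sprite; otherwise the
   sprite is alpha-composited and its support is written into an integer
   label map, overwriting earlier labels (foreground replacement, as when
   a seed lies on top of another).
4. Stop after `max_trials` trials (default 70).

Finally the canvas is center-cropped (default 1024 to 768 px), which
reproduces the cut-off seeds at the borders of real scans; instances
losing all visible pixels are dropped, the rest keep their cut masks.

Choices worth making explicit:

* **Overlap denominator.** "Overlap fraction" is measured against the
  *candidate's* support, giving one scalar per trial. Measuring against
  the occluded seed or the union would also be defensible; the threshold
  value itself was an empirical choice in the original workflow, so the
  package exposes it (`overlap_threshold`).
* **Perimeter blur.** The pasted opacity is Gaussian-blurred (sigma 1 px)
  only within the ~3 px band the kernel actually reaches around the
  support boundary; visible masks are thresholded at opacity 0.5, so the
  blur softens cut-out artifacts without shrinking masks.
* **Trial accounting.** A rejected position consumes one of the 70
  trials, keeping the loop bounded exactly; instance counts per scene are
  therefore a *result* of (trials, overlap threshold, sprite sizes), not
  a parameter.
* **Determinism.** Every scene is generated under its own RNG substream
  derived from the master seed by an integer hash, so image k of a
  dataset can be regenerated in isolation, and identical seeds reproduce
  pair files bit-exactly.
* **Label maps** are written as 16-bit grayscale TIFF (id 0 =
  background, ids in paste order) — the lossless 16-bit integer raster
  format the R ecosystem writes natively; the COCO JSON (column-major
  uncompressed RLE, one `"seed"` category, areas = visible pixel counts)
  is the primary interchange format.

The fixture generator (`make_fixture_pool()`) stands in for scanned
pools: superellipse silhouettes (exponent 1.5–3) with per-cultivar size
(semi-major axis 30–80 px, matching grain-sized objects at flatbed
resolution), aspect ratio (1.6–3.0) and color distributions, plus
multiplicative pixel noise for texture, over uniform scanner-blue tiles.
It emulates what the compositor must exercise — convex-ish elongated
textured shapes in distinguishable groups — and deliberately not what it
need not: no awns, husk texture, specular highlights, shadows or
lighting gradients. Tests passing on fixtures therefore validate the
*machinery* (geometry, masks, bookkeeping, metrics), not photorealism.

## Evaluation metrics

Ground truth and predictions meet as scored instances. Matching is
greedy: detections in descending confidence (ties by input order), each
claiming the unmatched ground-truth instance of highest IoU provided it
reaches the threshold, ground-truth ties breaking to the lower index.
Recall at IoU 0.5 is computed on *bounding boxes*; average precision on
*masks* — mirroring how object-detection and mask metrics are
conventionally split. AP applies the monotone precision envelope to the
precision–recall sequence over score prefixes and sums precision times
recall increment; `ap_sweep()` averages thresholds 0.50–0.95 in steps of
0.05 (exactly ten). Dataset values are unweighted means over images
(macro average — each image holds one cultivar in the scanned datasets
this mirrors, so macro averaging weights cultivars equally).

Empty-image conventions (the references are silent): with no ground
truth, recall and AP are 1 when there are also no detections, and AP is 0
when spurious detections exist — a perfect empty image scores perfectly.
For small problems the implementation is cross-checked in the tests
against a brute-force enumeration of the PR envelope written as a
separate routine.

## The filter cascade

Raw network output includes border-cut, occluded and misshapen regions
that would bias morphometry. The cascade removes them in three fixed
stages, each recomputing its threshold on the survivors of the previous
one (the stages are sequential, not joint):

1. **Margin** (default 5 px): any instance whose bounding box intersects
   the margin band is removed.
2. **Solidity**: instances strictly below the 25% quantile of solidity
   are removed. The quantile *is* the cutoff — a reading of the
   "lower-quantile threshold" rule at face value; an IQR-style fence
   would be an alternative reading.
3. **Length-to-width ratio**: instances strictly outside the 5%/95%
   quantile band are removed.

Quantiles are type-7 (linear interpolation), the default of both R and
the numerical Python ecosystem. Removal reasons are exclusive and
stage-ordered. Note the solidity stage removes about a quarter of *any*
continuous population — the rule assumes most detections are good and
trims a fixed tail; all thresholds are exposed in `filter_config()`.

## Morphometry

Contours are traced at the 0.5 iso-level by marching squares on a 1 px
zero-padded mask (`grDevices::contourLines`), so they are closed even for
border-touching regions and sub-pixel. When several closed curves exist,
the largest-area one is kept; orientation is normalized to positive
shoelace area.

The eight descriptors: area (pixel count), length and width (major/minor
axis lengths of the moment-equivalent ellipse — bounding-box sides would
be rotation-dependent), their ratio, eccentricity, solidity (area over
rasterized convex-hull area), perimeter (arc length of the iso-contour
polygon) and circularity 4πA/P². Two discretization facts matter when
interpreting values:

* The iso-contour of a *binary* mask is a half-pixel staircase whose
  length overestimates a smooth boundary by ~5.8% (a disc of radius 50
  measures 332.5 px against 2π·50 = 314.2) — identical to what the
  standard marching-squares implementations return on binary input.
  Circularity of a perfect disc is consequently ~0.89, and the measure is
  comparable *between* seeds, not an absolute isoperimetric quotient.
* Solidity of smooth rasterized shapes sits near 0.96–0.99 depending on
  size (staircase corners are concave); scale invariance holds to ~2%
  only for regions tens of pixels across, which seeds at scan resolution
  are.

Elliptic Fourier descriptors use the Kuhl–Giardina closed-form
coefficients of the contour polygon under chord-length parameterization,
20 harmonics by default. Normalization standardizes starting point,
rotation and size so the first harmonic is a unit semi-major-axis ellipse
aligned to x: (a1, b1, c1) = (1, 0, 0) to machine precision. The
starting-point angle is only determined up to half a period — a two-fold
branch that flips the sign of every even harmonic (shared, silently, by
the common implementations); seedpheno canonicalizes by requiring the
largest-magnitude even-harmonic entry to be positive, which makes
coefficients unique and similarity-invariant to 1e-4 on dense polygons.
Features flatten harmonic-major to 80 values and drop the three
constants, leaving 77.

PCA (`pca_fit()`) standardizes columns for the eight descriptors (their
units differ) and not for EFD features (already on a common scale after
normalization); loading signs are fixed so each component's
largest-magnitude loading is positive. `latent_axis_contours()` inverts
the transform at chosen positions along one axis (others at zero),
reinserts (1, 0, 0) and reconstructs the contour — the latent-space
interpolation view of a shape space. `mean_contour()` averages
coefficient arrays within a group and reconstructs the representative
shape.

## Numerical and degenerate-input policy

* Empty masks, empty sprite extractions, empty candidate masks in
  overlap computation, and mixed-harmonic averaging raise classed errors
  rather than returning NA.
* Multi-component masks are rejected by `compute_descriptors()` with a
  pointer to label/screen first.
* An all-equal trait vector removes nothing in quantile filtering
  (nothing is strictly outside the thresholds); a single instance is
  always kept.
* All randomness flows through explicit seeds; user RNG state is saved
  and restored around every internal draw.

## Problem sizes in the test suite

The suite validates the full study configuration — a 400-sprite pool
(20 cultivars x 20), 1024 px canvas cropped to 768, overlap 0.25, 70
trials, 1200 generated pairs split 989/11/200 — with the full-scale run
auditing scene metadata while the raster write path is exercised at
small n; module tests run on 256 px canvases and 3x3 pools where the
property under test does not depend on canvas size. The end-to-end
pipeline test composes 50 scenes, perturbs ground truth into simulated
detections by mask erosion and jitter (AP falls monotonically with
jitter), then filters, measures, extracts EFDs and fits the PCA.

## Known limitations

* Fixture realism: no de-husking, awns, shadows, or photometric
  variation; conclusions about real-scan accuracy require real scans and
  a trained model, neither of which this package supplies.
* The compositor does not model lighting or produce GAN-refined imagery.
* Heterogeneous populations (mixed cultivars in one image) are filtered
  per image by the same quantile rules, which assumes a dominant
  well-formed population.
* Descriptor absolute values inherit the discretization effects above;
  compare within a consistent pipeline rather than across perimeter
  estimators.
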