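---
title: "Methods: quantifying occlusal discoloration for caries screening"
author: "cariesFD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying occlusal discoloration for caries screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The diagnostic model

Early occlusal caries shows as dark staining in the pits and fissures of
the chewing surface.  As a lesion progresses, the stain changes shape:
isolated points become connected lines along the fissures and finally
spreading areas.  `cariesFD` turns that qualitative observation into two
numbers per tooth:

* **PA**, the fraction of the occlusal surface that is discolored — a
  volume-like measure of lesion extent; dimensionless, in [0, 1].
* **FD**, the box-counting fractal dimension of the binary discoloration
  pattern — a shape-complexity measure that is ≈0 for points, ≈1 for
  lines, and approaches 2 for filled areas; dimensionless, in [0, 2] for
  a 2D raster.

together with an optional **DD**, a DIAGNOdent laser-fluorescence
reading in 0–99 supplied externally (the mean of replicate readings when
replicates exist).  A linear discriminant score over any subset of
(FD, PA, DD) then decides between preventive and operative treatment.

The method's core assumption is statistical, not mechanistic: lesion
depth correlates with the shape and extent of surface discoloration.  It
therefore applies to *discolored* lesions only (not acute colorless
caries), and is intended for screening, not definitive diagnosis.

## Image pipeline

1. **Grayscale conversion** (`toGray8`): fixed ITU-R 601 luminance
   weights (0.299, 0.587, 0.114), linear mapping of the declared input
   range onto 0–255, rounding half-up.  Fixed weights keep the pipeline
   deterministic across image sources.
2. **Surface segmentation** (`segmentSurface`): the enamel surface is
   assumed brighter than the intraoral background, so the mask is
   `intensity > t`.  The default threshold is automatic Otsu
   (exhaustive between-class-variance maximization over all 256
   candidate splits of the integer histogram; ties go to the smallest
   maximizing threshold, making the choice deterministic).  A manual
   override is available for the historical workflow in which an
   observer set thresholds by eye, but the automatic default is what
   makes unattended batch screening possible.  After thresholding, only
   the largest 8-connected component is kept and its interior holes are
   filled: the occlusal surface is a single region, and dark fissures
   must not be subtracted from its area.
3. **Discoloration segmentation** (`segmentDiscoloration`): within the
   surface mask only, dark pixels are selected as `intensity < t`.  The
   automatic threshold is Otsu on the *surface-restricted* histogram;
   the recorded threshold is the smallest intensity of the bright
   class, so the mask is exactly the pixels strictly below it.  The
   discoloration mask is a subset of the surface mask by construction.
4. **PA** (`computeSegmentation`): exact pixel-count ratio.

A global per-image threshold is used for each of the two steps (not
per-region thresholds): it is the simplest reproducible reading of a
density-histogram workflow, and the synthetic experiments show it
suffices on two-level images.

Degenerate inputs: a uniform image has no histogram valley and raises
`"degenerate histogram"` rather than guessing; an empty surface mask is
an error; an empty discoloration mask is valid and yields PA = 0.

## Fractal dimension

`boxCount` counts, for each box side *s*, the cells of a grid anchored
at the raster origin that contain at least one foreground pixel;
partial boxes at the right/bottom edges count.  `fitFD` regresses
log N(s) on log s by unweighted ordinary least squares and reports
FD = −slope, the fit intercept, and R².  `estimateFD` composes the two
with these conventions:

* **Scale ladder**: powers of 2 from 2 up to `floor(min(H, W)/4)`,
  requiring at least 4 scales (so rasters must be ≥ 64 px in their
  smaller dimension).  Dyadic ladders give exactly collinear log-log
  points on the calibration shapes, which pins the estimator down: a
  512-px line fits FD = 1 and a filled 128×128 square FD = 2 exactly,
  and the depth-6 Sierpinski parity raster (3⁶ = 729 pixels in a 64×64
  grid) fits log 3 / log 2 exactly.
* **Anchoring**: the pattern is translated so its bounding-box corner
  sits at the grid origin — one fixed offset, no offset minimization,
  for determinism.  Whole-raster translations of a pattern therefore
  change nothing at all.
* **Fit-quality flag**: R² < 0.95 sets `lowFit` and warns.  Sparse
  point patterns (healthy C0 teeth) legitimately trigger it — a handful
  of dots is not a power law — which is informative rather than an
  error: their fitted FD still sits near 0 and below the line-like
  range.
* **Degenerate patterns**: an empty mask is an error (the dimension of
  nothing is undefined); a single pixel yields N(s) = 1 at every scale
  and hence FD = 0 through the fit, the correct dimension of a point.

FD is computed on the filled discoloration region as segmented (not on
its outline).

`minkowskiFD` is a deliberately independent estimator used as a
cross-check: the pattern is dilated by exact Euclidean discs of radii
r = 1…4 (offsets with dr² + dc² ≤ r² + ½), and the dimension is
2 − d log A(r)/d log r, computed as 1 + slope of log(A(r)/r) against
log(1/r).  Because a discrete disc of radius r spans 2r + 1 pixels, the
regression uses the effective radius r + ½; without this half-pixel
correction a 1-px line reads ≈1.23 instead of ≈0.99.  Radii are kept
small since the r → 0 limit is being approximated — large radii let the
boundary sausage of a filled shape bias the slope.  On the calibration
shapes the two estimators agree within 0.2, and both are exercised in
the test suite.

## Discriminant analysis

`fitDiscriminant` is a two-class Fisher linear discriminant with pooled
within-class covariance:

* weights `w = S_pooled⁻¹ (μ_operative − μ_preventive)`, rescaled so
  the pooled within-class variance of the score is 1 — this makes
  coefficients comparable across feature subsets and matches the
  magnitude convention of the built-in reference formulas;
* intercept such that Y = 0 at the class-frequency-weighted midpoint of
  the class score means, i.e. at the grand centroid of the training
  sample.  With unbalanced classes this pulls the cut toward the larger
  class's side of the unweighted midpoint, which is what reproduces the
  decision geometry of the reference formulas: with the reference class
  means (C0 1.09 at n = 64; operative pooled 1.43 at n = 36) the
  weighted-centroid cut lands at 1.20, exactly the threshold implied by
  Y = 6.74 FD − 8.12, while an unweighted midpoint (1.25) or a
  log-prior Bayes cut (≈1.28) would not.
* orientation: the operative class scores positive; the tie Y = 0 is
  resolved to preventive treatment — an arbitrary but fixed convention,
  chosen conservative and documented in the CLI help.

Exact reproduction of the reference coefficients is not expected — the
underlying clinical data are not available — but the decision geometry
(thresholds strictly between the class means, convergence to the
closed-form pooled cutoff with growing n) is asserted by tests.
Performance metrics computed on the training table are resubstitution
estimates and are labeled as such wherever they are reported.

Singular pooled covariance (e.g. a constant feature) raises
`"degenerate features"` rather than silently regularizing.

## What the synthetic data emulate — and what they do not

`simulateToothImage` renders: a bright elliptical "enamel" surface
(intensity 205) on a dark background (25) with dark discoloration (45),
axes ≈0.42/0.34 of the raster (default 256×256 px) with ±5% jitter;
per-pixel Gaussian intensity noise (default SD 3 gray levels, 0 =
noise-free two-level image).  Discoloration morphology follows the
point → line → area progression: C0 draws 1–4 small blobs, C1 one
meandering fissure polyline, C2 a branching fissure tree with widened
lesion patches.  Elements are added until the discolored pixel count
reaches `targetPA × surface area` (defaults 0.005 / 0.012 / 0.051, the
per-class reference PA means), so realized PA is within 20% relative of
target, with infeasible targets rejected.  Patterns are confined
strictly inside the surface ellipse.  Everything is deterministic per
seed.

`simulateFeatureTable` draws (FD, PA, DD) per class from truncated
Gaussians (FD in [0, 2.5], PA in [0, 1], DD in [0, 99]) at the
reference class means/SDs and sizes (64/24/12), independent across
features by default.  Only marginal moments are published for the
reference sample; cross-feature correlations are reported significant
but without usable coefficients, so independence is the default and a
Gaussian-copula `correlation` knob is exposed for sensitivity analyses.
Note the truncation matters: the C0 PA cell (mean 0.005, SD 0.009,
truncated at 0) has a realized mean above its nominal one, and tests
compare against the truncated-Gaussian closed form, not the naive mean.

What passing tests on these data do **not** show: robustness to
specular highlights, plaque, wetness, color constancy or camera
variation — real intraoral images are far richer than a two-level
ellipse, and the generator makes no attempt at photorealism.  The
synthetic experiments validate the *computational* pipeline
(segmentation exactness, estimator calibration, ordering of severity
classes, discriminant geometry), not clinical accuracy.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use: 256×256 synthetic
teeth; 50 seeds per severity class for the ordering/self-consistency
check in the test suite (20 per class in the acceptance script's
summary); 100 random 64×64 masks and 50 random images for the
brute-force oracle comparisons; 5 000 samples per class for discriminant
parameter recovery; 10 000 per class for the truncated-moment check;
20 replicate tables of the reference 64/24/12 design for resubstitution
metrics.  These sizes were chosen so the full suite completes in well
under a minute while keeping Monte-Carlo standard errors an order of
magnitude below the tolerances being asserted.

## Known limitations

* Otsu thresholding assumes a bimodal histogram; a tooth with *no*
  discoloration gives a near-unimodal surface histogram and the
  automatic discoloration threshold will then carve noise into a
  spurious mask.  Screening imagery should contain discoloration, or a
  manual threshold should be supplied.
* Box counting is only apt for (approximately) self-similar patterns;
  the R² flag reports when it is not, but the single-number FD cannot
  describe self-affine or multifractal structure.
* The reference formulas and thresholds were estimated on one clinical
  sample and are not universal; refitting on local data is the intended
  workflow (`fitDiscriminant` + `writeDiscriminantModel`).
* DD is consumed as a number; the device measurement itself, and
  clinical confounders of fluorescence readings, are out of scope.
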