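---
title: "Quantifying microtubule plus-end dynamics in growth cones: models and methods"
author: "conetrax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microtubule plus-end dynamics in growth cones: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

A migrating neuronal growth cone remodels its microtubule array on two
very different time scales: comets of end-binding protein (EB3) marking
polymerizing microtubule plus ends move at ~0.1 um/s, while the growth
cone itself advances or retreats at ~0.25 um/min. `conetrax` implements
the full measurement chain for burst-acquisition time-lapse data — short
high-frequency bursts (33 frames at 2-s intervals) repeated every 10 min
— and links comet-scale kinematics to cone-scale morphology and
behavior. Because no public raw data accompany this kind of experiment,
the package ships a seeded synthetic time-lapse generator with exact
ground truth, and every downstream stage is validated against it.

## The synthetic scene

The generator draws a growth cone as a low-order Fourier-perturbed
ellipse joined to a thin neurite stub entering from the left image edge;
the stub end defines "proximal" and gives the midline an unambiguous
orientation. The cone body translates rigidly at the configured
migration velocity (positive = extension). Comets nucleate uniformly in
the cone body as a Poisson process (`birth_rate`, per um^2 per second),
move with per-step displacement `speed * frame_interval` along a base
direction that is anterograde (tip-ward) with probability
`anterograde_frac`, jittered per step by Gaussian angular noise, and die
either at an exponential lifetime or on stepping outside the cone.
Within `damping_zone` (default 2 um) of the leading edge, speed is
multiplied by `damping_factor` (default 0.7), reproducing the near-edge
slow-down reported for polymerizing plus ends. Spots are rendered as
anisotropic Gaussians elongated along motion, over a constant
cytoplasmic plateau; the ideal image is blurred (sigma 0.2 um), then
Poisson shot noise and Gaussian read noise are applied.

Defaults (one choice, made once): cone area 50 um^2, elongation 1.8,
median speed 0.11 um/s with geometric SD 1.4 (log-normal; medians are
the field's summary statistic and the support must be positive),
lifetime mean 15 s (memoryless exponential, truncated at burst end),
85% anterograde, 15 deg angular jitter, background 40 photons, spot
amplitude 120, pixel size 0.211 um. The speed median, anterograde
fraction, slow-zone width and migration rate are literature-anchored
wild-type values; birth rate (0.01 /um^2/s) and lifetime were chosen so
that a 50-um^2 cone holds a realistic standing population of ~7 comets
with tracks a few to tens of frames long. An optional
`birth_exclusion_zone` suppresses nucleation within a set distance of
the front, emulating genotypes with depleted leading-edge
polymerization.

What the generator does *not* emulate: filopodia, photobleaching, an
optics-accurate PSF, comet intensity variation, uneven illumination, or
cone shape change during migration (translation is rigid). Passing
tests therefore demonstrate correctness of the measurement chain under
controlled conditions, not robustness to every property of real data.

## Segmentation and landmarks

The cone is segmented from its cytoplasmic background signal: Sobel
gradient magnitude, a threshold, dilation (disc, 2 px), hole filling,
erosion, and retention of the largest component. Two practical choices
matter:

* The threshold is Otsu's, but computed on the gradient of the
  *median-filtered* frame and applied to the raw gradient. Otsu on the
  raw gradient is normalised by the brightest structure in the frame; a
  single bright comet can raise the threshold past weaker stretches of
  the cone edge, at which point the edge ring fragments and hole
  filling fails. The median filter removes comet-scale structure, so
  the threshold scale tracks the edge and nothing else.
* The erosion radius (4 px) exceeds the dilation radius (2 px). The
  thresholded edge band straddles the true boundary, so symmetric radii
  inflate the mask by roughly its perimeter in pixels (~+15% area).
  The asymmetric default was calibrated once against ground-truth masks
  of noise-free synthetic cones (residual bias ~-4%; the acceptance
  property requires 5%).

The edge image is also sealed against the image border before filling,
because the boundary ring is open where the neurite stub leaves the
field of view.

Morphology scalars follow the `regionprops` conventions: length and
width are the major/minor axes of the second-moment equivalent ellipse
(with the 1/12-pixel variance term), eccentricity comes from the same
ellipse, the boundary is a sub-pixel marching-squares contour, and the
perimeter is its arc length.

The midline is the ridge of the interior distance transform, realised
as Zhang-Suen thinning, the maximum-arc-length endpoint-to-endpoint
path through the skeleton graph, a snapping step that moves each vertex
to the perpendicular local maximum of the distance transform (thinning
alone runs up to a pixel off the Euclidean ridge in wide regions), and
a short moving-average smooth. The endpoint farther from the declared
neurite-entry edge is the tip end. A disk-like mask thins to a
(correctly) degenerate midline near its centre.

The front is defined by the 1:1.7 division rule, read as a front:rear
split of midline arc length measured from the tip: the division point
sits at arc-length fraction 1/2.7 from the tip, and the front is the
contiguous boundary arc tip-ward of the perpendicular through that
point. The tip point is the boundary vertex farthest along the overall
proximal-to-distal midline direction; projecting the literal skeleton
endpoint instead proved unstable (it can flip between boundary lobes
frame to frame, which would corrupt tip-displacement scoring).

## Comet detection and localisation

Detection proceeds in four steps: background flattening, band-pass
(difference-of-Gaussians, 1/3 px) filtering, local maxima above an
adaptive photon-statistics threshold (`n_sigma` times the expected
noise of the filtered residual, from Poisson statistics of the
estimated background plus read noise), and sub-pixel localisation.

When a segmentation mask is available the background is modelled as a
constant plateau over its own intensity support — the half-level
crossing of the median-filtered frame — which removes the cone edge
from the residual almost exactly. Localisation is neighbour-aware
least-squares fitting of a fixed-shape oriented Gaussian: position and
orientation are optimised while amplitude, a constant offset and a
linear baseline ramp are profiled out linearly; already-fitted
neighbours are subtracted from each spot's window; pixels within 2 px
of the background-support edge are excluded from the fit; and a final
CLEAN-style pass subtracts all fitted spots and re-detects what
remains, recovering comets merged with a brighter neighbour. Detections
converging to the same spot are merged (brightest wins within 2 px).

This effort is not optional. A 2-s step at 0.11 um/s is ~1 px; simple
centroid or parabolic refinement localises to ~0.35-0.45 px at the
default photon budget, and that jitter inflates measured speeds by
~10% at 0.11 um/s and ~40% at 0.05 um/s. The fitting localiser reaches
~0.1-0.2 px, bringing median-speed bias to ~1% at 0.11 um/s. At
0.05 um/s the true step (0.36 px after damping) sits below the
Cramer-Rao localisation floor for this spot SNR, so a bias of order
+25% is irreducible there; the test suite asserts a documented loose
bound for that regime instead of pretending otherwise.

## Linking and track statistics

Frame-to-frame linking is a globally optimal one-to-one assignment
(Hungarian algorithm) minimising total displacement, with candidates
gated by a search radius clamped to the published 1.5-6 px range. The
radius adapts to the median per-frame displacement — scene-wide once at
least 20 step samples exist, and per track (its own motion scale) once
a track has more than three detections; a purely global radius locks
onto the slow majority and splits the fast tail of the log-normal speed
distribution. Tracks survive up to 3 missed frames; a gap-closing
continuation must lie in the forward cone (35 deg off the track's mean
direction over its last up-to-3 steps) or, for backward displacements
no larger than 1.4 times the track's mean growth step, in the 15-deg
backward cone. Displacements below the fluctuation radius (1.25 px,
scaled by the gap duration) are exempt from the angle tests; the
angle/shrinkage gates apply to gap closures only, not to direct
frame-to-frame links. Tracks with fewer than 3 detections are
discarded, and a track is complete-within-burst only if it appears
after the first and disappears before the last frame — only those
tracks enter birth/death front-distance analyses.

Instantaneous speed is the displacement between consecutive detections
divided by elapsed time; a gap-spanning displacement contributes one
sample over its whole duration rather than inventing unobserved
positions. Net paths are birth-to-death vectors; their angle to the
local tip-ward midline tangent classifies comets as anterograde
(|angle| <= 45 deg), retrograde (>= 135 deg) or lateral, thresholds
exposed in the API.

Identity preservation has a physical limit: two comets closer than
about 3 px (0.6 um) are not resolvable with these spot sizes, and
crossing tracks can swap under any distance-only cost. The
single-track-recovery property is therefore validated on noise-free
scenes sparse enough for comets to be resolvable (150 um^2 cone,
birth rate 1e-3 /um^2/s), where >= 95% of comets with at least three
rendered frames come back as single tracks with sub-half-pixel
positions. The direction-classification property additionally lowers
the angular jitter to 5 deg so the configured 85% anterograde fraction
is actually realised in the truth labels being recovered.

## Behavior scoring

Net behavior over a 10-min interval is the displacement of the tip
projected onto the earlier burst's proximal-to-tip axis: extension
above +1 um, retraction below -1 um, ambiguous between. The 1-um dead
zone is an automated surrogate for visual scoring; at the reference
migration rate (2.5 um per interval) labels are insensitive to this
threshold over a wide range (0.2-2 um). Measured tip displacement on
synthetic extending cones recovers 0.25 um/min within a few percent.

## Statistics

* **Median confidence intervals** use the boxplot-notch formula
  `q2 +/- 1.57 * IQR / sqrt(n)` with linear-interpolation quartiles.
* **Rank-sum tests** are two-sided Wilcoxon/Mann-Whitney: exact
  enumeration when both groups have at most 20 untied observations,
  tie-corrected normal approximation otherwise.
* **The median-difference resampling test** pools both samples and
  draws group-size-preserving resamples for the null. The default
  draws *without* replacement (a label permutation): with-replacement
  resampling of medians at small n is strongly conservative (measured
  type-I error ~0.01 at nominal 0.05, because bootstrap medians
  concentrate on order statistics), while the permutation form holds
  0.05 almost exactly. The with-replacement variant remains available
  (`replace = TRUE`).
* **Holm-Bonferroni** adjustment guards every family of per-bin
  comparisons.
* **Area stratification** uses half-open 20-um^2 bins from 10 to
  170 um^2 by default; the **sliding-window profile** (300
  observations, overlap 220, i.e. step 80) draws bootstrap medians per
  window, re-aggregates windows into the same area bins by their median
  area, and flags any bin whose 5-95% interval fails to overlap the
  fixed-bin notch interval — the binning-artifact check.
* **Differential probability distributions** histogram two groups on
  common bins spanning the pooled minimum to the pooled 97th percentile
  (25 bins by default; the count is a package choice, exposed in the
  API), normalise by each group's total observation count (so each
  histogram sums to its group's <= 97th-percentile mass), subtract, and
  wrap the difference in 5-95% bootstrap envelopes. Bin edges stay
  fixed at their original values during the bootstrap.
* **PCA** z-scores features, drops constant ones with a warning, and
  ranks features by absolute PC1 loading — the convention for reading
  off the main contributors to growth-cone variance.

## Problem sizes and numerical choices

The validation suite runs at desk scale by design: speed recovery uses
30 one-burst scenes (~7,000 instantaneous speed samples), migration
recovery 4 bursts, the tracker-correctness fixtures 6 sparse noise-free
scenes, the test-level check 1,000 null sample pairs at 199 resamples,
and profile consistency 3,000 synthetic observations. Seeds are fixed
everywhere; `simulate_sequence` restores the caller's RNG state, and
all stochastic statistics take explicit seeds with `n_boot = 1000` by
default. Zero-comet frames contribute zero to counts and densities but
are excluded from per-frame speed medians. Observations outside the
stratification range are excluded with a logged count.

## Known limitations

* Sub-pixel speed floors: medians below ~0.08 um/s are inflated by
  localisation noise at the default photon budget (see above).
* Comet pairs closer than ~0.6 um merge; crossing tracks can swap
  identity under the distance-only assignment cost.
* Segmentation assumes one dominant cone per field with the neurite
  entering through a declared image edge.
* The generator's rigid translation cannot probe shape-change-coupled
  behavior scoring; the tip landmark was made robust to boundary-lobe
  ambiguity precisely because real cones are not rigid.
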