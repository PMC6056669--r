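# conetrax

Multiscale quantification of microtubule plus-end ("EB3 comet")
dynamics in migrating neuronal growth cones.

Growth cones — the motile tips of growing neurites — steer axon
extension by continuously remodelling their microtubules. Fluorescent
end-binding protein 3 (EB3) marks polymerizing plus ends as small
moving "comets", and burst time-lapse imaging (e.g. 33 frames at 2-s
intervals, repeated every 10 min) captures both comet kinematics
(~0.1 µm/s) and whole-cone migration (~0.25 µm/min). `conetrax`
implements the full analysis chain for such recordings:

* **Growth-cone segmentation** from cytoplasmic background signal
  (Sobel edges + morphology), with landmark geometry: boundary,
  distance-transform midline, the leading-edge **front** defined by the
  1:1.7 midline division rule, tip point, and `regionprops`-style
  morphology scalars (area, perimeter, equivalent-ellipse length/width,
  eccentricity).
* **Comet detection and tracking**: band-pass detection with
  photon-statistics thresholds, neighbour-aware Gaussian fitting for
  sub-pixel localisation, and gap-closing trajectory linking by global
  optimal assignment under the published plus-end tracking constraints
  (search radius 1.5–6 px, minimum track length 3 frames, maximum gap
  3 frames, forward/backward cones 35°/15°, shrinkage factor 1.4,
  fluctuation radius 1.25 px).
* **Spatial mapping**: minimal Euclidean distances of comets to the
  front and midline, birth/death distances for burst-complete tracks,
  and anterograde/retrograde/lateral classification of net paths
  relative to the midline.
* **Behavior scoring**: extension vs. retraction per 10-min interval
  from the signed tip displacement along the proximal→tip axis.
* **Size-stratified statistics**: notch confidence intervals for
  medians (`q2 ± 1.57·IQR/√n`), exact/approximate Wilcoxon rank-sum
  tests, a calibrated resampling test for median differences,
  Holm–Bonferroni correction, 20-µm² area stratification, the
  sliding-window bootstrap profile (window 300 / overlap 220) with its
  binning-artifact check, differential probability distributions with
  97th-percentile histograms and bootstrap envelopes, and PCA of the
  growth-cone feature space.
* **A synthetic time-lapse generator** producing TIFF-ready image
  stacks of a migrating, comet-filled growth cone with exact ground
  truth, so the entire pipeline is testable end to end without raw
  microscopy data.

## Worked example

Simulate one imaging burst of a growth cone at wild-type conditions
(median comet speed 0.11 µm/s, 85% anterograde, 2-µm slow zone at the
front), then run segmentation, tracking and spatial mapping:

```r
library(conetrax)

sched <- make_schedule(frames_per_burst = 33, frame_interval = 2,
                       burst_interval = 600, n_bursts = 1,
                       pixel_size = 0.211)
sim <- simulate_sequence(sim_config(seed = 1), sched)
res <- analyze_burst(sim$stacks[[1]], sched)

res$geometries[[1]]
#> gc_geometry: area 52.5 um^2, perimeter 36.4 um, L 13.6 x W 5.3 um, ecc 0.92

median(res$kinematics$steps$speed)            # um/s
#> [1] 0.08276434
median(sim$truth$comets$step_speed, na.rm = TRUE)  # ground truth
#> [1] 0.08353957
```

The measured median instantaneous speed (0.0828 µm/s) recovers the
ground-truth median (0.0835 µm/s) within ~1%; both sit below the
configured 0.11 µm/s because comets inside the 2-µm front zone are
slowed by the configured damping factor. Comparing speeds by distance
to the front makes the slow zone visible directly:

```r
rec <- comet_landmark_distances(res$tracks, res$geometries)$records
m <- merge(res$kinematics$steps,
           rec[, c("track", "frame", "dist_front")],
           by = c("track", "frame"))
front_zone_speed_profile(m[, c("track", "frame", "dist_front")],
                         m[, c("track", "frame", "speed")])
#>   bin_lo bin_hi  n     median      ci_lo      ci_hi
#> 0      0      1 89 0.07131382 0.06182002 0.08080762
#> 1      1      2 74 0.08872371 0.07823959 0.09920782
#> 2      2      3 22 0.10925706 0.09103148 0.12748263
#> 3      3      4  2 0.14406617 0.12081137 0.16732098
#> 4      4      5  2 0.05347141 0.04881821 0.05812462
```

Comets within 2 µm of the leading edge run at ~0.7× the interior
speed, matching the configured damping. A full multi-burst,
one-or-two-group run — segmentation, tracking, mapping, behavior
scoring, observation tables and per-area-bin group comparisons with
Holm-adjusted p-values — is one call:

```r
run_pipeline(list(out_dir = "run1",
                  sim = list(seed = 1, migration_velocity = 0.25)))
```

which writes `growth_cones.csv`, `comets.csv`, `tracks.csv`,
`behavior.csv`, a provenance JSON and a log.

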