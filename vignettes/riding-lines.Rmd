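---
title: "Extracting riding lines from pose detections in a video fence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting riding lines from pose detections in a video fence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fencetrack)
```

## The problem

In off-road cycling disciplines such as cyclocross, short technical sectors —
a sandpit, a set of barriers — decide races. A fixed, roughly overhead camera
pointed at such a sector, combined with a skeleton detector, yields per-frame
pose detections (17 COCO keypoints per person). fencetrack turns that stream
into *riding lines*: the spatial path each rider took through a rectangular
region of interest (the fence), with how long they dwelt in it, whether they
rode or ran, and which team jersey the upstream classifier saw.

The package deliberately consumes detector output rather than video: pose
estimation, ride-mode detection and jersey classification are pluggable
per-frame inputs, so everything here is exact, fast, and testable without a
GPU or footage.

## The processing model

Frames are analyzed on a stride grid (every `frame_stride`-th frame; default
3, which on 30 fps footage keeps 10 samples per second — a good balance of
density and cost). All frame indices remain in original video numbering, so
times are always `frames / fps`.

**Tracking.** The tracker keeps, for each live track, its last known center
and the analyzed frame at which it was last seen. For each new frame the
matrix of Euclidean pixel distances between live centers and new pose centers
is formed. A new pose may only join its *nearest* live track, and only when
that distance is strictly below `match_frac` (default 0.25) times the
diagonal of the new pose's own bounding box — a gate that scales naturally
with apparent rider size. When two poses claim the same track, the closer one
wins (ties by lower track id, then pose index); the loser opens a fresh
track. Tracks unseen for more than `memory_frames` analyzed frames (default
5) are forgotten. The matcher is deterministic and seedless.

The gate/minimum-distance rule leaves a genuine design choice for resolving
simultaneous claims; we resolve globally in ascending distance with mutual
exclusivity because it is deterministic, cheap, and consistent with the
nearest-neighbour reading. The test suite pins this behavior against a
literal brute-force enumerator.

**Fragment merging.** Detector dropouts and occlusions fragment identities:
a rider reappears beyond the gate and receives a new id. Repair proceeds in
three steps. (1) Tracks are split at jumps in analyzed-frame numbers into
gap-free fragments. (2) Every time-ordered fragment pair is scored with a
spatiotemporal weight

w(a, b) = ‖end(a) − start(b)‖ + λ_t · Δt(a, b),

with Δt in analyzed frames and λ_t = 10 px per analyzed frame by default.
The weight must be strictly below a threshold set from the fence's
dimensions (default a quarter of the fence diagonal). (3) Links are accepted
greedily in ascending weight, each fragment taking at most one predecessor
and one successor, and only between fragments with disjoint frame support —
co-temporal fragments are necessarily different riders and never merge.
Because riders traverse the fence in one consistent direction, candidate
links that move backwards along the travel axis by more than `reverse_tol`
(default 10% of the fence extent on that axis) are rejected. The weighting
function itself is a modelling choice: it is the simplest dimensionally
coherent combination (pixels plus pixels-per-frame times frames) that
penalizes both spatial and temporal separation; λ_t is exposed in the
configuration for scenes with different speeds.

**Fence analysis.** A detection is inside the fence iff its bbox center lies
in the half-open rectangle `[xmin, xmax) × [ymin, ymax)` (half-open so
adjacent fences partition the image). A *valid* path entered and exited: at
least one detection strictly before its first inside detection, at least
`min_inside` (default 2) detections inside, and at least one detection after
its last inside one. Paths still inside when the stream ends are excluded
but reported separately as incomplete. In streaming operation, path
post-processing fires when the fence stays empty for
`empty_frames_to_finalize` (default 10) consecutive analyzed frames; the
batch pipeline reports these trigger frames.

**Timing.** `duration_s = (exit_frame − entry_frame) / fps` measures first
to last observation inside. Both endpoints are quantized outward on the
stride grid, so this systematically *underestimates* the true
boundary-to-boundary crossing time by up to two analyzed-frame periods (one
per end, `frame_stride/fps` each). The reported `crossing_s` therefore adds
half a period at each end: `crossing_s = duration_s + frame_stride/fps`.
For steady motion this estimate is provably within one analyzed-frame
period of the analytic crossing time, which the acceptance tests verify
over random speeds and strides. Both numbers are reported; `duration_s` is
the raw observable, `crossing_s` the recommended estimate.

**Metadata.** Over a path's inside-fence frames, the major ride mode is the
modal label; ties break by the fixed priority riding > running > crashing >
spectator > unknown (deterministic, biased toward the overwhelmingly common
case). The mode breakdown converts per-mode frame counts to seconds via the
analyzed-frame period. Team scores are the arithmetic mean of the per-frame
team probability vectors, renormalized; max-pooling is available via
`team_aggregation: max` for upstream classifiers whose confident frames are
more informative than their average. Metadata is aggregated only — it is
never used for matching.

**Homography.** When the scene configuration provides at least four
image/world correspondences on the ground plane, each path's polyline is
also emitted in world coordinates. Estimation is the normalized direct
linear transform: Hartley normalization (centroid to origin, mean distance
√2) on both sides, SVD solution of the 2n×9 system, denormalization, and
scaling to `H[3,3] = 1` — exact for four points, least squares beyond. The
output frame is whatever frame the correspondences define; meters by
convention. Lens distortion is out of scope.

## The simulator and what it does (not) show

`sim_scenario()` / `simulate_scene()` generate detection streams with ground
truth. Riders move along piecewise-linear waypoint paths at constant pixel
speed; keypoints are a fixed symmetric 17-point template scaled to the
rider's bbox diagonal and centered on the true position, plus i.i.d.
Gaussian noise; dropouts delete whole detections; *injected breaks* are
forced dropout runs placed so the rider reappears beyond the matching gate,
provoking exactly the re-identification failures the merger must repair.
Ride-mode schedules switch labels at chosen frames, emulating a rider
dismounting in deep sand.

The defaults are the reference study conditions used throughout the tests:
a 600 × 400 px fence, 30 fps, stride 3, bbox diagonal 100 px (so the gate is
25 px), speed 5 px/frame (15 px per analyzed frame, safely inside the gate),
three riders on separated lanes. A forced dropout of even one analyzed frame
produces a 30 px jump and a guaranteed split; breaks of up to 3 analyzed
frames yield merge weights (≤ 45 px + 10·4 px) comfortably under the
default 180 px threshold, so full recovery at zero noise is the expected —
and tested — outcome.

The simulator is deliberately not biomechanically realistic: no limb
articulation, no perspective scaling of the diagonal, no occlusion between
crossing riders, no identity *swaps* (only losses). Passing its tests
demonstrates that the association, merging, timing and geometry logic
implement their rules exactly; it does not certify performance of any
upstream detector on real footage, nor merger behavior under heavy mutual
occlusion from a low camera angle — the overhead camera placement this
pipeline assumes exists precisely to make those rare.

## Numerical and degenerate-input choices

* Matching and merge gates are strict (`<`), so a distance exactly at the
  gate does not match — boundary cases are thus deterministic.
* Ties anywhere (equal distances, equal merge weights, mode ties) break by
  the lowest id or the fixed priority list, never by input order hashes.
* A skeleton whose keypoints all fall below the confidence floor
  (`keypoint_min_conf`, default 0.05) falls back to using all keypoints
  rather than producing an empty bbox.
* Homography estimation refuses under four pairs, collinear triples and
  vanishing-scale solutions; applying a homography refuses points mapping
  to infinity (|w| < 1e-12), naming the offending point.
* The empty stream is valid everywhere: zero detections produce zero
  tracks, zero paths, an empty report and exit code 0.

## Problem sizes in the test suite

The bundled tests run on simulated scenes of one to four riders over
roughly 60–110 analyzed frames (a few hundred detections), 1000-instance
single-frame matcher comparisons against the brute-force oracle, 10^4
random occupancy strings for the finalize trigger, and 10^3-point
homography round trips — sizes chosen so the full suite exercises every
rule densely while completing in a few minutes on one core.

## A worked example

```{r example}
scene <- simulate_scene(sim_scenario(
  n_riders = 3, noise_sd = 2, dropout = 0.05,
  breaks = data.frame(rider = c(1, 2), frame = c(60, 90)), seed = 11))
cfg <- as_fencetrack_config(list(
  fence = list(xmin = 100, ymin = 50, xmax = 700, ymax = 450,
               fps = 30, frame_stride = 3)))
report <- run_pipeline(scene$detections, cfg,
                       annotations = scene$annotations, verbose = FALSE)
report
as.data.frame(attr(report, "fence_paths"))
```

```{r plot, fig.width = 7, fig.height = 5}
plot_ridelines(report)
```

## Known limitations

* Identity swaps between riders who pass within one gate radius of each
  other are not detected or repaired; the fenced overhead-camera setup is
  assumed to make them rare.
* The merger never retro-splits a previously accepted chain; overlap is
  prevented at link time instead.
* Entry/exit frames are reported as first/last inside detections; only the
  derived `crossing_s` corrects for stride quantization.
* World coordinates are only as good as the supplied ground-plane
  correspondences; no lens model is applied.
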