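---
title: "Fusing multi-camera 2D pose detections into validated 3D joint centres"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing multi-camera 2D pose detections into validated 3D joint centres}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinefuse)
```

## The problem

CNN pose estimators (OpenPose, AlphaPose, DeepLabCut and kin) return, per
camera and frame, a sparse set of 2D keypoints with confidences. Turning
those into 3D joint-centre trajectories that a movement scientist can use
requires a chain of non-trivial steps — camera geometry, outlier-robust
multi-view fusion, person tracking, temporal smoothing — and then a second
chain to *validate* the result against marker-based motion capture: spatial
and temporal alignment of the two systems, event detection, cycle
registration, and agreement statistics. `kinefuse` implements both chains
and, because real paired capture data of this kind is rarely shareable,
ships a synthetic multi-camera laboratory that generates every input with a
machine-readable answer key. Every claim the package makes about itself is
a recovery test against that key.

## Reconstruction model

**Cameras.** Each camera is a pinhole model with focal lengths and
principal point in pixels, a two-term radial distortion polynomial
`x_d = x (1 + k1 r^2 + k2 r^4)` on normalised coordinates, and a rigid
world-to-camera pose. World coordinates are millimetres in a Z-up
right-handed frame with the origin on the floor at the volume centre.
Back-projection inverts the distortion by fixed-point iteration (at most 20
steps, tolerance 1e-10 in normalised units); the round trip
project-then-back-project closes to better than 1e-3 mm across the volume
for |k1| up to 0.1.

**Fusion.** For one joint in one frame, every detection with confidence at
or above the gate (default 0.3) is back-projected to a ray. The point
minimising the sum of squared perpendicular distances to all rays has a
closed form (the 3x3 normal equations), but one mislabelled detection can
drag it arbitrarily far, so fusion is wrapped in RANSAC: hypotheses are
minimal two-ray intersections, the consensus set is every ray within
`inlier_tol_mm` (default 20 mm) of the hypothesis point, ties between equal
consensus sizes break toward the smaller inlier rms, and the winner is
refit on its inliers. With up to 12 rays all C(n,2) pairs are enumerated —
the search is exhaustive and deterministic; beyond that, pairs are sampled
under a caller-provided seed (default budget 100). A frame with no 2-ray
consensus is a masked gap, not an error. These three knobs (threshold,
budget, refit policy) are our choices; nothing in the underlying method
fixes them, and 20 mm is roughly 3x the single-frame noise floor of the
default rig at 2 px detection noise.

**Tracking.** When several people are visible, per-frame association uses a
ground-plane occupancy map: pelvis-level detections are back-projected and
their crossings with a floor-parallel plane accumulate in a grid (100 mm
cells by default). Only pelvis keypoints contribute, because a ray through
a joint far above or below the plane crosses it far from the person —
with cameras a few metres out, a 50 mm height mismatch displaces the
crossing by several hundred millimetres. For the same reason the plane
belongs at the expected pelvis height (default 950 mm standing; during
gait the pelvis bobs, so a gait analysis should set the plane at the
mid-gait pelvis height and may coarsen the cells — `analysis/02` shows the
pattern). Peaks (3x3-neighbourhood local maxima above a count threshold,
refined to the mean crossing position) are linked frame to frame by greedy
nearest neighbour with a 100 mm/frame gate; the subject is the longest
track, ties broken toward the volume centre.

**Smoothing.** Each axis of each trajectory is smoothed by a
constant-velocity Kalman filter run forward and backward, the passes fused
by their information matrices. The state is position and velocity with a
time step of one frame; the process covariance is the continuous
white-noise-acceleration form `q [[1/3, 1/2], [1/2, 1]]` (chosen over the
piecewise-constant form because it is invertible, which the backward
information recursion needs), measurements are positions with variance `r`.
Defaults `q = 1`, `r = 25` mm^2 suit 200 Hz human motion with a ~5 mm
reconstruction floor; as `r/q` goes to zero the smoother returns its input.
Two-filter fusion is algebraically a fixed-interval RTS smoother, and the
test suite holds the two to 1e-9 mm against an independently coded RTS
implementation. Gaps are bridged by prediction only and never published as
valid beyond 0.25 s; leading and trailing gaps stay masked.

## Reference model and validation machinery

The marker-based reference pipeline low-pass filters trajectories
(zero-phase Butterworth, 4th order, 12 Hz cut-off at 200 Hz — two passes,
so the cut-off emerges at half amplitude; edges are protected by
odd-reflection padding of three cut-off periods and mean-centring, making
the DC gain exactly 1). Joint centres are medial/lateral marker midpoints,
except the hip, which comes from a regression on pelvis geometry: each hip
centre is offset from its ASIS marker by fixed fractions of the inter-ASIS
distance along the pelvis axes. The fractions (medial 0.36, posterior
0.22, inferior 0.30) are configuration, exposed in
`bell_hip_coefficients()`, as published variants of the regression differ;
the construction is exactly equivariant under rigid motions and mirrors
left/right by symmetry.

The two systems' Euclidean frames are aligned with a Kabsch/orthogonal-
Procrustes fit (no scaling) on a shared single-marker trial; its `rms` is
the per-coordinate residual, which for isotropic per-axis noise of SD sigma
converges to sigma. The clocks are aligned by maximising the
cross-correlation of a shared LED flash sequence over integer lags, and a
wand of known length moved through the volume audits end-to-end
reconstruction accuracy (mean and SD of the resultant-length error).

**Events.** Jump trials: bodyweight and its SD come from a quiet-standing
window (first 1 s by default); first movement is the first frame of the
first run of at least 20 consecutive frames below bodyweight; stabilisation
is the first post-landing frame from which force stays within 3 SD of
bodyweight. The rule text leaves the hold duration open; we require 0.5 s
and expose it. Whether the SD is the pre-jump quiet-standing SD is also
not fixed by the rule; we use it and record the choice here. Gait trials:
with the generator's analytic contact flags, touch-down is a rising edge
and toe-off a falling edge, exactly; a kinematic stand-in (foot-height
minima at near-zero vertical velocity) exists for data without flags, but
only the exact flag mode feeds the validation experiments, since the
proprietary event function used with real marker data is out of scope.
Event indices detected on the reference are reused verbatim for the
markerless data — the systems share a clock. Each cycle is registered to
101 points by linear interpolation, endpoints inclusive, regardless of
cycle length; registration is idempotent.

**Agreement.** Differences are markerless minus marker (A − B), per axis
and as 3D Euclidean distances, pooled per joint/axis/activity across
cycles, trials and subjects (the pooling level is configurable). Bias is
the mean difference, random error its SD. The 95% limits of agreement are
`bias ± 1.96 SD` when a Shapiro–Wilk test does not reject normality at
0.05, else the 5th/95th percentiles with linear interpolation between
order statistics (`quantile` type 7 — fixed and documented, as percentile
conventions differ). Shapiro–Wilk accepts at most 5000 observations, so
longer pooled vectors are gated on a deterministic evenly spaced subsample
of 5000. Waveform similarity is summarised by OLS of the markerless on the
marker waveform: R^2 (strength), intercept (offset), gradient (scaling).

## The synthetic laboratory

`make_camera_rig()` places 9 cameras on a 6 m ring at alternating heights
around a 4 x 4 x 2 m volume; every volume corner is visible in all 9 (the
contract requires at least 6). Gait is a stylised sinusoidal kinematic
chain — a pelvis translating through the volume with anti-phased limb
phases, walking at 1.3 m/s with a 1.15 s stride (duty factor 0.62) and
running at 2.2 m/s with a 0.65 s stride (duty 0.35, so flight phases
exist). Defaults produce 4 complete TD-to-TD step cycles per walking trial
and 6 per running trial, both sides pooled; speeds were chosen once so
those cycles fit the rig's field of view. This is deliberately not a
biomechanically validated gait model: the validation experiments measure
recovery of known geometry, injected bias and event timing, none of which
needs realistic joint coordination — but it also means passing tests say
nothing about pose-estimator behaviour on real images, soft-tissue
dynamics, or true gait variability. Jumps are built from an acceleration
profile (half-sine unweighting of 0.3 s — 60 frames below bodyweight, three
times the rule's minimum — propulsion sized by impulse–momentum to the
requested apex, ballistic flight, a landing impulse and a damped settling
oscillation), so force and centre-of-mass motion are mutually consistent
and every event frame is known analytically.

Detections are projections plus isotropic Gaussian pixel noise; misses
(confidence 0) and outliers are Bernoulli per detection, with outliers
either uniform random pixels or the corresponding joint of a background
person — the failure modes of real pose estimators. Clean detections draw
confidence from U(0.7, 1), corrupted from U(0.1, 0.6); real confidence
distributions are estimator-specific, so this model is a stated
convention, not a calibration. The marker reference is ground truth plus a
constant per-joint offset (the hip/knee systematic-bias mechanism) plus
low-pass-filtered noise (4 Hz corner) emulating soft-tissue artefact.
Every corruption is logged; every injected quantity lands in the answer
key. Scenes regenerate bit-identically from a seed (R's default
Mersenne-Twister stream, isolated from the caller's RNG state).

## Numerical choices and degenerate inputs

Near-parallel ray bundles are rejected by a reciprocal-condition-number
check rather than silently solved; two-ray hypotheses with parallel rays
are skipped. Collinear point sets make the alignment problem rank-deficient
and error out. The C3D container common in motion capture has no reader or
writer in this package's dependency set, so trajectories round-trip through
a lossless long-format CSV (`frame, joint, x, y, z, valid`) at full double
precision instead. Frame indices are 1-based throughout, as is natural in
R; event examples stated on a 0-based clock translate by one.

## Problem sizes

The shipped experiments are sized for a laptop-class single core: the
bias-recovery experiment runs 3 subjects x 3 trials of walking (about 680
frames each at 200 Hz, 9 cameras) in roughly a minute; the analysis
scripts each finish in seconds to a couple of minutes. All sizes are
configuration, and scale linearly.

## Known limitations

- The gait generator has no double-float stance mechanics, no soft-tissue
  motion on the *markerless* side, and no image formation: 2D detections
  are corrupted projections, not CNN outputs.
- Tracking assumes people remain ground-plane-separable; two people
  embracing would merge into one occupancy peak.
- The occupancy plane height is a real tuning parameter on real data
  (pelvis height varies across subjects and activities); the defaults suit
  standing adults, and gait analyses should set it per activity.
- The hip regression coefficients are a configuration default; studies
  requiring a specific published calibration should set them explicitly.
- Confidence values carry no calibrated meaning beyond the gate.
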