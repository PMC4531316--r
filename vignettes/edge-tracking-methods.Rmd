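---
title: "Tracking cell-edge dynamics and correlating them with biosensor activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking cell-edge dynamics and correlating them with biosensor activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`edgefret` measures the spatiotemporal coordination between a
membrane-proximal FRET biosensor signal and the motion of the cell edge in
cells released from a micropatterned constraint. This vignette documents
the model behind each stage, the tunable parameters and their defaults,
the numerical choices, what the synthetic generator does and does not
emulate, and the package's known limitations.

## The measurement model

A two-channel movie (donor and acceptor emission) is reduced to two
functions on the cell edge: the emission ratio S(w, t) (dimensionless) and
the boundary translocation B(w, t) (µm), both indexed by sampling window
w along the boundary and frame time t (minutes, t = 0 at the constraint
release). All physical coordinates are micrometers; pixel centers sit at
integer pixel coordinates (x rightward, y downward), multiplied by the
pixel size.

### Ratio movie

Per frame and channel, the intensity at a low percentile of the whole
frame (default the 5th) is subtracted and negatives clipped: the cell
occupies a minority of the field of view, so a low percentile tracks the
camera-plus-background level without requiring a segmentation first. The
ratio donor/acceptor is computed only where the acceptor exceeds a
minimum intensity (default 3× the standard deviation of the
post-subtraction background); dimmer pixels are masked `NA`, never zero.
Ratio frames are not smoothed by default — an optional median filter
(radius in px) is exposed, since ratiometric noise suppression is a
judgment call the analyst should make explicitly.

### Boundary detection

Pixels are clustered into k intensity classes (default k = 3: background,
dim cell periphery, bright cell body) with `stats::kmeans`, initialized
deterministically on intensity levels evenly spaced over the frame's
range. Range-spaced initialization (rather than mass quantiles) matters:
when the cell covers a few percent of the field, mass quantiles place
several centers inside the background mode and the background splits
across classes; range-spaced centers keep the whole background in the
darkest class, which is exactly the class the mask rule discards. The
union of the non-darkest classes is closed morphologically (radius 1 px),
hole-filled, and reduced to its largest connected component (EBImage);
marching squares at the 0.5 level gives a sub-pixel boundary, stored
counter-clockwise and resampled to uniform spacing (default half a
pixel). The acceptor channel is used by default (brightest and most
uniform); donor or the channel sum are config options.

### Level-set boundary evolution

Each boundary Γ(t) is embedded as the zero level of a signed Euclidean
distance field φ (negative inside). Evolution onto Γ(t+1) solves the
Hamilton–Jacobi equation φ_t + V|∇φ| = 0 with the morphing speed
V = −φ_next, the signed distance to the target boundary: the front moves
along its normals toward the target and stalls on it, because V changes
sign exactly on the target's zero level. The speed is capped at
`v_cap` (default 10 grid cells) so the far field does not dictate a tiny
CFL step.

Numerics: first-order Godunov upwind differences, forward Euler with
dt = cfl · h / v_cap (cfl = 0.5), Neumann boundary replication,
Sussman PDE reinitialization toward |∇φ| = 1 every 25 steps (8
pseudo-time iterations of step 0.3 h). The evolution stops when the
residual max |φ_next| on the current front falls below 0.5 h, or errors
after `max_steps` (500) with the residual as diagnostic. Intermediate
fronts are snapshotted and returned as `n_intermediate` contours (default
10 per frame pair) evenly spaced in step count, the last being the
converged front. Exact signed distances are computed against the contour
polyline (vectorized over segments), with a far-field clamp for speed on
full frames; the near field is always exact.

### Correspondence and conflict correction

Reference points (the resampled vertices of Γ(t), default 0.5 µm
spacing) are chased through the intermediate fronts by nearest-point
projection, arriving on Γ(t+1) as 1-D normalized arc-length parameters.
The arc-length origin is anchored at the topmost-then-leftmost vertex of
the first frame and, in every later frame, at the vertex closest to the
previous origin, keeping window identities stable.

Three conflicts are corrected in order, each flagged per point:

* **missing** — a projection jump larger than 6× the median jump of that
  stage (floor 0.5 µm) marks the match lost; the target parameter is
  filled by circular linear interpolation of the neighbors.
* **crossing** — target parameters whose order is locally inverted are
  replaced by the circular isotonic projection (pool-adjacent-violators on
  the unwrapped parameters): the nearest circularly non-decreasing
  sequence. Isotonic projection was chosen over local pair swapping
  because it resolves runs of crossings deterministically in one pass.
* **direction** — where the displacement points more than 90° away from
  the locally averaged motion (circular window of ±5 points) *and* the
  local mean motion exceeds 0.25 µm, the target parameter is re-assigned
  from the neighbors. The motion floor keeps sub-pixel jitter of a static
  boundary from being treated as a conflict.

If more than half the points need correction the frame pair is rejected
as a tracking-quality error. Displacements are always recomputed from the
corrected parameters, so the stored vectors connect each source point to
its final target parameter.

### Windows, sampling, translocation

The sampling band is read off the distance field: pixels with
−depth ≤ φ < 0 (default depth 0.5 µm). The edge is cut into
n = ⌊perimeter/width⌋ windows of equal arc width (default 1.25 µm);
each band pixel joins the window containing the arc parameter of its
nearest boundary point. Windows are *material*: their boundary parameters
are mapped through each frame pair's correspondence, so widths drift
slightly rather than being re-equalized — preserving window identity is
worth more than exact equal widths. S(w, t) is the mean ratio over the
window's valid pixels (fewer than 3 valid pixels → missing). The window
displacement is the mean of the displacement vectors of the reference
points inside the window, projected on the window's outward normal
(protrusion positive). Translocation integrates displacements from the
release frame: B = 0 at release, forward partial sums after, backward
partial sums before, so B is the location change relative to the
constrained position. Ratio sampling happens on detected frames only; the
intermediate level-set fronts serve the correspondence, not sampling.

### P/NP classification

Per window, the peak is the maximum translocation over post-release
frames (pre-release translocation is ≈ 0 by construction of the
baseline). Windows with peak ≥ 75% of the cell's maximal peak are P
(inclusive, so the argmax window is always P). Runs shorter than 3
windows are suppressed and runs separated by ≤ 1 NP window merged — both
config-exposed; they exist to stop single-window noise regions from
flipping the cell class. Window topology is circular. A cell with exactly
one P-region is polarized. Peaks use signed B (protrusion), not |B|:
protrusive regions are what the classification is about, and retraction
regions are a non-goal.

### Globally normalized cross-correlation

For each window, ρ(τ) = Cov(S(t), B(t+τ)) / (σ_S σ_B) on the frame-time
lag grid, with each series centered once by its full-length mean,
covariance over the overlapping samples (truncation, no padding; pairs
with a missing value dropped; lags with fewer than 5 overlapping pairs
omitted), and σ_S, σ_B the *maxima over windows* of the centered series'
standard deviations. Dividing by shared maxima instead of each window's
own SD deliberately shrinks coefficients in low-change windows — the map
highlights regions where both signal and motion actually change. The
default maximal lag is half the post-release duration; beyond that the
overlap is too short to be meaningful.

Sign convention, stated once and used everywhere: **a negative CC minimum
at positive τ means the ratio change precedes the translocation change by
τ**. Ties at the minimum break to the smallest |τ|, then the positive τ.
A curve with no negative coefficient carries the flag
`no-negative-minimum` rather than a fabricated lag.

The spatial CC correlates the two line scans along the edge at one time
step as a function of circular window shift, normalized by the maxima
over time steps of the spatial standard deviations — computed separately
per map, mirroring the temporal case.

### Statistics

Bootstrap means use 5000 resamples with replacement and percentile 95%
CIs, deterministic given the seed. Group comparisons use the Welch
unequal-variance t-test (the safe default when only "t-test" is
specified); two constant groups with equal means give p = 1. Windows are
the sampling unit; the per-cell pseudo-replication this implies is
documented here rather than corrected, and a mixed-model treatment is out
of scope. Time courses can be normalized by their pre-release baseline
mean.

## The synthetic generator

Scenarios exist at two levels. Map-level scenarios write S and B
directly: B(w, t) = advance · g((t − t_B)/s) in sector windows (0
elsewhere) and S(w, t) = 1 − drop · g((t − t_S)/s), with g the logistic
sigmoid, t_S = t_B − τ, plus i.i.d. Gaussian noise scaled to each map's
dynamic range (default 5%). Because both series share the same shape g
shifted by τ, the programmed lead is the lag the cross-correlation should
recover.

One numerical subtlety governs the registered steepness s = 0.4 min.
The covariance at lag τ′ is computed over the truncated overlap with
full-series means, and for slowly varying sigmoids the plateau products
dominate, biasing the argmin below the programmed τ by 1–3 frames. The
transition time constant is therefore registered short relative to the
1-minute sampling (a switch-like protrusion onset), which makes the CC
minimum sharp and the noiseless argmin exactly τ — the property the
map-level scenarios are built to have. This is a statement about the
estimator's truncation behavior, worth remembering when interpreting lags
from slowly evolving real cells.

Registered map-level scenarios: `POL-A` (64 windows, 50 frames at 1 min,
release at frame 10, one 12-window sector advancing 25 µm, ratio floor
0.85, lead 10 min), `POL-B` (ensemble of 3 cells × 40 windows, lead
15 min, per-cell advance jitter ±10%), `NP-A` (three 8-window sectors,
30 µm, lead 0). Midpoints (15–20 min post-release) place both transitions
well inside the recorded window at the maximal lag considered.

The image-level scenario `POL-C` renders a 20 × 80 µm ellipse (the
micropatterned well footprint) in a 256 × 320 px field at 0.5 µm/px,
25 frames at 2 min, release at frame 3. One end sector advances 30 µm
along the local outward normals with a logistic time course (midpoint
5 min, steepness 1 min — the advance is essentially complete 10 min after
release). The sector profile has a flat core with cosine-squared
shoulders: the programmed advance is attained across a finite arc
(several windows wide) rather than at a single point, and the smooth
shoulders keep the offset boundary simple. The acceptor renders at
1000 counts inside / 50 outside with area-fraction anti-aliasing (a
one-pixel linear coverage ramp on the signed distance), the donor as
ratio × acceptor with the ratio at 0.85 in the sector (4-minute lead),
plus Poisson shot noise and Gaussian read noise (SD 10 counts); counts
are rounded to integers so written movies round-trip exactly.

What the generator does **not** emulate: actin/membrane mechanics,
texture inside the cell body, photobleaching, channel misregistration,
shading, or neighboring cells. Passing tests on these scenarios therefore
demonstrates that the algorithms recover what they are defined to
recover under realistic noise — not that detection or tracking is robust
to every pathology of real microscopy.

## Problem sizes and runtime choices

The test suite runs the full image pipeline on the 256 × 320 px, 25-frame
`POL-C` scenario (about a minute on one CPU) and on reduced 96 × 160 px
variants for the faster end-to-end checks; map-level analyses are
effectively instant. `scripts/acceptance.R` regenerates everything from
scratch with all randomness derived from `--seed`.

## Limitations

* Topology is fixed: one cell, one closed boundary; no splitting, fusion
  or multi-cell scenes.
* First-order upwind/Euler numerics: accuracy is sub-grid-cell by design
  budget, not spectral; halving the CFL number changes converged fronts
  by well under a grid cell (tested).
* The correspondence is the normal-flow (nearest-projection) map; under
  pure translation it is not the rigid-motion map on the trailing edge.
  Composition consistency is tested against the direct two-frame map, not
  against rigid motion.
* Global normalization makes CC values comparable across windows of one
  cell but not across cells with different dynamic ranges; cross-cell
  statistics therefore pool lags and minima, not raw curves.
* The isotonic crossing correction operates on the unwrapped parameter
  sequence anchored at the origin; a crossing that straddles the origin
  seam may survive in principle (not observed on the tested geometries).
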