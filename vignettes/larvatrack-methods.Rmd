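---
title: "Tracking bright animals on dark backgrounds: models and methods"
author: "larvatrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking bright animals on dark backgrounds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`larvatrack` quantifies the locomotion of small, elongated animals —
Drosophila larvae, C. elegans worms and similar organisms — recorded as
grayscale image sequences in which the animals appear bright on a
near-black background (the contrast profile produced by FTIR-based
dark-field imaging rigs, or by inverting transmitted-light recordings).
The pipeline has five stages: segmentation, posture-model extraction,
frame-to-frame association, trajectory-level head/tail correction, and
feature computation.  A synthetic scene generator with exact per-frame
ground truth and a deviation evaluator close the loop, so every stage is
validated without external data.

# Segmentation

Let $I_t(r,c)$ be the intensity at row $r$, column $c$ of frame $t$.
Because the animals are bright, move, and the rig is static, the
per-pixel minimum over time

$$B(r,c) = \min_t I_t(r,c)$$

is a background estimate that retains static artifacts (dust, substrate
impurities) precisely so that subtraction removes them.  The foreground
keeps original intensities:

$$F_t(r,c) = I_t(r,c) \;\text{ if } |I_t(r,c) - B(r,c)| \ge \tau,
\text{ else } 0,$$

with a user-set gray threshold $\tau$ (`gray_threshold`, default 40 of
255).  Since $B$ is a minimum, $I - B \ge 0$ always; the absolute value
is kept for robustness when a user supplies an external background
image.  The estimate assumes every animal moves by more than its own
body length during the recording — a stationary animal is absorbed into
$B$ and becomes invisible.  For protocols where that assumption fails,
`track_sequence()` accepts a `background` argument (e.g. a frame
recorded before animals were added), and `compute_background()` has a
`stride` argument that subsamples frames on long recordings; a
subsampled minimum is an upper bound of the true minimum, so it can only
make segmentation slightly more permissive.

Connected foreground components are labeled 8-connected and their outer
borders traced (border following; holes inside bodies are treated as
noise and ignored).  A contour's area $A$ is the number of enclosed
pixels, not a polygon area — the two differ by half the boundary length.
Contours outside the single-animal band
$\lambda_{\min} \le A \le \lambda_{\max}$ (`area_min`, `area_max`) are
discarded: below as artifacts, above as colliding animals.  Collisions
are deliberately not resolved; identities terminate at a merge and new
ones spawn after separation.

Coordinates are $x$ = column, $y$ = row, origin top-left, 0-based, with
pixel centers at integer positions.  No sub-pixel accuracy is used
anywhere in the pipeline.

# Posture model

Each filtered contour becomes a model
$(h, (s_1, r_1), \dots, (s_{L-2}, r_{L-2}), t, m)$: head, interior
spine points with local half-width radii, tail, and center of mass.

**Curvature.** Every contour point gets an angle from the first pass of
the IPAN corner detector: over flank offsets $a, b$ within an arm band
$[d_{\min}, d_{\max}]$ (in contour points), the sharpest admissible
triangle angle is kept.  The arm lengths are not dictated by the
geometry alone, so defaults are $d_{\min} = 4$, $d_{\max} = 7$, rescaled
by contour length / 100 and clamped to at least 2: arms must span
pixel-scale noise without blurring the head curvature, and should grow
with animal size.

**Head and tail.** A window of $2w + 1$ points ($w$ =
`curvature_window`, default 2) slides over the circular curvature
sequence; the sharpest mean marks one end, the sharpest remaining mean
at a circular distance of at least 25% of the contour
(`head_tail_min_separation_frac`) the other.  Sharpness alone orders the
ends only provisionally (the head end of a real larva is slightly
sharper, and the synthetic generator reproduces that); the decisive
orientation is made per trajectory (see below).

**Spine.** The contour is split at head and tail into two chains, both
running head → tail; the longer is resampled by linear interpolation to
the point count of the shorter, giving paired opposite points
$(p_1^j, p_2^j)$.  At $L - 2$ positions equidistant in arc length
(endpoints excluded, fractional indices rounded down — a deterministic
tie-break), the spine point is the pair midpoint and the radius half the
pair distance.  Radii are floored at half a pixel so that degenerate
pairs never produce a zero half-width.  $L$ counts all landmarks
including head and tail; the default `n_spine_points = 7` yields 5
interior points, matching the resolution of manual annotation protocols.
Contour orientation is normalized (positive shoelace area in image
coordinates) before splitting so the two chains are always taken in the
same order.  The center of mass is the mean of the enclosed pixel
coordinates, rounded to integers.

On a rendered bent capsule the extracted spine stays within ~0.3 px of
the true midline laterally; positions *along* the body are less exact
(up to ~3 px near the tips) because chain fractions include the cap
arcs.  Comparisons against ground truth should therefore measure
point-to-curve distance for midline accuracy and point-to-point distance
only for like-for-like landmarks.

# Tracking

Association between consecutive frames is bipartite assignment on a cost
matrix with three interchangeable cost measures: Euclidean distance of
centers of mass (smooth, can leave the body), distance of middle spine
points (inside the body, more jitter), and contour overlap in pixels (a
similarity — smooth *and* inside).  Two solvers are provided:

* **Hungarian** — optimal matching of $\min(N_t, N_{t+1})$ pairs
  (similarities are negated; rectangular matrices padded with a
  sentinel).  Optimal matching will happily pair a disappearing animal
  with a newly appearing one across the arena, so every accepted pair is
  validated: at least one landmark of the earlier model must lie inside
  the later contour (for overlap costs, a positive overlap is required
  instead).  Failing pairs terminate the earlier trajectory and spawn a
  new identity.
* **Greedy** — rows in ascending identity order each take their best
  unclaimed candidate, accepted only within `greedy_threshold` (a
  maximal distance, or a minimal overlap).  The iteration order and the
  lower-index tie-break make the result reproducible.

Overlap + Hungarian suits slow peristaltic crawling; when per-frame
displacement exceeds the body (rolling, or low frame rates) overlap
vanishes and identities terminate, while center-of-mass greedy with a
generous threshold tracks through — the synthetic `forward_crawl` and
`rolling` scenarios reproduce exactly this split.  Identities come from
a monotonically increasing counter and are never merged or reused.

# Head/tail correction

Per-frame curvature labels alternate on non-rigid bodies.  Correction is
per trajectory, in three steps.  First, nearest-predecessor anchoring
makes labels *consistent*: each frame's head label goes to whichever
endpoint is nearer the previous frame's head.  (Anchoring before voting
is deliberate: a vote over a stretch whose labels alternate frame to
frame carries no signal.)  Second, over every maximal uncoiled stretch
two cues vote on whether the consistent orientation is *correct*:

* *locomotion conformity* — the fraction of moving frame pairs in which
  the mid-point → head vector has a positive dot product with the
  center-of-mass displacement (these animals overwhelmingly move
  head-first);
* *bending conformity* — among slow frame pairs (center-of-mass step at
  or below `go_velocity_threshold`), the fraction in which the head
  endpoint moves farther than the tail endpoint (reorienting animals
  cast the head while the tail stays put).

The combined probability is the mean of the cues that had evidence;
below 0.5 (`orientation_flip_threshold`) the stretch is flipped — head
and tail swapped, spine and radii reversed, contour-derived quantities
untouched.  Equal cue weighting is a choice made in the absence of a
reason to prefer either cue; both weights are exposed through the
configurable threshold.  Coiled frames, where the spine is unreliable
anyway, inherit the decision of the preceding stretch.  The procedure is
idempotent and remains valid for any organism that moves forward in more
than half of the frames.

# Features

Per animal per frame: area $A$, perimeter $P$, and from the landmark
chain the bending angle

$$\gamma = 180^\circ + \operatorname{sign}(v_2 \times v_1)\,
  \arccos\!\frac{\langle v_1, v_2\rangle}{\|v_1\|\|v_2\|}
  \cdot \frac{180}{\pi},\qquad
  v_1 = h - s_{\mathrm{mid}},\; v_2 = s_{\mathrm{mid}} - t.$$

The arccos alone cannot distinguish sides, so the sign comes from the
2-D cross product of $v_2$ and $v_1$ in image coordinates ($y$ down):
$\gamma = 180^\circ$ is straight, $\gamma > 180^\circ$ a left bend,
$\gamma < 180^\circ$ a right bend, and label reversal mirrors the angle
($\gamma + \gamma_{\mathrm{rev}} = 360^\circ$).  Sweeps are declared at
$\gamma \ge 180^\circ + \tau_{\mathrm{bend}}$ (left) and
$\gamma \le 180^\circ - \tau_{\mathrm{bend}}$ (right) with closed
inequalities.

The spine length $S_l$ sums the landmark polyline.  A coiled posture —
body curled onto itself, midline unrecoverable — is flagged when either
$|P / S_l - \pi| \le 0.1\,\pi$ or $|2 r_{\mathrm{mid}} \pi / P - 1| \le
0.15$: both ratios converge to their circular limits as the body closes.
The tolerances were fixed so that straight capsules never fire (their
ratios are $\approx 2$ and $\ll 1$), which the test suite asserts.

Motion features use the center of mass only: accumulated distance
$d_{acc}(t) = \sum_{i<t} \|m_i - m_{i+1}\|$, distance to origin
$d_{org}(t) = \|m_1 - m_t\|$, velocity over a centered one-second window
$v_m(t) = \|m_{t-\lfloor fps/2\rfloor} - m_{t+\lfloor fps/2\rfloor}\| /
fps$ (px/frame; multiply by $fps$ for px/s), and acceleration
$a_m(t) = |v_m(t) - v_m(t+1)| / 2$ (the divisor is exposed as
`acceleration_divisor`).  A frame is a raw go-frame when $v_m$ exceeds
`go_velocity_threshold` (default 1 px/frame) and
$|\gamma - 180^\circ| < \tau_{\mathrm{bend}}$; only runs of at least
$\tau_{go}$ (`go_min_frames`, default 5) raw frames count as go phases,
everything else is reorientation.  Undefined values — window frames near
the sequence boundary, spine-derived features on coiled frames,
degenerate geometry — are emitted as explicit nulls, never as zeros.

Stimulus markers (point, line segment, axis-aligned rectangle,
axis-aligned ellipse) yield per frame the distance to the nearest marker
point, the bearing $\beta \in [0^\circ, 180^\circ]$ at the *tail*
between tail → center-of-mass and tail → nearest point (the tail is used
because head casts do not move it), and a region indicator.  The nearest
point on an ellipse is approximated by intersecting the line through the
animal and the ellipse center with the boundary — exact for circles and
on the axes, and never below the true distance by more than the
difference of the semi-axes for moderate eccentricity.

# Synthetic scenes

The generator emulates the recordings this tracker is built for:
near-black background (level 10), bright tapered-capsule bodies (level
200), optional static artifact blobs that exercise background
subtraction, and additive Gaussian noise (sd 3 in the standard
scenarios).  Each animal follows a parametric midline — anchor point,
heading, speed with optional peristaltic modulation, a bend schedule
spread uniformly (constant curvature) or over the head half only (head
casts), and optional lateral jumps (rolling).  The body is the union of
disks along the midline with a half-cosine width taper over the terminal
25% at each end; the head tip tapers sharper than the tail tip so the
curvature-based end detector has the same cue as on real larvae.
Ground truth (head, 5 interior spine points with radii, tail,
area-weighted midline centroid, bending, coiled flag, phase label) is
computed from the midline *before* rasterization; the rasterized
centroid agrees with the analytic one to within 1.5 px for non-coiled
postures.

The scenario library fixes the study conditions used throughout the
tests: `forward_crawl` is five animals of length 40 px and width 10 px
crawling at 1.5 px/frame with 20% peristaltic speed modulation and
±15° bend oscillation on non-intersecting circular orbits, 200 frames at
512×512; `rolling` uses 25 px/frame lateral jumps (over three body
widths, so consecutive contours cannot overlap); `headcast` sweeps the
head ±45° with the tail anchored while crawling at 0.35 px/frame — slow
enough to count as reorientation throughout, but enough travel (about
1.3 body lengths over 150 frames) for the minimum background to see
every pixel uncovered, which a strictly stationary animal would defeat;
`collision` drives two animals through a merge; `coiling` ramps the body
bend to 330°; `snake` undulates heading and body sinusoidally.  These
sizes keep a full pipeline run on one CPU around a minute while
preserving the per-animal resolution (~350 px² bodies) of the real
recordings the method targets.

What the generator does *not* emulate: soft-body deformation,
illumination gradients, motion blur, animals leaving the arena, and
genuine collisions with body contact physics.  Passing tests on
synthetic scenes therefore validate the algorithmic chain — they bound
discretization and algorithmic error, not biological image variability.

# Evaluation

`match_and_deviate()` matches trajectories to ground-truth identities by
majority vote over per-frame nearest centers of mass, then reports the
Euclidean deviations of center of mass and central spine point and the
absolute bending difference, pooled and per animal, each summarized with
mean, sd, median, min, max excluding outliers, max including outliers,
and the outlier count.  The outlier rule is Tukey's (beyond 1.5 IQR from
the quartiles, configurable), matching the boxplot presentation such
deviations are usually given.  Bending differences use the minimal
circular difference, *except* when the tracked head sits closer to the
true tail than to the true head: such head/tail swaps keep the raw
difference so they surface as the large outliers they are.  Only
trajectories spanning the full ground-truth range enter the statistics
(configurable via `min_coverage`); unmatched animals are reported as
lost.  The generator's analytic centroid differs by construction from a
contour-based one, which contributes a sub-pixel floor to the reported
center-of-mass deviations.

# Numerical choices and limitations

* All randomness (noise, scenario layout) is controlled by a single
  scene seed; rendering is bit-reproducible.
* Ties: greedy assignment breaks cost ties toward the lower column
  index; pair positions round fractional indices down; the mid-spine
  index is $\lceil (L-2)/2 \rceil$.
* Degenerate inputs: contours too short for curvature arms are skipped
  with a warning during batch extraction; zero-length bending vectors
  and empty velocity windows yield nulls; an ellipse queried at its
  center returns a deterministic boundary point with a warning.
* The Hungarian solver (potentials + shortest augmenting paths,
  $O(n^3)$) is implemented in the package and cross-checked against
  exhaustive enumeration in the tests.
* Collisions are not resolved, by design; overlap costs require some
  actual overlap, so very fast animals need distance costs and a greedy
  threshold instead.
* Velocities are reported in px/frame; conversion to physical units is
  the caller's responsibility via `fps` and the optical scale.
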