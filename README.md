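# larvatrack

Multi-animal tracking and locomotion analysis for dark-field recordings
of small animals (Drosophila larvae, C. elegans worms and similar
elongated organisms), for behavioral and neurogenetics labs that need
per-animal posture and motion time series from grayscale image
sequences in which the animals appear bright on a near-black background.

## What it computes

From a directory of TIFF/PNG frames the package produces, per animal
and frame, the posture model

&nbsp;&nbsp;&nbsp;&nbsp;*l* = (**h**, (**s**₁, r₁), …, (**s**₅, r₅), **t**, **m**)

— head, interior spine (midline) points with local half-width radii,
tail, center of mass — and from it area *A*, perimeter *P*, the signed
body bending angle γ (180° straight, >180° left, <180° right), spine
length *S*ₗ, a coiled-posture indicator, accumulated distance,
distance to origin, velocity *v*ₘ and acceleration *a*ₘ, go/reorientation
phases, and distance / bearing / inside indicators for user-defined
stimulus markers (point, line, rectangle, ellipse).

The pipeline: minimum-intensity background subtraction → 8-connected
contour extraction with an area band for single animals → curvature-based
head/tail candidates (IPAN first pass) → contour split/resample into a
paired midline → frame-to-frame bipartite assignment (Hungarian or
greedy; center-of-mass, mid-spine or contour-overlap costs, with an
inside-contour validation) → trajectory-level head/tail correction from
locomotion and bending conformity → feature extraction.  Colliding
animals are not resolved: their identities terminate and new ones spawn
after separation.  See the methods vignette
(`vignettes/larvatrack-methods.Rmd`) for the full model description.

A synthetic scene generator (`scenario()`, `render_scene()`) renders
FIM-style recordings with exact analytic ground truth, and
`match_and_deviate()` quantifies tracking accuracy against it.

## Worked example

Render five crawling animals, track them, and compare against the
generator's ground truth:

```r
library(larvatrack)

sc     <- render_scene(scenario("forward_crawl", seed = 1, frames = 40))
tracks <- track_sequence(sc$frames, seg = seg_config(area_min = 100, area_max = 1000))
tracks
#> <5 trajectories over 40 frames>

feats <- features_table(tracks, feature_config(fps = 10))
head(subset(feats, animal_id == 1 & frame >= 6)[, c("animal_id", "frame",
     "area", "bending", "spine_length", "velocity", "go_phase")], 3)
#>  animal_id frame area bending spine_length velocity go_phase
#>          1     6  357   188.7        43.24    1.565     TRUE
#>          1     7  357   188.3        42.72    1.476     TRUE
#>          1     8  358   187.3        42.63    1.432     TRUE

match_and_deviate(tracks, sc$truth)
#> Deviation report
#>              measure  mean    sd median    min   max max_star n_outliers
#>       center_of_mass 0.439 0.183  0.417 0.0678 0.864    0.864          0
#>  central_spine_point 0.880 0.582  0.739 0.0271 2.464    2.563          1
#>         body_bending 1.526 1.038  1.411 0.0141 4.300    5.809          2
#>  outlier_frac   n
#>         0.000 200
#>         0.005 200
#>         0.010 200
#> identity switches: 0
```

All five animals are tracked over all frames without identity switches;
the tracked center of mass stays within a pixel of the analytic ground
truth (median 0.42 px), the central spine point within ~0.7 px, and the
body bending within ~1.4° — the bodies are ~350 px², so these errors are
at the discretization floor.  The animals crawl at 1.5 px/frame, which
the one-second velocity window recovers (`velocity` ≈ 1.4–1.6), and
since they are fast and nearly straight they are in a go phase.

The same functions drive the command-line shell:

```sh
Rscript inst/cli/larvatrack.R synth --scenario forward_crawl --seed 1 --out frames/
Rscript inst/cli/larvatrack.R track --input frames/ --out results/ --config config.yaml
Rscript inst/cli/larvatrack.R eval  --tracked results/models.csv \
                                    --truth frames/ground_truth.csv --report results/dev
```

`track` writes `features_long.csv` (animal, frame, feature, value),
`features_wide.csv` (animals in columns), `models.csv` (the landmark
table) and `trajectories.png` (color-coded center-of-mass paths over the
last frame).

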