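# herdmotion

Continuous movement monitoring of group-housed pigs from overhead-camera
instance-segmentation contours.

Camera-based precision livestock farming needs a robust answer to a simple
question: *how much did the herd move today, and where did it spend its
time?* Tracking individual pigs across a full day is brittle — detections
drop out, bodies touch and identities swap. `herdmotion` instead condenses
each frame to a **single group position** and quantifies its displacement
over time. The package is detector-agnostic: it consumes per-frame polygon
label files (YOLO-segmentation dialect: class id, normalized vertex pairs,
optional confidence) plus a frame manifest, and never touches video or
network weights.

## Method

For each detected pig contour the centre point is the mass centroid of the
rasterized (filled) contour, computed from the raw spatial image moments

```
m_ji = Σ_{x,y} I(x, y) · x^j · y^i ,   x̄ = m10 / m00 ,   ȳ = m01 / m00
```

where `I(x, y)` is the binary intensity of the filled contour. Because
every interior pixel carries equal weight, this centre barely moves when a
lying pig shifts a leg — unlike the vertex mean, which is pulled toward
densely annotated appendages. Three comparison algorithms (vertex mean,
iterative least squares, signed-area/shoelace centroid) are included and
exposed everywhere the moment centre is.

The per-frame centres are merged bottom-up by **agglomerative clustering**
(Ward linkage by default, deterministic lowest-index tie-breaks) into one
group point per frame. Consecutive group points give the scale-invariant
displacement

```
D = 100 · sqrt((x_i − x_{i−1})² + (y_i − y_{i−1})²) / sqrt(W² + H²)  [%]
```

i.e. the Euclidean move as a percentage of the image diagonal, so tracks
computed at different image scales agree. Displacements aggregate into
daily totals, 24-hour profiles, pen-occupancy density grids with marginal
histograms, and quadrant statistics compared between observation periods.
A detection-evaluation module (mask IoU matching, precision / recall / F1)
and a clusterer runtime benchmark round out the toolkit.

Every stage is testable without data: `simulate_group_walk()` generates
pig-shaped contours (lying / sitting / standing, 30–50 vertices) around a
latent two-state random walk with a diurnal activity schedule, and records
the full ground truth.

## Worked example

Simulate one day of a 7-pig pen (3632 × 1632 px frames, one frame every
5 minutes), run the full pipeline, and read the analytics:

```r
library(herdmotion)

scene <- simulate_group_walk(pen_config(duration = 288L, seed = 42L))
write_scene(scene, "demo_scene")

res <- run_pipeline(pipeline_config("demo_scene/manifest.csv", "demo_out"))
#> pipeline: 288 frames (0 gaps), 287 displacement pairs (0 missing), 1 day(s)

res$daily
#>         date  total_D n_pairs n_missing flagged
#> 1 2023-05-13 960.5797     287         0   FALSE

head(res$hourly[order(-res$hourly$total_D), ], 3)
#>          date hour   total_D n_pairs
#> 10 2023-05-13    9 196.21808      12
#> 22 2023-05-13   21 127.23548      12
#> 23 2023-05-13   22  85.59637      12

scene$daily$total_D   # latent ground truth
#> [1] 992.781
```

The herd covered 961 % of the image diagonal over the day (within 4 % of
the latent ground-truth 993 %), and its two busiest hours are 9 h and
21 h — the activity peaks the generator schedules. `res$grid` and
`res$regions` hold the occupancy density grid and the quadrant counts
(convention `A` = top-left … `D` = bottom-right, printed in every output
header); `make_report(res, "figs")` renders the heatmap, daily bars and
hourly profiles as PNG.

The same workflow is scriptable from a shell via `inst/cli/herdmotion`
(subcommands `simulate`, `track`, `distance`, `occupancy`, `eval`,
`bench-cluster`, `report`).

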