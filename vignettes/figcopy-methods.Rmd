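---
title: "Quantifying the figure-copying process from digital pen data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the figure-copying process from digital pen data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(figcopy)
library(dplyr)
```

## The problem

Copy-a-complex-figure tests probe visuoconstruction: the participant copies
an abstract line figure shown in the upper half of a tablet (the *perceptual
space*) into the empty lower half (the *working space*). A conventional
rater scores only the finished drawing. A digital pen additionally records
*how* the drawing was produced — every contact sample at 60 Hz — and that
process carries clinically interesting signal: fragmented, piecemeal stroke
production; hesitation before long framework lines; drawings creeping upward
toward the model (the *closing-in* phenomenon, seen in Alzheimer disease and
vascular dementia); and reduced overall shape fidelity.

figcopy implements the full analysis pipeline for an eight-component
simplified complex figure: ingestion and physical calibration of pen-event
logs, stroke segmentation, three metric families (stroke kinematics, spatial
arrangement, shape similarity), stroke-order rendering, a synthetic session
generator, and a nonparametric group-comparison harness.

## Coordinate conventions

The reference device is a 12-inch tablet in portrait orientation:
1440 × 2160 px over 162 mm × 258 mm, sampled at 60 Hz. Pixel pitch is
computed per axis (the panel need not have square pixels). All metrics are
expressed in centimetres in a frame centred on the **working-space centre**,
+x rightward, +y upward, so negative values read as leftward/downward
deviations from the centre of the drawing area. The display-normalized
vertical coordinate `y_norm` spans −1..1 with 0 at the display centre;
`y_norm > 0` is the perceptual half. A sample exactly on the midline is
assigned to the working space: the closing-in ratio counts only input
strictly above the boundary.

## Stroke segmentation and validation

A *stroke* is the pen trajectory from surface contact (`attach`) to lift-off
(`detach`); its samples are the attach and move events. Logs violating the
contact state machine (moves before any attach, unmatched attaches) are
refused, mirroring how malformed recordings must be excluded from analysis
rather than silently repaired. Single-sample taps are dropped with a
warning: a zero-length stroke has no defined geometry. If timestamps are
absent they are synthesized from the sample rate, with a warning. Samples
with equal timestamps keep their file order.

## Stroke metrics

- **Long/short classification.** Stroke lengths are projected per axis as
  the axis-aligned extent (max − min). Each projection is split into two
  classes by one-dimensional k-means (k-means++ initialisation, 10 restarts,
  plus an exact prefix-sum threshold scan; in one dimension the k = 2
  optimum is a contiguous split, so the returned partition is the global
  optimum and is deterministic). A stroke is *long* if either projection
  labels it long (the union rule); x-only and y-only are available for
  sensitivity analysis. Ties at the class boundary go to *short*. Extents
  were chosen over summed |Δ| because they match the global-vs-local reading
  of long framework strokes; the summary "mean stroke length" uses the
  Euclidean path length instead, and both are exposed.
- **First-5 ratio** — fraction of long strokes among the first five strokes,
  the task's beginning.
- **Longest-stroke speed** — path length over duration of the stroke
  maximizing path length (ties to the earliest), since the longest line is
  the one most likely used for the figure's skeleton.
- **Transition time** — for every adjacent short→long pair, the gap between
  the short stroke's pen-up and the long stroke's pen-down; the summary mean
  excludes gaps above 60 s (a fixed outlier rule), and sessions with no
  short→long adjacency report a missing value, never zero.
- **Elapsed time of 5 early long strokes** — from the session's first
  pen-down to the fifth long stroke's pen-up (about the time needed to lay
  down the rectangle and its cross-lines). Where the clock should start is
  genuinely open; we start at the session's first pen-down, which includes
  any early dithering on details — deliberately, since that dithering is
  part of the impairment signal.

Classification is per session, not pooled across participants: pooling would
make one participant's labels depend on who else was in the batch.

## Spatial arrangement

The **whole area** is the axis-aligned bounding box of all samples. The
**skeleton area** approximates the framework rectangle: the drawing extent is
divided into a 10 × 10 grid, per-cell sample counts are taken, and samples in
cells below one quarter of a reference count are discarded before taking
extremums. Two details were open and are configurable:

- *Reference count.* "Below 1 out of 4" is read relative to the maximum cell
  count (`skeleton_mode = "relative"`, default — invariant to sampling
  rate), with the expected uniform share (total/100) as the alternative.
- *Grid extent.* The grid covers the drawing's own bounding box by default
  (`skeleton_grid = "drawing"`). A grid clamped to the lower display half
  would discard exactly the input that closing-in drawings place above the
  midline, forcing the skeleton's top edge below the boundary by
  construction; laying the grid over the drawing itself lets upward-shifted
  framework input survive the frequency filter. `"working_space"` restores
  the clamped behaviour.

Grid cells are half-open `[lo, hi)` with the final cell closed, so boundary
samples are counted exactly once.

The **centre of mass** uses binary per-cell masses: the drawing is
rasterized (0.2 cm cells by default) and the centre is the unweighted mean
of occupied cell centres, which makes the measure robust to dwell time — a
pen resting in place adds samples but only one occupied cell. The
**ratio of input** is the fraction of contact samples strictly above the
display midline; zero for a well-placed copy, climbing toward the stimulus
under closing-in.

## Shape similarity

The drawing and the stimulus are rasterized at a common cell size into
binary occupancy grids (cells marked by exact grid traversal of the stroke
segments, not by point sampling, so slow and fast pens ink the same cells).
The drawing raster is scanned over the stimulus at every integer cell shift;
at each shift the coefficient is the Pearson correlation of the overlapped
binary values, with means and SDs computed **on the overlap only**. Shifts
with fewer than 2 overlapping cells, under 25% area overlap (configurable —
tiny overlaps produce spurious perfect matches), or zero variance on either
side are masked as undefined rather than scored zero. The maximum defined
coefficient is the similarity; its shift is the centre of the attention
field. Because participants draw at different sizes, a second coefficient is
computed after rescaling the drawing's coordinates along x so its whole-area
width matches the stimulus width. Rescaling happens in vector space before
rasterization — resampling binary pixels would alias. Whether the published
size correction rescaled x only or both axes is ambiguous; x-only is the
default and both-axes is available (`rescale = "both"`).

Raster extents snap outward to whole cell multiples in the absolute frame,
so two copies of the same shape translated by whole cells produce
phase-aligned grids and the translation is recovered exactly (coefficient 1
at the displacing shift). Sub-nanometre boundary slivers produced by
floating-point drift are dropped during traversal, keeping rasterization
stable under translation.

## Stimulus template and scoring

The canonical stimulus has four global components — the 8 × 6 cm rectangle,
horizontal and vertical cross-lines, and the diagonal cross — and four local
components — four horizontal arrows in the upper-left quadrant, a square
hanging below the rectangle, double concentric circles upper-right, and
three triangles lower-left. The published figure fixes this composition but
not absolute coordinates, so the geometry constants here are versioned
package constants; every downstream metric is well defined for any
self-consistent geometry, and absolute similarity coefficients are
meaningful only relative to this template. Each component is rated by a
human as 2 / 1 / 0.5 / 0 and `aggregate_component_scores()` encodes the
aggregation (sum, range 0–16); the visual judgement itself is out of scope.

## The synthetic generator

No patient recordings are distributable, so every statistic is exercised on
synthetic sessions. `generate_session()` traces the template components in a
chosen order (`global_first`, `interleaved`, `local_first`), splits
components into extra strokes (Poisson-distributed splits at
length-proportional positions), emits samples at 60 Hz along the path at a
set speed, and applies a global scale, placement offsets, and smooth
positional noise (white noise at ~6 Hz knots, linearly interpolated — pen
wobble distorts shape without inflating path length the way independent
per-sample noise would). Inter-stroke pauses are log-normal (positive and
right-skewed, as real pause distributions are), with an extra
`transition_extra_s` before global components to emulate hesitation before
framework lines.

Defaults emulate a control participant: ~23 strokes (one extra split per
component over the 15 template polylines), 6.3 cm/s, 1.4 ± 0.6 s pauses,
0.2 mm sensor-scale jitter, no offsets. The `eoad_profile()` and
`load_profile()` presets add interleaved ordering, stronger fragmentation,
slower speed, longer transition pauses, upward offsets large enough to cross
the midline (closing-in), and — for the late-onset preset — a leftward bias.
These dials reproduce the *direction* of every published group effect; they
are a phenomenological trajectory model, not a biophysical handwriting
model, and they do not emulate pressure, tremor spectra, corner overshoot,
or stroke-order idiosyncrasies of real patients. Passing tests therefore
demonstrate that the metrics detect the phenotypes they were designed for,
not that the generator's absolute values match any clinical population.

Cohorts derive per-session seeds by hashing (master seed, group, index), so
generation is reproducible and order-independent.

## Group statistics

The harness mirrors the published analysis: Kruskal–Wallis across groups
(tie-corrected, χ² approximation), pairwise two-tailed Mann–Whitney U tests
(exact when the pooled sample is ≤ 20 and untied, otherwise the normal
approximation with continuity and tie correction — the published work names
the test but not the p-value method), and the Dunn–Šidák adjustment
p = 1 − (1 − p₀)³ with the family size 3 of the three-group design as the
default even when fewer pairs are tested. Normality pre-tests are not
gatekeepers — the nonparametric path is always taken, matching the actual
analysis choice — and Pearson correlation (two-tailed t transform) is
provided for validity analyses against conventional scores. Sessions missing
a metric are excluded from that metric's tests only, with per-group n
reported; a metric available in fewer than two groups flags its row rather
than failing the table.

## Numerical choices

- Raster cell 0.2 cm: fine enough to separate neighbouring components,
  coarse enough that binary overlap correlation is informative.
- Half-open cells with a closed final edge everywhere a grid is built.
- Correlation ties broken toward the smallest shift magnitude, then
  row-major order.
- k-means ties at the class boundary go to short; the classifier seed
  defaults to 0 and is part of `analysis_config()`.
- Degenerate inputs error with typed conditions (`figcopy_*_error`) rather
  than returning sentinel numbers; `analyze_session()` converts per-family
  failures into `NA`s with reason codes so one failed metric never aborts a
  session record.

## Verification problem sizes

The test suite verifies the correlation surface against a brute-force
per-shift Pearson oracle on rasters up to 16 × 16 (tolerance 1e−12), the
stroke classifier against exhaustive threshold enumeration, the centre of
mass against the direct binary-mass sum, and the coefficient bound on 1,000
random raster pairs. Statistical behaviour is checked on synthetic cohorts
of 12 sessions per group: injected transition (+3 s) and vertical-offset
(+2 cm) effects must be detected in at least 90 of 100 replicates, and
identical-profile cohorts must show nominal type-I error over 500
replicates (Kruskal–Wallis within 0.05 ± 3 binomial SE, Šidák-adjusted
pairwise family-wise rate at most 0.05 + 2 SE). These sizes were chosen to
match the published group sizes (11–16 per group) while keeping the suite
fast.

## Known limitations

- The template geometry is package-defined; absolute similarity values are
  comparable only within a fixed template and cell size.
- The generator produces idealized trajectories; its parameters set effect
  *directions* and plausible magnitudes, not clinical calibration.
- Pressure and tilt are recorded by real pens but unused here, as in the
  analysis this package implements.
- Rotation- and shear-invariant matching are out of scope; only translation
  (and optional axis rescaling) is searched.

## A worked example

```{r example}
cohort <- generate_cohort(
  list(nc = nc_profile(), eoad = eoad_profile(), load = load_profile()),
  n_per_group = 4, master_seed = 42)
metrics <- analyze_cohort(cohort, analysis_config(rescale = "none"))
metrics |>
  group_by(group) |>
  summarise(strokes = mean(n_strokes),
            transition = mean(transition_time_s, na.rm = TRUE),
            ratio = mean(input_ratio), xcorr = mean(xcorr_max))

cmp <- compare_groups(metrics,
                      metrics = c("transition_time_s", "input_ratio",
                                  "whole_center_y_cm", "xcorr_max"))
tidy(cmp)
```

```{r plot, fig.height = 5}
autoplot(cohort$session[[1]])
```
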