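---
title: "Methods: astrocyte morphometry and behavioral emotionality in astromorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: astrocyte morphometry and behavioral emotionality in astromorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astromorph)
```

## What the package computes

`astromorph` quantifies the arborization of GFAP-stained astrocytes from
fluorescence z-stacks and relates it to a composite behavioral
emotionality score. The image chain reproduces the standard ImageJ
workflow step for step:

1. **Maximum-intensity projection** of the `(z, y, x)` stack to 2D.
2. **8-bit conversion** with a linear display window.
3. **Thresholding** of the GFAP signal to a binary mask.
4. **Despeckling** (3x3 median) of the mask.
5. **Skeletonization** (topology-preserving thinning) and measurement of
   branches, endpoints and total process length.
6. **Convex-hull perimeter (CHP) and area (CHA)** as cell-territory
   proxies.
7. **Sholl analysis**: intersections of the skeleton with concentric
   rings at 5 um increments (13 rings by default), their total, and sums
   over a distal radius window.

On the behavioral side, four assays — sucrose preference (SPT, %),
social-interaction ratio (SIT, time with target / time without; < 1
flags reduced sociability), elevated-plus-maze open-arm time (EPMT, s)
and forced-swim immobility over the last 4 of 6 minutes (FST, s) — are
standardized per animal against the control group,

$$Z = d \cdot \frac{X - \mu_{ctl}}{\sigma_{ctl}},$$

with the sign $d$ fixed per test (SPT, SIT, EPMT: $-1$; FST: $+1$) so
that a higher positive $Z$ always means poorer performance, and averaged
with equal weights into the composite
$[Z_{SPT} + Z_{SIT} + Z_{EPMT} + Z_{FST}]/4$. Group statistics use
one-/two-way fixed-effects ANOVA with Tukey HSD comparisons
(`stats::aov` + `stats::TukeyHSD`, i.e. the studentized-range
distribution), and morphology-behavior association uses Pearson
correlation with Spearman reported alongside (the two conventions both
appear in practice; we emit both and default to Pearson).

## The synthetic-data generator

No raw images or per-animal measurements are publicly deposited for this
kind of study, so the package ships a generator that produces the two
inputs with known ground truth; all tests and the acceptance analysis
run end to end on it.

**Cells.** An `astrocyte_model()` is a soma disk plus a tree of straight
process segments grown outward from the soma centre. Every potential
node of the binary growth tree receives its random draws (segment
length, bifurcation decision, angular deviation) in a fixed enumeration,
which gives two useful monotonicity properties at fixed seed: shrinking
`deramification_factor` (a multiplier on the bifurcation probability)
only prunes branches, and `atrophy_factor` rescales segment lengths in
place. Sibling branches split to opposite sides by at least half the
`angle_spread`, and each primary's subtree is confined to its own
angular sector — an idealization of the territorial, largely
non-overlapping organization of astrocyte processes that also guarantees
subtrees of different primaries never cross, keeping the raster faithful
to the tree.

Ground truth is defined **on the continuous centerline tree, never on
the raster**: total length is the exact sum of segment lengths; branch
and endpoint counts come from the chain decomposition of the tree
(pass-through nodes merged); Sholl counts are exact segment-circle
intersections (quadratic roots, half-open at the proximal end so shared
vertices count once); CHP/CHA are the hull of the centerline silhouette.
Rasterization stamps disks of diameter `process_width` (default 1.5 um)
along each segment, plus the soma disk.

Default model values describe a control cortical astrocyte: soma radius
5 um, 6 primary processes, bifurcation probability 0.55 per node to
depth 4, segment lengths 12 +/- 3 um, angular spread 35 degrees. These
give cells extending ~50-60 um from the soma with total skeleton length
of a few hundred um and Sholl profiles peaking at intermediate radii —
the qualitative regime of GFAP morphometry in cortex and hippocampus.
The simulated disease state (PID, post-ischemic depression) uses
atrophy 0.8 and deramification 0.7; the treatment arm (EA,
electroacupuncture) 0.92 and 0.88, i.e. a partial rescue. Imaging noise
adds salt-and-pepper flips, optional Poisson shot noise and Gaussian
read noise to the 2D intensity image.

**Cohorts.** `simulate_cohort()` draws each behavioral metric per animal
from a truncated normal with the printed group means and SDs of the
sham/PID/EA arms (SPT clipped to [0, 100], times to their session
windows, the SI ratio to non-negative values). Only means and SDs are
reported for such cohorts, so independence across tests is the minimal
defensible assumption; a Gaussian-copula correlation parameter `rho` is
exposed for sensitivity analyses but defaults to 0.

**What the generator does not emulate:** staining chemistry and the
GFAP-negative fine leaflets (real GFAP masks undercover the true
arbor), 3D point-spread functions, overlapping neighbour cells (the
cell-selection criteria exclude them), within-animal correlation
structure, and any physiological coupling between morphology and
behavior beyond the group labels. Passing tests therefore demonstrate
that the *measurement chain* is correct and that *group-level effects
injected at known size* are recovered — not that real tissue would
yield these exact numbers.

## Numerical choices

* **Threshold.** The interactive brightness/contrast plus "threshold
  tool" step of the manual workflow is operator-dependent; for
  reproducibility the default is Otsu's method on the 256-bin 8-bit
  histogram (foreground = values at or above the level, ImageJ
  convention), with a fixed-level override. The level is always recorded
  in the result and the run log. Otsu on a constant image is an error,
  not a guess.
* **Despeckle.** 3x3 median with edge replication at the borders,
  applied after thresholding (a pre-threshold smoothing flag exists,
  default off). Note the median clips free-standing convex corners by
  construction; a pixel whose 3x3 neighbourhood is constant is never
  changed.
* **Skeletonization** is Zhang-Suen thinning plus a
  connectivity-preserving cleanup pass that removes residual 2x2 blocks,
  implemented in C++. Components and holes are preserved; endpoints are
  retained.
* **Pixel graph.** Skeleton pixels are 8-connected, but a diagonal link
  is discounted when its two pixels share an orthogonal foreground
  neighbour; degrees in this reduced graph classify pixels as endpoints
  (1), slabs (2) or junctions (>= 3). The raw 8-neighbour count would
  misclassify staircase bends as junctions. Diagonal steps contribute
  sqrt(2) pixel lengths; `calibrate_lengths = TRUE` switches to the
  Vossepoel-Smeulders weights (0.948, 1.340), which remove the up-to-8%
  orientation-dependent overestimate of digital path length.
* **Branch decomposition** counts every maximal path between nodes, like
  the ImageJ Skeleton plugin — including the short junction-junction
  bridges that thinning necessarily creates where several thick
  processes meet (this is why published branch counts exceed endpoint
  counts so strongly). `fuse_junctions_um` optionally collapses junction
  clusters connected by bridges up to that length (we use twice the
  process width when validating against continuous ground truth); spur
  pruning exists but is off by default because the original workflow
  does not prune.
* **Sholl counting.** A crossing is a skeleton step from inside a ring
  to outside; steps sharing pixels are grouped into runs on each side of
  the ring and the count is the larger of the two sides. This counts a
  bifurcation sitting exactly on a ring once per emerging child, ignores
  tangential grazes, and is robust to diagonal steps that jump the
  one-pixel annulus. Counting runs on the skeleton rather than the
  silhouette avoids merging adjacent processes through mask thickness.
* **Soma centre** is the maximum of the Euclidean distance transform
  (largest inscribed disk), ties broken to the lowest `(y, x)`; a manual
  override is accepted everywhere.
* **Degenerate inputs.** Hulls of fewer than three non-collinear pixels
  fall back to CHP = twice the maximum pairwise distance and CHA = 0
  with a warning; empty masks, constant images under Otsu, zero total
  fluid intake, a zero-variance correlation input and incomplete two-way
  layouts are errors, not silent values.

### Validation regimes

Correctness against the continuous ground truth is asserted in regimes
where the raster is geometrically faithful, because at finite process
width the raster genuinely merges structures: within
$(w/2)/\sin(\theta/2)$ of a bifurcation the two children are one thick
stroke, and no pixel-based counter can see two crossings there. The
skeleton-metric comparison therefore uses sparse trees (5 primaries,
bifurcation probability 0.4, depth 3) at 0.2 um/px with junction fusing
at twice the process width and calibrated lengths, and meets 1 branch /
1 endpoint / 5% length. The ring-by-ring Sholl comparison uses cells
whose nodes (~8.6 um) and tips (~16 um) sit between the 5-um rings, and
meets +/- 1 per ring. Denser default cells are validated against the
independent pixel-graph oracle (exact agreement) and through the
recovery of injected group effects.

## Problem sizes and determinism

The test suite and the acceptance analysis run the full chain at
0.5 um/px for cohort-scale simulations (3 groups x 10 animals x 5
cells) and 0.2 um/px for geometry validation; the type-I calibration
uses 2000 null ANOVA replicates and the effect-recovery analysis 100
simulated experiments in the test suite (60 in the acceptance script). Every random quantity flows from a single seed
(cell seeds and the cohort seed are derived from it), and identical
configs produce byte-identical CSV outputs.

## Open design points, resolved

* The distal Sholl window is reported inconsistently in this literature
  (text windows 35-45 um for prefrontal cortex and 40-55 um for CA1
  versus figure captions extending to 65 um); both are available as
  presets, the text windows are the defaults, and the window is a
  config key recorded in the run log.
* The correlation method is named differently in methods sections and
  figure legends (Spearman vs Pearson); both are computed, Pearson is
  the default, and the report carries both rows.
* Morphometric group statistics run at the cell level (matching how
  such data are usually plotted), correlations with behavior at the
  animal level after per-animal averaging of the 5 cells; both tables
  are emitted.
* Printed per-test Z group means for EPMT and FST in the source
  literature are not reproducible from the printed raw means and SDs
  under any sign convention; only internally consistent printed values
  are used as worked examples.

## Known limitations

2D only (projection first, as in the original workflow); no recovery of
GFAP-negative fine processes; branch counts are convention-dependent at
junction clusters (documented above); digital length is
orientation-biased unless calibrated weights are enabled; the cohort
simulator cannot express within-animal correlation between morphology
and behavior, so correlation recovery tests operate through group
structure only.
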