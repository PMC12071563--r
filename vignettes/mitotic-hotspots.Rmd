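---
title: "Mitotic hotspots and reader agreement: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mitotic hotspots and reader agreement: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitohotspot)
```

## The problem

In invasive breast carcinoma of no special type, the mitotic score (MS) — one
of the three components of the Elston–Ellis (Nottingham) grade — is derived
from a mitotic count (MC) performed in the *mitotic hotspot*, the tumor region
with the highest density of dividing cells. Finding that region on a
gigapixel whole-slide image (WSI) is the dominant source of inter-observer
variability: two pathologists who count carefully but in different places get
different counts.

AI pipelines address this by detecting candidate mitotic figures across the
whole slide and proposing counting regions. `mitohotspot` implements the
post-detection half of such a pipeline — everything downstream of "a list of
detected mitosis positions with confidences and a tumor outline" — plus the
statistical machinery needed to evaluate such a tool in a two-reader
crossover study. Pixel-level detection (the deep-learning stages) is out of
scope by design: detections are the ingestion boundary.

## Coordinate conventions

All geometry lives in microns in the level-0 pixel frame: origin top-left,
x rightward, y downward. Pixel inputs are converted on ingest via `mpp`
(microns per pixel, typically around 0.25 for a 40x-equivalent scan). Working
in microns rather than pixels matters because the counting zones are defined
by physical area (mm²) while magnifications and scanner resolutions vary.

## The hotspot score

Tumor regions are tiled into non-overlapping square patches (default
256 px at 0.5 µm/px, i.e. a 128 µm stride — the usual 20x tiling geometry).
Patch centers form the candidate set `P`. For each candidate `p` and the
confidence-filtered detection set `M`:

* `n1` = number of detections within the **core** circle centered on `p`
  (area 1 mm², radius ≈ 564.2 µm),
* `n2` = number within the concentric **context** circle (area 2 mm²,
  radius ≈ 797.9 µm),

and the hotspot score is

    h_p = n1 + eps * (n2 - n1),   eps in [0, 1].

The score interpolates between "count only the immediate core" (`eps = 0`)
and "count the whole 2 mm² neighborhood" (`eps = 1`); intermediate values
prefer dense cores embedded in active surroundings, which is how pathologists
describe biologically convincing hotspots. The weight is genuinely open — no
canonical production value exists — so the package defaults to the midpoint
`eps = 0.5` and surfaces the value in every output.

Numerical conventions, all deliberate:

* distance comparisons are **inclusive** (`dist <= r`), so a mitosis exactly
  on the circle boundary counts;
* confidence filtering is **strict** (`confidence > threshold`, default 0.5):
  a prediction must *exceed* the threshold to be retained;
* counting uses exact Euclidean distance — no spatial-index approximation;
* all grid centers are scored, including those with zero counts (scoring only
  mitosis-bearing patches is an equivalent optimization for every candidate
  with `n1 > 0`, and cannot change the ranking at the top).

### Selection of displayed hotspots

The ranked candidate list is reduced to at most `top_k` (default 5)
non-overlapping display zones by greedy non-maximum suppression: walk the
list in rank order and accept a candidate iff its 2 mm² display circle
intersects no previously accepted circle (tangency counts as intersecting,
mirroring the inclusive counting convention). Ties in score are broken by
core count (descending), then x, then y (ascending), making selection fully
deterministic. A candidate whose context circle contains no mitosis is never
reported as a hotspot, so a slide with no retained detections yields an empty
result rather than an arbitrary zone.

Two choices here were genuinely open and are package decisions: the grid is
phase-aligned to the region bounding box (no tiling phase is canonical, and
this one is reproducible), and overlap suppression uses the display circles
themselves (the minimal deterministic rule consistent with viewers showing
disjoint circles).

## Mitotic count and score

The counting zone for the MS is the 2 mm² context circle of the chosen
hotspot — the same region a viewer highlights for review. The count maps to
the three-grade score through configurable cut-offs `(t1, t2)`:
score 1 for `count <= t1`, 2 for `t1 < count <= t2`, 3 above `t2`. The
defaults `(7, 14)` per 2 mm² follow the convention of the 2 mm²
hotspot-counting literature (≤7 / 8–14 / ≥15); because published studies
rarely print their exact table, the thresholds are configuration, echoed in
every report, and any site table can be substituted.

## Reader-agreement statistics

The evaluation module implements the statistics a crossover reader study
reports, each from first principles:

* **Accuracy** against the expert consensus: the trace proportion of the 3×3
  confusion matrix (rows = investigator, columns = consensus; this
  orientation is fixed in all I/O).
* **Linear weighted Cohen's kappa**: agreement weights
  `w_ij = 1 - |i - j| / (k - 1)`, chance agreement from the product of the
  observed marginals. The default 95% CI uses the large-sample
  Fleiss–Cohen–Everitt variance (not assuming kappa = 0); a percentile
  bootstrap over rater pairs is available because published CI methods are
  rarely stated. A rater who used a single category for every slide makes
  kappa undefined; the package raises an error rather than reporting 0.
* **ICC**: the default form is ICC(2,1) — two-way random effects, absolute
  agreement, single rater — computed from the mean-squares decomposition,
  with the F-based McGraw–Wong interval (Satterthwaite degrees of freedom).
  Reader studies citing Koo & Li rarely name the exact form, so the form is
  a parameter (`ICC(3,1)` and `ICC(1,1)` are available) and alternates can
  be compared against printed values.
* **Zone intersection rate**: the fraction of slides on which two circular
  counting zones intersect (inclusive tangency) — the spatial-agreement
  metric for hotspot selection. The AI-vs-reader variant treats all of the
  AI's selected zones as one side and counts intersection with any of them.
  A slide explicitly flagged "no zone recorded" counts as non-intersecting;
  a slide with silently missing coordinates is excluded and reported in `n`.
* **Subgroup reports** re-run the whole block per stratum (consensus score
  1/2/3; biopsy vs surgical) and per condition. Sparse strata where a
  statistic's preconditions fail (degenerate marginals, zero variance)
  report `NA` for that cell with the stratum size intact — matching how
  published subgroup tables leave undefined kappas blank.

## What the synthetic generators emulate

The slide generator produces the mitotic density landscape the hotspot score
assumes: a homogeneous Poisson background of intensity `lambda_bg` per mm²
over the tumor polygon, plus planted isotropic Gaussian clusters (truncated
to the polygon by redrawing, not clipping). Detection confidences are i.i.d.
Beta draws. The defaults are one fixed set of study conditions: a 5 × 5 mm
tumor at 0.24 µm/px, background 2 mitoses/mm², and one planted cluster of
200 mitoses with σ = 200 µm — dense enough that hotspot recovery is
well-posed, sparse enough that it is not trivial — with confidences
Beta(8, 2) (mean 0.8, so most true detections survive the 0.5 threshold).

The reader simulator draws each reader's score independently from a
row-stochastic misgrading kernel `K[t, s] = P(reported s | true t)` whose
off-diagonal mass favors adjacent grades, and places counting zones at the
true hotspot center plus condition-specific Gaussian jitter. Its defaults
encode the operating characteristics reported for AI-assisted mitotic
scoring: kernel diagonals 0.63 (unassisted) and 0.77 (assisted) match
reported accuracy ranges, and the true-score prevalence (29, 12, 9)/50
matches a typical 50-slide cohort. The jitter spreads come from a closed
form: if both readers' zone centers are the true center plus independent
N(0, σ²I₂) noise, the distance between them satisfies
`P(d <= c) = 1 - exp(-c² / (4σ²))`, so a target intersection rate `p` for
2 mm² zones (`c = 2r ≈ 1595.8 µm`) gives `σ = c / (2 sqrt(-log(1 - p)))`:
44% → σ ≈ 1050 µm (unassisted), 60% → σ ≈ 830 µm (assisted).

What the generators do **not** emulate — and hence what passing tests do not
establish about real data: false-positive and missed detections (confidences
are attached to true mitoses only), spatially varying background intensity,
correlation between the two readers beyond the shared truth, reader drift
between crossover sessions, and any pixel-level appearance effects (staining,
artifacts, z-plane blur). Results on synthetic slides bound the geometry and
statistics of the pipeline, not detector quality.

## Numerical notes and degenerate inputs

* Circle areas and radii are mutual inverses to 1e-9 relative tolerance;
  radius counting compares squared distances to avoid a needless `sqrt`.
* An empty region list yields an empty grid; a degenerate (zero-area)
  polygon contributes no centers; an empty detection list yields an empty
  hotspot result. None of these error.
* Self-intersecting region rings are rejected at read time (exact
  orientation-test segment intersection, adjacent edges excluded); ring
  orientation is normalized on ingest, and point-in-polygon uses the even-odd
  rule so holes exclude and disjoint polygons union.
* File round trips write coordinates at full double precision; write→read
  reproduces positions to better than 1e-9 µm.
* All simulations are driven by a single seed surfaced in configs, the CLI
  and outputs; identical seed and config give byte-identical results.

## Problem sizes used in the shipped tests

The test suite exercises: oracle equivalence of the scoring engine on 100
random slides (grids up to 40 × 40, up to 2000 mitoses) against an
independent all-pairs distance-matrix implementation; planted-cluster
recovery over 100 seeded slides at the default study conditions (top-1
hotspot within 600 µm of the planted center on at least 95); ICC parameter
recovery over 200 simulated two-rater studies of 50 subjects at true
intraclass correlations 0.3/0.6/0.9 (mean bias ≤ 0.03); and simulator
consistency at 10⁴ slides against the closed-form expected-confusion-matrix
kappa (±0.03). These sizes make every statistical check sharp while keeping
the default suite fast.

## Known limitations

* Scores assume a three-grade ordinal scale; the agreement machinery is not
  generalized to other category counts except where noted (kappa accepts any
  square table).
* The greedy suppression rule is one reasonable convention; a production
  system with a different overlap rule will select different lower-ranked
  hotspots (the top hotspot is unaffected).
* ICC on 3-level ordinal scores treats grades as equally spaced numbers —
  standard practice in reader studies, but an approximation.
* The package does not read WSI rasters or render overlays; GeoJSON circles
  are exported for viewers instead.
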