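---
title: "Characterizing trajectories of forest change from annual land-cover grids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing trajectories of forest change from annual land-cover grids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foresttraj)
```

## The analysis in one paragraph

Annual categorical land-cover maps record, for every pixel, which of a small
set of aggregated categories (cropland, forest, grassland, wetland,
settlement, shrubland, bare, water) occupies it in a given year.
`foresttraj` analyses such series at the level of fixed-size grid cells
(by default 18 × 18 = 324 pixels, the footprint of a 3 arc-minute cell for a
300 m product). For each cell it identifies the *dominant land-cover
transition* between the first and last year, the *interval* over which the
cell's forest pixel count changed, the *amount* (net pixels changed, as a
proportion of the cell) and the *relative rate* of that change (the
reciprocal of the interval duration), whether the trajectory was *persistent*
(one-directional) or not, and the amount and spatial arrangement — the
*Landscape Configuration Index* (LCI) — of the non-forest "transition"
land cover at the moment change began. Cells are then compared across
transition land covers (group summaries and Cliff's delta) and the initial
conditions are related to the outcomes with penalized smooth regressions.
A seeded synthetic landscape generator reproduces every structural property
the analysis relies on, so the full pipeline runs and is tested without any
external data.

## Dominant transitions and their certainty

`transition_matrix(first, last)` counts ordered (from, to) class changes
over *changed pixels only*. Identity pairs are excluded on purpose: a
"transition" denotes change, and the certainty of the dominant transition —
`count / total_changed` — is only interpretable as "share of all pixel
transitions" when the denominator counts transitions. `dominant_transition()`
returns the argmax pair; when forest is on either side, the other class is
the cell's transition land cover. Ties are broken deterministically
(forest-involving pairs first, then the fixed category order
cropland < forest < grassland < wetland < settlement < shrubland < bare <
water on the origin class, then the destination class) and flagged, since a
tied dominant transition is genuinely ambiguous.

## Unlike-adjacency and the Landscape Configuration Index

The spatial arrangement of the transition land cover is quantified by the
*unlike-adjacency* (UA): the number of Queen-adjacent pixel pairs with one
member in the transition class and one in the complementary landscape, each
mixed pair counted once. Neighbourhoods are truncated at the cell boundary —
corner, edge and core pixels have 3, 5 and 8 neighbours — with no
wraparound. UA counts neighbouring *pixels*, not distinct neighbouring
class *types*: a fragmented arrangement of 189 pixels can have a UA of
several hundred, which a type-count reading could never produce.

UA grows with the amount of the focal class, so raw values are not
comparable across cells with different amounts. For every possible pixel
count `k` the package therefore computes the minimum and maximum UA
attainable on the grid, and normalizes:

    LCI = (UA_obs − UA_min) / (UA_max − UA_min)

yielding 0 for maximally compact and 1 for maximally fragmented
arrangements. When `k` is 0 or fills the cell there is no arrangement to
measure (`UA_min = UA_max = 0`); the LCI is then undefined and such cells
are excluded from configuration analyses rather than assigned a value.

### How the bounds are obtained, and what is (not) claimed

Grids with at most 20 pixels are solved *exactly* by enumerating all
C(n, k) placements. For larger grids the bounds are constructive:

* **Minimum.** Greedy sequential placement (each step adds the pixel whose
  toggle increases UA least, ties anchored at the north-west corner) raced
  against a corner-anchored quasi-square block fill; the better arrangement
  is then improved by steepest single-swap refinement. Boundary truncation
  makes corner-hugging shapes strictly better than free-floating blocks —
  the refinement routinely discovers non-obvious staircase shapes that beat
  the naive square block.
* **Maximum.** Greedy dispersal raced against spaced-lattice and
  alternating-stripe fills, plus the same swap refinement.

Because UA is invariant under complementing the mask, bounds are symmetric
in `k ↔ n − k`; only the sparse half is constructed and the dense half
reuses the complemented arrangements. The full table for a grid size is
built once per session (about a tenth of a second for 18 × 18), cached, and
can be persisted with `write_ua_bounds_table()`.

Exact optimality of the constructive bounds on large grids is *not*
claimed. They are certified empirically, from two directions: every
constructed extremal arrangement attains its tabulated bound exactly
(attainability), and tens of thousands of random arrangements per pixel
count never fall outside the bounds (dominance). On small grids the
constructive minima coincide with exhaustive enumeration everywhere; the
constructive maxima can be conservative by one shared-edge count very close
to half-filling, where optimal patterns stop being nested.

`arrange_binary()` inverts the index: given `k` and a target LCI it
hill-climbs single-pixel swaps toward the corresponding UA, accepting the
arrangement once the realized LCI is within ±0.05 of the target (targets of
exactly 0 or 1 return the constructed extremal arrangements; because UA is
integer-valued, some targets on very small grids are only approximately
achievable, and the closest arrangement found is returned).

## Interval, rate, amount, persistence

The interval of forest change runs from the last year before the first
change in the cell's forest count to the first year after which the count
never changes again. Duration is the number of inter-annual steps spanned
(`E − S`), so with 29 annual maps it ranges from 1 (abrupt) to 28, and the
relative rate `1/duration` ranges from 1 down to 1/28 per year. The amount
of change is the difference of forest counts between the interval endpoints
as a proportion of the cell.

Persistence is read *non-strictly*: a trajectory is persistent loss when no
year inside the interval gains forest (and at least one loses), so stepped
decline with interior plateau years is still persistent; only trajectories
showing both a loss and a gain are non-persistent. Initial conditions
(amount and LCI of the transition land cover) are taken from the map at the
interval start year, before any change has occurred.

## Exclusion filters

Four filters select cells suitable for analysis, each recorded with its
reason so the exclusion accounting is order-independent and sums exactly:

1. **incomplete** — cells with fewer than the full pixel complement in any
   year (edge remainders of the tessellation, nodata). This is the
   conservative reading: one missing pixel-year disqualifies the cell.
2. **non_forest_dominant** — the dominant transition does not involve
   forest (including no-change cells); the cohort of interest is cells
   where forest formed part of the dominant transition.
3. **min_change** — net forest change between the first and last year below
   the threshold `floor(0.05 × cell_size) + 1`, i.e. 17 pixels on a
   324-pixel cell: 16/324 = 4.9% is within plausible misclassification
   noise, 17/324 = 5.2% is the first "substantial" count. The threshold
   scales with cell size through the same 5% rule. First-versus-last counts
   (not max-versus-min) define the net change.
4. **degenerate_lci** — the transition land cover is absent from, or fills,
   the cell at the interval start, so no LCI exists.
5. **non_persistent** — both loss and gain observed; net amount and a
   single rate cannot summarize such dynamics.

## Group comparisons

`summarize_groups()` reports n, quartiles (linear-interpolation, R's
default type-7 definition), mean, SD, and `mean_diff`, the divergence of
each group's mean from the pooled mean of all groups. `cliffs_delta()` is
the probability-based effect size (P(x > y) − P(x < y)); ties contribute
zero. The implementation is counting-based (sort + rank), so group sizes in
the hundreds of thousands are no obstacle, and is verified in the tests
against explicit double-loop enumeration. Confidence intervals use Cliff's
consistent asymptotic variance with the standard asymmetric transformation,
which keeps the interval inside [−1, 1]; at complete separation
(delta = ±1) the variance estimate collapses and the interval degenerates
toward the point estimate — reported as such rather than papered over.

## Smooth-effect models

The mediating influence of initial conditions on amount and rate of change
is modelled as `y ~ s(x)` with cubic regression splines capped at **4 basis
functions**, Gaussian errors, identity link, and smoothness chosen by REML
(`mgcv`). The deliberately small cap keeps fitted effects interpretable as
broad trends; an effective degrees of freedom near 1 flags an essentially
linear effect. The proportion of null deviance explained equals
1 − RSS/TSS under this model. A constant response carries no estimable
scale for REML and is returned directly as the exact flat fit (edf 0,
deviance explained 0).

`summarize_fit()` evaluates the curve on 200 evenly spaced points spanning
the observed predictor range (the grid size is a documented, configurable
choice) and reports the predictor values at the curve's maximum and
minimum, the mean of the signed finite-difference slopes (average effect of
a unit predictor change) and the mean absolute slope (sensitivity
regardless of direction). Since LCI values above 0.6 occur almost
exclusively at extreme transition-amounts, the pipeline reports the share
of each model's data above that cap (`prop_lci_gt_cap`) as an
interpretation flag; the fit itself is never constrained.

One calibration subtlety is worth recording: with only 4 basis functions
the model family can only represent effects that are *broad* relative to
the predictor range. The calibration experiments therefore generate humps
of width ≈0.3 of the range (with an interior, off-centre peak). A much
narrower bump is outside the family's resolution and its peak location is
recovered with a systematic offset that no sample size removes — that is
misspecification of the truth relative to the model class, not a defect of
the fitting, and matches how the capped basis is meant to be used: for
broad dose-response-like trends, not feature localization.

## The synthetic landscape generator

`cell_spec()` + `generate_lc_series()` produce one cell's annual grids:
year 1 holds exactly the requested transition-class amount, arranged at a
target LCI if asked, optionally with static background classes; all other
pixels are forest. The forest count then follows the trajectory
specification *exactly* — direction (loss, gain, non-persistent, none),
total pixels changed, start year, duration, and shape (gradual: spread
evenly, at least one pixel every year; abrupt: a single step; plateaued:
changes at the interval ends with quiet years inside; mixed: losses then
gains). Conversions happen at randomly chosen forest/transition interface
pixels when any exist, else at random pixels, which keeps arrangements
contiguous-looking as they grow. Feasibility (never converting more forest
or transition pixels than exist) is validated at spec construction.
`generate_mosaic()` assembles many cells with per-cell seeds derived from a
master seed; everything is byte-reproducible.

`apply_misclassification()` perturbs a series with symmetric, *independent*
per-pixel-year label noise: each pixel-year is relabelled with probability
`rate` to a uniformly drawn different category. This is a deliberately
simple one-parameter stand-in for classification uncertainty. Its
independence is also its limitation, and an instructive one: real
classification error is strongly correlated in time (a confused pixel tends
to stay confused), whereas independent noise makes every cell's forest
count jitter every year. Interval detection then saturates (durations
collapse to the series length) and persistence filtering rejects
essentially all cells — so rate-based contrasts do *not* survive this noise
model, and the test suite measures exactly that. Amount-based quantities,
which depend only on interval endpoints, are far more robust. Conclusions
about real products, where errors are temporally coherent, should not be
drawn from the independent-noise experiment alone.

### What the generator does and does not emulate

It emulates: category-coded grids, controllable initial composition and
configuration, exact trajectory shapes, interface-preferring growth,
label noise. It does not emulate: real geography or climate forcing,
spatially correlated or temporally coherent classification error,
multi-class churn beyond the focal pair (unless background classes are
given), or sub-annual dynamics. Passing tests therefore demonstrate
correctness of the measurement pipeline under controlled conditions, not
accuracy of any particular satellite product.

## Numerical and design choices, in one place

* Duration = steps spanned (`E − S`), reproducing the 1/30-versus-1 rate
  contrast for 30 pixels lost over 30 years versus in one year.
* Certainty denominator = changed pixels only.
* Tie-breaks: fixed category order, forest-involving first, tie flagged.
* Min-change filter: first-vs-last counts; threshold
  `floor(0.05 × cell_size) + 1` (17 at 324 pixels).
* Quantiles: type 7 (linear interpolation).
* Cliff's delta CI: consistent asymptotic variance, asymmetric transform,
  degenerate guard at ±1.
* Smooths: cubic regression splines, `k = 4`, REML, identity link; summary
  grid 200 points; constant response short-circuited to the flat fit.
* UA bounds: exhaustive at ≤ 20 pixels, constructive + swap-refined above,
  complement symmetry, certified by attainability and randomized dominance.
* Pixel areas: spherical Earth (R = 6371 km) haversine edge lengths divided
  by row/column counts — a reporting convenience, not an analysis input.
* Problem sizes used by the test suite (chosen to exercise the claims while
  staying desk-scale): 1,000 random grids for the UA oracle, 10,000 random
  arrangements per sampled pixel count for bounds dominance, 200 random
  cells for exact parameter recovery, 50 mosaic replicates for the noise
  experiment, 100 simulations per effect-model calibration claim.

## A worked run

```{r, eval = FALSE}
specs <- c(random_cell_specs(20, seed = 1, direction = "loss"),
           random_cell_specs(20, seed = 2, direction = "gain"))
res <- run_pipeline(specs = specs, seed = 3, out_dir = "results")
res
head(res$summaries)
```

The run writes `records.csv`, `retained.csv`, `excluded.csv`,
`group_summaries.csv`, `cliffs_delta.csv`, `smooth_effects.csv`,
`mosaic_meta.csv`, the UA bounds table, and a `manifest.json` with the
seed, thresholds, a configuration hash and the per-reason exclusion funnel.
Re-running with the same configuration reproduces every file byte for byte.

## Known limitations

* Constructive UA bounds on large grids are certified, not proven, optimal.
* The LCI is defined for the binary transition-versus-complement landscape
  only; multi-class configuration metrics are out of scope.
* The uncertainty stand-in is independent noise (see above); temporally
  coherent error models are not implemented.
* Dominant transitions use the first and last maps only; year-by-year
  transition chains are out of scope.
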