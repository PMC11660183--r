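---
title: "Methods: classifying the food environment from storefront names"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying the food environment from storefront names}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Health departments repurpose administrative food data — retail
directories, licensing and inspection extracts — to study the food
environment, but those sources are rarely categorized in a way that
supports analysis. The store *name* is the one feature common to all of
them, and names signal what a store is: "La Vina Deli Grocery" reads as
a corner store with a deli counter, "Butcher Bar" as a restaurant with a
bar. `foodenv` operationalizes that intuition as a tested pipeline: ten
non-exclusive food retail classes, a taxonomy converter for surveyor
tags, leakage-controlled dataset construction, a multi-label name
classifier, banded evaluation, hexbin churn surfaces, and tag-agreement
auditing of secondary datasets.

## The ten classes and why they overlap

The class system (`food_class_table()`) divides food retail roughly into
goods (Specialty, Convenience, Discount, Grocery, Alcohol Store) and
services (Fast Food, Restaurant, Alcohol Bar, Juice/Coffee,
Sweets/Desserts). Membership is deliberately **not** exclusive: a New
York bodega is simultaneously a convenience store and a fast-food deli
counter, so labels are modeled as independent per-class indicators and
every subset of the ten classes — including the empty set — is a valid
label. All label containers in the package are logical matrices with a
fixed, documented column order.

## Taxonomy conversion

Administrative directories describe stores with their own taxonomy of
meta-categories, tags and flags. The converter (`load_taxonomy()`,
`map_records()`) uses a small rule language — required meta-categories,
any-of tag sets, required flags, and a `disqualify_if_only` set — whose
semantics were chosen to be the *minimal* grammar expressing the
documented conversions:

* records outside the `Food`/`Essentials`/`Drink` meta-categories get no
  labels;
* `supermarket` or `grocery store` tags yield Grocery, but a record
  tagged *only* `convenience store` never does (pharmacies and gas
  stations carry that tag) — `disqualify_if_only` fails a rule when the
  record's whole tag set, including the empty set, lies inside the
  disqualifying list;
* restaurant-subcategory tags (pizzeria, diner, deli, ...) yield Fast
  Food and/or Restaurant solely through the surveyor `quick-bites` /
  `dine-in` flags; both flags yield both labels.

Because rules only union their emitted classes, the mapping is
order-independent, and adding a tag can never remove a label (a rule
disabled by `disqualify_if_only` was already disabled for any subset).
Tag matching is case-insensitive after trimming, since administrative
casing is unreliable. Tag lists for the six classes whose source
vocabulary is not publicly documented are plausible defaults intended
for synthetic data; the YAML config is user-extensible and round-trips
through `save_taxonomy()`.

## Dataset construction and leakage control

Names are normalized (NFC, case-folded, whitespace-collapsed;
punctuation kept because it is part of the name). Deduplication is exact
on the normalized string: one example per name, labeled with the **modal
whole multi-label combination** across that name's records — not
per-class marginals, because tie-breaking reasons about combinations.
Frequency ties go to the combination on the most recently surveyed
record, then to record-id order for determinism.

Names appearing at more than 10 distinct locations are chains: they are
set aside before the split and appended to the training set so the model
memorizes them, and they never appear in validation or test — held-out
scores are therefore a lower bound on inference performance. The
remainder is shuffled with a caller-supplied seed and partitioned
50/25/25; integer remainders go to train, preserving the larger share.
Chain detection uses location counts computed after the meta-category
restriction (configurable in principle; the directory generator only
emits food records, so the distinction is moot for synthetic data).

## The classifier

The pipeline is backend-agnostic: any scorer that maps a non-empty
string to ten independent raw scores in $[0,1]$ satisfies the contract,
and a `transformer` backend identifier is reserved for fine-tuned
encoder models on uncased text (Adam, learning rate $10^{-6}$,
$\beta_1 = 0.9$, $\beta_2 = 0.999$), which require external weights and
GPU resources. The shipped **reference backend** is a one-vs-rest
ridge-penalized logistic model over word tokens and boundary-padded
character 3–5-grams of the normalized name — the standard strong
baseline for short-text classification, and small enough to train on a
desk machine in seconds.

Early stopping mirrors validation-monitored training: the fitter sweeps
a shared decreasing regularization path (default 25 checkpoints spanning
six decades around `regularization_strength` = 1e-3), computes
validation macro-F1 at each checkpoint, keeps the best, and stops after
`patience` (default 5) non-improving evaluations. A class with no
positive training examples degenerates to a constant-0 scorer with a
warning rather than an error. Scores are thresholded at 0.5 with an
**inclusive** boundary (a score of exactly 0.500 assigns the label); the
convention is documented because the boundary case is otherwise
unspecified. Thresholding is monotone: raising the threshold never adds
a label. Models serialize to a single file with an embedded manifest
(config, FNV-1a hash of the training names, stopped checkpoint) and
reload with bit-identical predictions.

## Evaluation

Per class: precision $TP/(TP+FP)$, recall $TP/(TP+FN)$, and
$F_1 = 2pr/(p+r)$; $0/0$ ratios are defined as 0 with a warning. Macro
$F_1$ is the arithmetic mean of the ten per-class values; micro $F_1$
pools counts across classes,
$\sum TP \,/\, (\sum TP + \tfrac{1}{2}(\sum FP + \sum FN))$ — the
pooled-count formula, not an example-averaged variant.

Published sensitivity cutoffs for food-environment classifiers are
attached as ordinal bands. The printed cutoffs ("< 20% very poor, 21–30%
poor, 31–50% fair, 51–71% moderate, 71–90% good, > 90% excellent") leave
hairline gaps between bands, so they are resolved as contiguous
half-open intervals with boundaries 0.20 / 0.30 / 0.50 / 0.71 / 0.90,
the upper band owning each boundary — the only contiguous resolution
consistent with the band attributions those cutoffs are used with
(0.928 excellent, 0.616 moderate, 0.439 fair). The package ships the
published per-class reference table and example score table as worked
examples; recomputing $F_1$ from the printed precision/recall matches
the printed $F_1$ column to within one unit in the third decimal (the
source rounded $p$ and $r$ for printing after computing $F_1$), and the
mean of the printed $F_1$ column reproduces the published macro value.

## Churn surfaces

Operating intervals are evident, not declared: a store runs from its
earliest inspection date to its out-of-business date (or latest
inspection when none is recorded), and counts as operating in any
calendar year its interval intersects. Stores are binned on a flat-top
hexagonal grid whose **centroid spacing** — not edge length — is 2,640
ft (half a mile, roughly a ten-minute walk), because the geography is
defined by walkable centroid-to-centroid distance; the custom grid
avoids anchoring the analysis to administrative boundaries (the
modifiable areal unit problem). Assignment is exact nearest-centroid via
cube rounding of fractional axial coordinates.

Coordinates arrive as WGS84 and are projected to planar feet with a
local equirectangular projection centred on the bounding box — adequate
at city scale, where the distortion across a metropolitan extent is far
below the half-mile cell size; geographic CRS identifiers are rejected
since binning needs linear units. Mean annual change per cell is
$(c_{y_1} - c_{y_0})/(y_1 - y_0)$, identical by telescoping to the mean
of consecutive annual differences. Group membership uses label-set
intersection, so a Grocery+Convenience store contributes to both group
maps; never-occupied cells are reported with change 0. Export is
GeoJSON (one polygon per cell with the two counts and the change) plus
a flat CSV.

## Data quality enhancement

On a secondary dataset carrying independent service/venue tags, the
classifier becomes an audit tool. The agreement table restricts to
records the model labels FastFood or Restaurant (records labeled only
Sweets/Desserts or Juice/Coffee are excluded to avoid overlap — a bubble
tea shop may carry a takeout service tag without being a restaurant) and
counts one cell per held class × tag value; multi-label records count
once per held restricted class, and missing tags fall under a reserved
`(missing)` column. `impute_other()` partitions `'Other'`-venue records
into restaurant-without-bar, restaurant-with-bar, other-classes, and
unlabeled shares (summing to 1), and `discrepancy_report()` ranks cells
that contradict a user-supplied tag-to-class alignment. The module
deliberately reports rather than rewrites: the analyst decides.

## The synthetic generator

Licensed directory data cannot be redistributed, so the generator
replaces all three sources with synthetic analogues whose statistical
structure matches what the pipeline assumes:

* **Names** follow "[proper noun] [class token(s)] [suffix]" with
  multi-label names concatenating one token per held class ("la vina
  bodega deli"); with probability `noise_rate` the name carries only
  generic tokens and is uninformative. Class token phrases are chosen
  not to be substrings of one another so that zero noise implies exact
  token separability (a simple token-lookup classifier reaches macro-F1
  1.0).
* **Labels** are independent Bernoulli draws at the configured
  prevalences, with co-occurrence pairs (the bodega
  Convenience∧FastFood pair, default joint 0.05) planted by a
  residual-adjusted joint draw that preserves every marginal exactly.
* **Tags/flags** are emitted consistently with the ground truth, so the
  taxonomy converter recovers labels exactly at `tag_corruption = 0`.
* **Chains** replicate one name at ≥ 11 distinct locations (the
  memorization threshold is > 10).
* **Longitudinal dynamics**: at least one inspection per operating year
  (scheduled January–June, closures July–December so the
  out-of-business date always follows the final inspection), a per-year
  closure hazard, and planted churn anchors whose dedicated stores
  realize exact per-year count deltas. Plants are anchored at a
  lon/lat point rather than a grid index because the generator does not
  own a grid; all stores of a plant share the exact anchor coordinate
  so they can never straddle a cell boundary, and deltas are exact when
  the background closure rate is 0 (a store operating in all years
  contributes equally to both endpoint counts).
* **Restaurant file**: labels concentrate on the five service classes,
  service descriptions are drawn conditionally on FastFood/Restaurant
  membership (vague with probability `service_vague_rate`), and a
  `fraction_other` share of venue tags is masked to `'Other'` with the
  withheld truth kept in `venue_true` for recovery testing.

Default scale is 2,000 independent stores plus 5 chains over a 3-year
window — large enough for stable per-class metrics, small enough that
the full pipeline trains in seconds. Geographic placement is uniform in
the bounding box: the generator makes no attempt to model realistic
urban name distributions, spatial clustering, borough geography, or
socioeconomic covariates. Passing tests on synthetic data therefore
demonstrate that the machinery is correct — recovery of planted
structure, leakage control, metric identities — not that any particular
real-world performance level will be achieved; real directories have
noisier names, richer vocabularies, and spatially structured churn.

## Numerical and design choices

* Determinism everywhere: all generators take explicit seeds through a
  scoped RNG, the fitter is deterministic given data, and end-to-end
  reruns produce byte-identical metrics files and serialized models.
* The test and acceptance suites run the pipeline at 2,000 stores (the
  default study scale) for the headline check and 800 stores for the
  five-seed noise ladder; these sizes give stable metrics while keeping
  the whole suite fast on one CPU.
* Remainders, ties and boundaries are all resolved deterministically
  and documented where they occur (train-side remainders, recency then
  record-id tie-breaks, inclusive thresholds, upper-band boundary
  ownership).

## Known limitations

The reference backend is a linear n-gram model: it memorizes and
separates token-signaled synthetic names, but it cannot capture the
contextual nuance a fine-tuned deep encoder brings to real store names;
the backend contract exists precisely so such a model can be swapped in.
The equirectangular projection is a city-scale approximation, not a
general cartographic tool. The taxonomy default config covers only the
documented conversions plus invented tag lists for synthetic use. And
churn counts distinct storefront records — whether real directories
should additionally deduplicate by name within a cell is a judgment the
analyst must make for their source.
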