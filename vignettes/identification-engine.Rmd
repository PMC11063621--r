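---
title: "The identification engine: reciprocal-prevalence ranking, QDS mapping, and synthetic keys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The identification engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ericakey)
```

## The problem

Multi-access keys let an observer constrain any subset of characters in any
order. For a genus such as *Erica* — hundreds of similar species, a coding
matrix that is chronically incomplete, and observers of very mixed
expertise — a key needs two complementary modes: a strict filter for clean
material, and a forgiving ranking that still says something useful when a
character was misjudged or has simply not yet been coded for some taxa.

## The scoring model

The dataset is a matrix of taxa by character groups; a cell holds a
possibly empty *set* of states (polymorphism is OR: the taxon shows one
state or another across its populations, though rarely on one specimen).
A *selection* constrains groups $g$ with state sets $S_g$.

Let $n_g$ be the number of taxa in the ranking population whose coding for
$g$ intersects $S_g$. The group contributes
$$p_g = 1 / n_g,$$
a taxon earns $p_g$ iff it is one of those $n_g$ carriers, and its score is
the sum of earned contributions. Three properties follow directly and are
enforced as tests:

* **Normalization** — each constrained group distributes exactly one unit
  of probability over its carriers ($n_g \cdot p_g = 1$).
* **Rarity reward** — a state carried by fewer taxa contributes more than a
  common one.
* **Uncertainty penalty** — enlarging $S_g$ (the observer hesitating
  between states) can only enlarge the carrier set, never shrink it, so
  $p_g$ never rises. The denominator is the count of taxa carrying *one or
  other* selected state, deliberately not the smaller count carrying both.
* **Strict ≡ argmax** — when some taxon matches every constrained group,
  the strict result is exactly the set of taxa attaining the maximum
  possible score $\sum_g p_g$.

The scores are not Bayesian posteriors: groups are treated as independent
and equally weighted, and no attempt is made to model character
correlation or observation reliability. The model's value is its
transparency — every score decomposes into per-group reciprocals that a
user can inspect (`probability_rank()` returns the full breakdown).

### Numerical choices

* Scores are carried at full double precision; *display* cuts them at
  seven decimal places by truncation toward zero (`format_probability()`),
  reproducing the aid's printed arithmetic ($1/361 = 0.0027700$,
  $1/115 = 0.0086956$). Rounding half-up would print $0.0027701$ instead.
* A selected state carried by **no** taxon makes $1/n_g$ undefined. The
  group then contributes 0 to everyone and the engine warns, naming the
  group: the ranking stays total and a likely observation error is
  surfaced without aborting.
* Missing coding earns 0 in probability mode and excludes in strict mode —
  a taxon cannot be credited for an unobserved character, which is exactly
  why the ranking is less sensitive to incomplete coding than the filter.
* Ties are broken by case-insensitive, accent-stripped name comparison
  (then taxon id), so orderings are deterministic across platforms and
  locales.

### The ranking population

The population used both for the denominators and for the listing is
configurable and defaults to the *terminal accepted taxa*: species without
accepted subspecific taxa, plus all accepted subspecies and varieties
(`ranking_population()`, alternative `"species"`). Using one population for
both keeps the normalization invariant exact. Synonyms and unplaced names
are never coded or ranked; they exist so `find_name()` can resolve any name
met in the literature to its accepted taxon.

## Schema and vocabularies

The default schema has the aid's 21 groups (morphology, phenology,
geography). The *group list* is canonical; the *state vocabularies* are
configuration: they ship as `inst/extdata/default_schema.json` and can be
replaced wholesale with `read_schema()`. Only a handful of states are
treated as fixed points by the tests (e.g. corolla shape `tube`; regions
`Cape Peninsula`, `KZ-Natal`, `North South Africa`); the remainder are
reasonable defaults, not ground truth. Group order is fixed for stable
display and never affects scores.

## QDS geocoding

Southern-African collections are gridded in quarter-degree squares: code
`3318CD` = degree cell 33°S 18°E, quadrant C (SW, 30′), quarter D (SE,
15′); letters run A = NW, B = NE, C = SW, D = SE from the cell's NW origin,
the convention of the national herbarium grids the distribution summaries
derive from. Containment is half-open, lower-edge-inclusive in
*(southing, easting)* coordinates, so the sixteen quarters tile a degree
cell exactly and every in-domain point maps to exactly one square —
`point_to_qds(-33.75, 18.25)` is `3318CD`. The geocoder's domain is the
southern/eastern hemisphere; codes in data that do not parse (e.g. European
extensions) are carried as opaque labels with a warning rather than
dropped.

KML export writes one polygon per (taxon, square) and one placemark per
occurrence point, at most `point_limit` points per export call (default
5000 — all curated data for most taxa while staying loadable in modest
RAM; the cap applies per call, not per taxon). Subsampling at the limit
takes the head of the table in file order: reproducible, unlike a random
thinning. Colours cycle a fixed palette with species-rank taxa first in
name order, so an inclusive species maps red and each subspecies gets its
own colour. Exported documents are checked by `kml_check()`, a structural
validator (root/namespace, one geometry per placemark, closed rings,
coordinate ranges, resolvable style references) built with `xml2`.

## What the generators emulate — and what they do not

`generate_dataset()` reproduces the *statistical* shape of a working key:
polymorphic codings (default rate 0.15), incomplete coding (default
missing rate 0.10 — real coding is documented as incomplete), a checklist
with subspecies (0.05) and synonyms (0.10), distributions of 1 + Poisson(2)
squares drawn from a 96-square south-western Cape pool, and Poisson(3)
occurrence points per taxon placed inside coded squares at six-decimal
(GPS-like) precision. Requested state prevalences are honoured exactly in
expectation: target states are only ever assigned by the primary draw, and
polymorphic second states are drawn from the untargeted remainder.
Everything is driven by one Mersenne-Twister stream seeded from the spec,
with the caller's RNG state restored, so a spec serialises to
byte-identical CSVs on every run.

Not emulated: trait correlations between groups, spatially coherent range
shapes, uneven detection effort. Passing property tests on these fixtures
therefore demonstrates the *algebraic* correctness of the engines on data
of realistic shape — not identification accuracy on real specimens.

`worked_example()` is the one fixture with externally anchored numbers:
exactly 361 carriers of corolla-shape `tube` and 115 of region
`Cape Peninsula`. How many taxa carry both is not anchored; the fixture
fixes 20 by construction (456 taxa in all). Because the overlap is a
construction choice, tests assert the two carrier counts and the
per-group contributions, and treat the joint top score only as the sum of
the two full-precision reciprocals.

## Problem sizes used in the checks

The property suites run the engines against an independent brute-force
oracle over 200 seeded random datasets of 10–200 taxa (scores must agree
within $10^{-12}$ and orders exactly), plus a 10,000-taxon run for
prevalence convergence (±0.02, about four binomial standard deviations)
and a 6,000-point layer for the KML cap. These sizes give each stochastic
check comfortable resolution while the whole suite stays fast enough to
run habitually.

## Known limitations

* Character groups are independent and unweighted in the score; no
  diagnostic power beyond state prevalence is modelled.
* The QDS geocoder does not cover the northern/western hemispheres.
* `kml_check()` is structural, not a full OGC schema validation.
* The CSV importer targets the canonical dialect defined by this package;
  external archives in other layouts need reshaping first.
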