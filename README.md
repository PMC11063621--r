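# ericakey

An open, scriptable engine for **multi-access species identification keys**,
modelled on the identification aid for the heath genus *Erica* — at 851
accepted species one of the largest flowering-plant genera, notoriously hard
to identify and rich in threatened, narrowly endemic taxa. Unlike a
dichotomous key, a multi-access key lets the observer enter *any* subset of
observed characters in any order: corolla size, shape and colour, hairiness
of six organs, exsertion of style and anthers, organ counts, sepal:corolla
ratio, resprouting after fire, flowering month, and geographic region — 21
character groups in all, each with a controlled vocabulary of states.
Taxa may be coded with several states per group (polymorphic, OR semantics),
reflecting within-species variation.

The package is for botanists, conservation practitioners and biodiversity
informaticians who want the identification logic, checklist handling and
distribution mapping of such an aid as a library and command-line tool
rather than a desktop GUI.

## The two identification modes

**Strict matching** returns the taxa whose coding intersects the selected
states in *every* constrained group.

**Probability ranking** tolerates mismatches and missing data. For a
selection constraining groups *g* with state sets *S<sub>g</sub>*, let
*n<sub>g</sub>* be the number of taxa carrying at least one state of
*S<sub>g</sub>* (the *carriers*). The group contributes

&nbsp;&nbsp;&nbsp;&nbsp;*p<sub>g</sub>* = 1 / *n<sub>g</sub>*

and a taxon's score is the sum of *p<sub>g</sub>* over the groups in which
it is a carrier. Rare states therefore weigh more than common ones
(reciprocal prevalence); selecting several states in one group expresses
uncertainty and dilutes that group's contribution (the carrier set can only
grow); and a taxon missing a coding simply earns nothing from that group
instead of being eliminated. Taxa are listed in descending score order,
ties broken alphabetically. Whenever the strict result is nonempty it
equals the set of taxa attaining the maximum possible score.

Around the core the package provides the coded-matrix data model with CSV
persistence and validation, name lookup across accepted names, synonyms and
unplaced names, taxon comparison tables, quarter-degree-square (QDS)
geocoding (the southern-African 15′ × 15′ herbarium grid, codes like
`3318CD`), per-square taxon lists, KML export of grid squares and
occurrence points for Google Earth, grid-versus-point coverage reports, and
deterministic synthetic-data generators.

## Worked example

Observing a tubular-flowered plant on the Cape Peninsula:

```r
library(ericakey)
we <- worked_example()   # 361 taxa coded "tube", 115 coded "Cape Peninsula"

group_contribution(we$dataset, "corolla_shape", "tube")
#> <group contribution> corolla_shape = {tube}: 361 carriers, value 0.0027700
group_contribution(we$dataset, "region", "Cape Peninsula")
#> <group contribution> region = {Cape Peninsula}: 115 carriers, value 0.0086956

probability_rank(we$dataset, we$selection)
#> <probability ranking> 456 taxa
#>   taxon_id                 name     score matched_groups contrib_corolla_shape contrib_region
#> 1    WE342 Erica exemplaris-342 0.0114657              2             0.0027700      0.0086956
#> 2    WE343 Erica exemplaris-343 0.0114657              2             0.0027700      0.0086956
#> 3    WE344 Erica exemplaris-344 0.0114657              2             0.0027700      0.0086956
#>   ...
```

The corolla-shape group is shared by 361 taxa, so it contributes
1/361 = 0.0027700 to every tube-coded taxon; the region group, rarer, is
worth 1/115 = 0.0086956. The 20 taxa coded for both states share the top
score (displayed values are cut at seven decimal places; full precision is
kept internally). `strict_match(we$dataset, we$selection)` returns exactly
those 20 taxa.

The same session from the shell:

```sh
ericakey fixtures worked-example --out demo/
ericakey rank --data demo/ --set "corolla shape=tube" \
              --set "region=Cape Peninsula" --top 5
ericakey identify --data demo/ --set "corolla shape=tube" \
                  --set "region=Cape Peninsula"
ericakey map --data demo/ "Erica exemplaris-342" --out map.kml
```

## See also

The methods vignette (`vignettes/identification-engine.Rmd`) documents the
scoring model and its assumptions, the QDS geocoding conventions, what the
synthetic generators do and do not emulate, and the numerical and design
choices.
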