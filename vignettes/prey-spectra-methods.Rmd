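---
title: "Methods: combined metabarcoding and macro-photography prey spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combined metabarcoding and macro-photography prey spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preyspectra)
```

## The measurement problem

Metabarcoding of bulk arthropod samples from sticky-trap leaves answers
*what* was captured but not *how much*: CO1 read counts scale with DNA
quantity and digestion state, not with individuals, so all compositional
analysis in this package treats detections as presence/absence. Photographs
of the sampled leaves, taken in the field before collection, answer *how
much* (a raw prey count per sample) and provide a one-way error check on
the barcoding: a large-bodied taxon reported by sequencing but invisible in
the photographs is implausible, whereas absence of a small taxon from the
photographs proves nothing, because digested small prey turn into
unidentifiable crumbs. The package wires these two information channels
together with explicit, auditable decision rules.

## Consensus taxonomy

Each OTU arrives with two independent identifications (a BOLD-style and a
GenBank-style BLAST hit), each a six-rank lineage
(phylum–class–order–family–genus–species). The consensus keeps ranks from
phylum downward while both names agree after trimming and case-folding, and
truncates at the first disagreement. Two modes handle the common case of a
rank assigned in one database and missing in the other:

* **strict** (default): a gap stops the consensus — "level of agreement"
  requires both databases to speak;
* **lenient**: the assigned name is inherited and the scan continues.

Strict is the default because it is the conservative reading; real
reference libraries are gappy, so the lenient switch exists for users who
prefer coverage over caution. No percent-identity threshold is applied to
hits: the Hit-%-ID value is carried through for reporting and optional
user-side filtering. Sub-ranks (subfamily, tribe) in inputs are ignored,
and no synonym resolution is attempted — a known limitation; name matching
is purely lexical.

Lineages violating the prefix invariant (an assigned rank below an
unassigned one) are repaired by truncation at construction, with a warning.

## Cleaning and the exclusion cascade

Relative-abundance cleaning zeroes every OTU-table cell below
`threshold_fraction` (default `1e-4`, i.e. 0.01 %) of the read total. The
default denominator is the grand total of the whole table — the literal
reading of "of the total" — with a per-sample alternative behind a config
switch, since both conventions are common in metabarcoding practice. The
threshold is computed once from the incoming table, so the operation is
idempotent; it is not applied recursively to its own output.

Pooling assigns every surviving OTU to its consensus family, or to an
`"Other <Order>"` pseudo-family when the consensus stops at order. These
pseudo-families are first-class taxa in all family-level analyses — the
unassignable fraction of an order is itself informative. OTUs whose
consensus stops above order are dropped and counted.

Exclusions never delete rows; they set `status = "excluded"` with a reason,
so the complete audit trail is reconstructable. Three rules fire, in order:
non-Arthropoda phyla (human, bacterial, fungal contamination); a
user-editable contaminant blocklist (marine taxa cannot be recognised from
the lineage alone, so they are handled here — the default list carries one
marine family and its order, the order entry catching detections whose
consensus stops above family); and a plant-parasite blocklist (default:
family Pseudococcidae, orders Trombidiformes and Mesostigmata) for
phytophagous taxa that infest the plant rather than being captured.

## Pictorial plausibility control

The control is deliberately conservative and asymmetric. A detection is
*confirmed* when an identifiable photo item of the same sample matches it —
at family rank exactly, or at order rank for any family of that order
(photographic identification is often only possible to order). An
unmatched detection is *excluded* only when the family is flagged
large-bodied in the conspicuity table; otherwise it is *not excludable* and
stays in the analysis. The conspicuity table is data, not code: a
two-column tibble shipping with a default list of large families (wasps,
beetles, moths, large flies, orb-weavers, grasshoppers) that users should
edit for their system. A family missing from the table is treated as
small-bodied, i.e. never excludable — the conservative default. No numeric
size threshold is defined; "large" is an expert judgement encoded in the
table. Endoparasite bycatch (e.g. Strepsiptera in their hosts) is
deliberately never excluded: such taxa are digested with their host and
contribute to plant nutrition.

The reverse report (`photo_only_report()`) lists identifiable photo items
with no corresponding detection; an empty report is the healthy outcome and
means the barcoding data are a superset of the photographic record.
Verdicts never touch read counts or prey counts: composition comes from
barcoding, quantity solely from photographs.

## Community statistics

On presence/absence data the Bray–Curtis dissimilarity reduces to the
Sørensen form `d = (b + c) / (2a + b + c)` with `a` shared taxa and `b`,
`c` unique to each sample. A pair of all-absent samples is defined as
`d = 0` with a warning. Taxa present nowhere are dropped before distances:
they cannot affect `d` but would distort taxon counts.

ANOSIM uses Clarke's statistic `R = (r̄_B − r̄_W) / (n(n−1)/4)` on the
mid-ranked dissimilarities; mid-ranks are essential for presence/absence
data, where ties are massive. The permutation p-value uses the
`(count ≥ observed + 1)/(N + 1)` estimator (999 permutations by default,
the PRIMER convention) so p is never zero; an exact mode enumerates all
distinct labellings for small designs. All distances tied yields `R = 0`
with a warning. Pairwise comparisons recompute distances on each pair's
sample subset rather than slicing the global ranking, and are not
multiplicity-adjusted by default (matching common PRIMER-style reporting);
a Bonferroni flag is available.

SIMPER uses the same binary Bray–Curtis decomposition: for each
between-group sample pair, taxon k contributes
`100·|x_ik − x_jk| / Σ_l (x_il + x_jl)`, and contributions are averaged
over the pairs. This guarantees internal consistency — taxon contributions
sum exactly to the average between-group percentage dissimilarity — and the
test suite asserts both that identity and agreement with vegan's
implementation. Identical groups make the decomposition undefined and
raise an informative error.

Prey quantity divides the per-sample photo count by the *sum* of the five
leaf lengths (equivalently count over five times the mean leaf length) —
the only reading consistent with per-sample counts on the order of
rate × total leaf length; since the sum is five times the mean, this also
honours conventions phrased in terms of the mean. Group comparison uses
the tie-corrected Kruskal–Wallis H (chi-square approximation, standard at
ten samples per group) and Dunn's z on pooled mid-ranks with tie
correction, two-sided p-values Bonferroni-multiplied by the number of
pairs and capped at 1.

## The synthetic-data generator

The generator's defaults are the study conditions the package targets:
three sundew species, ten plants per species, five leaves per plant.
Species parameters are the published field values — prey capture rates of
2.25, 1.80 and 0.81 items per cm leaf length and leaf lengths of 7.1 ± 1.3,
5.3 ± 1.1 and 10.4 ± 0.6 cm for *D. margaritacea*, *D. hartmeyerorum* and
*D. finlaysoniana* respectively.

Design choices where only means ± SD are published:

* leaf lengths are normal, truncated at 0.5 cm (resampling);
* per-sample prey counts are Poisson with mean
  `prey_rate_per_cm × Σ leaf lengths` — the simplest count-per-unit-effort
  model; overdispersion in real counts is not claimed or emulated;
* per-detection read counts are log-normal (`meanlog = 6.5`, `sdlog = 1`,
  floored at 200 reads): metabarcoding read counts are heavy-tailed and
  non-quantitative, and the floor keeps genuine detections above the
  cleaning threshold at the default table size so that injected noise
  cells are exactly the sub-threshold ones;
* each prey family is backed by one to a few OTUs (one arthropod can yield
  several OTUs), shared across samples.

The twelve-order inventory is shared by all species. `family_separation`
(default 0.6, moderate overlap) controls how disjoint the species' family
pools are within the shared orders: at 0 all species draw from one pool, at
1 the pools are disjoint. Family sampling weights are heavy-tailed
(lognormal family weight × lognormal order multiplier), because real
arthropod communities are dominated by a few abundant taxa and rare orders
must exist for order-level presence to vary. Private-family weights are
rescaled so each species' per-order total weight is identical: order-level
composition is a property of the shared site inventory, and only family
identity separates species. This is what makes the generator reproduce the
qualitative contrast of strong family-level but weak order-level
separation, rather than having it imposed anywhere downstream.

Nuisance channels, all independently switchable: contaminant OTUs drawn
from a fixed catalogue of human, *Wolbachia*-like, fungal, marine and
plant-parasite lineages (`contaminant_rate` per sample, default 1.5);
stray sub-threshold cells in empty OTU-table positions
(`noise_cell_rate = 0.02`); one database's lineage truncated
(`rank_dropout_rate = 0.35`) or perturbed below some rank
(`db_disagreement_rate = 0.15`). With every rate at zero the pipeline
output equals the generator's ground truth exactly — the clean-channel
identity asserted in the tests. All draws run under a single seed;
identical config and seed give byte-identical fixture files.

What the generator does **not** emulate: sequence-level artefacts
(chimeras, index hopping beyond stray cells, primer bias), true ecological
overdispersion and spatial structure, abundance-correlated detection
probability, inter-annotator disagreement in photo labels, and real
reference-database taxonomy (synthetic genus/species names fill the deep
ranks). Passing tests therefore demonstrate correctness of the decision
rules and statistics under a plausible data-generating model, not
robustness to every failure mode of real sequencing data.

## Problem sizes and reproducibility

The test suite exercises the exact ANOSIM enumeration on all group layouts
with up to ten samples, property checks on randomly generated presence
matrices of eight to twelve samples, and full pipeline runs at the default
study size (30 samples, ~140 OTUs). The separation-recovery check averages
family- and order-level R over twenty generator seeds at separations 0,
0.5 and 1 with the R statistic only (no permutations), which keeps it fast
while the permutation machinery is validated separately against exact
enumeration. The acceptance script runs the default study once with 999
permutations plus ten-seed recovery means; every random draw derives from
its `--seed` argument.

## Reproducing the original study's numbers

The conditional-reproduction check (92 confirmed families in 12 orders, 25
photo-excluded families, global family-level R of 0.784, and so on)
requires the original study's supplementary tables, for which no public
accession exists. The pipeline accepts them as the package's interchange
formats under `inst/extdata/supplementary/` (`otu_table.tsv`,
`hits_bold.csv`, `hits_ncbi.csv`, `photos.csv`, `samples.csv`); the
corresponding acceptance test states exactly this and fails until the
files are supplied. Everything else in the package is desk-reproducible
from the synthetic generator.
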