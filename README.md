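# preyspectra

Reliable prey-spectra analysis for carnivorous plants, combining bulk-sample
DNA metabarcoding with *in-situ* macro photography.

## The problem

The prey spectrum of a carnivorous plant — which arthropod taxa it captures,
and how many — is central to its ecology, but hard to measure. Morphological
identification of half-digested prey is slow and often impossible; CO1
metabarcoding of pooled trap leaves identifies even heavily digested prey to
family or below, but read counts are not quantitative and the method is
exquisitely sensitive to contamination. `preyspectra` implements a combined
workflow for sticky-trap sundews (*Drosera*): metabarcoding answers *what*
was caught, macro photographs of the sampled leaves act as a conservative
plausibility control and provide the prey *counts*.

The pipeline stages are:

1. **Consensus taxonomy** — each OTU carries two BLAST identifications
   (BOLD-style and GenBank-style); the consensus lineage keeps only the
   deepest ranks on which both databases agree
   (`parse_hit_table()`, `consensus_table()`, `rank_summary()`).
2. **OTU-table cleaning** — read counts below 0.01 % of the table total are
   zeroed (`clean_low_reads()`).
3. **Family pooling + exclusion cascade** — OTUs pool to prey families (or
   `"Other <Order>"` when the consensus stops at order); non-arthropods,
   blocklisted contaminants and plant parasites (Pseudococcidae,
   Trombidiformes, Mesostigmata) are flagged, never deleted
   (`pool_to_family()`, `apply_exclusions()`).
4. **Pictorial plausibility control** — a detected family is excluded only
   if it is large-bodied (wasps, beetles, moths, ...) *and* absent from the
   sample's photographs; small taxa degrade into unidentifiable crumbs and
   are never excludable (`reconcile()`, `photo_only_report()`).
5. **Community statistics on presence/absence** — binary Bray–Curtis
   (Sørensen) dissimilarity `d = (b + c) / (2a + b + c)`, ANOSIM
   `R = (r̄_between − r̄_within) / (n(n−1)/4)` with permutation p-values,
   and SIMPER decomposition of between-species dissimilarity
   (`build_presence_matrix()`, `binary_bray_curtis()`, `anosim()`,
   `pairwise_anosim()`, `simper()`).
6. **Prey quantity** — photo prey counts per cm of summed leaf length,
   compared across species with a Kruskal–Wallis test and Dunn–Bonferroni
   post-hocs (`prey_quantity()`).

A seeded synthetic-data generator (`simulate_prey_study()`) emulates the
complete input family — OTU table, dual hit tables, photo annotations,
sample metadata — with controllable species separation, contamination and
noise, so the whole pipeline is testable without any sequencing data.

## Worked example

```r
library(preyspectra)

rep <- run_pipeline(pipeline_config(
  generator = generator_config(seed = 1),   # 3 species x 10 samples x 5 leaves
  n_permutations = 999, seed = 1
))
rep
#> Prey-spectra pipeline report
#>   OTUs: 138 in, 128 after cleaning, 0 dropped above order
#>   Prey taxa kept: 69 families in 12 orders (0 photo-excluded)
#>   ANOSIM family level: R = 0.990 (p = 0.001)
#>   ANOSIM order level:  R = 0.048 (p = 0.153)
#>   Kruskal-Wallis prey/cm: H = 25.81 (p = 2.49e-06)

rep$quantity
#> Prey quantity per cm leaf length
#>   D. finlaysoniana     0.82 +/- 0.17 (n = 10)
#>   D. hartmeyerorum     1.67 +/- 0.20 (n = 10)
#>   D. margaritacea      2.25 +/- 0.17 (n = 10)
#>   Kruskal-Wallis H = 25.81, df = 2, p = 2.49e-06
```

The headline contrast — strong, significant separation of the three species'
prey spectra at family level (R = 0.99, p = 0.001) but not at order level
(R = 0.05, p = 0.15) — is the signature of closely related sundews drawing
on the same orders of flying insects while catching site-specific families.
Per-cm prey capture differs strongly across species (H = 25.8): the
smallest-leaved species capture the most prey per cm.

Results objects are tidyverse-friendly: `tidy()`/`glance()` methods for
ANOSIM, SIMPER and quantity results, `autoplot()` for permutation nulls and
prey-quantity boxplots, `plot_presence_percentages()` for prey-spectrum bar
charts, and `write_report()` for a full plain-text audit trail (every OTU's
fate: cleaned, pooled, dropped above order, or excluded with a reason).

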