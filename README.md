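# barcodeval

Evaluate candidate DNA barcode markers for a regional flora and rank the
surveyed species for conservation priority.

Regional barcoding surveys of plants ask two questions. First, which marker
— typically the nuclear ITS region, the plastid *matK* and *rbcL* genes, or
a concatenation — best discriminates the species at hand? That is answered
by comparing markers on sequence variability, the barcoding gap,
reference-library identification success, distance-based MOTU delimitation
and tree-based monophyly. Second, which of the surveyed species most
urgently need protection? That is a multi-criteria decision problem,
answered here with the Analytic Hierarchy Process (AHP). `barcodeval`
implements both halves as a reusable, tested pipeline for researchers and
conservation practitioners who work with desk-scale regional datasets and
need every number to be reproducible offline.

## What it computes

* **Sequence characteristics** per marker: length and GC ranges, aligned
  length, conserved / variable / parsimony-informative / singleton sites,
  and nucleotide diversity π (mean pairwise p-distance, pairwise deletion).
* **Genetic distances**: p-distance and Kimura 2-parameter,
  *d* = −½·ln{(1−2P−Q)·√(1−2Q)} with transition proportion *P* and
  transversion proportion *Q*, pairwise deletion, saturation flagging, and
  a site bootstrap for standard errors.
* **Barcoding gap**: intra- vs inter-specific distance pools, per-species
  verdicts (gap present iff max intra < min inter, strictly), pooled
  summaries and histogram tables. Combinations are analysed on
  concatenated alignments.
* **MOTU delimitation**: an ABGD implementation (recursive barcode-gap
  detection over a ladder of priors) and an ASAP-style ranker over
  single-linkage merge heights, plus discrimination rates against
  morphological taxonomy under an exact one-to-one match rule.
* **Identification**: best-hit percent identity against a local reference
  library (leave-one-out by default) with species/genus/family success
  rates.
* **Monophyly**: support-thresholded conspecific-cluster rates on input
  trees (unrooted bipartition test; supports read from Newick labels), with
  an NJ builder as plumbing.
* **AHP**: eigenvector weights from Saaty judgment matrices with
  consistency ratio, composite species scores S = Σ wᵢ·pᵢ/pᵢᵐᵃˣ, and the
  three-class priority ranking (class 1: S ≥ 0.60; class 2: 0.40 ≤ S <
  0.60; class 3: S < 0.40). A published 13-criterion scheme and the
  published 23-species class-1 table ship as fixtures.
* **Synthetic data**: seeded generators for multi-marker floras with
  controlled divergences, decoy reference libraries and criterion-score
  tables, so the full pipeline runs with no download.

## Worked example

```r
library(barcodeval)

cfg <- sim_config(seed = 11)          # 3 markers, 12 species, 2-3 samples each
bundle <- run_pipeline(cfg, model = "k2p")
bundle$summary
#>           label overlap_fraction abgd_rate asap_rate monophyly_rate ident_species_rate
#> 1           ITS                0    100.00       100            100                100
#> 2          matK                0    100.00       100            100                100
#> 3          rbcL                0     83.33       100            100                100
#> 4      ITS+matK                0    100.00       100            100                 NA
#> 5      ITS+rbcL                0    100.00       100            100                 NA
#> 6     matK+rbcL                0    100.00       100            100                 NA
#> 7 ITS+matK+rbcL                0    100.00       100            100                 NA
```

One row per marker or concatenation. `overlap_fraction` is the share of
species without a barcoding gap (0 = clean separation), the `*_rate`
columns are percentages of species correctly recovered by ABGD's modal
partition, ASAP's top partition, and the NJ-tree monophyly test;
`ident_species_rate` is leave-one-out best-hit success (single markers
only, where a reference library exists). On these gap-enforced synthetic
data most methods are perfect by construction; the slow-evolving `rbcL`
profile already costs ABGD accuracy, mirroring the lumping that slow
markers show in practice.

```r
bundle$ahp$class_tally
#> class1 class2 class3
#>      3      6      3
head(bundle$ahp$ranked, 3)
#>   rank    species   family  score class
#> 1    1 Species004 Family01 0.7066     1
#> 2    2 Species005 Family02 0.6885     1
#> 3    3 Species012 Family03 0.6786     1
```

Composite AHP scores rank the simulated flora into the three priority
classes. The AHP engine itself:

```r
res <- derive_weights(consistent_judgment(c(0.6, 0.3, 0.1)))
round(res$weights, 4); res$CR
#> [1] 0.6 0.3 0.1
#> [1] 0
```

The shipped survey fixtures work the published class-1 table end to end:

```r
t3 <- tianshan_class1()
rk <- rank_species(data.frame(species = t3$species, family = t3$family,
                              score = t3$ahp_value))
rk$class_tally        # 23 species, all class 1
rk$class1_families    # Asteraceae 4, Fabaceae 3, Lamiaceae 3, ...
```

## Vignette

`vignettes/barcode-evaluation-methods.Rmd` documents the models, the
parameter conventions (pairwise deletion, saturation flagging, strict gap
inequality, singleton handling, class boundaries), what the synthetic
generator does and does not emulate, and the package's known limitations.
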