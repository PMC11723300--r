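---
title: "Evaluating DNA barcodes and ranking conservation priorities: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating DNA barcodes and ranking conservation priorities: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`barcodeval` evaluates candidate DNA barcode markers — typically the nuclear
ITS region and the plastid *matK* and *rbcL* genes used for land plants —
for a regional flora, and ranks the surveyed species for conservation
priority with an Analytic Hierarchy Process (AHP) engine. This vignette is
the package's own account of the models and procedures it implements, the
tunable parameters that matter, and the choices made where the design was
genuinely open.

```{r setup}
library(barcodeval)
```

## Distance kernel

Sequences are compared column-wise after alignment, with *pairwise
deletion*: any site where either sequence carries a gap or an IUPAC
ambiguity code is excluded for that pair only (the convention MEGA uses by
default). Two distances are offered:

* the p-distance, the proportion of differing comparable sites, and
* the Kimura 2-parameter (K2P) distance
  $d = -\tfrac{1}{2}\ln\{(1-2P-Q)\sqrt{1-2Q}\}$,
  where $P$ and $Q$ are the transition (A↔G, C↔T) and transversion
  proportions.

Both are provided because the two conventions coexist in barcoding studies;
every downstream table records which model produced it. When the K2P log
argument is non-positive the pair is *saturated*: it is flagged
inapplicable (`NA`) rather than raising an error, is excluded from pooled
summaries, and is counted in the matrix's `n_inapplicable`. K2P ≥ p holds
for every applicable pair and K2P converges to p as divergence goes to
zero; both properties are exercised in the test suite against a per-site
brute-force tally. The site bootstrap resamples alignment columns with
replacement and reports the standard deviation of the per-replicate
distances as the SE; replicates in which a pair loses all comparable sites
are skipped for that pair and counted.

## Alignment statistics

Per-marker summaries report sequence counts, ungapped length range, GC
content (G+C over unambiguous bases only), and the site classification:
after dropping gap/ambiguity-carrying rows per column, a column with fewer
than two unambiguous bases is excluded; one state means conserved; two or
more states each in at least two sequences means parsimony-informative;
otherwise the column is a singleton site. Nucleotide diversity π is the
mean pairwise p-distance under pairwise deletion. Note that π defined this
way is a per-site quantity in [0, 1]; no attempt is made to reproduce
published tables whose π estimator is not stated.

## Barcoding-gap analysis

Off-diagonal distances are pooled into intraspecific (both samples share a
species) and interspecific pairs. Per species, the *barcoding gap* is
present when its maximum intraspecific distance is strictly less than its
minimum distance to any other species. Singleton species cannot show
intraspecific variation; they are judged on `min_inter` alone with
`max_intra = 0` and a `singleton` flag, rather than being silently dropped
— in regional surveys most species are singletons, so this choice is
material and is surfaced in every report. The `overlap_fraction` is the
share of species without a gap. Marker combinations are always analysed by
recomputing distances on the concatenated alignment over the samples shared
by all requested markers, not by averaging per-marker distances.

## MOTU delimitation

Two distance-based delimitation methods are implemented.

**ABGD.** For each prior intraspecific divergence $P$ (default: 10 priors
log-spaced on [0.001, 0.1], mirroring the public web server, with relative
gap width $X = 1.5$), the ascending sorted pairwise distances are scanned
for the first gap at or above $P$ whose width exceeds $X$ times the running
mean of the distances below it. Samples linked at or below the gap's lower
edge form MOTUs as connected components, and each MOTU is re-scanned
recursively; groups of fewer than 3 samples are not split further. Without
a qualifying gap all samples form one MOTU. Since one partition per prior
is produced while surveys report a single MOTU count, the *modal* partition
(most frequent MOTU count across priors, ties toward fewer MOTUs) is the
default choice.

**ASAP-style ranker.** Single-linkage agglomeration generates one candidate
partition per merge interval, from all singletons down to two MOTUs (the
trivial one-MOTU partition is not a candidate). Each candidate is scored by
the mean of two ranks, larger being better: the width of the merge-height
interval over which the partition is stable, and the separation statistic
(mean between-MOTU minus mean within-MOTU distance). A candidate with no
within-MOTU pair makes no statement about intraspecific variation, so its
separation is undefined and takes the worst rank. This is a deliberately
simple rank-based analogue of the published ASAP score — the published
probability model (panmixia p-values) is not reproduced — and every report
header says so. Ties are broken toward fewer MOTUs.

**Discrimination rate.** A species counts as successfully discriminated
only under the exact bidirectional rule: all of its samples fall into one
MOTU and that MOTU contains no other species. This is the strictest
reasonable reading, stated in the output metadata; published studies often
leave their rule implicit.

## Reference-library identification

Live database queries are irreproducible, so identification runs against a
local reference library with full taxonomy. Each query is aligned to each
reference — co-aligned equal-length sequences are compared column-wise;
otherwise an end-gap-free global alignment is used, appropriate for
amplicon-scale barcodes — and scored by percent identity,
PI = 100 × matches / (matches + mismatches). The best hit is the highest
PI, ties broken by coverage then lexicographic id; hits below
`min_identity` are discarded (this filter replaces BLAST E-value
screening). Verdicts compare the best hit's taxonomy to the query's at
species, genus and family rank; with internally consistent taxonomies the
success rates are monotone nonincreasing from family to species.
Leave-one-out (`exclude_self = TRUE`) is the default evaluation mode,
emulating a query against independent records.

## Tree-based monophyly

Monophyly is tested as an *unrooted bipartition*: a species with two or
more tips forms a conspecific cluster when some split of the tree separates
exactly its tips from the rest, so re-rooting cannot change verdicts.
Support values are read from numeric internal node labels (0–100, the
UFBoot convention) of input Newick trees; they are never recomputed. With
an active threshold (default 95, strict inequality) a species additionally
counts as supported only when the split's support exceeds the threshold;
splits without a recorded support count as unsupported. Threshold 0
disables gating — the right setting for the bundled neighbor-joining
plumbing trees, which carry no supports. Singleton species are reported but
excluded from the headline rate, since one tip can neither support nor
refute monophyly; the per-species table keeps them visible. NJ construction
itself is delegated to `ape::nj()` and, on an additive matrix, reproduces
the input distances exactly along tree paths.

## AHP priority scoring

Criterion weights may be supplied directly or derived from a Saaty-scale
pairwise-comparison judgment matrix (positive, reciprocal, entries in
[1/9, 9]). Weights are the normalized principal eigenvector, computed by
power iteration to relative tolerance 1e-10; row geometric means are the
documented cross-check estimator. Consistency is the standard companion:
$CI = (\lambda_{max} - n)/(n - 1)$, $CR = CI/RI$ with Saaty's random-index
table, acceptable when $CR < 0.1$. The two estimators agree closely only
for plausibly consistent matrices — on wildly inconsistent random
Saaty-scale matrices (which AHP itself rejects at $CR \ge 0.1$) they can
disagree by an order of magnitude more — so the cross-check suite uses
bounded perturbations of consistent matrices.

The package ships a 13-criterion scheme for wild-plant conservation
priority (endangered category and hereditary value dominate, with weights
0.3938 and 0.3270; the printed weights sum to 1.0001 and are kept as
printed). Composite scores use the declared convention
$S = \sum_i w_i \, p_i / p_i^{max}$, normalizing each criterion's points by
its own maximum level; the alternative global normalization by 9 is
available via `normalization = "global_nine"`, and every report names the
convention used. No claim is made that this reproduces any published
composite value from unpublished per-species points. Classes follow the
published intervals with the boundary resolved by the published table
itself: S ≥ 0.60 is class 1 (species printed at exactly 0.60 appear in
class 1), 0.40 ≤ S < 0.60 class 2, S < 0.40 class 3.

## Synthetic data generator

The generator exists so the whole pipeline is testable offline, and its
defaults are fixed study conditions, not tuning knobs. Sequences evolve
down a family → genus → species ancestor cascade: each level mutates at
half the marker's interspecific rate, so congeners — the closest species
pairs — diverge at about `inter`, and individuals mutate from their species
ancestor at half the intraspecific rate, giving within-species pairwise
distances of about `intra`. Substitutions follow a two-rate
transition/transversion process (default ratio 2), the minimal model under
which K2P is the matched estimator, which makes parameter recovery a
meaningful test. Root composition targets the marker's GC fraction;
substitution drift pulls realized GC slightly toward 50%, so concentration
checks apply to the dataset mean. Generation is columnwise independent:
no indels, so data emerge aligned — alignment inference is out of scope.

With `gap_present = TRUE` the configuration must satisfy `intra < inter`
and realized pools separate cleanly at barcode-scale lengths. With
`gap_present = FALSE` the flora contains a cryptic species pair — two
species sharing their ancestor, one carrying threefold intraspecific
divergence — which reliably overlaps the intra- and inter-specific pools,
the way recently diverged species do in real data. Simple uniform inflation
of intraspecific rates does *not* create overlap, because individual
mutations inflate the interspecific distances too.

The default profiles mirror a three-marker plant survey at reduced scale:
ITS (700 bp, GC 0.56) and matK (800 bp, GC 0.34) fast-diverging, rbcL
(600 bp, GC 0.44) slow and conserved, over 12 species in 6 genera and
3 families with 2–3 samples per species. Reference libraries add two fresh
conspecific records per species plus the congeneric and confamilial decoys
implied by the flora; omitting conspecifics for selected species emulates
database gaps that force genus-level identification.

What passing tests on these data do **not** show: robustness to alignment
error, indels, heterotachy, chimeric sequences, contamination, or the
deep-versus-shallow rate heterogeneity of real floras. The generator makes
the statistical structure each stage *assumes*; real surveys violate those
assumptions to varying degrees.

## Problem sizes and numerical choices

Property suites run 50 seeded replicates of a 5-species, 800 bp,
`intra = 0.02` / `inter = 0.10` configuration for delimitation, gap and
monophyly checks, and reduced-scale configurations elsewhere; these sizes
give stable Monte-Carlo estimates while keeping the suite fast. Power
iteration stops at relative tolerance 1e-10; NJ path-distance recovery is
asserted to 1e-9; saturated K2P pairs are flagged, never silently dropped;
ABGD stops splitting below 3 samples; ties in ranking break alphabetically
(species) or toward fewer MOTUs (partitions), so all outputs are
deterministic given a seed.

## Known limitations

* The ASAP-style ranker is a rank-based analogue, not the published
  probability model; on data without clear structure its top candidate is
  less meaningful than the published score would be.
* ABGD's recursion follows the spec'd simple rule (first qualifying gap,
  connected components); the reference implementation's refinements for
  heterogeneous intraspecific rates are not reproduced.
* Identification uses exhaustive pairwise alignment — appropriate for
  desk-scale libraries, not for database-scale searches.
* Maximum-likelihood tree inference, model selection and bootstrap
  resampling are out of scope; externally estimated trees with support
  labels are consumed via Newick.
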