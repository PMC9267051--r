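---
title: "Methods: comparative genome profiling with genoprof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative genome profiling with genoprof}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genoprof)
library(dplyr)
```

`genoprof` implements the downstream, tabular analyses of a comparative
draft-genome study: genome-size estimation from k-mer spectra, transposable
element (TE) landscape scoring, a pseudo-count log-odds statistic for
gene-family expansion, single-genus cluster extraction from gene trees, and
domain-architecture classification. This vignette explains each model, its
assumptions and tunable parameters, the numerical conventions, and what the
synthetic-data generators do and do not emulate.

## K-mer spectrum model

A histogram of k-mer depths from shotgun reads decomposes into a
sequencing-error component that decays from depth 1 and a genomic component
peaking at the sequencing coverage *C*, with repeat families adding peaks at
multiples of *C*. The analysis makes three choices:

* **Trough rule.** The error/signal cutoff is the *first local minimum* at
  depth ≥ 2 (`find_cutoff()`): the smallest depth whose count is ≤ both
  neighbours, ties toward smaller depth. This is a reproducible, inspectable
  rule; a centred moving-average window (`smooth`, default 1 = off, odd
  widths only) is available because raw histograms at low counts are
  Poisson-noisy and a single noisy bin can otherwise stop the scan early.
  On strictly monotone histograms (no error component) the function refuses
  and asks for an explicit cutoff rather than guessing.
* **Peaks.** *C* is the argmax of the count beyond the cutoff, smallest
  depth on ties (so a flat tail yields the cutoff itself, deterministically).
  Secondary peaks are all other local maxima beyond the cutoff at least
  `secondary_frac` (default 0.1) of the main peak's height; the first bin of
  a plateau represents the plateau. Note that a Poisson hump with integer
  mean *C* has tied modes at *C* − 1 and *C*, so the reported peak may sit
  one bin left of the nominal coverage.
* **Two estimators, both reported.** The read-based identity
  `n * (L - k + 1) / C` (reads × k-mers per read ÷ coverage) needs external
  read statistics; the spectrum-based estimator
  `sum(d * count(d), d >= cutoff) / C` needs only the histogram and counts
  repeats at their copy number. They answer slightly different questions and
  published size figures cannot always be attributed to one read set and
  one *k*, so `analyze_kmer_spectrum()` reports both rather than preferring
  one.

Degenerate inputs are errors, not warnings: no bins beyond the cutoff, zero
k-mer mass, read length ≤ *k*.

## TE landscape

TE genes are called from a per-gene domain-hit digest (gene id, GyDB clade,
E-value, alignment span) at an inclusive E-value cutoff, default 1.0 — a
deliberately permissive screen, since any recognizable retroelement domain
marks a TE-derived gene. Each gene then receives exactly one clade, its
lowest-E-value hit, with ties broken by longer alignment span and then
lexicographic clade name so the assignment is a total, deterministic
function. One-clade-per-gene is what keeps the landscape percentages summing
to 100.

The *accumulation score* of a clade is the percentage of total TE-occupied
length attributable to it. Occupancy is measured on protein-coordinate hit
spans — the union of a gene's spans from its assigned clade, merged so
overlaps are not double-counted — because TE detection here operates on
predicted transcripts/proteins and absolute lengths cancel in the ratio.
Whether published clade tables weight by occupied length or by element count
is ambiguous; length-union is the default and `weight = "count"` is exposed.
TE density is `round(total_te_genes / genome_size_gb)` with halves away from
zero (the convention that reproduces published TEs/Gb figures exactly).

## Multiplication odds score

Given a genus × superfamily count matrix *N* (distinct genes per genus
carrying a signature — a gene with several hits of one signature counts
once, a gene with two signatures counts under both), the score is

$$\mathrm{score}(g, s) = \log_2 \frac{N(g,s) + PS}{\bar N(s) + PS}, \qquad
\bar N(s) = \tfrac{1}{G}\sum_{g'} N(g', s)$$

with pseudo-count `PS = 5.00` by default. Design points:

* **The mean includes the focal genus.** The alternative (leave-one-out)
  does not reproduce published score tables; the inclusive mean does,
  verified cell-by-cell in the acceptance tests. Including the focal count
  with weight 1/G also makes the score strictly increasing in the focal
  count (property-tested), and guarantees each signature has at least one
  genus scoring ≥ 0 and one ≤ 0, since the mean lies within the count range.
* **Pseudo-count.** `PS` bounds the score for zero counts (a zero-count
  genus floors at `-log2((N̄+PS)/PS)`) and shrinks scores of rare
  signatures toward 0. `PS = 0` is allowed only when no count is zero.
* **Rounding.** Reported scores round to 2 decimals, halves away from zero
  (`round_half_away()`), with an ASCII hyphen for negatives in rendered
  tables; rendered cells are `"score(count)"` and `parse_odds_table()`
  inverts them exactly.
* **Category labels** (biodefense / signaling / metabolism) are curated
  input, not computed — no rule derives them from the annotation.

No significance test is attached: the score is a descriptive effect size,
and birth–death family modeling is out of scope.

## Single-genus ("multiplied") clusters

On a rooted, genus-labelled tree, a multiplied cluster is a *maximal* clade
whose leaves all carry one genus and number at least `min_size = 2` — a
singleton leaf is not evidence of duplication, and reporting only maximal
clades keeps leaf sets disjoint and fractions ≤ 1. The per-genus multiplied
fraction is the share of that genus's leaves inside such clusters, printed
as an integer percentage (halves away from zero).

Unrooted trees are rejected rather than silently rooted; `midpoint_root()`
(longest leaf-to-leaf path, via phangorn) is the offered remedy when no
outgroup is designated. Collapsing weakly supported internal nodes into
polytomies before extraction is available (`collapse_below`) but **off by
default**: publications often state bootstrap values without stating a
collapse rule, and inventing a threshold silently would change reported
fractions. Whether published percentages count leaves or clusters is equally
unstated; leaf counting is implemented and recorded in the result object.

The extraction is a linear-time postorder sweep (propagating single-genus
status up the tree); tests verify it against an exhaustive enumeration of
every internal node's clade on 200 random trees.

## Domain architecture

RIP typing and Venn partitioning are pure set algebra over per-gene domain
sets: presence means ≥ 1 annotation record for the signature, any
coordinates, any E-value that survived upstream filtering (the upstream
domain scan provides presence/absence only). Type II = RIP domain plus ricin
B-like lectin domain; type I = RIP without lectin; genes without the RIP
domain are not RIPs. The two Venn signature ids are configuration, not
hard-coded, because cross-database id mappings (e.g. CDD domain names to
InterPro accessions) are curation.

## Synthetic data: what it emulates, and what it does not

The generators produce every input with attached ground truth:

* `simulate_kmer_histogram()` superimposes a geometric error component
  (mass `error_mass`, default 2× the genome size; retention `error_decay`
  0.5), a Poisson hump at coverage *C* carrying the unique genome fraction,
  and a Poisson hump at 2*C* carrying the two-copy repeat fraction, plus
  per-bin Poisson noise. Expected k-mer mass beyond the trough is exactly
  `genome_size * C`, so the spectrum estimator is unbiased by construction.
  It does **not** model heterozygosity (no *C*/2 peak), higher-order repeat
  copy numbers, or GC-coverage bias — passing recovery tests says the
  estimator arithmetic is right, not that real heterozygous genomes are this
  clean.
* `simulate_annotations()` draws baseline counts per (genus, signature) from
  a shared Poisson rate (negative binomial behind `dispersion` for
  overdispersion) and multiplies planted cells by a fold. Poisson was chosen
  over negative binomial as the default for simplicity: the odds score
  operates on the counts themselves, not on their variance structure.
  Duplicate-hit noise exercises gene-level deduplication without touching
  the truth matrix.
* `simulate_genus_tree()` builds the truth *by construction*, not by
  birth–death simulation: each genus's planted share of leaves forms one
  clade and the remaining leaves are interleaved along a caterpillar
  backbone where only prefixes are clades, with the two deepest positions
  forced to different genera, so no unplanned single-genus clade of size ≥ 2
  can arise. Recovery tests are therefore exact equalities, not statistical
  checks. Real TE trees, with their uncertain topologies and support values,
  are messier than this.

All generators are deterministic given `seed`.

## Problem sizes and numerical conventions

The test suite runs the genome-size recovery at a 1 Mb toy genome over a
20-case grid (coverage 30 and 44, repeat fraction up to 0.3, Poisson noise),
recovering size within 5%; the clade-enumeration equivalence uses 200 random
trees of 4–12 leaves; the set-algebra oracles use 500-gene profiles over 20
seeds; the planted-landscape check uses 5,000 TE genes. These sizes were
chosen so each property is exercised well past its edge cases while the full
suite stays fast enough to run habitually. Recovery in the spectrum suite
uses `smooth = 5`, the intended guard for Poisson-noisy bins near the
trough.

Throughout: protein coordinates are 1-based inclusive; interval unions merge
book-ended runs; all reported rounding is half away from zero; ordering
tie-breaks (smaller depth, longer span, lexicographic labels) are fixed so
identical inputs give byte-identical outputs, which `run_pipeline()` asserts
by writing a manifest (parameters, seed, input digests) alongside the
reports.

## Known limitations

* The k-mer model has no heterozygosity or ploidy mixture; spectra from
  highly heterozygous genomes need a mixture-model tool instead.
* Accumulation scores measure protein-span occupancy, not nucleotide-level
  genomic masking; they are comparable across clades within a genome, not an
  absolute repeat content.
* The odds score has no attached significance; with few genera the
  cross-genus mean is noisy and `PS` dominates small counts.
* Cluster extraction trusts the input topology; low-support resolution
  inflates multiplied fractions unless `collapse_below` is used.
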