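---
title: "Matrilineal diversity analysis of cattle mitogenomes with mitohap"
author: "mitohap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matrilineal diversity analysis of cattle mitogenomes with mitohap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitohap)
```

## Scope and model

`mitohap` analyzes cohorts of complete mitochondrial genomes that have
already been assembled and placed in a common reference coordinate frame
(for cattle, 1-based "np" positions on the bovine reference sequence).
Because the mitochondrion is maternally inherited and non-recombining,
each animal's mitogenome is a single haplotype, and the population
structure of a breed's maternal lines is summarized by four linked
analyses, which the package implements as composable steps:

1. **Haplotype collapsing and Nei diversity statistics** — identical
   sequences (over the analyzed sites) form one haplotype; the cohort is
   summarized by the number of variable sites *S* (split into singletons
   and parsimony-informative sites), the haplotype count *H*, Nei's
   haplotype diversity *Hd*, the mean number of pairwise differences *k*,
   and the nucleotide diversity *Pi = k / L*.
2. **Sliding-window diversity scan** — *Pi* per window of reference
   positions, which localizes hypervariable regions; in cattle mtDNA the
   peak is expected in the D-loop (control region).
3. **Diagnostic-motif haplogroup classification** — cattle matrilines
   fall into two deeply divergent clades, taurine (T) and indicine (I),
   subdivided into haplogroups (T1–T6, I1, I2) defined by diagnostic
   substitutions relative to the reference. The classifier assigns
   clade, haplogroup and sub-haplogroup, and flags sequences that match
   a clade but no known haplogroup motif as novel matrilines.
4. **Phylogeny and network** — a neighbor-joining tree over haplotypes
   with column-resampling bootstrap supports, and a median-joining
   network whose edges are labelled with the mutated positions and whose
   unobserved intermediates ("median vectors") are inferred.

A seeded synthetic cohort generator produces alignments with known
haplogroup structure so that every stage can be validated against ground
truth without downloading sequence archives.

## Site filtering and coordinates

All statistics operate on the *usable* columns selected by
`build_site_index()`. The default policy is **complete deletion**: any
column containing a gap or an `N` in any sample is excluded. This is the
convention of the classical diversity software for which results such as
"405 variable sites" are typically reported, and it makes per-column
arithmetic exact (every usable column is observed in all *n* samples).
Pairwise deletion is available as an option; under it, each column is
normalized by its own number of valid sample pairs. Columns inserted
relative to the reference (gap in the reference row) carry no np
coordinate and are excluded from motif matching and from the scan.
Mitogenome circularity is ignored: all coordinates are linear np values.

## Diversity estimators

Let $p_i = n_i/n$ be haplotype frequencies. The package uses Nei's
small-sample estimator

$$Hd = \frac{n}{n-1}\Bigl(1 - \sum_i p_i^2\Bigr)$$

with the Nei (1987) sampling variance
$V(Hd) = \frac{2}{n(n-1)}\bigl[2(n-2)(\sum p_i^3 - (\sum p_i^2)^2) +
\sum p_i^2 - (\sum p_i^2)^2\bigr]$, reported as an SD. The mean pairwise
difference $k$ is computed in $O(nL)$ from per-column base counts
(at a usable column with counts $n_b$, the number of mismatching pairs
is $\binom{n}{2} - \sum_b \binom{n_b}{2}$), which equals the brute-force
double loop over all pairs exactly; the tests enforce this equivalence,
and also the equivalence with the haplotype-frequency-weighted route.
$Pi = k/L$ over the usable sites, with the Nei (1987) eq. 10.7 variance
(stochastic plus sampling terms) reported as its SD. Variable-site
classification is at column level — a column is parsimony informative
iff at least two bases each occur in at least two samples, singleton
otherwise — so the split is additive: $S = \text{singletons} +
\text{informative}$, including multiallelic columns.

The sliding-window scan defaults to 200 np windows moved by 25 np.
These values are a package convention (fine enough to localize a ~400 np
control-region peak, wide enough that a window holds several usable
sites); both are parameters. Windows with no usable site report `Pi =
NA` rather than zero, so alignment gaps are not mistaken for conserved
regions.

## The motif classifier

The packaged motif table (`default_motif_table()`) follows the cattle
haplogroup scheme with two design choices worth spelling out:

* **Backbone haplogroups.** The reference backbone *is* a T3 sequence,
  so T3 has no derived diagnostic variants; symmetrically I1, the most
  common indicine haplogroup, is modelled as the indicine backbone
  (diagnosed by the clade-divergence motif alone). The backbone's match
  score is the fraction of *reference* alleles over the union of the
  other in-clade motifs' positions, so a T1 sequence does not also score
  1 for T3.
* **Clade assignment.** One clade-divergence motif of 233 positions
  separates the two clades; the indicine score is the fraction of
  derived alleles, the taurine score the fraction of reference alleles
  at those positions. The count mirrors the mutational separation of
  the two clusters in the published haplotype network, so the synthetic
  cohorts reproduce that large-scale structure.

Only the T6 motif (12 positions) and the I1a motif (5 positions, nested
in I1) are published coordinates. The clade-divergence set and the
remaining haplogroup motifs are synthetic stand-ins, and the published
positions come without ref/alt bases, so the table assigns alleles
deterministically (derived allele = transition of the reference base,
the dominant substitution class in mammalian mtDNA). The packaged table
is therefore suitable for the synthetic reference frame; real-data use
against the bovine reference requires regenerating the alleles from that
sequence, which `load_motif_table()` supports via the documented TSV
format.

A haplogroup label is accepted when at least 80% of its assessable
diagnostic alleles match (N or gap at a diagnostic position is dropped
from both numerator and denominator). Ties are broken toward the motif
with more assessable positions, then lexicographically, and recorded in
the call. A sub-haplogroup label additionally requires its full motif.
Two situations yield `"<clade>-novel"`: no in-clade motif reaches the
threshold, or the best match is the clade backbone while the sequence
carries at least `novel_min_private = 10` derived variants outside all
known diagnostic positions. The second rule exists because a pure
threshold test can never reject a zero-variant backbone; the historical
novel-haplogroup discovery — two animals matching the taurine backbone
except for 12 unexplained substitutions — is exactly this situation, and
the default of 10 is set just below that count. `detect_novel()` then
reports each flagged sequence's unexplained derived positions, the same
style in which novel motifs are published.

## Tree and network

NJ agglomeration, rooting and bipartition counting are delegated to
`ape`; distances default to raw pairwise differences (no substitution
model), matching the usual practice for within-species mitogenome trees.
Bootstrap supports resample usable columns with replacement; since only
variable columns can change a Hamming distance, each replicate's
distance matrix is computed as a matrix–vector product over
precomputed per-pair difference indicators, which is exactly equivalent
to rebuilding from the resampled alignment. Supports are reported as
percentages on internal nodes and written into the Newick output.

The median-joining network is implemented in the package (no installed R
package provides it): an $\varepsilon$-relaxed minimum spanning network —
edge $(u,v)$ is feasible iff $d(u,v) \le \text{bottleneck}(u,v) +
\varepsilon$, with bottleneck distances read off a minimum spanning
tree — alternating with median-vector proposal (column-wise majority of
connected triples, ties resolved toward the first node in label order)
and pruning of median vectors whose degree falls below 3. With
$\varepsilon = 0$ (the default, also the classical default) the
haplotype subgraph contains a union of minimum spanning trees, so the
network attains the MST weight; raising $\varepsilon$ only ever adds
feasible links. All characters carry equal weight. Post-processing
heuristics of the desktop NETWORK program (star contraction, frequency
criteria) are out of scope.

## The synthetic generator

`synthetic_config()` defaults describe the emulated study: 129 animals
split T1:19, T2:5, T3:37, T4:7, T6:2, I1:54, I2:5 across the seven
observed haplogroups, collapsing to 47 haplotype templates
(T1:7, T2:2, T3:12, T4:3, T6:1, I1:19, I2:3 — T6 deliberately a single
haplotype carried by two animals), with 18 I1a animals in 6 templates
forming the star-like sub-cluster. The per-template private-mutation
count is Poisson with mean 3 — chosen, together with the template
counts, to give realistic singleton/informative proportions at this
cohort size — drawn over a 16,338 np frame with a 20× rate multiplier
inside the np 15909–16315 hotspot (the control-region interval), with a
10:1 transition:transversion ratio. The sub-haplogroup allocation is a
package choice (about a third of I1) since no per-sub-haplogroup count
is published. Sample-to-template allocation is a random composition, so
haplotype frequencies are skewed as in real cohorts. Private mutations
avoid diagnostic positions by default, keeping classification ground
truth exact; a collision mode exists for robustness testing. An
optional indel mode inserts 1–2 gap columns in the hotspot to emulate
small alignment length variation; there is no indel simulation
otherwise, and no coalescent realism — the generator plants structure,
it does not simulate genealogies. Fixed seeds give byte-identical
cohorts and fixtures.

What passing tests on these cohorts demonstrate, and what they do not:
recovery of planted haplogroup structure, haplotype counts, hotspot
location and cluster separation shows the estimators and the classifier
are correct *given* the model above. Real mitogenomes add alignment
error, ambiguous bases, heteroplasmy, recurrent mutation at hypervariable
sites and motif definitions whose alleles must be taken from the real
reference — none of which the generator emulates.

## Numerical conventions and degenerate inputs

Percentages in frequency tables are `100 * count / n` rounded half away
from zero to 2 decimals, the convention of printed frequency reports.
Haplotype labels `H1…Hk` are assigned by descending count, ties by first
occurrence; published haplotype labels follow unstated schemes and are
not reproduced. Cohorts need $n \ge 2$ for diversity statistics, 3+
haplotypes for a tree; zero variable sites make bootstrap supports 0
with a warning; a breed with one sample is reported with `NA`
statistics. Pipeline outputs are never overwritten unless requested,
and each run writes a JSON manifest with input checksums and the seed.

## Problem sizes

The shipped analysis scripts and tests run on full-scale cohorts
(129 × 16,338) for the headline numbers, and on a 400 np mini frame with
a proportionally scaled motif table for the many per-operation checks;
the hotspot-recovery experiment uses 100 seeded full-scale replicates.
These sizes were chosen so the complete workflow re-runs in a few
minutes on a laptop while still exercising the estimators at the
magnitudes where their results are interpreted.
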