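# mitohap

Matrilineal diversity and haplogroup analysis of cattle mitogenomes.

`mitohap` is for population geneticists who work with cohorts of complete
mitochondrial genomes — typically a breed survey in which every animal's
mitogenome has been assembled and aligned to a common reference frame —
and who need the standard matrilineal analyses as reproducible, tested
code rather than a chain of desktop programs:

* **Haplotype collapsing and Nei diversity statistics.** Identical
  sequences over the analyzed sites form one haplotype. The cohort is
  summarized by the number of variable sites *S* (singletons +
  parsimony-informative), haplotype count *H*, haplotype diversity
  *Hd = n(1 − Σpᵢ²)/(n − 1)* with Nei's sampling SD, the mean number of
  pairwise differences *k*, and nucleotide diversity *Pi = k/L*, under a
  complete-deletion site policy (pairwise deletion optional).
* **Sliding-window diversity scan** to localize hypervariable regions
  such as the D-loop/control region.
* **Diagnostic-motif haplogroup classification.** Cattle matrilines split
  into the taurine (T) and indicine (I) clades with haplogroups T1–T6 and
  I1/I2 defined by diagnostic substitutions at published np positions
  (1-based reference coordinates), including the 12-mutation T6 motif and
  the 5-mutation I1a sub-haplogroup motif. Sequences matching a clade but
  no known haplogroup motif are flagged as novel matrilines, with their
  unexplained derived variants listed.
* **Neighbor-joining tree** over haplotypes with column-resampling
  bootstrap supports (via `ape`), written as Newick.
* **Median-joining network** (Bandelt relaxed minimum-spanning network
  with majority-consensus median vectors, implemented in the package)
  with mutation-labelled edges and frequency-annotated nodes.
* **Synthetic cohort generator**: seeded mitogenome cohorts with known
  haplogroup composition, haplotype templates, private mutations, a
  control-region mutation hotspot and ground-truth tables, so the whole
  pipeline is testable without sequence downloads.

## Worked example

A small synthetic demo cohort (24 animals, 400 np frame, scaled-down
motif table) ships with the package:

```r
library(mitohap)
demo <- system.file("extdata", "synthetic_demo", package = "mitohap")
tb  <- load_motif_table(file.path(demo, "motifs.tsv"), ref_length = 400L)
ref <- as.character(Biostrings::readBStringSet(
  file.path(demo, "reference.fasta"))[[1]])
aln <- read_alignment(file.path(demo, "alignment.fasta"),
                      file.path(demo, "breeds.tsv"), ref_seq = ref)
idx <- build_site_index(aln)
diversity_stats(aln, idx)
#> S=57 (singletons 17, informative 40)  H=24  k=15.333
#> Hd=1.000 +/- 0.012  Pi=0.03833 +/- 0.01978  (L=400 sites)

calls <- classify_cohort(aln, tb)
subset(haplogroup_frequencies(calls), level == "haplogroup")
#>   breed      level label count  n   pct
#> 1   all haplogroup    I1     6 24 25.00
#> 2   all haplogroup    I2     3 24 12.50
#> 3   all haplogroup    T1     4 24 16.67
#> 4   all haplogroup    T2     2 24  8.33
#> 5   all haplogroup    T3     5 24 20.83
#> 6   all haplogroup    T4     2 24  8.33
#> 7   all haplogroup    T6     2 24  8.33

median_joining(collapse_haplotypes(aln, idx))
#> haplo_network: 24 haplotypes + 1 median vectors; 24 edges (epsilon = 0)
```

Every animal's haplotype is distinct here (Hd = 1 at n = 24), all 24
labels match the generator's ground truth in `truth.tsv`, and the
network links the two clades through the planted 20-mutation clade
divergence. `run_pipeline(run_config(...))` runs all stages at once and
writes the report, calls, profile, Newick tree, network tables, FASTA
haplotype representatives and a JSON run manifest into an output
directory.

## The analysis workflow

`analysis/` contains the numbered drivers that re-run the full study on
a seeded synthetic cohort emulating the published sampling (129 animals,
haplogroups T1:19, T2:5, T3:37, T4:7, T6:2, I1:54, I2:5, 47 haplotype
templates, hotspot np 15909–16315):

```sh
Rscript analysis/01_simulate_cohort.R   # cohorts + fixtures under results/cohort/
Rscript analysis/02_diversity.R         # Table-style report + window scan
Rscript analysis/03_haplogroups.R       # calls, frequencies, T6 rediscovery
Rscript analysis/04_phylogeny_network.R # NJ tree (1000 bootstraps) + MJ network
```

On the default seed the workflow prints, among others: `S=428 (37
singletons, 391 informative), H=47, Hd=0.978 +/- 0.003`, `k=128.259,
Pi=0.00785`, a diversity peak inside the hotspot, haplogroup frequencies
`I1 41.86% … T3 28.68% … T1 14.73%`, a taurine/indicine network
separation of 233 mutations, and — after removing the T6 motif from the
table — exactly the 2 carrier animals flagged as a novel taurine
matriline.

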