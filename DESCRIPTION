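Package: mitohap
Title: Matrilineal Diversity and Haplogroup Analysis of Cattle Mitogenomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for matrilineal population analysis of aligned complete
    mitochondrial genomes: haplotype collapsing, Nei haplotype and nucleotide
    diversity with sampling standard deviations, sliding-window diversity
    scans, diagnostic-motif haplogroup classification for cattle (taurine
    T1-T6 and indicine I1/I2, including the T6 and I1a motifs), detection of
    novel divergent matrilines, neighbor-joining trees with bootstrap
    supports, and median-joining haplotype networks. Includes a seeded
    synthetic mitogenome cohort generator with known haplogroup structure,
    private mutations and a hypervariable control-region hotspot, so the
    whole pipeline can be exercised and validated without sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
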