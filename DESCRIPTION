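Package: tescreen
Title: Transposable-Element Misannotation Screening for Genome Gene Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects transposable-element (TE) misannotation in genome gene
    sets and performs the supporting annotation-hygiene steps of a genome
    annotation project. Classifies genes by TE- and PCWDE-associated Pfam
    domain keywords, estimates per-gene genomic copy number by merging
    tabular similarity hits under identity and distance thresholds, audits
    copies for premature stop codons, and produces TE-adjusted species gene
    counts. Also resolves overlapping repeat annotations by 50/50 and
    25/50/25 splitting rules, scans sequences for microsatellite (SSR)
    arrays with per-period unit thresholds, filters TE-dominated
    transcripts, clusters mapped transcripts into loci with
    representative-transcript selection, extrapolates maximum gene counts
    from BUSCO completeness, and flags X-chromosome candidates from
    male/female normalized read-coverage ratios. A seeded synthetic-data
    generator emits truth-labelled genomes, annotations, hit tables and
    coverage tracks so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    methods,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
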