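# tescreen

Screening genome gene sets for transposable-element (TE) misannotation,
with the annotation-hygiene steps that surround the screen in a genome
annotation project.

## The problem

Annotation pipelines routinely emit transposable elements as
protein-coding genes: TEs carry ORFs (transposase, reverse transcriptase,
integrase, gag), and when repeats are incompletely masked, a genome can
appear to have thousands more genes than its relatives. `tescreen`
implements a screen for this artefact built on two signatures that
separate misannotated TEs from real genes — dispersed genomic copy number
and decayed coding sequence — together with the supporting computations of
an annotation workflow:

* **Domain-keyword classification** — genes are classed `TE-domain`,
  `PCWDE` (plant cell wall-degrading enzyme) or `other` by
  case-insensitive substring search over Pfam domain names
  (TE set: DDE, hAT, integrase, RVT, MULE, Retrotrans, rve, gag, Tnp,
  Helitron, THAP).
* **Copy-number estimation** — tabular similarity hits of ≥ 50 aa are
  merged per scaffold by single linkage at gap ≤ *d*, for the grid of
  identity ∈ {50, 75} % × *d* ∈ {20, 50} kb; each merged region is one
  genomic copy.
* **Stop-codon audit** — each copy's supporting hit spans are translated
  (frame 0, strand-aware); copies with internal stops are flagged and
  per-gene stop fractions compared between TE-domain genes and the 12
  largest non-TE control families.
* **Adjusted gene counts** — with *T* total genes, *F* functionally
  annotated and *k* TE-domain genes among them, the expected TE-derived
  total is *k·T/F* and the adjusted count *T − k·T/F*.
* **Annotation hygiene** — repeat-overlap resolution (50/50 partial,
  25/50/25 containment splits), SSR scanning (unit minima 6/4/3/3/3 for
  periods 2–6, single-nucleotide bridges), TE-transcript filtering
  (≥ 50 % TE coverage removed), locus building with
  representative-transcript selection (ORF completeness, then ORF
  length), BUSCO-based maximum-gene-count extrapolation
  (`round(n_loci × busco_txome / busco_loci)`), and X-chromosome
  detection from male/female normalized read-coverage ratios.
* **Synthetic data** — a seeded generator (`simulate_dataset()`) plants
  repeat families, gene families with known copy numbers and stop
  fractions, SSR arrays, domain tables, truth-consistent hit tables and
  Poisson coverage tracks, so every stage is testable without downloads.

## Worked example

```r
library(tescreen)

cfg <- sim_config(seed = 101)        # 4 scaffolds, planted TE gene families
sim <- simulate_dataset(cfg)

## classify genes by domain keywords
cl <- classify_genes(sim$domain_table, all_genes = sim$genes$gene_id)
table(cl$class)
#>       other   TE-domain unannotated
#>           8           1           5

## copy numbers under the standard parameter grid
ct <- copy_number_table(sim$hits, sim$genes$gene_id)
ct[ct$gene_id == "gene_te_1", c("min_identity", "max_gap", "copy_count")]
#>    min_identity max_gap copy_count
#> 49           50   20000          5
#> 50           75   20000          5
#> 51           50   50000          5
#> 52           75   50000          5

## stop-codon audit at 50% / 20 kb
aud <- audit_stop_codons(ct[ct$min_identity == 50 & ct$max_gap == 20000, ],
                         sim$genome, sim$hits)
aud$genes[aud$genes$gene_id %in% c("gene_te_1", "gene_neutral_01"),
          c("gene_id", "n_copies", "n_stop_flagged", "stop_fraction")]
#>            gene_id n_copies n_stop_flagged stop_fraction
#> 1  gene_neutral_01        1              0           0.0
#> 13       gene_te_1        5              2           0.4

## TE-adjusted species gene count
adjust_gene_count(total_genes = nrow(sim$genes),
                  annotated = sum(cl$class != "unannotated"),
                  te_domain_genes = sum(cl$class == "TE-domain"))
#>   total_genes annotated te_domain_genes expected_te_total adjusted_genes
#> 1          14         9               1          1.555556       12.44444

## X-chromosome candidate from coverage ratios
lens <- setNames(Biostrings::width(sim$genome), names(sim$genome))
call_x_candidates(normalize_coverage(sim$depth_female, sim$depth_male, lens))
#> [1] "scaffold_4"

## BUSCO-based maximum gene count
max_gene_count(13354, 95.1, 97.2)
#> [1] 13649
```

The planted truth is recovered exactly: `gene_te_1` was simulated with 5
genomic copies, 2 of them carrying a premature stop (fraction 0.4), and
`scaffold_4` was simulated at half male depth.

## Scope

The package consumes standard outputs of upstream tools (repeat
annotations, transcript-to-genome GFF3, tabular similarity hits,
functional-annotation domain tables, orthogroup count matrices, depth
dumps); it does not run assembly, repeat discovery, alignment, ORF
prediction, orthology inference or functional annotation itself.
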