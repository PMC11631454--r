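---
title: "Screening gene sets for transposable-element misannotation"
author: "tescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening gene sets for transposable-element misannotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tescreen)
```

## The problem

Annotated gene counts vary wildly across related genomes — in beetles,
sibling lineages differ by thousands of "genes". Part of that variation is
biology (gene family birth and death), but part is artefact: interspersed
transposable elements (TEs) carry open reading frames (transposase,
reverse transcriptase, integrase, gag), and annotation pipelines routinely
emit them as protein-coding genes. A genome with poorly masked repeats can
therefore appear to have a dramatically expanded gene complement.

`tescreen` implements a screen for this artefact, plus the
annotation-hygiene steps that surround it in a genome-annotation project.
The screen rests on two signatures that distinguish a misannotated TE from
a real gene:

1. **Copy number.** A real gene typically aligns to a handful of genomic
   loci; a TE-derived "gene" aligns to tens or hundreds of dispersed
   copies.
2. **Coding integrity.** Most genomic copies of a TE are decayed and carry
   premature stop codons; copies of a real gene family mostly do not.

## The screen, step by step

**Classification** (`classify_genes()`). Genes are classed by
case-insensitive substring search of TE-associated keywords over their
Pfam domain names (`DDE`, `hAT`, `integrase`, `RVT`, `MULE`,
`Retrotrans`, `rve`, `gag`, `Tnp`, `Helitron`, `THAP`), with a parallel
set for plant cell wall-degrading enzymes (`Pectinesterase`,
`Glyco_hydro`, `PL4`). Substring matching can hit incidentally (`gag`
inside an unrelated name), which is why the sets are user-overridable and
the matched keywords are reported per gene.

**Copy number** (`estimate_copy_number()`, `copy_number_table()`). From a
tabular protein-vs-genome similarity search, hits of at least
`min_aln_aa = 50` amino acids and at least `min_identity` percent identity
are merged per scaffold by single linkage whenever the gap between them is
at most `max_gap`; each merged region counts as one copy. The standard
grid crosses identity 50/75&nbsp;% with gap 20/50&nbsp;kb. Two invariants
hold on any input and are property-tested: raising the identity threshold
or the merge distance can only lower the count. Merging is
strand-agnostic, and regions are computed per query gene independently —
overlapping regions of different genes are not deduplicated, because the
statistic is per-gene copy number, not genome TE content.

**Stop-codon audit** (`audit_stop_codons()`). For each supporting hit of a
copy region the genomic span is extracted, reverse-complemented for
minus-strand hits, and translated in frame&nbsp;0 of the span; a copy is
flagged when any supporting hit contains an internal stop (terminal stops
are ignored). Frame&nbsp;0 of the hit span is a proxy — the tabular hit
dialect carries no frame column — but it is applied identically to TE and
control genes, so the *comparison* between groups remains valid even
where individual calls are conservative.

**Controls** (`select_control_families()`). The contrast group is the 12
non-TE families with the highest mean gene count across species in an
orthogroup count matrix (ties broken by family id), i.e. large *bona
fide* families, which is the hard case for the copy-number signature.

**Adjusted counts** (`adjust_gene_count()`). With $T$ total genes, $F$
functionally annotated genes and $k$ TE-domain genes among them, the
expected TE-derived total is $k \cdot T / F$ and the adjusted count is
$T - kT/F$. The extrapolation assumes TE-derived genes occur among
unannotated genes at the same rate as among annotated ones; that
assumption is stated here once and flagged in the output columns rather
than hidden.

## Annotation hygiene around the screen

**Repeat-overlap resolution** (`resolve_overlaps()`). Overlapping repeat
annotations are split so that every base is counted once: partial
overlaps 50/50 at the overlap midpoint, full containments 25/50/25 with
the outer quarters of the contained span going to the larger (by original
annotated length) repeat. Decisions the rule itself does not fix are made
deterministically: an odd overlap gives its extra base to the
earlier-starting repeat; 25/50/25 boundaries sit at
$\lfloor L/4 \rfloor$ and $L - \lfloor L/4 \rfloor$ so the outer segments
stay equal; identical spans keep the first annotation; chains of more
than two overlapping repeats are resolved pairwise against the running
resolved set after sorting by (start, −length). The implementation is
checked base-for-base against a painting oracle on random instances, with
exact base conservation.

**SSR scanning** (`scan_ssrs()`). An SSR is a chain of perfect unit runs
of one 2–6&nbsp;nt motif in which runs may be bridged by exactly one
nucleotide; two adjacent non-motif bases (or any `N`) terminate the
array. Unit minima are 6 (di), 4 (tri) and 3 (tetra/penta/hexa);
interruptions do not count toward the tally. Motifs are reported as their
smallest rotation, and arrays whose motif is a repetition of a shorter
word are reported at the shorter period only (so homopolymers are never
SSRs here). One selection rule deserves its rationale spelled out: when
calls of different periods overlap at a locus, the call with fewer
interruptions wins first, and only then the smaller period. Preferring
the smaller period unconditionally looks natural but is degenerate under
the 1-nt-bridge rule — any perfect $(p{+}1)$-mer array also chains as an
interrupted $p$-mer (`abcde abcde abcde` = `abcd·e·abcd·e·abcd`), so no
perfect penta- or hexanucleotide array could ever be reported at its true
period. Likewise, an array whose span is contained in a longer
same-period chain of a different phase is not reported separately.

**Transcript filtering and locus building** (`filter_te_transcripts()`,
`cluster_loci()`, `select_main_transcript()`). Transcripts whose merged
TE-library hit coverage reaches 50&nbsp;% of the spliced length
(inclusive) are removed; the denominator is the spliced transcript
length because the filter runs on assembled transcripts before mapping.
Loci are single-linkage components of exon overlap (default) or span
overlap, stranded by default — exon overlap is the stricter and
biologically safer linkage, and both are exposed because either choice is
defensible. Each locus's representative is chosen by ORF completeness
class (both ends &gt; one &gt; none, ignoring which end is missing), then
ORF length, then transcript id — a total order, so the choice is
permutation-invariant.

**BUSCO extrapolation** (`max_gene_count()`, `busco_total()`). The
maximum plausible gene count scales the locus count by the ratio of
transcriptome to locus-set BUSCO total completeness, rounding half away
from zero: `max_gene_count(13354, 95.1, 97.2)` returns 13&nbsp;649.

**X detection** (`normalize_coverage()`, `call_x_candidates()`). Scaffold
mean depths are normalized by the sample's length-weighted genome-wide
mean over scaffolds of at least 100&nbsp;kb (small repeat-rich scaffolds
distort the mean; positions absent from a zero-suppressed depth dump
count as zero). Under an XY system the X sits near male/female ratio 0.5
against 1.0 for autosomes; the default flagging rule — ratio at most
0.75 with female normalized depth inside [0.8, 1.25] — is the midpoint
between those expectations, an engineering default rather than a
published cutoff, and both knobs are arguments. Note that normalization
includes the X in the male genome-wide mean, so the observed ratio on a
genuine X sits slightly above 0.5 (≈0.55 when the X is ~18&nbsp;% of the
genome).

## The synthetic-data generator

Every stage is tested against `simulate_dataset()`, which plants truth:
uniform-random scaffolds carrying interspersed-repeat families
(consensus copies mutated at a set divergence), gene families with a
chosen number of genomic copies, divergence and premature-stop fraction
(one internal in-frame `TAA`; clean copies are repaired so mutation never
introduces an accidental stop), microsatellite arrays padded with a
letter absent from the motif, a domain table covering a fixed fraction of
genes, a hit table emitted from truth (one row per planted copy, identity
$100(1-d)$ plus small noise), and windowed Poisson coverage tracks with
the X scaffold at a set male ratio. All randomness flows from one seed;
identical configs are byte-identical on disk.

Three generator choices matter for interpreting green tests:

* Hit tables are emitted from truth, not from running an aligner, so
  tests exercise the estimator, not alignment heuristics. An adapter for
  real search output is simply `read_hits()`.
* The annotated subset is chosen as the first $\lfloor f \cdot n \rfloor$
  genes by sorted id *within* each class (TE-derived vs rest). This
  enforces exactly the missing-at-random assumption the $kT/F$
  extrapolation makes, which is deliberate: the end-to-end test is meant
  to verify the adjustment arithmetic under its own assumption, not the
  assumption itself.
* Copy spacing defaults to 60&nbsp;kb for gene families — beyond the
  largest merge distance — so planted copy numbers are recoverable
  exactly. Real TE copies cluster and nest; recovering them is a harder
  problem than these tests certify.

Consequently, passing tests show the computations are correct on data
satisfying the generator's assumptions (uniform background, substitution-
only divergence, non-overlapping planted features, frame-0 hits). They do
not certify behaviour on nested/fragmented repeats, indel-rich
alignments, or GC-heterogeneous genomes.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally everywhere; conversion
  happens only in the readers/writers (GFF3 and tabular hits 1-based
  inclusive, BED as-is; minus-strand subject hits, `s_start > s_end`, are
  normalized to (min, max) plus a strand flag on demand and written back
  as read).
* A gene with no qualifying hits has copy count 0 and is reported, not
  dropped — zeros belong in group means.
* `filter_te_transcripts()` removes at exactly the threshold (coverage
  ≥ 0.5), matching the inclusive phrasing of the rule it implements.
* Stop-audit spans shorter than two codons are skipped rather than
  translated.
* Depth tables may be per-base or windowed; both reduce to scaffold mean
  depth over the full scaffold length.
* Tests run at desk scale: oracle equality on 1000 random interval
  instances and 1000 random 2-kb sequences, 200 random transcript sets,
  simulations with 4 scaffolds of 0.12–0.42 Mb. The full suite runs in
  about two minutes; `scripts/acceptance.R` in well under one.

## Known limitations

* Keyword classification inherits every weakness of substring matching
  over domain names; it is a screen, not a verdict, and candidate genes
  deserve locus-level inspection.
* The copy-number estimator can inflate counts for genuine multi-exon
  genes whose exons fall within the merge distance of paralogues; no
  correction is applied, which is conservative for the TE-vs-control
  contrast (it inflates the control side).
* The stop-codon audit's frame-0 proxy under-detects stops in frames the
  hit does not anchor; group comparisons remain valid, absolute
  stop fractions on real data are lower bounds.
* X calling assumes a male-heterogametic XY system and one sample per
  sex; neo-XY structure and coverage batch effects are out of scope.
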