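## TE-transcript filtering, locus building, representative-transcript
## selection and BUSCO-based gene-count extrapolation.

#' Remove transcripts dominated by transposable-element sequence
#'
#' Merges each transcript's TE-library hit intervals (union on the
#' transcript) and removes transcripts whose merged TE coverage is greater
#' than or equal to `threshold` of the spliced transcript length. The
#' threshold is inclusive.
#'
#' @param transcript_lengths Named numeric vector of spliced transcript
#'   lengths (nt), or a transcript data.frame with `transcript_id` and
#'   `length` columns.
#' @param te_hits Hit table (see [read_hits()]) of transcripts vs a TE
#'   library; `query_id` must name transcripts and `q_start`/`q_end` are
#'   1-based inclusive transcript coordinates.
#' @param threshold Removal threshold on the covered fraction
#'   (default 0.5).
#' @return List with `kept` and `removed` (character vectors of
#'   transcript ids) and `report`, a data.frame with per-transcript
#'   `length`, `covered_bases`, `coverage` and `removed` flag.
#' @export
filter_te_transcripts <- function(transcript_lengths, te_hits,
                                  threshold = 0.5) {
  if (is.data.frame(transcript_lengths)) {
    transcript_lengths <- setNames(transcript_lengths$length,
                                   transcript_lengths$transcript_id)
  }
  if (is.null(names(transcript_lengths))) {
    stop("transcript_lengths must be named by transcript id")
  }
  unknown <- setdiff(unique(te_hits$query_id), names(transcript_lengths))
  if (length(unknown)) {
    stop("hit query id(s) absent from transcript set: ",
         paste(unknown, collapse = ", "))
  }
  covered <- setNames(numeric(length(transcript_lengths)),
                      names(transcript_lengths))
  if (nrow(te_hits) > 0L) {
    qs <- pmin(te_hits$q_start, te_hits$q_end)
    qe <- pmax(te_hits$q_start, te_hits$q_end)
    if (any(qe > transcript_lengths[te_hits$query_id])) {
      stop("hit coordinates exceed transcript length for: ",
           paste(unique(te_hits$query_id[
             qe > transcript_lengths[te_hits$query_id]]), collapse = ", "))
    }
    by_tx <- split(seq_len(nrow(te_hits)), te_hits$query_id)
    for (tx in names(by_tx)) {
      ir <- IRanges::reduce(IRanges::IRanges(qs[by_tx[[tx]]],
                                             qe[by_tx[[tx]]]))
      covered[tx] <- sum(IRanges::width(ir))
    }
  }
  report <- data.frame(
    transcript_id = names(transcript_lengths),
    length = as.numeric(transcript_lengths),
    covered_bases = as.numeric(covered),
    coverage = as.numeric(covered) / as.numeric(transcript_lengths),
    stringsAsFactors = FALSE
  )
  report$removed <- report$coverage >= threshold
  rownames(report) <- NULL
  list(kept = report$transcript_id[!report$removed],
       removed = report$transcript_id[report$removed],
       report = report)
}

## union-find with path compression
.uf_new <- function(n) seq_len(n)
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Cluster mapped transcripts into loci
#'
#' Single-linkage clustering: two transcripts are linked when any pair of
#' their exons overlaps by at least one base (`mode = "exon"`) or when
#' their genomic spans overlap (`mode = "span"`), on the same scaffold and
#' - when `stranded` - the same strand. Loci are the connected components.
#'
#' @param transcripts Transcript data.frame (see [transcript_model()]).
#' @param mode Linkage mode, `"exon"` (default) or `"span"`.
#' @param stranded Require equal strand for linkage (default `TRUE`).
#' @return Data.frame of loci with `locus_id` (deterministic:
#'   `LOC` + rank by scaffold and leftmost start), `scaffold`, `start`,
#'   `end` (envelope of members), `strand` (of the main transcript),
#'   `n_transcripts`, `main_transcript_id`, `n_exons_main` and a
#'   list-column `members` of transcript ids.
#' @export
cluster_loci <- function(transcripts, mode = c("exon", "span"),
                         stranded = TRUE) {
  mode <- match.arg(mode)
  n <- nrow(transcripts)
  if (n == 0L) stop("no transcripts to cluster")
  if (mode == "exon") {
    ex <- do.call(rbind, lapply(seq_len(n), function(i) {
      e <- transcripts$exons[[i]]
      data.frame(i = i, start = e$start, end = e$end)
    }))
  } else {
    ex <- data.frame(i = seq_len(n), start = transcripts$start,
                     end = transcripts$end)
  }
  str <- transcripts$strand[ex$i]
  str[!str %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = transcripts$scaffold[ex$i],
    ranges = IRanges::IRanges(ex$start + 1L, ex$end),
    strand = if (stranded) str else "*")
  ov <- GenomicRanges::findOverlaps(gr, ignore.strand = !stranded,
                                    drop.self = TRUE, drop.redundant = TRUE)
  parent <- .uf_new(n)
  a <- ex$i[S4Vectors::queryHits(ov)]
  b <- ex$i[S4Vectors::subjectHits(ov)]
  for (k in seq_along(a)) {
    ra <- .uf_find(parent, a[k])
    rb <- .uf_find(parent, b[k])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  comp <- vapply(seq_len(n), function(i) .uf_find(parent, i), integer(1))
  groups <- split(seq_len(n), comp)
  loci <- lapply(groups, function(ii) {
    mem <- transcripts[ii, , drop = FALSE]
    main <- select_main_transcript(mem)
    mrow <- mem[mem$transcript_id == main, , drop = FALSE]
    out <- data.frame(scaffold = mem$scaffold[1L],
                      start = min(mem$start), end = max(mem$end),
                      strand = mrow$strand[1L],
                      n_transcripts = nrow(mem),
                      main_transcript_id = main,
                      n_exons_main = mrow$n_exons[1L],
                      stringsAsFactors = FALSE)
    out$members <- list(sort(mem$transcript_id))
    out
  })
  loci <- do.call(rbind, loci)
  loci <- loci[order(loci$scaffold, loci$start, loci$end,
                     loci$main_transcript_id), , drop = FALSE]
  loci <- cbind(data.frame(locus_id = sprintf("LOC%05d",
                                              seq_len(nrow(loci)))),
                loci)
  rownames(loci) <- NULL
  loci
}

#' Select the representative transcript of a locus
#'
#' Ordering: ORF completeness class first (both start and stop codon
#' present, then exactly one, then neither), then ORF length descending,
#' then transcript id ascending as the deterministic tie-break.
#'
#' @param members Transcript data.frame of the locus members (non-empty).
#' @return The selected `transcript_id`.
#' @export
select_main_transcript <- function(members) {
  if (is.null(members) || nrow(members) == 0L) {
    stop("empty member list")
  }
  completeness <- ifelse(is.na(members$orf_has_start), 0L,
                         as.integer(members$orf_has_start)) +
    ifelse(is.na(members$orf_has_stop), 0L,
           as.integer(members$orf_has_stop))
  orf_len <- ifelse(is.na(members$orf_length), 0L, members$orf_length)
  ord <- order(-completeness, -orf_len, members$transcript_id)
  members$transcript_id[ord[1L]]
}

#' Extrapolate the maximum gene count from BUSCO completeness
#'
#' Scales the number of predicted loci by the ratio of the transcriptome's
#' BUSCO total completeness to that of the loci set:
#' `round(n_loci * busco_total_transcriptome / busco_total_loci)`,
#' rounding half away from zero.
#'
#' @param n_loci Number of predicted loci.
#' @param busco_total_loci BUSCO total (complete + fragmented, percent)
#'   of the loci gene set.
#' @param busco_total_transcriptome BUSCO total (percent) of the
#'   transcriptome.
#' @return Integer extrapolated maximum gene count.
#' @examples
#' max_gene_count(13354, 95.1, 97.2)  # 13649
#' @export
max_gene_count <- function(n_loci, busco_total_loci,
                           busco_total_transcriptome) {
  if (busco_total_loci == 0) stop("busco_total_loci must be > 0")
  if (busco_total_loci < 0 || busco_total_transcriptome < 0) {
    stop("BUSCO percentages must be non-negative")
  }
  if (busco_total_loci > busco_total_transcriptome ||
      busco_total_transcriptome > 100) {
    warning("expected 0 < busco_total_loci <= busco_total_transcriptome ",
            "<= 100; computing anyway")
  }
  x <- n_loci * busco_total_transcriptome / busco_total_loci
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' BUSCO total completeness
#'
#' @param complete,fragmented BUSCO complete and fragmented percentages.
#' @return Their sum (percent).
#' @examples
#' busco_total(92.2, 2.9)  # 95.1
#' @export
busco_total <- function(complete, fragmented) {
  stopifnot(complete >= 0, complete <= 100, fragmented >= 0,
            fragmented <= 100)
  if (complete + fragmented > 100) {
    stop("complete + fragmented exceeds 100%")
  }
  complete + fragmented
}

#' Summary statistics over built loci
#'
#' @param loci Locus data.frame from [cluster_loci()].
#' @param transcripts The transcript data.frame the loci were built from.
#' @param scaffold_subset Optional character vector of scaffold ids; the
#'   fraction of loci on these scaffolds is reported.
#' @return List with `n_loci`, `mean_locus_length` (bp, envelope),
#'   `mean_exons_main` (mean exon count of main transcripts),
#'   `fraction_on_subset` (`NA` when no subset given) and `empty` flag.
#' @export
locus_stats <- function(loci, transcripts, scaffold_subset = NULL) {
  if (is.null(loci) || nrow(loci) == 0L) {
    return(list(n_loci = 0L, mean_locus_length = 0, mean_exons_main = 0,
                fraction_on_subset = if (is.null(scaffold_subset)) NA_real_
                                     else 0,
                empty = TRUE))
  }
  list(
    n_loci = nrow(loci),
    mean_locus_length = mean(loci$end - loci$start),
    mean_exons_main = mean(loci$n_exons_main),
    fraction_on_subset = if (is.null(scaffold_subset)) NA_real_ else
      mean(loci$scaffold %in% scaffold_subset),
    empty = FALSE
  )
}
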