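## Readers and writers for the external formats the pipeline touches.
## All genomic coordinates are converted to 0-based half-open on read and
## back to each standard's convention on write:
##   FASTA          - sequence only
##   GFF3           - 1-based inclusive
##   BED6           - 0-based half-open (same as internal)
##   outfmt-6 hits  - 1-based inclusive; s_start > s_end encodes minus strand
##   depth tables   - per-base (1-based position) or windowed (0-based start)

#' Read a FASTA file of genome scaffolds
#'
#' Sequences are case-normalized to upper case and validated against the
#' alphabet `{A,C,G,T,N}`. Duplicate ids (first whitespace-delimited word of
#' the header) and empty sequences are errors.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet] in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(Biostrings::width(seqs) < 1)) {
    stop("empty sequence for id(s): ",
         paste(ids[Biostrings::width(seqs) < 1], collapse = ", "))
  }
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  af <- Biostrings::alphabetFrequency(seqs)
  extra <- af[, setdiff(colnames(af), c("A", "C", "G", "T", "N")), drop = FALSE]
  if (any(rowSums(extra) > 0)) {
    stop("sequence(s) contain letters outside {A,C,G,T,N}: ",
         paste(ids[rowSums(extra) > 0], collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs)) || anyNA(names(seqs))) {
    stop("sequences must be named")
  }
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Read a 12-column tabular similarity-hit file (outfmt-6 dialect)
#'
#' Columns: query id, subject id, percent identity, alignment length
#' (alignment columns; amino acids for protein-vs-genome hits), mismatches,
#' gap opens, query start/end, subject start/end (1-based inclusive;
#' `s_start > s_end` encodes a minus-strand hit and is preserved as read),
#' e-value, bit score. Lines starting with `#` are skipped. Wrong column
#' counts and non-numeric fields are errors reported with their line number.
#'
#' @param path Path to the tab-separated hit table.
#' @return A data.frame with the 12 columns, in file order.
#' @seealso [hit_subject_intervals()] for strand-normalized coordinates.
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    i <- which(nf != 12L)[1L]
    stop(sprintf("line %d: expected 12 tab-separated columns, got %d",
                 lineno[i], nf[i]))
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  num_cols <- c(3:10, 11, 12)
  names(num_cols) <- c("pct_identity", "aln_length", "mismatches",
                       "gap_opens", "q_start", "q_end", "s_start", "s_end",
                       "evalue", "bit_score")
  vals <- lapply(seq_along(num_cols), function(k) {
    v <- suppressWarnings(as.numeric(m[, num_cols[k]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop(sprintf("line %d: non-numeric value '%s' in column %d (%s)",
                   lineno[i], m[i, num_cols[k]], num_cols[k],
                   names(num_cols)[k]))
    }
    v
  })
  names(vals) <- names(num_cols)
  hits <- data.frame(
    query_id = m[, 1L], subject_id = m[, 2L],
    pct_identity = vals$pct_identity,
    aln_length = as.integer(vals$aln_length),
    mismatches = as.integer(vals$mismatches),
    gap_opens = as.integer(vals$gap_opens),
    q_start = as.integer(vals$q_start), q_end = as.integer(vals$q_end),
    s_start = as.integer(vals$s_start), s_end = as.integer(vals$s_end),
    evalue = vals$evalue, bit_score = vals$bit_score,
    stringsAsFactors = FALSE
  )
  if (any(hits$pct_identity < 0 | hits$pct_identity > 100)) {
    stop("percent identity outside [0,100] at line ",
         lineno[which(hits$pct_identity < 0 | hits$pct_identity > 100)[1L]])
  }
  if (any(hits$aln_length < 1L)) {
    stop("alignment length < 1 at line ",
         lineno[which(hits$aln_length < 1L)[1L]])
  }
  hits
}

#' Write a hit table in the 12-column tabular dialect
#'
#' @param hits Data.frame as returned by [read_hits()].
#' @param path Output path.
#' @export
write_hits <- function(hits, path) {
  cols <- c("query_id", "subject_id", "pct_identity", "aln_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start",
            "s_end", "evalue", "bit_score")
  stopifnot(all(cols %in% names(hits)))
  write.table(hits[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Strand-normalized subject coordinates of tabular hits
#'
#' Converts 1-based inclusive subject coordinates (minus strand encoded as
#' `s_start > s_end`) to internal 0-based half-open intervals plus a strand
#' flag.
#'
#' @param hits Data.frame as returned by [read_hits()].
#' @return Data.frame with columns `scaffold`, `start`, `end`, `strand`,
#'   one row per hit, in input order.
#' @export
hit_subject_intervals <- function(hits) {
  data.frame(
    scaffold = hits$subject_id,
    start = pmin(hits$s_start, hits$s_end) - 1L,
    end = pmax(hits$s_start, hits$s_end),
    strand = ifelse(hits$s_start > hits$s_end, "-", "+"),
    stringsAsFactors = FALSE
  )
}

## ---- transcripts (GFF3) ----------------------------------------------------

#' Construct a transcript model
#'
#' The in-memory representation of a mapped transcript: a spliced alignment
#' with exon coordinates plus the ORF summary (completeness flags and
#' length) produced upstream by the ORF caller. Coordinates are 0-based
#' half-open.
#'
#' @param transcript_id,gene_id Identifiers (`gene_id` may be `NA`).
#' @param scaffold Scaffold id.
#' @param exons Data.frame with columns `start`, `end` (0-based half-open);
#'   exons are sorted and must not overlap.
#' @param strand `"+"`, `"-"` or `"."`.
#' @param orf_has_start,orf_has_stop Logical ORF completeness flags.
#' @param orf_length ORF length in nucleotides.
#' @param has_cds Whether a CDS was annotated for the transcript.
#' @return A one-row data.frame with a list-column `exons`; rows from
#'   repeated calls can be combined with `rbind()`.
#' @export
transcript_model <- function(transcript_id, scaffold, exons,
                             strand = "+", gene_id = NA_character_,
                             orf_has_start = NA, orf_has_stop = NA,
                             orf_length = NA_integer_, has_cds = NA) {
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons <- exons[order(exons$start), , drop = FALSE]
  if (any(exons$end <= exons$start)) stop("exon with end <= start")
  if (nrow(exons) > 1 &&
      any(exons$start[-1] < exons$end[-nrow(exons)])) {
    stop("overlapping exons in transcript ", transcript_id)
  }
  len <- sum(exons$end - exons$start)
  if (!is.na(orf_length) && orf_length > len) {
    stop("orf_length exceeds spliced transcript length for ", transcript_id)
  }
  out <- data.frame(
    transcript_id = transcript_id, gene_id = gene_id,
    scaffold = scaffold, start = min(exons$start), end = max(exons$end),
    strand = strand, length = len, n_exons = nrow(exons),
    orf_has_start = orf_has_start, orf_has_stop = orf_has_stop,
    orf_length = as.integer(orf_length), has_cds = has_cds,
    stringsAsFactors = FALSE
  )
  out$exons <- list(exons)
  out
}

#' Read transcript models from a GFF3 file
#'
#' Expects gene/mRNA/exon (and optionally CDS) features with `ID`/`Parent`
#' attributes. Coordinates are converted from GFF3 1-based inclusive to the
#' internal 0-based half-open convention. ORF attributes written by
#' [write_gff3_transcripts()] (`orf_has_start`, `orf_has_stop`,
#' `orf_length` on the mRNA feature) are recovered when present.
#'
#' @param path Path to a GFF3 file.
#' @return Data.frame of transcript models (see [transcript_model()]),
#'   one row per mRNA.
#' @export
read_gff3_transcripts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  typ <- as.character(mc$type)
  ids <- if ("ID" %in% names(mc)) as.character(mc$ID) else rep(NA, length(gr))
  parents <- if ("Parent" %in% names(mc)) {
    vapply(mc$Parent, function(p) if (length(p)) p[[1L]] else NA_character_,
           character(1))
  } else rep(NA_character_, length(gr))

  is_mrna <- typ %in% c("mRNA", "transcript")
  is_exon <- typ == "exon"
  is_cds <- typ == "CDS"
  if (!any(is_mrna)) stop("no mRNA/transcript features in ", path)
  mrna_ids <- ids[is_mrna]
  if (anyNA(mrna_ids)) stop("mRNA feature without ID attribute")
  if (anyDuplicated(mrna_ids)) {
    stop("duplicate mRNA id(s): ",
         paste(unique(mrna_ids[duplicated(mrna_ids)]), collapse = ", "))
  }
  bad <- !(parents[is_exon] %in% mrna_ids)
  if (any(bad)) {
    stop("exon with unknown parent id(s): ",
         paste(unique(parents[is_exon][bad]), collapse = ", "))
  }
  cds_parents <- unique(parents[is_cds])

  orf_attr <- function(name, i) {
    if (name %in% names(mc)) as.character(mc[[name]])[i] else NA_character_
  }
  out <- vector("list", sum(is_mrna))
  mrna_idx <- which(is_mrna)
  for (k in seq_along(mrna_idx)) {
    i <- mrna_idx[k]
    tid <- ids[i]
    ei <- which(is_exon & parents == tid)
    if (length(ei) == 0L) stop("mRNA ", tid, " has no exon children")
    ex <- data.frame(start = GenomicRanges::start(gr)[ei] - 1L,
                     end = GenomicRanges::end(gr)[ei])
    span_start <- GenomicRanges::start(gr)[i] - 1L
    span_end <- GenomicRanges::end(gr)[i]
    if (min(ex$start) < span_start || max(ex$end) > span_end) {
      stop("exon outside mRNA span for ", tid)
    }
    flag <- function(x) if (is.na(x)) NA else x %in% c("1", "true", "TRUE")
    out[[k]] <- transcript_model(
      transcript_id = tid,
      gene_id = parents[i],
      scaffold = as.character(GenomicRanges::seqnames(gr))[i],
      exons = ex,
      strand = as.character(GenomicRanges::strand(gr))[i],
      orf_has_start = flag(orf_attr("orf_has_start", i)),
      orf_has_stop = flag(orf_attr("orf_has_stop", i)),
      orf_length = suppressWarnings(as.integer(orf_attr("orf_length", i))),
      has_cds = tid %in% cds_parents
    )
  }
  do.call(rbind, out)
}

#' Write transcript models to GFF3
#'
#' Emits gene / mRNA / exon (and CDS when `has_cds`) features; ORF summary
#' fields are stored as mRNA attributes so that
#' [read_gff3_transcripts()] round-trips them.
#'
#' @param transcripts Data.frame of transcript models.
#' @param path Output path.
#' @export
write_gff3_transcripts <- function(transcripts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  gff_line <- function(scaf, type, start0, end0, strand, attrs) {
    sprintf("%s\ttescreen\t%s\t%d\t%d\t.\t%s\t.\t%s",
            scaf, type, start0 + 1L, end0, strand, attrs)
  }
  tr <- transcripts[order(transcripts$scaffold, transcripts$start,
                          transcripts$transcript_id), , drop = FALSE]
  gene_ids <- unique(tr$gene_id[!is.na(tr$gene_id)])
  for (g in gene_ids) {
    rows <- tr[!is.na(tr$gene_id) & tr$gene_id == g, , drop = FALSE]
    writeLines(gff_line(rows$scaffold[1L], "gene", min(rows$start),
                        max(rows$end), rows$strand[1L],
                        paste0("ID=", g)), con)
  }
  for (k in seq_len(nrow(tr))) {
    r <- tr[k, ]
    attrs <- paste0("ID=", r$transcript_id)
    if (!is.na(r$gene_id)) attrs <- paste0(attrs, ";Parent=", r$gene_id)
    if (!is.na(r$orf_has_start)) {
      attrs <- paste0(attrs, ";orf_has_start=", as.integer(r$orf_has_start))
    }
    if (!is.na(r$orf_has_stop)) {
      attrs <- paste0(attrs, ";orf_has_stop=", as.integer(r$orf_has_stop))
    }
    if (!is.na(r$orf_length)) {
      attrs <- paste0(attrs, ";orf_length=", r$orf_length)
    }
    writeLines(gff_line(r$scaffold, "mRNA", r$start, r$end, r$strand,
                        attrs), con)
    ex <- r$exons[[1L]]
    for (j in seq_len(nrow(ex))) {
      writeLines(gff_line(r$scaffold, "exon", ex$start[j], ex$end[j],
                          r$strand,
                          sprintf("ID=%s.exon%d;Parent=%s",
                                  r$transcript_id, j, r$transcript_id)),
                 con)
      if (isTRUE(r$has_cds)) {
        writeLines(gff_line(r$scaffold, "CDS", ex$start[j], ex$end[j],
                            r$strand, paste0("Parent=", r$transcript_id)),
                   con)
      }
    }
  }
  invisible(path)
}

## ---- BED6 ------------------------------------------------------------------

#' Read a BED6 file
#'
#' @param path Path to a 6-column BED file (`#` comment lines skipped).
#' @return Data.frame with columns `scaffold`, `start`, `end`, `name`,
#'   `score`, `strand` (coordinates 0-based half-open, as in BED).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#|^track|^browser", lines) & nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    i <- which(nf < 6L)[1L]
    stop(sprintf("line %d: expected >= 6 BED columns, got %d", lineno[i],
                 nf[i]))
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  if (anyNA(start) || anyNA(end)) {
    stop("non-integer BED coordinates at line ",
         lineno[which(is.na(start) | is.na(end))[1L]])
  }
  if (any(end <= start)) {
    stop("BED interval with end <= start at line ",
         lineno[which(end <= start)[1L]])
  }
  data.frame(scaffold = m[, 1L], start = start, end = end, name = m[, 4L],
             score = m[, 5L], strand = m[, 6L], stringsAsFactors = FALSE)
}

#' Write a BED6 file
#'
#' @param bed Data.frame with `scaffold`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @param path Output path.
#' @export
write_bed <- function(bed, path) {
  cols <- c("scaffold", "start", "end", "name", "score", "strand")
  stopifnot(all(cols %in% names(bed)))
  write.table(bed[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- depth, domain and orthogroup tables -----------------------------------

#' Read a read-depth table
#'
#' Two dialects are supported and distinguished by column count: per-base
#' (`scaffold`, 1-based `pos`, `depth`; 3 columns) and windowed
#' (`scaffold`, 0-based half-open `start`, `end`, `mean_depth`; 4 columns).
#'
#' @param path Path to a tab-separated depth table (no header; `#` lines
#'   skipped).
#' @return Data.frame in one of the two layouts above; the windowed layout
#'   is marked with attribute `windowed = TRUE`.
#' @export
read_depth_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  if (!any(keep)) stop("empty depth table: ", path)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- unique(lengths(fields))
  if (length(nf) != 1L || !nf %in% c(3L, 4L)) {
    stop("depth table must have uniformly 3 (per-base) or 4 (windowed) ",
         "columns: ", path)
  }
  m <- matrix(unlist(fields), ncol = nf, byrow = TRUE)
  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) stop("non-numeric ", what, " in depth table ", path)
    v
  }
  if (nf == 3L) {
    out <- data.frame(scaffold = m[, 1L],
                      pos = as.integer(num(2L, "position")),
                      depth = num(3L, "depth"), stringsAsFactors = FALSE)
    attr(out, "windowed") <- FALSE
  } else {
    out <- data.frame(scaffold = m[, 1L],
                      start = as.integer(num(2L, "start")),
                      end = as.integer(num(3L, "end")),
                      mean_depth = num(4L, "depth"),
                      stringsAsFactors = FALSE)
    attr(out, "windowed") <- TRUE
  }
  out
}

#' Write a depth table
#' @param depth Data.frame in either [read_depth_table()] layout.
#' @param path Output path.
#' @export
write_depth_table <- function(depth, path) {
  write.table(depth, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a per-gene domain-annotation table
#'
#' Dialect: `gene_id<TAB>domain1,domain2,...` with one row per annotated
#' gene (functional-annotation output reduced to Pfam domain-name lists).
#'
#' @param path Path to the tab-separated table (`#` lines skipped).
#' @return Data.frame with `gene_id` and list-column `domains`.
#' @export
read_domain_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    i <- which(nf != 2L)[1L]
    stop(sprintf("line %d: expected 2 tab-separated columns, got %d",
                 lineno[i], nf[i]))
  }
  gene <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(gene)) {
    stop("duplicate gene id(s) in domain table: ",
         paste(unique(gene[duplicated(gene)]), collapse = ", "))
  }
  doms <- strsplit(vapply(fields, `[`, character(1), 2L), ",", fixed = TRUE)
  doms <- lapply(doms, trimws)
  out <- data.frame(gene_id = gene, stringsAsFactors = FALSE)
  out$domains <- doms
  out
}

#' Write a per-gene domain-annotation table
#' @param domain_table Data.frame as returned by [read_domain_table()].
#' @param path Output path.
#' @export
write_domain_table <- function(domain_table, path) {
  lines <- paste0(domain_table$gene_id, "\t",
                  vapply(domain_table$domains, paste, character(1),
                         collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read an orthogroup gene-count matrix
#'
#' Dialect: header row with `Orthogroup` followed by one column per
#' species; one row per orthogroup with integer per-species gene counts.
#'
#' @param path Path to the tab-separated matrix.
#' @return Data.frame with character column `orthogroup` and numeric
#'   species columns.
#' @export
read_orthogroup_counts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2L) stop("orthogroup table needs >= 2 columns")
  names(df)[1L] <- "orthogroup"
  for (j in 2:ncol(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(v)) {
      stop("non-numeric count in species column '", names(df)[j], "'")
    }
    df[[j]] <- v
  }
  if (anyDuplicated(df$orthogroup)) stop("duplicate orthogroup id(s)")
  df
}

#' Write an orthogroup gene-count matrix
#' @param counts Data.frame as returned by [read_orthogroup_counts()].
#' @param path Output path.
#' @export
write_orthogroup_counts <- function(counts, path) {
  out <- counts
  names(out)[1L] <- "Orthogroup"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
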