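## The core analysis: keyword classification of genes, hit-based genomic
## copy-number estimation, stop-codon auditing of copies, control-family
## selection, TE-vs-control comparison and TE-adjusted species gene
## counts.

#' Default domain-keyword sets
#'
#' The TE set targets domains characteristic of transposon machinery
#' (transposase, reverse transcriptase, integrase, gag, ...); the PCWDE
#' set targets plant cell wall-degrading enzymes (carbohydrate esterases,
#' glycoside hydrolases and PL4 polysaccharide lyases). Matching is
#' case-insensitive substring over domain names, so incidental hits (e.g.
#' "gag" inside an unrelated name) are possible; override the sets to
#' tighten them.
#'
#' @return Named list of two character vectors, `te` and `pcwde`.
#' @export
default_keyword_sets <- function() {
  list(
    te = c("DDE", "hAT", "integrase", "RVT", "MULE", "Retrotrans", "rve",
           "gag", "Tnp", "Helitron", "THAP"),
    pcwde = c("Pectinesterase", "Glyco_hydro", "PL4")
  )
}

#' Classify genes by domain keywords
#'
#' A gene matches a keyword set when any keyword is a case-insensitive
#' substring of any of its domain names. Genes absent from the domain
#' table are classed `unannotated`; a gene matching both sets is classed
#' `TE-domain` (precedence over `PCWDE`).
#'
#' @param domain_table Data.frame with `gene_id` and list-column `domains`
#'   (see [read_domain_table()]).
#' @param keyword_sets Named list with `te` and `pcwde` keyword vectors
#'   (default [default_keyword_sets()]).
#' @param all_genes Optional character vector of the full gene universe;
#'   genes not in the domain table are reported as `unannotated`.
#' @return Data.frame with `gene_id`, `class` (one of `TE-domain`,
#'   `PCWDE`, `other`, `unannotated`), `matched_keywords`
#'   (comma-separated) and list-column `domains`.
#' @export
classify_genes <- function(domain_table, keyword_sets = default_keyword_sets(),
                           all_genes = NULL) {
  stopifnot(all(c("te", "pcwde") %in% names(keyword_sets)),
            length(keyword_sets$te) > 0, length(keyword_sets$pcwde) > 0)
  match_set <- function(domains, kws) {
    hit <- vapply(kws, function(k) {
      any(grepl(tolower(k), tolower(domains), fixed = TRUE))
    }, logical(1))
    kws[hit]
  }
  n <- nrow(domain_table)
  cls <- character(n)
  matched <- character(n)
  for (i in seq_len(n)) {
    doms <- domain_table$domains[[i]]
    te_hit <- match_set(doms, keyword_sets$te)
    pc_hit <- match_set(doms, keyword_sets$pcwde)
    if (length(te_hit)) {
      cls[i] <- "TE-domain"
      matched[i] <- paste(te_hit, collapse = ",")
    } else if (length(pc_hit)) {
      cls[i] <- "PCWDE"
      matched[i] <- paste(pc_hit, collapse = ",")
    } else {
      cls[i] <- "other"
      matched[i] <- ""
    }
  }
  out <- data.frame(gene_id = domain_table$gene_id, class = cls,
                    matched_keywords = matched, stringsAsFactors = FALSE)
  out$domains <- domain_table$domains
  if (!is.null(all_genes)) {
    missing <- setdiff(all_genes, out$gene_id)
    if (length(missing)) {
      extra <- data.frame(gene_id = missing, class = "unannotated",
                          matched_keywords = "", stringsAsFactors = FALSE)
      extra$domains <- rep(list(character(0)), length(missing))
      out <- rbind(out, extra)
    }
  }
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Estimate a gene's genomic copy number from similarity hits
#'
#' Retains hits of the query gene with alignment length of at least
#' `min_aln_aa` amino acids and percent identity of at least
#' `min_identity`, then merges hit intervals per subject scaffold by
#' single linkage whenever the gap between them is at most `max_gap` bp
#' (overlapping hits always merge; merging is strand-agnostic). Each
#' merged region counts as one genomic copy.
#'
#' @param hits Hit table (see [read_hits()]).
#' @param gene_id Query gene to count copies for.
#' @param min_identity Minimum percent identity (50 or 75 in the standard
#'   parameter grid).
#' @param max_gap Maximum gap between hits to merge, in bp (20e3 or 50e3
#'   in the standard grid).
#' @param min_aln_aa Minimum alignment length in amino acids (default 50).
#' @return List with `copy_count` (integer, 0 when no hit survives the
#'   filters) and `regions`, a data.frame of merged copy regions
#'   (`scaffold`, `start`, `end`, 0-based half-open).
#' @export
estimate_copy_number <- function(hits, gene_id, min_identity, max_gap,
                                 min_aln_aa = 50) {
  h <- hits[hits$query_id == gene_id &
              hits$aln_length >= min_aln_aa &
              hits$pct_identity >= min_identity, , drop = FALSE]
  if (nrow(h) == 0L) {
    return(list(copy_count = 0L,
                regions = data.frame(scaffold = character(0),
                                     start = integer(0),
                                     end = integer(0))))
  }
  iv <- hit_subject_intervals(h)
  regions <- do.call(rbind, lapply(split(iv, iv$scaffold), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end),
                          min.gapwidth = max_gap + 1L)
    data.frame(scaffold = d$scaffold[1L], start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  }))
  regions <- regions[order(regions$scaffold, regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  list(copy_count = nrow(regions), regions = regions)
}

#' Copy-number table over the standard parameter grid
#'
#' Runs [estimate_copy_number()] for every gene and every combination of
#' identity and gap thresholds. Genes with no qualifying hits are reported
#' with copy count 0, not dropped (zeros matter for group means).
#'
#' @param hits Hit table.
#' @param gene_ids Genes to count.
#' @param identities,gaps Parameter grids (defaults: 50/75 % identity and
#'   20/50 kb maximum gap).
#' @param min_aln_aa Minimum alignment length (aa).
#' @return Data.frame with one row per gene x parameter combination:
#'   `gene_id`, `min_identity`, `max_gap`, `copy_count`, and a list-column
#'   `regions` of the merged copy regions.
#' @export
copy_number_table <- function(hits, gene_ids, identities = c(50, 75),
                              gaps = c(20000, 50000), min_aln_aa = 50) {
  combos <- expand.grid(min_identity = identities, max_gap = gaps,
                        KEEP.OUT.ATTRS = FALSE)
  rows <- list()
  for (g in gene_ids) {
    for (k in seq_len(nrow(combos))) {
      est <- estimate_copy_number(hits, g, combos$min_identity[k],
                                  combos$max_gap[k], min_aln_aa)
      row <- data.frame(gene_id = g,
                        min_identity = combos$min_identity[k],
                        max_gap = combos$max_gap[k],
                        copy_count = est$copy_count,
                        stringsAsFactors = FALSE)
      row$regions <- list(est$regions)
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Audit copy regions for premature stop codons
#'
#' For every supporting hit of a copy region the genomic subsequence over
#' the hit's subject span is extracted, reverse-complemented for
#' minus-strand hits, and translated in frame 0 of the span under the
#' standard genetic code. A copy is stop-flagged when any supporting
#' hit's translation contains an internal stop (a stop in the final codon
#' does not count). This frame-0 proxy is applied identically to TE and
#' control genes, which preserves the validity of the group comparison.
#'
#' @param copy_table Output of [copy_number_table()] (or a compatible
#'   data.frame with `gene_id`, `min_identity`, `max_gap`, `regions`).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param hits The hit table the copy regions were derived from.
#' @param min_aln_aa Minimum alignment length (aa), as used for the copy
#'   table.
#' @return List with `copies` (one row per copy region plus `stop_flag`)
#'   and `genes` (per gene x parameter combination: `n_copies`,
#'   `n_stop_flagged`, `stop_fraction`).
#' @export
audit_stop_codons <- function(copy_table, genome, hits, min_aln_aa = 50) {
  slen <- setNames(Biostrings::width(genome), names(genome))
  copies <- list()
  for (r in seq_len(nrow(copy_table))) {
    regions <- copy_table$regions[[r]]
    if (nrow(regions) == 0L) next
    g <- copy_table$gene_id[r]
    h <- hits[hits$query_id == g &
                hits$aln_length >= min_aln_aa &
                hits$pct_identity >= copy_table$min_identity[r], ,
              drop = FALSE]
    iv <- hit_subject_intervals(h)
    for (k in seq_len(nrow(regions))) {
      sc <- regions$scaffold[k]
      if (!sc %in% names(genome)) {
        stop("copy region on scaffold absent from genome: ", sc)
      }
      if (regions$end[k] > slen[[sc]]) {
        stop("copy region extends past end of scaffold ", sc)
      }
      sup <- which(iv$scaffold == sc & iv$start >= regions$start[k] &
                     iv$end <= regions$end[k])
      if (length(sup) == 0L) {
        stop("copy region without supporting hit for gene ", g)
      }
      flagged <- FALSE
      for (s in sup) {
        dna <- Biostrings::subseq(genome[[sc]], iv$start[s] + 1L,
                                  iv$end[s])
        if (iv$strand[s] == "-") dna <- Biostrings::reverseComplement(dna)
        L <- 3L * (length(dna) %/% 3L)
        if (L < 6L) next
        aa <- as.character(Biostrings::translate(
          Biostrings::subseq(dna, 1L, L), if.fuzzy.codon = "X"))
        internal <- substr(aa, 1L, nchar(aa) - 1L)
        if (grepl("*", internal, fixed = TRUE)) {
          flagged <- TRUE
          break
        }
      }
      copies[[length(copies) + 1L]] <- data.frame(
        gene_id = g, min_identity = copy_table$min_identity[r],
        max_gap = copy_table$max_gap[r], scaffold = sc,
        start = regions$start[k], end = regions$end[k],
        stop_flag = flagged, stringsAsFactors = FALSE)
    }
  }
  copies <- if (length(copies)) do.call(rbind, copies) else
    data.frame(gene_id = character(0), min_identity = numeric(0),
               max_gap = numeric(0), scaffold = character(0),
               start = integer(0), end = integer(0), stop_flag = logical(0))
  genes <- if (nrow(copies)) {
    agg <- stats::aggregate(stop_flag ~ gene_id + min_identity + max_gap,
                            data = copies,
                            FUN = function(v) c(n = length(v),
                                                flagged = sum(v)))
    data.frame(gene_id = agg$gene_id, min_identity = agg$min_identity,
               max_gap = agg$max_gap,
               n_copies = as.integer(agg$stop_flag[, "n"]),
               n_stop_flagged = as.integer(agg$stop_flag[, "flagged"]),
               stop_fraction = agg$stop_flag[, "flagged"] /
                 agg$stop_flag[, "n"],
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = character(0), min_identity = numeric(0),
               max_gap = numeric(0), n_copies = integer(0),
               n_stop_flagged = integer(0), stop_fraction = numeric(0))
  }
  genes <- genes[order(genes$gene_id, genes$min_identity, genes$max_gap), ,
                 drop = FALSE]
  rownames(genes) <- NULL
  rownames(copies) <- NULL
  list(copies = copies, genes = genes)
}

#' Select control gene families
#'
#' Ranks families not flagged as TE-derived by their mean gene count
#' across all species (descending; ties broken by family id ascending)
#' and returns the top `n`.
#'
#' @param og_counts Orthogroup gene-count matrix (see
#'   [read_orthogroup_counts()]).
#' @param te_flagged Character vector of TE-flagged family ids to exclude.
#' @param n Number of control families (default 12).
#' @return Character vector of `n` family ids in rank order.
#' @export
select_control_families <- function(og_counts, te_flagged = character(0),
                                    n = 12L) {
  elig <- og_counts[!og_counts$orthogroup %in% te_flagged, , drop = FALSE]
  if (nrow(elig) < n) {
    stop("only ", nrow(elig), " eligible non-TE families, need ", n)
  }
  means <- rowMeans(as.matrix(elig[, -1L, drop = FALSE]))
  ord <- order(-means, elig$orthogroup)
  elig$orthogroup[ord[seq_len(n)]]
}

#' Compare copy numbers of TE-domain genes against controls
#'
#' @param copy_table Copy-number table ([copy_number_table()]), optionally
#'   merged with stop fractions (column `stop_fraction`).
#' @param te_genes,control_genes Gene id vectors defining the two groups
#'   (both non-empty).
#' @return Data.frame with one row per parameter combination x group:
#'   `min_identity`, `max_gap`, `group`, `n`, `mean_copies`,
#'   `median_copies` and, when available, `mean_stop_fraction`.
#' @export
compare_te_vs_control <- function(copy_table, te_genes, control_genes) {
  if (length(te_genes) == 0L || length(control_genes) == 0L) {
    stop("both gene groups must be non-empty")
  }
  ct <- copy_table
  combos <- unique(ct[, c("min_identity", "max_gap")])
  members <- list("TE-domain" = te_genes, control = control_genes)
  rows <- list()
  for (k in seq_len(nrow(combos))) {
    for (grp in c("TE-domain", "control")) {
      d <- ct[ct$min_identity == combos$min_identity[k] &
                ct$max_gap == combos$max_gap[k] &
                ct$gene_id %in% members[[grp]], ,
              drop = FALSE]
      if (nrow(d) == 0L) stop("empty group '", grp, "' at combination ",
                              combos$min_identity[k], "%/",
                              combos$max_gap[k], " bp")
      row <- data.frame(min_identity = combos$min_identity[k],
                        max_gap = combos$max_gap[k], group = grp,
                        n = nrow(d), mean_copies = mean(d$copy_count),
                        median_copies = median(d$copy_count),
                        stringsAsFactors = FALSE)
      if ("stop_fraction" %in% names(d)) {
        row$mean_stop_fraction <- mean(d$stop_fraction, na.rm = TRUE)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$min_identity, out$max_gap, out$group), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' TE-adjusted species gene count
#'
#' Extrapolates the expected total number of TE-domain genes from the
#' functionally annotated subset, assuming TE-derived genes occur among
#' unannotated genes at the same rate as among annotated ones:
#' `expected_te_total = k * T / F`, and
#' `adjusted_genes = T - expected_te_total`.
#'
#' @param total_genes Total annotated genes `T`.
#' @param annotated Functionally annotated genes `F` (> 0).
#' @param te_domain_genes TE-domain genes among the annotated, `k`
#'   (`0 <= k <= F <= T`).
#' @return One-row data.frame: `total_genes`, `annotated`,
#'   `te_domain_genes`, `expected_te_total`, `adjusted_genes`.
#' @export
adjust_gene_count <- function(total_genes, annotated, te_domain_genes) {
  if (annotated <= 0) stop("annotated gene count must be > 0")
  if (te_domain_genes < 0 || te_domain_genes > annotated) {
    stop("need 0 <= te_domain_genes <= annotated")
  }
  if (annotated > total_genes) {
    stop("annotated gene count exceeds total gene count")
  }
  expected <- te_domain_genes * total_genes / annotated
  data.frame(total_genes = total_genes, annotated = annotated,
             te_domain_genes = te_domain_genes,
             expected_te_total = expected,
             adjusted_genes = total_genes - expected)
}

#' Per-species TE-domain gene fractions
#'
#' @param species_classifications Named list of classification tables
#'   ([classify_genes()] output), one per species.
#' @return Data.frame ordered by species id: `species`, `annotated` (F,
#'   genes with at least one domain annotation), `te_domain_genes` (k) and
#'   `te_fraction` (k/F).
#' @export
te_fraction_report <- function(species_classifications) {
  sp <- sort(names(species_classifications))
  rows <- lapply(sp, function(s) {
    cl <- species_classifications[[s]]
    ann <- cl[cl$class != "unannotated", , drop = FALSE]
    k <- sum(ann$class == "TE-domain")
    data.frame(species = s, annotated = nrow(ann), te_domain_genes = k,
               te_fraction = if (nrow(ann) > 0) k / nrow(ann) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
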