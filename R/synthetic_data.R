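## Truth-labelled synthetic data with the statistical structure the
## analysis assumes: a multi-scaffold genome of i.i.d. uniform background
## sequence carrying planted interspersed-repeat families
## (divergence-stratified copies), planted gene families (single- and
## multi-copy, optionally TE-derived or PCWDE, with a controlled fraction
## of copies carrying one premature in-frame stop), microsatellite
## arrays, a domain table covering a fixed fraction of genes, a hit table
## consistent with the planted copies, single-exon transcript models at
## the exemplar copies, and Poisson coverage tracks in which the X
## scaffold runs at a reduced depth in the male sample.
##
## All randomness flows from config$seed; identical configs give
## byte-identical outputs.

#' Describe a transposable-element family to plant
#'
#' @param family_id Family name.
#' @param consensus_length Consensus length (bp).
#' @param n_copies Number of genomic copies; copies are spread over at
#'   least two scaffolds whenever `n_copies >= 2`.
#' @param divergence Per-copy substitution fraction from the consensus,
#'   in `[0, 0.5]`.
#' @param premature_stop_fraction Fraction of copies given one internal
#'   in-frame stop codon.
#' @param min_copy_spacing Minimum gap between same-family copies on one
#'   scaffold (bp).
#' @param class_label Repeat class recorded in the truth annotation.
#' @return A `te_family` spec (list).
#' @export
te_family <- function(family_id, consensus_length, n_copies, divergence,
                      premature_stop_fraction = 0,
                      min_copy_spacing = 2000,
                      class_label = "DNA_transposon") {
  stopifnot(consensus_length >= 30, n_copies >= 1,
            divergence >= 0, divergence <= 0.5,
            premature_stop_fraction >= 0, premature_stop_fraction <= 1)
  structure(list(family_id = family_id,
                 consensus_length = as.integer(consensus_length),
                 n_copies = as.integer(n_copies),
                 divergence = divergence,
                 premature_stop_fraction = premature_stop_fraction,
                 min_copy_spacing = as.integer(min_copy_spacing),
                 class_label = class_label),
            class = "te_family")
}

#' Describe a gene family to plant
#'
#' One annotated gene (the exemplar, always on the plus strand) plus
#' `n_copies - 1` additional genomic copies mutated at `divergence`;
#' roughly half the extra copies land on the minus strand. Copies are
#' separated by at least `min_copy_spacing` on a scaffold and spread over
#' at least two scaffolds when `n_copies >= 2`.
#'
#' @param family_id Family name; also the gene id of the exemplar.
#' @param n_copies Total genomic copies (>= 1).
#' @param cds_length CDS length in bp, a multiple of 3 (includes the
#'   start and the terminal stop codon).
#' @param is_te_derived Whether the gene carries TE-derived domains.
#' @param divergence Substitution fraction of non-exemplar copies.
#' @param premature_stop_fraction Fraction of copies given one internal
#'   in-frame stop.
#' @param pcwde Whether the gene is a plant cell wall-degrading enzyme
#'   (receives Glyco_hydro / Pectinesterase domain names).
#' @param min_copy_spacing Minimum same-family gap on one scaffold (bp).
#'   The default (60 kb) exceeds the largest standard merge distance
#'   (50 kb), so planted copies remain distinct under every parameter
#'   combination of the copy-number estimator.
#' @return A `gene_family` spec (list).
#' @export
gene_family <- function(family_id, n_copies, cds_length,
                        is_te_derived = FALSE, divergence = 0,
                        premature_stop_fraction = 0, pcwde = FALSE,
                        min_copy_spacing = 60000) {
  stopifnot(cds_length %% 3 == 0, cds_length >= 150, n_copies >= 1,
            divergence >= 0, divergence <= 0.5,
            premature_stop_fraction >= 0, premature_stop_fraction <= 1,
            !(is_te_derived && pcwde))
  structure(list(family_id = family_id, n_copies = as.integer(n_copies),
                 cds_length = as.integer(cds_length),
                 is_te_derived = is_te_derived, divergence = divergence,
                 premature_stop_fraction = premature_stop_fraction,
                 pcwde = pcwde,
                 min_copy_spacing = as.integer(min_copy_spacing)),
            class = "gene_family")
}

#' Describe microsatellite arrays to plant
#'
#' @param motif Motif (2-6 nt, at most 3 distinct letters so the
#'   generator can pad the array with a letter absent from the motif,
#'   preventing accidental extension into the flanks).
#' @param n_units Number of perfect units per array.
#' @param count Number of arrays to plant.
#' @return An `ssr_array` spec (list).
#' @export
ssr_array <- function(motif, n_units, count = 1L) {
  motif <- toupper(motif)
  stopifnot(nchar(motif) >= 2, nchar(motif) <= 6,
            length(unique(strsplit(motif, "")[[1]])) <= 3,
            n_units >= 1, count >= 1)
  structure(list(motif = motif, n_units = as.integer(n_units),
                 count = as.integer(count)),
            class = "ssr_array")
}

#' Simulation configuration
#'
#' Defaults emulate the data regime of a bark-beetle-style annotation
#' project at desk scale: a handful of sub-megabase scaffolds, two
#' interspersed-repeat families, a mixture of neutral, PCWDE and
#' TE-derived gene families, a few microsatellite arrays, 72.5% of genes
#' functionally annotated, ~30x coverage and an X scaffold at half male
#' depth.
#'
#' @param seed Integer seed fixing all outputs bit-for-bit.
#' @param scaffold_lengths Named integer vector (>= 2 scaffolds).
#' @param te_families List of [te_family()] specs.
#' @param gene_families List of [gene_family()] specs.
#' @param ssr_spec List of [ssr_array()] specs.
#' @param x_scaffold Scaffold carrying the X signature (default: the last
#'   scaffold).
#' @param male_x_depth_ratio Male X depth relative to autosomes
#'   (default 0.5).
#' @param mean_depth Autosomal Poisson mean depth per window.
#' @param depth_window Coverage window width (bp).
#' @param annotated_fraction Fraction of genes present in the domain
#'   table (floor per class; deterministic first-by-sorted-gene-id
#'   choice).
#' @return A validated `sim_config` (list).
#' @export
sim_config <- function(seed = 1L,
                       scaffold_lengths = c(scaffold_1 = 200000L,
                                            scaffold_2 = 180000L,
                                            scaffold_3 = 150000L,
                                            scaffold_4 = 120000L),
                       te_families = list(
                         te_family("TEfam_DNA1", 400, 30, 0.10, 0.4,
                                   class_label = "DNA_transposon"),
                         te_family("TEfam_LTR1", 500, 15, 0.15, 0.4,
                                   class_label = "retrotransposon")),
                       gene_families = NULL,
                       ssr_spec = list(ssr_array("AT", 8, 3),
                                       ssr_array("ACG", 6, 2),
                                       ssr_array("AAGC", 4, 2)),
                       x_scaffold = NULL,
                       male_x_depth_ratio = 0.5,
                       mean_depth = 30,
                       depth_window = 1000L,
                       annotated_fraction = 0.725) {
  if (is.null(gene_families)) {
    gene_families <- c(
      lapply(1:10, function(i) {
        gene_family(sprintf("gene_neutral_%02d", i), 1, 900)
      }),
      list(gene_family("gene_pcwde_1", 1, 900, pcwde = TRUE),
           gene_family("gene_pcwde_2", 1, 900, pcwde = TRUE),
           gene_family("gene_te_1", 5, 900, is_te_derived = TRUE,
                       divergence = 0.10, premature_stop_fraction = 0.4),
           gene_family("gene_te_2", 5, 900, is_te_derived = TRUE,
                       divergence = 0.10, premature_stop_fraction = 0.4)))
  }
  stopifnot(length(scaffold_lengths) >= 2,
            !is.null(names(scaffold_lengths)),
            all(scaffold_lengths >= 10 * depth_window),
            male_x_depth_ratio > 0, male_x_depth_ratio <= 1,
            mean_depth > 0, annotated_fraction >= 0,
            annotated_fraction <= 1)
  if (is.null(x_scaffold)) {
    x_scaffold <- names(scaffold_lengths)[length(scaffold_lengths)]
  }
  stopifnot(x_scaffold %in% names(scaffold_lengths))
  gids <- vapply(gene_families, `[[`, character(1), "family_id")
  tids <- vapply(te_families, `[[`, character(1), "family_id")
  if (anyDuplicated(c(gids, tids))) stop("duplicate family id(s)")
  structure(list(seed = as.integer(seed),
                 scaffold_lengths = scaffold_lengths,
                 te_families = te_families,
                 gene_families = gene_families,
                 ssr_spec = ssr_spec, x_scaffold = x_scaffold,
                 male_x_depth_ratio = male_x_depth_ratio,
                 mean_depth = mean_depth,
                 depth_window = as.integer(depth_window),
                 annotated_fraction = annotated_fraction),
            class = "sim_config")
}

.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")

## random stop-free CDS: ATG + sense codons + TAA, as a character vector
.random_cds <- function(len_bp) {
  n_codons <- len_bp %/% 3L
  codons <- apply(matrix(sample(.BASES, 3L * (n_codons - 2L),
                                replace = TRUE), ncol = 3L), 1L, paste,
                  collapse = "")
  bad <- codons %in% .STOPS
  codons[bad] <- paste0(substr(codons[bad], 1L, 2L), "C")
  strsplit(paste0("ATG", paste(codons, collapse = ""), "TAA"), "")[[1L]]
}

## substitute exactly round(d * L) positions to a different base
.mutate_seq <- function(ch, divergence) {
  m <- round(divergence * length(ch))
  if (m == 0L) return(ch)
  pos <- sample(length(ch), m)
  for (p in pos) {
    ch[p] <- sample(setdiff(.BASES, ch[p]), 1L)
  }
  ch
}

## remove internal frame-0 stops a mutation may have created
.repair_internal_stops <- function(ch) {
  n_codons <- length(ch) %/% 3L
  if (n_codons < 3L) return(ch)
  for (k in seq_len(n_codons - 1L)) {
    codon <- paste(ch[(3L * k - 2L):(3L * k)], collapse = "")
    if (codon %in% .STOPS) ch[3L * k] <- "C"
  }
  ch
}

.revcomp_chars <- function(ch) {
  rev(c(A = "T", C = "G", G = "C", T = "A", N = "N")[ch])
}

.TE_DOMAIN_NAMES <- c("DDE_Tnp_1", "RVT_1", "rve", "Retrotrans_gag",
                      "MULE", "hAT-Ac", "THAP", "Helitron_like_N",
                      "Integrase_H2C2", "gag_pre-integrs")
.PCWDE_DOMAIN_NAMES <- c("Glyco_hydro_45", "Glyco_hydro_28",
                         "Pectinesterase", "Glyco_hydro_5")
.NEUTRAL_DOMAIN_NAMES <- c("WD40", "Ank_2", "zf-C2H2", "Pkinase", "EGF",
                           "Lectin_C", "Ras", "SH3_1", "PDZ", "BTB",
                           "Myb_DNA-binding", "Homeodomain")

## sequential feature allocator; keeps per-family spacing and a global
## per-scaffold cursor so planted features never overlap
.make_allocator <- function(scaffold_lengths, buffer = 400L) {
  cursor <- setNames(rep(1000L, length(scaffold_lengths)),
                     names(scaffold_lengths))
  fam_last_end <- list()
  place <- function(scaffold, len, family = NULL, spacing = 0L) {
    start <- cursor[[scaffold]]
    key <- paste0(scaffold, "\r", family)
    if (!is.null(family) && !is.null(fam_last_end[[key]])) {
      start <- max(start, fam_last_end[[key]] + spacing)
    }
    end <- start + len
    if (end > scaffold_lengths[[scaffold]] - 1000L) {
      stop("infeasible packing: planted features exceed capacity of ",
           scaffold, call. = FALSE)
    }
    cursor[[scaffold]] <<- end + buffer
    if (!is.null(family)) fam_last_end[[key]] <<- end
    c(start = start, end = end)
  }
  place
}

#' Generate a truth-labelled synthetic dataset
#'
#' See [sim_config()] for the knobs. Everything is generated in memory;
#' [write_simulation()] serializes a run to the on-disk dialects the
#' package readers consume.
#'
#' @param config A [sim_config()].
#' @return List with elements `genome` (DNAStringSet), `repeats`
#'   (truth repeat intervals), `ssrs` (truth SSR records), `genes`
#'   (one row per gene family exemplar), `copies` (one row per planted
#'   gene copy with `stop_flag`), `hits` (tabular hit rows consistent
#'   with the planted copies), `domain_table`, `transcripts`
#'   (transcript models at the exemplars), `depth_female`/`depth_male`
#'   (windowed tracks), `truth` (compact summary incl. per-gene copy
#'   number, TE gene ids and the X scaffold) and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  sl <- config$scaffold_lengths
  scaffs <- lapply(sl, function(L) sample(.BASES, L, replace = TRUE))
  place <- .make_allocator(sl)
  scaff_names <- names(sl)
  rr <- function(i) scaff_names[((i - 1L) %% length(scaff_names)) + 1L]

  ## --- interspersed repeat families ---------------------------------------
  repeats <- list()
  for (fi in seq_along(config$te_families)) {
    fam <- config$te_families[[fi]]
    consensus <- sample(.BASES, fam$consensus_length, replace = TRUE)
    n_stop <- round(fam$premature_stop_fraction * fam$n_copies)
    for (k in seq_len(fam$n_copies)) {
      ch <- .mutate_seq(consensus, fam$divergence)
      if (k <= n_stop) {
        mid <- (length(ch) %/% 6L) * 3L + 1L
        ch[mid:(mid + 2L)] <- c("T", "A", "A")
      }
      sc <- rr(k + fi - 1L)
      at <- place(sc, length(ch), family = fam$family_id,
                  spacing = fam$min_copy_spacing)
      scaffs[[sc]][(at[["start"]] + 1L):at[["end"]]] <- ch
      repeats[[length(repeats) + 1L]] <- data.frame(
        scaffold = sc, start = at[["start"]], end = at[["end"]],
        strand = "+", repeat_id = sprintf("%s#%d", fam$family_id, k),
        class_label = fam$class_label, family_id = fam$family_id,
        stop_planted = k <= n_stop, stringsAsFactors = FALSE)
    }
  }
  repeats <- if (length(repeats)) do.call(rbind, repeats) else NULL

  ## --- gene families -------------------------------------------------------
  genes <- list()
  copies <- list()
  hits <- list()
  transcripts <- list()
  for (fi in seq_along(config$gene_families)) {
    fam <- config$gene_families[[fi]]
    cds <- .random_cds(fam$cds_length)
    n_stop <- round(fam$premature_stop_fraction * fam$n_copies)
    aln_aa <- fam$cds_length %/% 3L
    for (k in seq_len(fam$n_copies)) {
      ch <- if (k == 1L) cds else
        .repair_internal_stops(.mutate_seq(cds, fam$divergence))
      stop_flag <- k > fam$n_copies - n_stop
      if (stop_flag) {
        mid <- ((length(ch) %/% 3L) %/% 2L) * 3L + 1L
        ch[mid:(mid + 2L)] <- c("T", "A", "A")
      }
      minus <- k > 1L && k %% 2L == 0L
      placed <- if (minus) .revcomp_chars(ch) else ch
      sc <- rr(k + fi - 1L)
      at <- place(sc, length(ch), family = fam$family_id,
                  spacing = fam$min_copy_spacing)
      scaffs[[sc]][(at[["start"]] + 1L):at[["end"]]] <- placed
      copies[[length(copies) + 1L]] <- data.frame(
        gene_id = fam$family_id, copy_index = k, scaffold = sc,
        start = at[["start"]], end = at[["end"]],
        strand = if (minus) "-" else "+", stop_flag = stop_flag,
        stringsAsFactors = FALSE)
      ident <- if (k == 1L) 100 else
        max(0, min(100, 100 * (1 - fam$divergence) + rnorm(1L, 0, 0.2)))
      hits[[length(hits) + 1L]] <- data.frame(
        query_id = fam$family_id, subject_id = sc,
        pct_identity = round(ident, 2L), aln_length = aln_aa,
        mismatches = as.integer(round(fam$divergence * aln_aa)),
        gap_opens = 0L, q_start = 1L, q_end = aln_aa,
        s_start = if (minus) at[["end"]] else at[["start"]] + 1L,
        s_end = if (minus) at[["start"]] + 1L else at[["end"]],
        evalue = 1e-50, bit_score = round(2 * aln_aa * ident / 100, 1L),
        stringsAsFactors = FALSE)
      if (k == 1L) {
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = fam$family_id, scaffold = sc, start = at[["start"]],
          end = at[["end"]], strand = "+", cds_length = fam$cds_length,
          n_copies = fam$n_copies, is_te_derived = fam$is_te_derived,
          pcwde = fam$pcwde, stringsAsFactors = FALSE)
        transcripts[[length(transcripts) + 1L]] <- transcript_model(
          transcript_id = paste0(fam$family_id, ".t1"),
          gene_id = fam$family_id, scaffold = sc,
          exons = data.frame(start = at[["start"]], end = at[["end"]]),
          strand = "+", orf_has_start = TRUE, orf_has_stop = TRUE,
          orf_length = fam$cds_length, has_cds = TRUE)
      }
    }
  }
  genes <- if (length(genes)) do.call(rbind, genes) else NULL
  copies <- if (length(copies)) do.call(rbind, copies) else NULL
  hits <- if (length(hits)) do.call(rbind, hits) else NULL
  transcripts <- if (length(transcripts)) do.call(rbind, transcripts) else
    NULL

  ## --- microsatellite arrays ----------------------------------------------
  ssrs <- list()
  for (fi in seq_along(config$ssr_spec)) {
    spec <- config$ssr_spec[[fi]]
    motif_ch <- strsplit(spec$motif, "")[[1L]]
    pad <- setdiff(.BASES, motif_ch)[1L]
    arr <- c(rep(pad, 2L), rep(motif_ch, spec$n_units), rep(pad, 2L))
    for (k in seq_len(spec$count)) {
      sc <- rr(k + fi - 1L)
      at <- place(sc, length(arr))
      scaffs[[sc]][(at[["start"]] + 1L):at[["end"]]] <- arr
      ssrs[[length(ssrs) + 1L]] <- data.frame(
        scaffold = sc, start = at[["start"]] + 2L,
        end = at[["end"]] - 2L, period = nchar(spec$motif),
        motif = .canonical_rotation(spec$motif), n_units = spec$n_units,
        stringsAsFactors = FALSE)
    }
  }
  ssrs <- if (length(ssrs)) do.call(rbind, ssrs) else NULL

  ## --- domain table --------------------------------------------------------
  pick_domains <- function(is_te, is_pcwde) {
    if (is_te) {
      c(sample(.TE_DOMAIN_NAMES, 1L), sample(.NEUTRAL_DOMAIN_NAMES, 1L))
    } else if (is_pcwde) {
      sample(.PCWDE_DOMAIN_NAMES, 1L)
    } else {
      sample(.NEUTRAL_DOMAIN_NAMES, sample(1:2, 1L))
    }
  }
  domain_rows <- lapply(seq_len(NROW(genes)), function(i) {
    data.frame(gene_id = genes$gene_id[i], stringsAsFactors = FALSE,
               domains = I(list(pick_domains(genes$is_te_derived[i],
                                             genes$pcwde[i]))))
  })
  domain_table <- if (length(domain_rows)) do.call(rbind, domain_rows) else
    data.frame(gene_id = character(0),
               domains = I(list()), stringsAsFactors = FALSE)
  ## annotated_fraction, floor per class, first-by-sorted-id within class
  keep_first <- function(ids) {
    sort(ids)[seq_len(floor(config$annotated_fraction * length(ids)))]
  }
  te_ids <- if (is.null(genes)) character(0) else
    genes$gene_id[genes$is_te_derived]
  other_ids <- if (is.null(genes)) character(0) else
    genes$gene_id[!genes$is_te_derived]
  annotated_ids <- c(if (length(te_ids)) keep_first(te_ids),
                     if (length(other_ids)) keep_first(other_ids))
  domain_table <- domain_table[domain_table$gene_id %in% annotated_ids, ,
                               drop = FALSE]
  domain_table <- domain_table[order(domain_table$gene_id), , drop = FALSE]
  rownames(domain_table) <- NULL

  ## --- coverage tracks -----------------------------------------------------
  w <- config$depth_window
  depth_track <- function(ratio_on_x) {
    rows <- lapply(scaff_names, function(sc) {
      starts <- seq(0L, sl[[sc]] - w, by = w)
      mu <- config$mean_depth *
        if (sc == config$x_scaffold) ratio_on_x else 1
      data.frame(scaffold = sc, start = starts, end = starts + w,
                 mean_depth = rpois(length(starts), mu),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    attr(out, "windowed") <- TRUE
    out
  }
  depth_female <- depth_track(1)
  depth_male <- depth_track(config$male_x_depth_ratio)

  genome <- Biostrings::DNAStringSet(vapply(scaffs, paste, character(1),
                                            collapse = ""))
  names(genome) <- scaff_names

  truth <- list(
    te_gene_ids = if (is.null(genes)) character(0) else
      genes$gene_id[genes$is_te_derived],
    pcwde_gene_ids = if (is.null(genes)) character(0) else
      genes$gene_id[genes$pcwde],
    copy_number = if (is.null(genes)) integer(0) else
      setNames(genes$n_copies, genes$gene_id),
    stop_fraction = if (is.null(copies)) numeric(0) else
      setNames(vapply(split(copies$stop_flag, copies$gene_id), mean,
                      numeric(1))[genes$gene_id], genes$gene_id),
    annotated_gene_ids = sort(annotated_ids),
    x_scaffold = config$x_scaffold
  )
  list(genome = genome, repeats = repeats, ssrs = ssrs, genes = genes,
       copies = copies, hits = hits, domain_table = domain_table,
       transcripts = transcripts, depth_female = depth_female,
       depth_male = depth_male, truth = truth, config = config)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Add spurious rows to a hit table
#'
#' Appends false-positive hits - short alignments (< 50 aa) or
#' low-identity alignments (< 50%) at random subject positions - at the
#' given rate. True rows are never removed, and every spurious row
#' violates at least one copy-number filter, so filtered results are
#' unchanged.
#'
#' @param hits Hit table.
#' @param fp_rate Expected spurious rows per true row, in `[0, 1)`.
#' @param seed Integer seed.
#' @param scaffold_lengths Named lengths used to draw subject positions;
#'   defaults to generous bounds from the hits themselves.
#' @return The hit table with spurious rows appended.
#' @export
emit_hit_noise <- function(hits, fp_rate, seed,
                           scaffold_lengths = NULL) {
  stopifnot(fp_rate >= 0, fp_rate < 1)
  if (fp_rate == 0 || nrow(hits) == 0L) return(hits)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_add <- rbinom(1L, nrow(hits), fp_rate)
  if (n_add == 0L) return(hits)
  if (is.null(scaffold_lengths)) {
    scaffold_lengths <- tapply(pmax(hits$s_start, hits$s_end),
                               hits$subject_id, max) + 10000
  }
  rows <- lapply(seq_len(n_add), function(i) {
    short <- runif(1L) < 0.5
    aln <- if (short) sample(5:49, 1L) else sample(50:200, 1L)
    ident <- if (short) round(runif(1L, 50, 100), 2L) else
      round(runif(1L, 5, 49.9), 2L)
    sc <- sample(names(scaffold_lengths), 1L)
    s0 <- sample(max(1L, as.integer(scaffold_lengths[[sc]]) - 3L * aln),
                 1L)
    data.frame(query_id = sample(unique(hits$query_id), 1L),
               subject_id = sc, pct_identity = ident, aln_length = aln,
               mismatches = as.integer(aln * 0.3), gap_opens = 0L,
               q_start = 1L, q_end = aln, s_start = s0,
               s_end = s0 + 3L * aln - 1L, evalue = 1e-4,
               bit_score = 40, stringsAsFactors = FALSE)
  })
  rbind(hits, do.call(rbind, rows))
}

#' Write a simulated dataset to a run directory
#'
#' Emits the exact on-disk dialects the package readers consume, plus the
#' truth tables and a manifest. Deterministic: the same simulation writes
#' byte-identical files.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_fasta(sim$genome, p("genome.fa"))
  if (!is.null(sim$repeats)) {
    write_bed(repeats_to_bed(sim$repeats), p("repeats.bed"))
  }
  if (!is.null(sim$transcripts)) {
    write_gff3_transcripts(sim$transcripts, p("transcripts.gff3"))
  }
  if (!is.null(sim$hits)) write_hits(sim$hits, p("hits.tsv"))
  write_domain_table(sim$domain_table, p("domains.tsv"))
  write_depth_table(sim$depth_female, p("depth_female.tsv"))
  write_depth_table(sim$depth_male, p("depth_male.tsv"))
  if (!is.null(sim$ssrs)) {
    write.table(sim$ssrs, p("truth_ssrs.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(sim$copies)) {
    write.table(sim$copies, p("truth_copies.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  files <- sort(list.files(dir))
  writeLines(c("# tescreen simulation manifest",
               paste0("seed\t", sim$config$seed),
               paste0("x_scaffold\t", sim$truth$x_scaffold),
               paste0("file\t", setdiff(files, "manifest.tsv"))),
             p("manifest.tsv"))
  invisible(dir)
}
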