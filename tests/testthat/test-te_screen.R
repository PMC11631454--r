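mk_hit <- function(query, subject, ident, aln, s_start, s_end) {
  data.frame(query_id = query, subject_id = subject,
             pct_identity = ident, aln_length = aln, mismatches = 0L,
             gap_opens = 0L, q_start = 1L, q_end = aln,
             s_start = s_start, s_end = s_end, evalue = 0,
             bit_score = 100, stringsAsFactors = FALSE)
}

test_that("keyword classification follows the TE/PCWDE/other precedence", {
  dom <- data.frame(gene_id = c("g1", "g2", "g3", "g4"))
  dom$domains <- list(c("DDE_Tnp_1"), c("Glyco_hydro_45"), c("WD40"),
                      c("Glyco_hydro_28", "RVT_1"))
  cl <- classify_genes(dom, all_genes = c("g1", "g2", "g3", "g4", "g5"))
  expect_equal(cl$class[cl$gene_id == "g1"], "TE-domain")
  expect_setequal(strsplit(cl$matched_keywords[cl$gene_id == "g1"],
                           ",")[[1]], c("DDE", "Tnp"))
  expect_equal(cl$class[cl$gene_id == "g2"], "PCWDE")
  expect_equal(cl$class[cl$gene_id == "g3"], "other")
  ## TE-domain takes precedence when both sets match
  expect_equal(cl$class[cl$gene_id == "g4"], "TE-domain")
  expect_equal(cl$class[cl$gene_id == "g5"], "unannotated")
  ## matching is case-insensitive substring
  dom2 <- data.frame(gene_id = "gx")
  dom2$domains <- list("retrotrans_GAG")
  expect_equal(classify_genes(dom2)$class, "TE-domain")
})

test_that("copy-number estimation filters hits and merges by gap", {
  hits <- rbind(mk_hit("g", "sc", 90, 60, 1, 1000),
                mk_hit("g", "sc", 90, 60, 5001, 6000),
                mk_hit("g", "sc", 90, 60, 100001, 101000))
  est <- estimate_copy_number(hits, "g", 50, 20000)
  expect_equal(est$copy_count, 2L)
  expect_equal(est$regions$start, c(0L, 100000L))
  expect_equal(est$regions$end, c(6000L, 101000L))
  ## identity threshold: 60% counted at 50, excluded at 75
  h60 <- mk_hit("g2", "sc", 60, 60, 1, 180)
  expect_equal(estimate_copy_number(h60, "g2", 50, 20000)$copy_count, 1L)
  expect_equal(estimate_copy_number(h60, "g2", 75, 20000)$copy_count, 0L)
  ## "at least 50 amino acids": 49 excluded, no-hit genes give 0
  h49 <- mk_hit("g3", "sc", 90, 49, 1, 147)
  expect_equal(estimate_copy_number(h49, "g3", 50, 20000)$copy_count, 0L)
  expect_equal(estimate_copy_number(hits, "absent", 50, 20000)$copy_count,
               0L)
  ## minus-strand hits merge with plus-strand neighbours
  hmix <- rbind(mk_hit("g4", "sc", 90, 60, 1, 1000),
                mk_hit("g4", "sc", 90, 60, 3000, 2001))
  expect_equal(estimate_copy_number(hmix, "g4", 50, 20000)$copy_count, 1L)
})

test_that("copy counts are monotone in identity and gap thresholds", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    s0 <- sort(sample.int(3e5, n))
    hits <- do.call(rbind, lapply(seq_len(n), function(k) {
      mk_hit("g", sample(c("sc1", "sc2"), 1), runif(1, 30, 100),
             sample(30:200, 1), s0[k], s0[k] + sample(100:500, 1))
    }))
    ct <- copy_number_table(hits, "g")
    cc <- function(id, gap) {
      ct$copy_count[ct$min_identity == id & ct$max_gap == gap]
    }
    expect_lte(cc(75, 20000), cc(50, 20000))
    expect_lte(cc(75, 50000), cc(50, 50000))
    expect_lte(cc(50, 50000), cc(50, 20000))
    expect_lte(cc(75, 50000), cc(75, 20000))
  }
})

test_that("stop-codon audit translates hit spans on both strands", {
  ## plus-strand copy with an internal TAA; minus-strand clean copy
  left <- "ATGAAACCCTAACCCGGG"   # internal TAA at codon 4
  clean <- "ATGAAACCCGAACCCGGGTAA"  # terminal stop only
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  genome <- Biostrings::DNAStringSet(c(
    sc1 = paste0(strrep("G", 10), left, strrep("G", 50000),
                 rc(clean), strrep("G", 10))))
  h <- rbind(mk_hit("g", "sc1", 90, 6, 11, 10 + nchar(left)),
             mk_hit("g", "sc1", 90, 7, 10 + nchar(left) + 50000 +
                      nchar(clean), 10 + nchar(left) + 50001))
  ct <- copy_number_table(h, "g", identities = 50, gaps = 20000,
                          min_aln_aa = 5)
  expect_equal(ct$copy_count, 2L)
  aud <- audit_stop_codons(ct, genome, h, min_aln_aa = 5)
  expect_equal(aud$copies$stop_flag, c(TRUE, FALSE))
  ## terminal stops do not count; fraction = flagged / total
  expect_equal(aud$genes$stop_fraction, 0.5)
})

test_that("stop-fraction recovery on simulated gene families is exact", {
  cfg <- sim_config(seed = 21, gene_families = list(
    gene_family("famA", 5, 900, is_te_derived = TRUE, divergence = 0.1,
                premature_stop_fraction = 0.4),
    gene_family("famB", 4, 900, is_te_derived = TRUE, divergence = 0.1,
                premature_stop_fraction = 1),
    gene_family("famC", 3, 900, divergence = 0.05)))
  sim <- simulate_dataset(cfg)
  ct <- copy_number_table(sim$hits, sim$genes$gene_id,
                          identities = 50, gaps = 20000)
  expect_equal(setNames(ct$copy_count, ct$gene_id),
               sim$truth$copy_number[ct$gene_id])
  aud <- audit_stop_codons(ct, sim$genome, sim$hits)
  expect_equal(setNames(aud$genes$stop_fraction, aud$genes$gene_id),
               sim$truth$stop_fraction[aud$genes$gene_id])
})

test_that("control families are the top non-TE means with id tie-break", {
  og <- data.frame(orthogroup = sprintf("OG%02d", 1:16),
                   spA = c(16:2, 2), spB = c(16:2, 2))
  picked <- select_control_families(og, te_flagged = c("OG01", "OG02"),
                                    n = 12)
  expect_equal(picked[1], "OG03")
  expect_equal(length(picked), 12L)
  expect_false(any(c("OG01", "OG02") %in% picked))
  ## tie on the mean resolves by id order (OG15 and OG16 both mean 2)
  expect_equal(picked[12], "OG14")
  expect_error(select_control_families(og[1:10, ], n = 12),
               "10 eligible")
  ## brute-force sort oracle on random matrices
  set.seed(5)
  for (i in 1:10) {
    og2 <- data.frame(orthogroup = sprintf("F%03d", 1:30),
                      a = sample(1:9, 30, TRUE),
                      b = sample(1:9, 30, TRUE))
    flagged <- sample(og2$orthogroup, 5)
    elig <- og2[!og2$orthogroup %in% flagged, ]
    mu <- (elig$a + elig$b) / 2
    oracle <- elig$orthogroup[order(-mu, elig$orthogroup)][1:12]
    expect_equal(select_control_families(og2, flagged), oracle)
  }
})

test_that("TE vs control comparison summarizes each parameter combination", {
  ct <- expand.grid(gene_id = c("te1", "te2", "c1", "c2"),
                    min_identity = c(50, 75), max_gap = c(20000, 50000),
                    stringsAsFactors = FALSE)
  ct$copy_count <- ifelse(ct$gene_id %in% c("te1", "te2"),
                          c(10, 20), c(1, 2))
  cmp <- compare_te_vs_control(ct, c("te1", "te2"), c("c1", "c2"))
  expect_equal(nrow(cmp), 8L)
  expect_equal(unique(cmp$mean_copies[cmp$group == "TE-domain"]), 15)
  expect_equal(unique(cmp$mean_copies[cmp$group == "control"]), 1.5)
  ## identical groups give equal means
  cmp2 <- compare_te_vs_control(ct, c("te1", "c1"), c("te1", "c1"))
  expect_equal(cmp2$mean_copies[cmp2$group == "TE-domain"],
               cmp2$mean_copies[cmp2$group == "control"])
  expect_error(compare_te_vs_control(ct, character(0), "c1"), "non-empty")
})

test_that("gene-count adjustment implements k*T/F and its invariants", {
  adj <- adjust_gene_count(10000, 8000, 400)
  expect_equal(adj$expected_te_total, 500)
  expect_equal(adj$adjusted_genes, 9500)
  expect_equal(adjust_gene_count(5000, 5000, 100)$adjusted_genes, 4900)
  expect_equal(adjust_gene_count(5000, 4000, 0)$adjusted_genes, 5000)
  ## scale consistency: doubling T, F, k doubles both outputs
  a1 <- adjust_gene_count(1200, 900, 60)
  a2 <- adjust_gene_count(2400, 1800, 120)
  expect_equal(a2$expected_te_total, 2 * a1$expected_te_total)
  expect_equal(a2$adjusted_genes, 2 * a1$adjusted_genes)
  expect_error(adjust_gene_count(100, 0, 0), "> 0")
  expect_error(adjust_gene_count(100, 50, 60), "te_domain_genes")
  expect_error(adjust_gene_count(100, 150, 60), "exceeds")
})

test_that("per-species TE fractions report k/F deterministically", {
  mk_cl <- function(k, f) {
    data.frame(gene_id = sprintf("g%03d", seq_len(f + 2)),
               class = c(rep("TE-domain", k), rep("other", f - k),
                         rep("unannotated", 2)),
               stringsAsFactors = FALSE)
  }
  rep <- te_fraction_report(list(spB = mk_cl(25, 100), spA = mk_cl(0, 50)))
  expect_equal(rep$species, c("spA", "spB"))
  expect_equal(rep$te_fraction, c(0, 0.25))
  expect_equal(rep$annotated, c(50, 100))
})
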