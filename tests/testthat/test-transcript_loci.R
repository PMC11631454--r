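test_that("TE-coverage filtering merges hits and applies an inclusive 50%", {
  lens <- c(tx1 = 1000, tx2 = 1000, tx3 = 500)
  hits <- data.frame(
    query_id = c("tx1", "tx1", "tx2"), subject_id = "te_lib",
    pct_identity = 90, aln_length = 100, mismatches = 0, gap_opens = 0,
    q_start = c(1, 201, 1), q_end = c(300, 600, 500),
    s_start = 1, s_end = 300, evalue = 0, bit_score = 100)
  res <- filter_te_transcripts(lens, hits)
  rep <- res$report
  ## [0,300) u [200,600) merges to [0,600): coverage 0.60 -> removed
  expect_equal(rep$coverage[rep$transcript_id == "tx1"], 0.60)
  ## coverage exactly 0.50 is removed (inclusive threshold)
  expect_equal(rep$coverage[rep$transcript_id == "tx2"], 0.50)
  expect_setequal(res$removed, c("tx1", "tx2"))
  ## no hits -> coverage 0 -> kept
  expect_equal(rep$coverage[rep$transcript_id == "tx3"], 0)
  expect_true("tx3" %in% res$kept)
  ## partition and monotonicity in the threshold
  expect_setequal(c(res$kept, res$removed), names(lens))
  stricter <- filter_te_transcripts(lens, hits, threshold = 0.4)
  expect_true(all(res$removed %in% stricter$removed))
  ## unknown query transcript is an error naming the id
  bad <- hits
  bad$query_id[1] <- "nope"
  expect_error(filter_te_transcripts(lens, bad), "nope")
})

test_that("locus clustering links by exon overlap and respects strand", {
  tr <- rbind(
    transcript_model("tA", "s1", data.frame(start = 0, end = 100)),
    transcript_model("tB", "s1", data.frame(start = 99, end = 200)),
    transcript_model("tC", "s1", data.frame(start = 500, end = 600)),
    transcript_model("tD", "s1", data.frame(start = 500, end = 600),
                     strand = "-"))
  loci <- cluster_loci(tr, stranded = TRUE)
  expect_equal(nrow(loci), 3L)
  expect_equal(loci$members[[1]], c("tA", "tB"))
  ## same coordinates on opposite strands: two loci when stranded
  expect_equal(sum(vapply(loci$members, function(m)
    any(c("tC", "tD") %in% m), logical(1))), 2L)
  loci2 <- cluster_loci(tr, stranded = FALSE)
  expect_equal(nrow(loci2), 2L)
  ## span mode links through introns that exon mode keeps apart
  tr2 <- rbind(
    transcript_model("tE", "s1",
                     data.frame(start = c(0, 900), end = c(100, 1000))),
    transcript_model("tF", "s1", data.frame(start = 400, end = 500)))
  expect_equal(nrow(cluster_loci(tr2, mode = "exon")), 2L)
  expect_equal(nrow(cluster_loci(tr2, mode = "span")), 1L)
})

test_that("clustering equals the pairwise union-find oracle", {
  set.seed(31)
  for (i in 1:25) {
    tr <- random_transcripts(sample(10:40, 1))
    for (mode in c("exon", "span")) {
      loci <- cluster_loci(tr, mode = mode, stranded = TRUE)
      got <- loci$members[order(vapply(loci$members, `[`, character(1),
                                       1L))]
      names(got) <- NULL
      expect_equal(got, cluster_oracle(tr, mode = mode, stranded = TRUE))
    }
  }
})

test_that("main-transcript selection: completeness, then length, then id", {
  m <- rbind(
    transcript_model("t1", "s", data.frame(start = 0, end = 1000),
                     orf_has_start = TRUE, orf_has_stop = TRUE,
                     orf_length = 300),
    transcript_model("t2", "s", data.frame(start = 0, end = 1000),
                     orf_has_start = TRUE, orf_has_stop = FALSE,
                     orf_length = 900))
  expect_equal(select_main_transcript(m), "t1")
  m$orf_has_stop <- TRUE
  m$orf_length <- c(300L, 600L)
  expect_equal(select_main_transcript(m), "t2")
  ## one-ended ties resolve by id
  m2 <- rbind(
    transcript_model("tB", "s", data.frame(start = 0, end = 1000),
                     orf_has_start = FALSE, orf_has_stop = TRUE,
                     orf_length = 300),
    transcript_model("tA", "s", data.frame(start = 0, end = 1000),
                     orf_has_start = TRUE, orf_has_stop = FALSE,
                     orf_length = 300))
  expect_equal(select_main_transcript(m2), "tA")
  ## permutation invariance (total order)
  set.seed(8)
  m3 <- random_transcripts(12)
  picks <- vapply(1:10, function(i) {
    select_main_transcript(m3[sample(nrow(m3)), ])
  }, character(1))
  expect_equal(length(unique(picks)), 1L)
  expect_error(select_main_transcript(m3[0, ]), "empty")
})

test_that("BUSCO extrapolation and totals behave arithmetically", {
  expect_equal(max_gene_count(13354, 95.1, 97.2), 13649L)
  expect_equal(max_gene_count(10000, 50.0, 100.0), 20000L)
  ## identity when percentages are equal
  for (n in c(1, 137, 13354)) {
    expect_equal(max_gene_count(n, 77.7, 77.7), as.integer(n))
  }
  expect_error(max_gene_count(100, 0, 50), "> 0")
  expect_warning(max_gene_count(100, 80, 60), "computing anyway")
  expect_equal(busco_total(92.2, 2.9), 95.1)
  expect_equal(busco_total(0, 0), 0)
  expect_error(busco_total(60, 50), "exceeds")
})

test_that("locus statistics summarize main transcripts", {
  tr <- rbind(
    transcript_model("t1", "s1",
                     data.frame(start = c(0, 300, 600, 900),
                                end = c(100, 400, 700, 1000)),
                     orf_has_start = TRUE, orf_has_stop = TRUE,
                     orf_length = 300))
  loci <- cluster_loci(tr)
  st <- locus_stats(loci, tr, scaffold_subset = "s1")
  expect_equal(st$n_loci, 1L)
  expect_equal(st$mean_locus_length, 1000)
  expect_equal(st$mean_exons_main, 4)
  expect_equal(st$fraction_on_subset, 1)
  empty <- locus_stats(loci[0, ], tr)
  expect_true(empty$empty)
  expect_equal(empty$n_loci, 0L)
})
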