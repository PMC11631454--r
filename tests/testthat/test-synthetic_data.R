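test_that("identical config and seed give byte-identical run directories", {
  cfg <- sim_config(seed = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(simulate_dataset(cfg), d1)
  write_simulation(simulate_dataset(cfg), d2)
  files <- list.files(d1)
  expect_true(length(files) >= 8)
  for (f in files) {
    expect_equal(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                 info = f)
  }
  ## a different seed changes the genome
  d3 <- withr::local_tempdir()
  write_simulation(simulate_dataset(sim_config(seed = 4)), d3)
  expect_false(identical(readLines(file.path(d1, "genome.fa")),
                         readLines(file.path(d3, "genome.fa"))))
})

test_that("planted features respect the config and never overlap", {
  cfg <- sim_config(seed = 9)
  sim <- simulate_dataset(cfg)
  ## per-family copy counts and stop-flag counts follow the spec list
  for (fam in cfg$gene_families) {
    cp <- sim$copies[sim$copies$gene_id == fam$family_id, ]
    expect_equal(nrow(cp), fam$n_copies)
    expect_equal(sum(cp$stop_flag),
                 round(fam$premature_stop_fraction * fam$n_copies))
    ## multi-copy families span at least two scaffolds
    if (fam$n_copies >= 2) {
      expect_gte(length(unique(cp$scaffold)), 2L)
    }
  }
  ## all planted intervals are mutually disjoint and inside scaffolds
  feats <- rbind(sim$repeats[, c("scaffold", "start", "end")],
                 sim$copies[, c("scaffold", "start", "end")],
                 sim$ssrs[, c("scaffold", "start", "end")])
  lens <- setNames(Biostrings::width(sim$genome), names(sim$genome))
  expect_true(all(feats$end <= lens[feats$scaffold]))
  for (sc in unique(feats$scaffold)) {
    f <- feats[feats$scaffold == sc, ]
    ir <- IRanges::IRanges(f$start + 1L, f$end)
    expect_equal(sum(IRanges::width(IRanges::reduce(ir))),
                 sum(IRanges::width(ir)))
  }
  ## hit table has one row per planted copy with consistent identity
  expect_equal(nrow(sim$hits), nrow(sim$copies))
  for (fam in cfg$gene_families) {
    h <- sim$hits[sim$hits$query_id == fam$family_id, ]
    expect_equal(h$aln_length, rep(fam$cds_length %/% 3L, fam$n_copies))
    if (fam$n_copies > 1) {
      expect_equal(sort(h$pct_identity, decreasing = TRUE)[1], 100)
      expect_true(all(abs(h$pct_identity[h$pct_identity < 100] -
                            100 * (1 - fam$divergence)) < 2))
    }
  }
})

test_that("domain table covers the configured fraction with truthful labels", {
  cfg <- sim_config(seed = 13, annotated_fraction = 0.5)
  sim <- simulate_dataset(cfg)
  n_te <- sum(sim$genes$is_te_derived)
  n_other <- sum(!sim$genes$is_te_derived)
  expect_equal(nrow(sim$domain_table),
               floor(0.5 * n_te) + floor(0.5 * n_other))
  cl <- classify_genes(sim$domain_table)
  ann_te <- intersect(cl$gene_id[cl$class == "TE-domain"],
                      sim$truth$te_gene_ids)
  expect_equal(sort(cl$gene_id[cl$class == "TE-domain"]), sort(ann_te))
  pc <- cl$gene_id[cl$class == "PCWDE"]
  expect_true(all(pc %in% sim$truth$pcwde_gene_ids))
})

test_that("packing beyond scaffold capacity fails before emitting", {
  cfg <- sim_config(seed = 1, scaffold_lengths = c(a = 20000L, b = 20000L),
                    te_families = list(te_family("big", 2000, 30, 0.1)),
                    gene_families = list(), ssr_spec = list())
  expect_error(simulate_dataset(cfg), "infeasible packing")
})

test_that("hit noise adds only filter-violating rows and keeps truth", {
  sim <- simulate_dataset(sim_config(seed = 6))
  ## rate 0 is the identity
  expect_identical(emit_hit_noise(sim$hits, 0, seed = 1), sim$hits)
  noisy <- emit_hit_noise(sim$hits, 0.5, seed = 2)
  ## true rows retained verbatim, in order
  expect_equal(noisy[seq_len(nrow(sim$hits)), ], sim$hits,
               ignore_attr = "row.names")
  added <- noisy[-seq_len(nrow(sim$hits)), ]
  expect_gt(nrow(added), 0)
  ## deterministic under the seed
  expect_identical(emit_hit_noise(sim$hits, 0.5, seed = 2), noisy)
  ## every spurious row violates a copy-number filter
  expect_true(all(added$aln_length < 50 | added$pct_identity < 50))
  ## so filtered copy counts are unchanged by noise
  ct_clean <- copy_number_table(sim$hits, sim$genes$gene_id)
  ct_noisy <- copy_number_table(noisy, sim$genes$gene_id)
  expect_equal(ct_noisy$copy_count, ct_clean$copy_count)
  expect_equal(setNames(ct_noisy$copy_count[ct_noisy$min_identity == 50 &
                                              ct_noisy$max_gap == 20000],
                        ct_noisy$gene_id[ct_noisy$min_identity == 50 &
                                           ct_noisy$max_gap == 20000]),
               sim$truth$copy_number[ct_noisy$gene_id[
                 ct_noisy$min_identity == 50 & ct_noisy$max_gap == 20000]])
})

test_that("simulated transcripts read back through the GFF3 boundary", {
  sim <- simulate_dataset(sim_config(seed = 2))
  d <- withr::local_tempdir()
  write_simulation(sim, d)
  tr <- read_gff3_transcripts(file.path(d, "transcripts.gff3"))
  expect_equal(nrow(tr), nrow(sim$transcripts))
  m <- match(sim$transcripts$transcript_id, tr$transcript_id)
  expect_equal(tr$start[m], sim$transcripts$start)
  expect_equal(tr$end[m], sim$transcripts$end)
  expect_true(all(tr$orf_has_start & tr$orf_has_stop))
  ## genome and hit table round-trip through their readers too
  genome <- read_fasta(file.path(d, "genome.fa"))
  expect_equal(as.character(genome), as.character(sim$genome))
  expect_equal(read_hits(file.path(d, "hits.tsv"))$pct_identity,
               sim$hits$pct_identity)
})
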