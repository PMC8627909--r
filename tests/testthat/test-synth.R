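test_that("generators are byte-deterministic under a fixed seed", {
  cfg <- synth_config(n_transcripts = 10, n_reads = 50, seed = 7)
  t1 <- simulate_transcripts(cfg)
  t2 <- simulate_transcripts(cfg)
  expect_identical(t1, t2)
  a1 <- simulate_assemblies(t1$transcripts, cfg)
  a2 <- simulate_assemblies(t1$transcripts, cfg)
  expect_identical(lapply(a1$assemblies, contig_strings),
                   lapply(a2$assemblies, contig_strings))
  r1 <- simulate_reads(t1$transcripts, cfg)
  r2 <- simulate_reads(t1$transcripts, cfg)
  expect_identical(as.character(r1$reads), as.character(r2$reads))
  # and FASTA bytes round-trip identically
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(assembly(t1$transcripts, "t"), f1)
  write_fasta(assembly(t2$transcripts, "t"), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("every simulated transcript carries a complete ORF of at least 30 residues", {
  cfg <- synth_config(n_transcripts = 25, seed = 11)
  tr <- simulate_transcripts(cfg)
  for (s in tr$transcripts) {
    calls <- find_orfs(s, min_aa = 30)
    expect_gte(nrow(calls), 1L)
  }
  # fixed-length config produces exactly that length
  cfg300 <- synth_config(n_transcripts = 10, length_range = c(300, 300),
                         seed = 3)
  expect_true(all(nchar(simulate_transcripts(cfg300)$transcripts) == 300))
  expect_error(simulate_transcripts(
    synth_config(n_transcripts = 2, length_range = c(60, 90), seed = 1)),
    "ORF")
})

test_that("assembly simulation plants the configured number of exact duplicates", {
  cfg <- synth_config(n_transcripts = 40, redundancy_rate = 0.3, seed = 13)
  tr <- simulate_transcripts(cfg)
  sa <- simulate_assemblies(tr$transcripts, cfg)
  prov <- sa$truth$contig_provenance
  expect_equal(length(sa$assemblies), 4L)
  expect_equal(sort(vapply(sa$assemblies, function(a) a$label, character(1))),
               paste0("asm", 1:4))
  for (a in sa$assemblies) {
    p <- prov[prov$assembly == a$label, ]
    expect_equal(sum(p$is_planted), floor(0.3 * 40))
    expect_equal(n_contigs(a), 40 + floor(0.3 * 40))
    # each planted duplicate is a verbatim substring of its container
    seqs <- contig_strings(a)
    for (r in which(p$is_planted)) {
      expect_true(grepl(seqs[[p$contig_id[r]]],
                        seqs[[p$container_contig_id[r]]], fixed = TRUE))
    }
  }
})

test_that("with error-free contigs dedup removes exactly the planted duplicates", {
  for (r in c(0.1, 0.3, 0.5)) {
    cfg <- synth_config(n_transcripts = 30, redundancy_rate = r,
                        sub_error_rate = 0, seed = 17)
    tr <- simulate_transcripts(cfg)
    sa <- simulate_assemblies(tr$transcripts, cfg)
    prov <- sa$truth$contig_provenance
    for (a in sa$assemblies) {
      res <- remove_redundant(a)
      planted <- prov$contig_id[prov$assembly == a$label & prov$is_planted]
      expect_setequal(names(res$report$removed), planted)
    }
  }
})

test_that("simulated reads respect the configured length range and provenance", {
  cfg <- synth_config(n_transcripts = 20, n_reads = 300, seed = 19)
  tr <- simulate_transcripts(cfg)
  rd <- simulate_reads(tr$transcripts, cfg)
  w <- Biostrings::width(rd$reads)
  expect_true(all(w >= 50 & w <= 270))
  # error-free reads are exact transcript substrings and all map back
  cfg0 <- synth_config(n_transcripts = 20, n_reads = 300,
                       read_error_rate = 0, low_quality_fraction = 0,
                       seed = 19)
  rd0 <- simulate_reads(tr$transcripts, cfg0)
  prov <- rd0$truth$read_provenance
  seqs <- as.character(rd0$reads)
  for (i in sample(length(seqs), 25)) {
    span <- substr(tr$transcripts[[prov$transcript_id[i]]],
                   prov$start[i] + 1, prov$end[i])
    got <- if (prov$strand[i] == "-") revcomp(seqs[[i]]) else seqs[[i]]
    expect_identical(got, span)
  }
  idx <- build_index(assembly(tr$transcripts, "truth"))
  expect_equal(map_rate(rd0$reads, idx)$pct_mapped, 100.00)
})

test_that("the low-quality read fraction is recovered by the filter within binomial tolerance", {
  cfg <- synth_config(n_transcripts = 20, n_reads = 4000,
                      low_quality_fraction = 0.2, seed = 23)
  tr <- simulate_transcripts(cfg)
  rd <- simulate_reads(tr$transcripts, cfg)
  res <- filter_reads(rd$reads)
  p_hat <- res$stats$reasons[["low_quality"]] / res$stats$n_in
  # 4 sigma around 0.2 at n = 4000 (sd ~ 0.0063)
  expect_lt(abs(p_hat - 0.2), 4 * sqrt(0.2 * 0.8 / 4000))
})
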