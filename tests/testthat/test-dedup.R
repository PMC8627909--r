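test_that("merging concatenates contigs with source-prefixed ids", {
  a <- assembly(c(x = "ACGTACGTACG", y = "TTTTCCCCAAA", z = "GACGATTACAG"), "a1")
  b <- assembly(c(x = "ACGTACGTACG", w = "CATCATCATGG", v = "GGGTTTAAACC",
                  u = "TACGATCGATC"), "a2")
  m <- merge_assemblies(list(a, b), label = "meta")
  expect_equal(n_contigs(m), 7L)
  expect_equal(contig_ids(m)[1:3], c("a1|x", "a1|y", "a1|z"))
  expect_equal(m$source, c(rep("a1", 3), rep("a2", 4)))
  # single assembly: identical content, prefixed ids
  one <- merge_assemblies(list(a))
  expect_equal(unname(contig_strings(one)), unname(contig_strings(a)))
  # id collision after prefixing errors
  expect_error(merge_assemblies(list(a, a)), "collision")
})

test_that("substring and identical-duplicate contigs are removed deterministically", {
  res <- remove_redundant(assembly(c(A = "ATGCAT", B = "GCA"), "t"))
  expect_equal(res$report$retained, "A")
  expect_equal(res$report$removed, c(B = "A"))

  # identical pair: lexicographically smaller id survives
  res <- remove_redundant(assembly(c(bb = "ACGTACGT", aa = "ACGTACGT"), "t"))
  expect_equal(res$report$retained, "aa")
  expect_equal(res$report$removed, c(bb = "aa"))

  # reverse-complement containment counts by default, can be disabled
  res <- remove_redundant(assembly(c(A = "AAATGCATCC", B = "ATGCGTT"), "t"))
  expect_equal(res$report$retained, c("A", "B"))  # B not a fwd/rc substring
  rc_in <- assembly(c(A = "AAATGCATCC", B = revcomp("ATGCATC")), "t")
  expect_equal(remove_redundant(rc_in)$report$retained, "A")
  expect_equal(remove_redundant(rc_in,
                                consider_revcomp = FALSE)$report$retained,
               c("A", "B"))
})

test_that("container reporting prefers the longest retained container", {
  x <- assembly(c(long = paste0("AAAA", "TTTGGGCCC", "AAAA"),
                  mid = paste0("TTTGGGCCC", "A"),
                  short = "TTTGGGCCC"), "t")
  res <- remove_redundant(x)
  expect_equal(unname(res$report$removed["short"]), "long")
})

test_that("dedup matches the quadratic all-pairs oracle on planted instances", {
  withr::local_seed(101)
  for (rep in 1:8) {
    n_base <- sample(40:120, 1)
    seqs <- vapply(sample(60:800, n_base, replace = TRUE),
                   random_dna, character(1))
    # plant substrings and revcomp substrings
    n_dup <- sample(10:40, 1)
    for (d in seq_len(n_dup)) {
      src <- sample(length(seqs), 1)
      L <- nchar(seqs[src])
      dl <- sample(50:L, 1)
      st <- sample(0:(L - dl), 1)
      dup <- substr(seqs[src], st + 1, st + dl)
      if (runif(1) < 0.5) dup <- rc_chr(dup)
      seqs <- c(seqs, dup)
    }
    names(seqs) <- sprintf("c%04d", seq_along(seqs))
    res <- remove_redundant(assembly(seqs, "t"))
    expect_equal(sort(res$report$retained), oracle_retained(seqs))
    # every removed contig truly occurs in its container
    for (j in seq_along(res$report$removed)) {
      rid <- names(res$report$removed)[j]
      cid <- res$report$removed[[j]]
      expect_true(grepl(seqs[[rid]], seqs[[cid]], fixed = TRUE) ||
                    grepl(rc_chr(seqs[[rid]]), seqs[[cid]], fixed = TRUE))
    }
  }
})

test_that("dedup is idempotent and retained sequences are order-insensitive", {
  withr::local_seed(55)
  seqs <- vapply(sample(60:400, 60, replace = TRUE), random_dna, character(1))
  seqs <- c(seqs, vapply(sample(seq_along(seqs), 25, replace = TRUE),
                         function(i) {
                           L <- nchar(seqs[i])
                           dl <- sample(50:L, 1)
                           st <- sample(0:(L - dl), 1)
                           substr(seqs[i], st + 1, st + dl)
                         }, character(1)))
  names(seqs) <- sprintf("c%03d", seq_along(seqs))
  once <- remove_redundant(assembly(seqs, "t"))
  twice <- remove_redundant(once$assembly)
  expect_equal(twice$report$n_after, once$report$n_after)
  expect_equal(length(twice$report$removed), 0L)

  perm <- sample(seq_along(seqs))
  shuffled <- remove_redundant(assembly(seqs[perm], "t"))
  expect_equal(sort(unname(contig_strings(shuffled$assembly))),
               sort(unname(contig_strings(once$assembly))))
  # retained contigs preserve input order
  expect_equal(once$report$retained,
               intersect(names(seqs), once$report$retained))
})

test_that("retention percentage reproduces the published meta-assembly figures", {
  expect_identical(reduction_percent(169232, 68414), 40.4)
  expect_identical(reduction_percent(133070, 32466), 24.4)
  expect_identical(reduction_percent(1000, 1000), 100)
  expect_error(reduction_percent(0, 0), "positive")
})

test_that("coding-only filter keeps exactly the ORF-bearing contigs", {
  withr::local_seed(9)
  orf <- paste0("ATG", paste(rep("GCT", 35), collapse = ""), "TAA")
  coding <- paste0(random_dna(50), orf, random_dna(50))
  noncoding <- paste(rep("GGC", 80), collapse = "")
  x <- assembly(c(yes = coding, no = noncoding), "t")
  expect_equal(contig_ids(coding_filter(x, min_aa = 30)), "yes")
})
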