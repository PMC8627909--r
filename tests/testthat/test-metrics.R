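test_that("N50 follows the cumulative-half definition", {
  expect_equal(n50(c(6, 5, 4, 3, 2)), 5)
  expect_equal(n50(c(42)), 42)
  expect_equal(n50(rep(7, 13)), 7)
  expect_error(n50(integer(0)), "empty")
  withr::local_seed(13)
  for (i in 1:20) {
    lens <- sample(1:5000, sample(1:200, 1), replace = TRUE)
    expect_equal(n50(lens), oracle_n50(lens))
    expect_gte(n50(lens), median(lens))
  }
})

test_that("length statistics match a naive recomputation and the published mean", {
  expect_equal(mean_contig_length(46440750, 68414), 678.8)
  a <- assembly(stats::setNames(
    vapply(c(1, 2, 3, 4) * 10, random_dna, character(1)),
    c("a", "b", "c", "d")), "t")
  st <- length_stats(a)
  expect_equal(st$median_len, 25)  # even count averages central values
  withr::local_seed(29)
  lens <- sample(100:2000, 31, replace = TRUE)
  a <- assembly(stats::setNames(vapply(lens, random_dna, character(1)),
                                sprintf("c%02d", 1:31)), "t")
  st <- length_stats(a)
  expect_equal(st$n_contigs, 31L)
  expect_equal(st$total_len, sum(lens))
  expect_equal(st$mean_len, round_half_up(sum(lens) / 31, 1))
  expect_equal(st$median_len, sort(lens)[16])
  expect_equal(st$max_len, max(lens))
  expect_true(st$max_len >= st$n50 && st$n50 >= st$median_len)
  expect_error(length_stats(assembly(character(0), "e")), "empty")
})

test_that("identical query/target aligns full span at identity 1", {
  withr::local_seed(31)
  s <- random_dna(400)
  h <- local_align(s, s)
  expect_equal(nrow(h), 1L)
  expect_equal(h$identity, 1.0)
  expect_equal(c(h$cds_start, h$cds_end), c(0L, 400L))
  expect_equal(h$strand, "+")
})

test_that("k-mer-disjoint sequences yield no hits and planted inserts are recovered", {
  withr::local_seed(37)
  repeat {
    q <- random_dna(300)
    t <- random_dna(500)
    shared <- intersect(substring(q, 1:(300 - 30), 31:300),
                        substring(t, 1:(500 - 30), 31:500))
    rcq <- rc_chr(q)
    shared_rc <- intersect(substring(rcq, 1:(300 - 30), 31:300),
                           substring(t, 1:(500 - 30), 31:500))
    if (length(shared) == 0 && length(shared_rc) == 0) break
  }
  expect_equal(nrow(local_align(q, t)), 0L)

  # plant a 200-nt exact insert of the query inside the target
  insert <- substr(q, 51, 250)
  t2 <- paste0(random_dna(150), insert, random_dna(150))
  h <- local_align(q, t2)
  expect_gte(max(h$length), 200L)
  best <- h[which.max(h$length), ]
  expect_equal(best$identity, 1.0)
})

test_that("alignment hits are strand-symmetric", {
  withr::local_seed(41)
  t <- random_dna(600)
  q <- paste0(random_dna(40), substr(t, 101, 400), random_dna(40))
  fwd <- local_align(q, t)
  rev <- local_align(rc_chr(q), t)
  expect_equal(nrow(fwd), nrow(rev))
  o1 <- order(fwd$cds_start, fwd$cds_end)
  o2 <- order(rev$cds_start, rev$cds_end)
  expect_equal(fwd$cds_start[o1], rev$cds_start[o2])
  expect_equal(fwd$cds_end[o1], rev$cds_end[o2])
  expect_equal(fwd$identity[o1], rev$identity[o2])
  expect_true(all(fwd$strand[o1] != rev$strand[o2]))
})

test_that("CDS recovery reports coverage, the 95% class and contig-hit percentage", {
  withr::local_seed(43)
  ref <- stats::setNames(vapply(c(400, 500, 600), random_dna, character(1)),
                         c("cds1", "cds2", "cds3"))
  # contigs identical to the reference: everything detected and full
  a <- assembly(stats::setNames(unname(ref), c("k1", "k2", "k3")), "t")
  rec <- cds_recovery(a, ref)
  expect_setequal(rec$detected, names(ref))
  expect_setequal(rec$full95, names(ref))
  expect_equal(rec$pct_contigs_with_hit, 100)
  expect_equal(unname(rec$coverage[order(names(rec$coverage))]), rep(1, 3))

  # one contig covering 90% of one CDS: detected but not full95
  a90 <- assembly(c(p = substr(ref[["cds1"]], 1, 360)), "t")
  rec <- cds_recovery(a90, ref)
  expect_equal(rec$detected, "cds1")
  expect_equal(length(rec$full95), 0L)
  expect_equal(unname(rec$coverage["cds1"]), 0.9)

  # empty assembly: all counts zero
  rec <- cds_recovery(assembly(character(0), "e"), ref)
  expect_equal(length(rec$detected), 0L)
  expect_equal(rec$pct_contigs_with_hit, 0)
})

test_that("coverage is monotone under added contigs", {
  withr::local_seed(47)
  ref <- stats::setNames(vapply(rep(600, 4), random_dna, character(1)),
                         sprintf("cds%d", 1:4))
  frags <- lapply(1:4, function(i) substr(ref[[i]], 100, 450))
  a1 <- assembly(stats::setNames(unlist(frags[1:2]), c("f1", "f2")), "t")
  a2 <- assembly(stats::setNames(unlist(frags), sprintf("f%d", 1:4)), "t")
  r1 <- cds_recovery(a1, ref)
  r2 <- cds_recovery(a2, ref)
  expect_true(all(r1$detected %in% r2$detected))
  expect_true(all(r1$full95 %in% r2$full95))
  for (cid in r1$detected) {
    expect_gte(r2$coverage[[cid]], r1$coverage[[cid]])
  }
})
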