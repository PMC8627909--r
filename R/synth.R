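#' Configuration for the synthetic-data generators
#'
#' Defines the study conditions the generators emulate: a set of
#' protein-coding transcripts, several error-bearing, partially fragmented
#' assemblies of them with planted substring-redundant contigs, and an
#' IonTorrent-like single-end read library of variable length (50-270 nt)
#' with per-base Phred qualities.
#'
#' @param n_transcripts number of transcripts (default 100).
#' @param length_range transcript length range in nt (default 300-3000;
#'   every transcript carries a complete ORF of at least `min_aa` codons, so
#'   the minimum feasible length is `3 * (min_aa + 2)`).
#' @param gc GC fraction of background sequence (default 0.45, a typical
#'   plant-transcript composition).
#' @param n_assemblies number of candidate assemblies (default 4, the usual
#'   several-assembler setting).
#' @param redundancy_rate fraction of planted substring-duplicate contigs
#'   added per assembly (default 0.3).
#' @param fragmentation_rate fraction of transcripts represented only by a
#'   partial contig in a given assembly (default 0.3).
#' @param sub_error_rate per-base substitution probability in contigs
#'   (default 0.005).
#' @param n_reads reads in the simulated library (default 2000).
#' @param read_length_range read length range (default c(50, 270)).
#' @param read_error_rate per-base substitution probability in reads
#'   (default 0.01).
#' @param low_quality_fraction fraction of reads given low per-base
#'   qualities (mean Phred < 20) for filter testing (default 0.1).
#' @param min_aa minimum planted ORF length in residues (default 30).
#' @param seed integer RNG seed; each generator uses `seed` plus a fixed
#'   per-generator offset so the three generators are independently
#'   reproducible.
#' @return list of class `"synth_config"`.
#' @export
synth_config <- function(n_transcripts = 100L,
                         length_range = c(300L, 3000L),
                         gc = 0.45,
                         n_assemblies = 4L,
                         redundancy_rate = 0.3,
                         fragmentation_rate = 0.3,
                         sub_error_rate = 0.005,
                         n_reads = 2000L,
                         read_length_range = c(50L, 270L),
                         read_error_rate = 0.01,
                         low_quality_fraction = 0.1,
                         min_aa = 30L,
                         seed = 1L) {
  cfg <- list(n_transcripts = as.integer(n_transcripts),
              length_range = as.integer(length_range),
              gc = gc, n_assemblies = as.integer(n_assemblies),
              redundancy_rate = redundancy_rate,
              fragmentation_rate = fragmentation_rate,
              sub_error_rate = sub_error_rate,
              n_reads = as.integer(n_reads),
              read_length_range = as.integer(read_length_range),
              read_error_rate = read_error_rate,
              low_quality_fraction = low_quality_fraction,
              min_aa = as.integer(min_aa),
              seed = as.integer(seed))
  rates <- c(cfg$gc, cfg$redundancy_rate, cfg$fragmentation_rate,
             cfg$sub_error_rate, cfg$read_error_rate,
             cfg$low_quality_fraction)
  stopifnot(all(rates >= 0 & rates <= 1),
            cfg$length_range[1] > 0,
            cfg$length_range[1] <= cfg$length_range[2],
            cfg$read_length_range[1] > 0,
            cfg$read_length_range[1] <= cfg$read_length_range[2],
            cfg$n_transcripts >= 1L, cfg$n_assemblies >= 1L)
  structure(cfg, class = "synth_config")
}

# uniform integer draw on [lo, hi], safe against R's scalar-sample rule
.rint <- function(lo, hi, n = 1L) {
  if (lo >= hi) rep(as.integer(lo), n) else
    sample(seq.int(lo, hi), n, replace = TRUE)
}

.BASES <- c("A", "C", "G", "T")
.NONSTOP_CODONS <- {
  cod <- as.vector(outer(as.vector(outer(.BASES, .BASES, paste0)),
                         .BASES, paste0))
  setdiff(cod, c("TAA", "TAG", "TGA"))
}

.random_dna <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(.BASES, n, replace = TRUE, prob = p), collapse = "")
}

.mutate <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(.BASES, ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

#' Simulate CDS-bearing transcripts
#'
#' Each transcript is random background sequence at the configured GC with
#' one planted complete ORF (ATG, at least `min_aa` sense codons, stop), so
#' six-frame ORF scanning and coding-only filtering always have signal.
#' Output is byte-identical across runs with the same config.
#'
#' @param config a [synth_config()].
#' @return list with `transcripts` (named character vector, ids `t0001`...)
#'   and `truth`, a list with `orf` (data.frame of planted ORF spans).
#' @export
simulate_transcripts <- function(config) {
  stopifnot(is(config, "synth_config"))
  min_nt <- 3L * (config$min_aa + 2L)
  if (config$length_range[2] < min_nt) {
    stop("length_range too short to hold an ORF of ", config$min_aa,
         " residues (needs >= ", min_nt, " nt)")
  }
  with_seed(config$seed + 101L, {
    n <- config$n_transcripts
    ids <- sprintf("t%04d", seq_len(n))
    lens <- .rint(max(config$length_range[1], min_nt),
                  config$length_range[2], n)
    seqs <- character(n)
    orf_rows <- vector("list", n)
    for (i in seq_len(n)) {
      L <- lens[i]
      max_aa <- min(300L, (L - 6L) %/% 3L - 1L)
      aa <- .rint(config$min_aa, max_aa)
      orf_nt <- 3L * (aa + 2L)
      start <- .rint(0L, L - orf_nt)
      orf <- paste0("ATG",
                    paste(sample(.NONSTOP_CODONS, aa, replace = TRUE),
                          collapse = ""),
                    "TAA")
      bg <- .random_dna(L, config$gc)
      seqs[i] <- paste0(substr(bg, 1L, start), orf,
                        substr(bg, start + orf_nt + 1L, L))
      orf_rows[[i]] <- data.frame(transcript_id = ids[i], start = start,
                                  end = start + orf_nt, aa_length = aa)
    }
    names(seqs) <- ids
    list(transcripts = seqs,
         truth = list(orf = do.call(rbind, orf_rows)))
  })
}

#' Simulate redundant multi-source assemblies
#'
#' Each assembly holds one contig per transcript — full length, or a
#' fragment (at least 200 nt) with probability `fragmentation_rate` — with
#' substitution errors at `sub_error_rate`; contigs are strand-flipped with
#' probability 1/2, as de novo contigs are strand-ambiguous.  Then
#' `floor(redundancy_rate * n_base)` planted duplicates are added: exact
#' substrings (at least 200 nt) of already-mutated contigs of the same
#' assembly, flagged in the provenance table, so redundancy-removal ground
#' truth is exact even when `sub_error_rate > 0`.
#'
#' @param transcripts named character vector from [simulate_transcripts()].
#' @param config a [synth_config()].
#' @return list with `assemblies` (list of [assembly()], labels `asm1`...)
#'   and `truth`: data.frame `contig_provenance` with columns `contig_id`,
#'   `assembly`, `transcript_id`, `start`, `end`, `strand`, `is_planted`,
#'   `container_contig_id`.
#' @export
simulate_assemblies <- function(transcripts, config) {
  stopifnot(is(config, "synth_config"), length(transcripts) >= 1L)
  with_seed(config$seed + 202L, {
    assemblies <- vector("list", config$n_assemblies)
    prov <- list()
    min_frag <- 200L
    for (a in seq_len(config$n_assemblies)) {
      lab <- paste0("asm", a)
      ids <- character(0); seqs <- character(0)
      for (ti in seq_along(transcripts)) {
        tseq <- transcripts[[ti]]
        L <- nchar(tseq)
        frag <- runif(1) < config$fragmentation_rate && L > min_frag
        if (frag) {
          flen <- .rint(min_frag, L)
          fstart <- .rint(0L, L - flen)
        } else {
          flen <- L; fstart <- 0L
        }
        s <- substr(tseq, fstart + 1L, fstart + flen)
        s <- .mutate(s, config$sub_error_rate)
        strand <- if (runif(1) < 0.5) "+" else "-"
        if (strand == "-") s <- revcomp(s)
        cid <- sprintf("%s_c%04d", lab, length(ids) + 1L)
        ids <- c(ids, cid); seqs <- c(seqs, s)
        prov[[length(prov) + 1L]] <- data.frame(
          contig_id = cid, assembly = lab,
          transcript_id = names(transcripts)[ti],
          start = fstart, end = fstart + flen, strand = strand,
          is_planted = FALSE, container_contig_id = NA_character_)
      }
      n_base <- length(ids)
      n_dup <- floor(config$redundancy_rate * n_base)
      eligible <- which(nchar(seqs) >= min_frag)
      if (length(eligible) == 0L) n_dup <- 0L
      for (d in seq_len(n_dup)) {
        ci <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
        cs <- seqs[ci]
        dlen <- .rint(min_frag, nchar(cs))
        dstart <- .rint(0L, nchar(cs) - dlen)
        dup <- substr(cs, dstart + 1L, dstart + dlen)
        cid <- sprintf("%s_c%04d", lab, n_base + d)
        ids <- c(ids, cid); seqs <- c(seqs, dup)
        prov[[length(prov) + 1L]] <- data.frame(
          contig_id = cid, assembly = lab,
          transcript_id = NA_character_,
          start = dstart, end = dstart + dlen, strand = "+",
          is_planted = TRUE, container_contig_id = ids[ci])
      }
      names(seqs) <- ids
      assemblies[[a]] <- assembly(seqs, lab)
    }
    list(assemblies = assemblies,
         truth = list(contig_provenance = do.call(rbind, prov)))
  })
}

# Phred+33 quality string from integer scores
.qual_string <- function(q) {
  intToUtf8(q + 33L)
}

#' Simulate an IonTorrent-like single-end read library
#'
#' Read lengths are uniform over `read_length_range` (capped at the source
#' transcript length), strand uniform, substitutions at `read_error_rate`.
#' Per-base qualities are drawn from a high range (mean Phred well above 20)
#' except for a `low_quality_fraction` of reads drawn from a low range
#' (mean below 20), so the quality filter has a known positive class.
#'
#' @param transcripts named character vector from [simulate_transcripts()].
#' @param config a [synth_config()].
#' @return list with `reads` (a [Biostrings::QualityScaledDNAStringSet],
#'   ids `r000001`...), and `truth`: data.frame `read_provenance` with
#'   `read_id`, `transcript_id`, `start`, `end`, `strand`, `low_quality`.
#' @export
simulate_reads <- function(transcripts, config) {
  stopifnot(is(config, "synth_config"), length(transcripts) >= 1L)
  with_seed(config$seed + 303L, {
    n <- config$n_reads
    ids <- sprintf("r%06d", seq_len(n))
    tidx <- sample(length(transcripts), n, replace = TRUE)
    seqs <- character(n)
    quals <- character(n)
    rows <- vector("list", n)
    low <- runif(n) < config$low_quality_fraction
    for (i in seq_len(n)) {
      tseq <- transcripts[[tidx[i]]]
      L <- nchar(tseq)
      rl <- .rint(config$read_length_range[1], config$read_length_range[2])
      rl <- min(rl, L)
      start <- .rint(0L, L - rl)
      s <- substr(tseq, start + 1L, start + rl)
      s <- .mutate(s, config$read_error_rate)
      strand <- if (runif(1) < 0.5) "+" else "-"
      if (strand == "-") s <- revcomp(s)
      q <- if (low[i]) sample(2:15, rl, replace = TRUE) else
        sample(28:40, rl, replace = TRUE)
      seqs[i] <- s
      quals[i] <- .qual_string(q)
      rows[[i]] <- data.frame(read_id = ids[i],
                              transcript_id = names(transcripts)[tidx[i]],
                              start = start, end = start + rl,
                              strand = strand, low_quality = low[i])
    }
    dna <- Biostrings::DNAStringSet(seqs)
    names(dna) <- ids
    reads <- Biostrings::QualityScaledDNAStringSet(
      dna, Biostrings::PhredQuality(quals))
    list(reads = reads,
         truth = list(read_provenance = do.call(rbind, rows)))
  })
}
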