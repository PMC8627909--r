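# Independent brute-force oracles and small fixture builders.  These are
# deliberately naive (loops, all-pairs, codon-by-codon) so they share no
# code path with the package implementations they check.

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

rc_chr <- function(x) {
  vapply(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# O(n^2) all-pairs substring-containment dedup: greedy longest-first
# (ties: smallest id), a contig is removed iff contained in an
# already-retained contig (forward, or revcomp when consider_revcomp).
oracle_retained <- function(seqs, consider_revcomp = TRUE) {
  ids <- names(seqs)
  ord <- order(-nchar(seqs), ids)
  retained <- character(0)
  for (j in ord) {
    contained <- FALSE
    for (rid in retained) {
      if (grepl(seqs[[j]], seqs[[rid]], fixed = TRUE) ||
          (consider_revcomp &&
           grepl(rc_chr(seqs[[j]]), seqs[[rid]], fixed = TRUE))) {
        contained <- TRUE
        break
      }
    }
    if (!contained) retained <- c(retained, ids[j])
  }
  sort(retained)
}

GENETIC_CODE_TAB <- local({
  b <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- character(0)
  for (b1 in b) for (b2 in b) for (b3 in b) {
    codons <- c(codons, paste0(b1, b2, b3))
  }
  names(aa) <- codons
  aa
})

oracle_translate_codon <- function(codon) {
  if (grepl("N", codon, fixed = TRUE)) return("X")
  unname(GENETIC_CODE_TAB[codon])
}

# Naive six-frame codon walk: per strand and offset, track the leftmost ATG
# of the current stop-free segment and emit on every in-frame stop.
oracle_orfs <- function(seq, min_aa = 30) {
  L <- nchar(seq)
  out <- list()
  for (sgn in c(1, -1)) {
    s <- if (sgn == 1) seq else rc_chr(seq)
    for (off in 0:2) {
      first_atg <- NA
      pos <- off
      while (pos + 3 <= L) {
        codon <- substr(s, pos + 1, pos + 3)
        aa <- oracle_translate_codon(codon)
        if (is.na(first_atg) && aa == "M") first_atg <- pos
        if (aa == "*") {
          if (!is.na(first_atg)) {
            aa_len <- (pos - first_atg) / 3
            if (aa_len >= min_aa) {
              a <- first_atg; b <- pos + 3
              out[[length(out) + 1]] <- data.frame(
                frame = sgn * (off + 1),
                start = if (sgn == 1) a else L - b,
                end = if (sgn == 1) b else L - a,
                aa_length = aa_len)
            }
          }
          first_atg <- NA
        }
        pos <- pos + 3
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(frame = integer(0), start = integer(0),
                      end = integer(0), aa_length = integer(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$frame), , drop = FALSE]
}

oracle_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  half <- sum(s) / 2
  acc <- 0
  for (x in s) {
    acc <- acc + x
    if (acc >= half) return(x)
  }
}

# brute-force exclusive Venn regions via per-item membership keys
oracle_regions <- function(lists) {
  labels <- names(lists)
  universe <- unique(unlist(lists))
  counts <- list()
  for (item in universe) {
    members <- labels[vapply(lists, function(s) item %in% s, logical(1))]
    key <- paste(members, collapse = "&")
    counts[[key]] <- (counts[[key]] %||% 0L) + 1L
  }
  unlist(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# quality-scaled read set from plain sequences and integer qualities
make_reads <- function(seqs, quals = NULL) {
  if (is.null(quals)) quals <- lapply(nchar(seqs), function(n) rep(35L, n))
  dna <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) names(dna) <- sprintf("r%04d", seq_along(seqs))
  q <- Biostrings::PhredQuality(vapply(quals, function(x) {
    intToUtf8(x + 33L)
  }, character(1)))
  Biostrings::QualityScaledDNAStringSet(dna, q)
}
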