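#' Translate a nucleotide sequence (standard genetic code)
#'
#' Length must be a multiple of 3.  Codons containing N translate to `X`;
#' stop codons to `*`.
#'
#' @param seq nucleotide string over {A,C,G,T,N}.
#' @return amino-acid string.
#' @export
#' @examples
#' translate_dna("ATGAAATAA")  # "MK*"
translate_dna <- function(seq) {
  seq <- close_alphabet(seq)
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    stop("sequence length (", n, ") is not a multiple of 3")
  }
  if (n == 0L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(seq),
                                     no.init.codon = TRUE,
                                     if.fuzzy.codon = "X"))
}

# Scan one translated frame for ORFs.  P is the protein string of the frame,
# off the 0-based nt offset of codon 0 within the scanned strand.  Returns a
# data.frame of codon-index coordinates (0-based): start_codon, stop_codon
# (stop_codon = index of the '*' codon, NA for partial ORFs).
.scan_frame <- function(P, min_aa, complete_only) {
  chars <- strsplit(P, "", fixed = TRUE)[[1]]
  stops <- which(chars == "*")
  out <- list()
  seg_start <- 1L
  for (s in stops) {
    if (s > seg_start) {
      seg <- chars[seg_start:(s - 1L)]
      m <- match("M", seg)
      if (!is.na(m)) {
        start_codon <- seg_start + m - 2L  # 0-based codon index
        aa_len <- (s - 1L) - (seg_start + m - 1L) + 1L
        if (aa_len >= min_aa) {
          out[[length(out) + 1L]] <- c(start_codon, s - 1L, aa_len)
        }
      }
    }
    seg_start <- s + 1L
  }
  if (!complete_only && seg_start <= length(chars)) {
    seg <- chars[seg_start:length(chars)]
    m <- match("M", seg)
    if (!is.na(m)) {
      start_codon <- seg_start + m - 2L
      aa_len <- length(chars) - (seg_start + m - 1L) + 1L
      if (aa_len >= min_aa) {
        out[[length(out) + 1L]] <- c(start_codon, NA_integer_, aa_len)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start_codon = integer(0), stop_codon = integer(0),
                      aa_length = integer(0)))
  }
  m <- do.call(rbind, out)
  data.frame(start_codon = m[, 1], stop_codon = m[, 2], aa_length = m[, 3])
}

#' Find open reading frames in all six frames
#'
#' Reports every complete ORF (ATG through the next in-frame stop codon)
#' whose protein is at least `min_aa` residues (the stop is not counted).
#' Nested ORFs sharing a stop are reported once, from the leftmost ATG.
#' Reverse-strand ORFs are reported in forward-strand coordinates (0-based,
#' half-open, BED-style; the span includes the stop codon).
#'
#' @param seq contig nucleotide string, or an [assembly()] (then all contigs
#'   are scanned and `contig_id` is filled from the contig names).
#' @param min_aa minimum protein length in residues (default 30).
#' @param complete_only if `FALSE`, also report ORFs running off the 3' end
#'   of a frame without a stop codon (`complete = FALSE` rows; their
#'   `aa_length` counts all residues from the ATG).
#' @param id contig id used in the output when `seq` is a plain string.
#' @return data.frame with columns `contig_id`, `frame` (+1,+2,+3,-1,-2,-3),
#'   `start`, `end` (0-based half-open on the forward strand), `aa_length`,
#'   `protein` (no terminal stop), `complete`; sorted by (start, frame).
#' @export
find_orfs <- function(seq, min_aa = 30L, complete_only = TRUE, id = "contig") {
  stopifnot(min_aa >= 1L)
  if (is(seq, "assembly")) {
    res <- lapply(seq_along(seq$contigs), function(i) {
      find_orfs(as.character(seq$contigs[[i]]), min_aa = min_aa,
                complete_only = complete_only, id = contig_ids(seq)[i])
    })
    return(do.call(rbind, res))
  }
  seq <- close_alphabet(seq)
  L <- nchar(seq)
  empty <- data.frame(contig_id = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      aa_length = integer(0), protein = character(0),
                      complete = logical(0))
  if (L < 3L) return(empty)
  strands <- list(`+` = seq, `-` = revcomp(seq))
  rows <- list()
  for (sgn in c(1L, -1L)) {
    s <- strands[[if (sgn == 1L) "+" else "-"]]
    for (off in 0:2) {
      nc <- (L - off) %/% 3L
      if (nc == 0L) next
      sub <- substr(s, off + 1L, off + 3L * nc)
      P <- translate_dna(sub)
      calls <- .scan_frame(P, min_aa, complete_only)
      if (nrow(calls) == 0L) next
      complete <- !is.na(calls$stop_codon)
      # nt span on the scanned strand, 0-based half-open, incl. stop codon
      a <- off + 3L * calls$start_codon
      b <- ifelse(complete, off + 3L * (calls$stop_codon + 1L),
                  off + 3L * (calls$start_codon + calls$aa_length))
      if (sgn == 1L) {
        start <- a; end <- b
      } else {
        start <- L - b; end <- L - a
      }
      # protein substring: codon indices start_codon .. start_codon+aa_len-1
      prot <- substring(P, calls$start_codon + 1L,
                        calls$start_codon + calls$aa_length)
      rows[[length(rows) + 1L]] <- data.frame(
        contig_id = id,
        frame = sgn * (off + 1L),
        start = start, end = end,
        aa_length = calls$aa_length,
        protein = prot,
        complete = complete)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  frame_rank <- match(out$frame, c(1L, 2L, 3L, -1L, -2L, -3L))
  out <- out[order(out$start, frame_rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Longest ORF of a contig
#'
#' Ties on protein length are broken by smallest forward-strand start, then
#' by frame order +1, +2, +3, -1, -2, -3.
#'
#' @inheritParams find_orfs
#' @return a one-row data.frame as in [find_orfs()], or `NULL` when no ORF
#'   of at least `min_aa` residues exists.
#' @export
longest_orf <- function(seq, min_aa = 30L, id = "contig") {
  orfs <- find_orfs(seq, min_aa = min_aa, id = id)
  if (nrow(orfs) == 0L) return(NULL)
  frame_rank <- match(orfs$frame, c(1L, 2L, 3L, -1L, -2L, -3L))
  orfs[order(-orfs$aa_length, orfs$start, frame_rank), , drop = FALSE][1L, ]
}

#' Write an ORF table as TSV and/or proteins as FASTA
#'
#' The TSV carries 0-based half-open coordinates plus a GFF3-style
#' 1-based-inclusive attribute column.
#'
#' @param orfs data.frame from [find_orfs()].
#' @param tsv,fasta output paths (either may be `NULL` to skip).
#' @return invisibly, the `orfs` table.
#' @export
write_orfs <- function(orfs, tsv = NULL, fasta = NULL) {
  if (!is.null(tsv)) {
    tab <- orfs[, c("contig_id", "frame", "start", "end", "aa_length")]
    tab$gff3_span <- sprintf("start=%d;end=%d;strand=%s",
                             orfs$start + 1L, orfs$end,
                             ifelse(orfs$frame > 0, "+", "-"))
    write_tsv(tab, tsv)
  }
  if (!is.null(fasta)) {
    prot <- Biostrings::AAStringSet(orfs$protein)
    names(prot) <- sprintf("%s_orf%d", orfs$contig_id, seq_len(nrow(orfs)))
    Biostrings::writeXStringSet(prot, fasta)
  }
  invisible(orfs)
}
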