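#' Build a canonical k-mer index over an assembly
#'
#' Every k-mer of every contig is stored in canonical form (lexicographic
#' minimum of the k-mer and its reverse complement) together with the set of
#' contigs it occurs in.  K-mers containing N are skipped.
#'
#' @param x an [assembly()].
#' @param k odd k-mer length, 11 <= k <= 63 (default 31, the common
#'   pseudo-aligner default).
#' @return an object of class `"kmer_index"`: list with `k`, `table` (an
#'   environment mapping canonical k-mer -> integer contig indices),
#'   `contig_ids` and `n_kmers`.
#' @export
build_index <- function(x, k = 31L) {
  stopifnot(is(x, "assembly"))
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("k must be odd")
  if (k < 11L || k > 63L) stop("k must be in [11, 63]")
  tab <- new.env(hash = TRUE, parent = emptyenv())
  seqs <- contig_strings(x)
  for (i in seq_along(seqs)) {
    for (km in unique(canonical_kmers(seqs[[i]], k))) {
      tab[[km]] <- c(tab[[km]], i)
    }
  }
  structure(list(k = k, table = tab, contig_ids = contig_ids(x),
                 n_kmers = length(ls(tab))),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("kmer_index: k=%d, %d distinct canonical k-mers over %d contigs\n",
              x$k, x$n_kmers, length(x$contig_ids)))
  invisible(x)
}

# mapped/unmapped decision for one read sequence
.read_is_mapped <- function(seq, index, min_frac) {
  km <- canonical_kmers(seq, index$k)
  if (length(km) == 0L) return(FALSE)
  sets <- lapply(km, function(x) index$table[[x]])
  present <- !vapply(sets, is.null, logical(1))
  if (sum(present) / length(km) < min_frac) return(FALSE)
  if (!any(present)) return(FALSE)
  compat <- Reduce(intersect, sets[present])
  length(compat) > 0L
}

#' Pseudo-alignment mapping rate of a read library
#'
#' A read is mapped iff (a) the intersection of the contig sets of its
#' canonical k-mers, skipping k-mers absent from the index, is non-empty,
#' and (b) at least `min_frac` of its k-mers are present in the index.
#' Reads shorter than `k` are unmapped.  This is a mapped/unmapped
#' pseudo-alignment decision, not an abundance estimate.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet],
#'   [Biostrings::DNAStringSet] or character vector of read sequences.
#' @param index a [build_index()] result.
#' @param min_frac minimum fraction of a read's k-mers that must be present
#'   (default 0.5, tolerant of IonTorrent-style errors).
#' @return list with `n_reads`, `n_mapped` and `pct_mapped`
#'   (`100 * n_mapped / n_reads`, two decimals).
#' @export
map_rate <- function(reads, index, min_frac = 0.5) {
  stopifnot(is(index, "kmer_index"))
  if (is(reads, "XStringSet")) reads <- as.character(reads)
  reads <- unname(reads)
  n <- length(reads)
  if (n == 0L) return(list(n_reads = 0L, n_mapped = 0L, pct_mapped = NA_real_))
  mapped <- vapply(reads, .read_is_mapped, logical(1),
                   index = index, min_frac = min_frac, USE.NAMES = FALSE)
  list(n_reads = n,
       n_mapped = sum(mapped),
       pct_mapped = round_half_up(100 * sum(mapped) / n, 2))
}
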