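#' Construct an assembly of contigs
#'
#' An assembly is a labelled, ordered set of contigs.  Sequences are
#' uppercased and the alphabet closed to {A,C,G,T,N} (other IUPAC ambiguity
#' codes become N).  Contig ids must be unique and sequences non-empty.
#'
#' @param seqs named character vector or [Biostrings::DNAStringSet] of
#'   contig sequences; names are the contig ids.
#' @param label single string naming the assembly (also the default source
#'   label of every contig).
#' @param source optional character vector giving, per contig, the label of
#'   the assembly it originally came from (defaults to `label`).
#' @return an object of class `"assembly"`: a list with elements `label`,
#'   `contigs` (a named [Biostrings::DNAStringSet]) and `source`.
#' @export
#' @examples
#' a <- assembly(c(c1 = "ATGAAATAA", c2 = "ACGTACGT"), "demo")
#' n_contigs(a)
assembly <- function(seqs, label, source = NULL) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop("'label' must be a single non-empty string")
  }
  if (is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (length(seqs) > 0L) {
    if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
      stop("every contig must have a non-empty id (name)")
    }
    dup <- names(seqs)[duplicated(names(seqs))]
    if (length(dup) > 0L) {
      stop("duplicate contig id(s): ", paste(unique(dup), collapse = ", "))
    }
    seqs <- vapply(seqs, close_alphabet, character(1))
    if (any(nchar(seqs) == 0L)) stop("contig sequences must be non-empty")
  }
  if (is.null(source)) source <- rep(label, length(seqs))
  stopifnot(length(source) == length(seqs))
  structure(list(label = label,
                 contigs = Biostrings::DNAStringSet(seqs),
                 source = unname(source)),
            class = "assembly")
}

#' @rdname assembly
#' @param x an `assembly`.
#' @export
n_contigs <- function(x) length(x$contigs)

#' @rdname assembly
#' @export
contig_ids <- function(x) names(x$contigs)

#' Contig sequences as a character vector
#' @param x an `assembly`.
#' @return named character vector of sequences.
#' @export
contig_strings <- function(x) {
  s <- as.character(x$contigs)
  names(s) <- names(x$contigs)
  s
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("assembly '%s': %d contigs, total %d nt\n",
              x$label, n_contigs(x),
              if (n_contigs(x)) sum(Biostrings::width(x$contigs)) else 0L))
  invisible(x)
}

#' Read a FASTA file as an assembly
#'
#' The header token up to the first whitespace becomes the contig id;
#' multi-line sequences are joined; sequences are uppercased and ambiguity
#' codes other than N mapped to N.
#'
#' @param path FASTA file path.
#' @param label assembly label (defaults to the file name without extension).
#' @return an [assembly()].
#' @export
read_fasta <- function(path, label = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(seqs))
  s <- as.character(seqs)
  names(s) <- ids
  assembly(s, label)
}

#' Write an assembly to FASTA
#'
#' @param x an [assembly()].
#' @param path output file path.
#' @param wrap line width for sequence wrapping; 0 writes each sequence on a
#'   single line.
#' @return `path`, invisibly.  Round-trips with [read_fasta()].
#' @export
write_fasta <- function(x, path, wrap = 60L) {
  stopifnot(is(x, "assembly"), wrap >= 0L)
  if (n_contigs(x) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  w <- if (wrap == 0L) max(Biostrings::width(x$contigs)) else as.integer(wrap)
  Biostrings::writeXStringSet(x$contigs, path, width = w)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path FASTQ file path (4-line records).
#' @return a [Biostrings::QualityScaledDNAStringSet]; ids are the header
#'   token up to the first whitespace.  Truncated records or sequence/quality
#'   length mismatches raise a format error.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  n_lines <- length(readLines(path, warn = FALSE))
  if (n_lines %% 4L != 0L) {
    stop("malformed FASTQ in ", path,
         ": truncated record (line count not a multiple of 4)")
  }
  # Biostrings emits a cosmetic metadata-columns warning here; muffle it
  withCallingHandlers({
    reads <- tryCatch(
      Biostrings::readQualityScaledDNAStringSet(path),
      error = function(e) stop("malformed FASTQ in ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    names(reads) <- sub("\\s.*$", "", names(reads))
  }, warning = function(w) {
    if (grepl("metadata columns", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
  reads
}

#' Per-read integer Phred qualities
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet] from [read_fastq()].
#' @return an [IRanges::IntegerList], one vector of Phred scores per read.
#' @export
read_qualities <- function(reads) {
  as(Biostrings::quality(reads), "IntegerList")
}

#' Filter reads on mean quality and length
#'
#' A read is kept iff its arithmetic mean Phred score is at least
#' `min_mean_quality` and its length lies in `[min_len, max_len]`.  All
#' boundaries are inclusive: length 50, length 270 and mean quality exactly
#' 20 pass under the defaults.  Removal reasons are assigned with priority
#' too_short > too_long > low_quality, so the reason counts partition the
#' removed reads.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param min_mean_quality minimum arithmetic mean Phred score (default 20).
#' @param min_len,max_len inclusive length bounds (defaults 50 and 270,
#'   matching IonTorrent-style variable-length libraries).
#' @return list with `reads` (the kept subset) and `stats`, a list of counts
#'   `n_in`, `n_kept`, `n_removed` and a named vector `reasons` with
#'   `too_short`, `too_long`, `low_quality`.
#' @export
filter_reads <- function(reads, min_mean_quality = 20, min_len = 50L,
                         max_len = 270L) {
  stopifnot(min_mean_quality > 0, min_len > 0, max_len >= min_len)
  n <- length(reads)
  if (n == 0L) {
    return(list(reads = reads,
                stats = list(n_in = 0L, n_kept = 0L, n_removed = 0L,
                             reasons = c(too_short = 0L, too_long = 0L,
                                         low_quality = 0L))))
  }
  len <- Biostrings::width(reads)
  mq <- vapply(read_qualities(reads), function(q) mean(as.numeric(q)),
               numeric(1))
  too_short <- len < min_len
  too_long <- !too_short & len > max_len
  low_q <- !too_short & !too_long & mq < min_mean_quality
  keep <- !(too_short | too_long | low_q)
  list(reads = reads[keep],
       stats = list(n_in = n,
                    n_kept = sum(keep),
                    n_removed = sum(!keep),
                    reasons = c(too_short = sum(too_short),
                                too_long = sum(too_long),
                                low_quality = sum(low_q))))
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  Biostrings::writeQualityScaledXStringSet(reads, path)
  invisible(path)
}
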