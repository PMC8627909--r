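#' N50 of a set of contig lengths
#'
#' The length of the contig at which the cumulative sum of lengths, sorted
#' longest-first, first reaches at least half the total assembly length.
#'
#' @param lengths positive integer vector of contig lengths.
#' @return the N50, in nucleotides.
#' @export
#' @examples
#' n50(c(6, 5, 4, 3, 2))  # 5
n50 <- function(lengths) {
  if (length(lengths) == 0L) stop("empty length set")
  stopifnot(all(lengths > 0))
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

#' Mean contig length at one-decimal precision
#'
#' @param total_len total assembly length in nucleotides.
#' @param n_contigs number of contigs.
#' @return `total_len / n_contigs`, rounded half away from zero to one
#'   decimal.
#' @export
#' @examples
#' mean_contig_length(46440750, 68414)  # 678.8
mean_contig_length <- function(total_len, n_contigs) {
  stopifnot(n_contigs > 0)
  round_half_up(total_len / n_contigs, 1)
}

#' Contig-length statistics of an assembly
#'
#' @param x an [assembly()] with at least one contig.
#' @return list with `n_contigs`, `total_len`, `mean_len` (one decimal),
#'   `median_len` (even counts average the two central values), `max_len`
#'   and `n50`.
#' @export
length_stats <- function(x) {
  stopifnot(is(x, "assembly"))
  if (n_contigs(x) == 0L) stop("empty assembly")
  len <- Biostrings::width(x$contigs)
  list(n_contigs = length(len),
       total_len = sum(as.numeric(len)),
       mean_len = mean_contig_length(sum(as.numeric(len)), length(len)),
       median_len = median(len),
       max_len = max(len),
       n50 = n50(len))
}

# Hash of target k-mer start positions (forward orientation, 0-based).
.kmer_positions <- function(seq, k) {
  km <- kmers_of(seq, k)
  keep <- !grepl("N", km, fixed = TRUE)
  split(which(keep) - 1L, km[keep])
}

# Ungapped X-drop extension of one seeded diagonal.  match is a logical
# vector over the diagonal's overlap segment; seeds are 1-based positions in
# that segment where a full k-mer match starts.  Returns (start, end)
# 1-based inclusive spans within the segment.
.extend_diagonal <- function(match, seeds, k, xdrop) {
  score <- ifelse(match, 1, -2)
  spans <- list()
  covered_to <- 0L
  for (s in sort(seeds)) {
    if (s <= covered_to) next
    # right extension from seed end
    right <- s + k - 1L
    best_right <- right
    run <- 0
    i <- right + 1L
    while (i <= length(score)) {
      run <- run + score[i]
      if (run > 0) { best_right <- i; run <- 0 }
      if (run < -xdrop) break
      i <- i + 1L
    }
    # left extension from seed start
    left <- s
    best_left <- left
    run <- 0
    i <- left - 1L
    while (i >= 1L) {
      run <- run + score[i]
      if (run > 0) { best_left <- i; run <- 0 }
      if (run < -xdrop) break
      i <- i - 1L
    }
    spans[[length(spans) + 1L]] <- c(best_left, best_right)
    covered_to <- best_right
  }
  if (length(spans) == 0L) return(NULL)
  m <- do.call(rbind, spans)
  # merge overlapping spans
  m <- m[order(m[, 1]), , drop = FALSE]
  merged <- m[1, , drop = FALSE]
  for (r in seq_len(nrow(m))[-1]) {
    last <- nrow(merged)
    if (m[r, 1] <= merged[last, 2] + 1L) {
      merged[last, 2] <- max(merged[last, 2], m[r, 2])
    } else {
      merged <- rbind(merged, m[r, ])
    }
  }
  merged
}

#' Seed-and-extend local alignment of a contig against a CDS
#'
#' Exact shared k-mers anchor ungapped extensions scored +1 per match and -2
#' per mismatch with X-drop termination; both strands of the query are
#' searched; overlapping hits on the same diagonal are merged.  Hits shorter
#' than `k` or below `min_identity` are dropped.
#'
#' @param query contig nucleotide string.
#' @param target CDS nucleotide string.
#' @param k seed k-mer length (at least 11; default 31).
#' @param min_identity minimum fraction of matching bases within a hit
#'   (default 0.70).
#' @param xdrop score drop at which extension stops (default 20).
#' @param query_id,target_id ids used in the output.
#' @return data.frame with columns `contig_id`, `cds_id`, `identity`,
#'   `cds_start`, `cds_end`, `contig_start`, `contig_end` (all 0-based
#'   half-open), `strand` and `length`.
#' @export
local_align <- function(query, target, k = 31L, min_identity = 0.70,
                        xdrop = 20, query_id = "query", target_id = "target") {
  stopifnot(k >= 11L)
  query <- close_alphabet(query)
  target <- close_alphabet(target)
  tpos <- .kmer_positions(target, k)
  res <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else revcomp(query)
    lq <- nchar(q)
    lt <- nchar(target)
    if (lq < k || lt < k) next
    qk <- kmers_of(q, k)
    hit_idx <- which(qk %in% names(tpos))
    if (length(hit_idx) == 0L) next
    # seed pairs (qpos, tpos), 0-based
    qp <- integer(0); tp <- integer(0)
    for (i in hit_idx) {
      tps <- tpos[[qk[i]]]
      qp <- c(qp, rep(i - 1L, length(tps)))
      tp <- c(tp, tps)
    }
    diag <- qp - tp
    for (d in unique(diag)) {
      # overlap segment on this diagonal (0-based query coords)
      q0 <- max(0L, d)
      q1 <- min(lq, lt + d)  # half-open
      if (q1 - q0 < k) next
      qseg <- strsplit(substr(q, q0 + 1L, q1), "", fixed = TRUE)[[1]]
      tseg <- strsplit(substr(target, q0 - d + 1L, q1 - d), "",
                       fixed = TRUE)[[1]]
      mvec <- qseg == tseg & qseg != "N"
      seeds <- qp[diag == d] - q0 + 1L  # 1-based within segment
      spans <- .extend_diagonal(mvec, seeds, k, xdrop)
      if (is.null(spans)) next
      for (r in seq_len(nrow(spans))) {
        a <- spans[r, 1]; b <- spans[r, 2]
        len <- b - a + 1L
        ident <- sum(mvec[a:b]) / len
        if (len < k || ident < min_identity) next
        qs <- q0 + a - 1L; qe <- q0 + b  # 0-based half-open on strand q
        ts <- qs - d; te <- qe - d
        if (strand == "-") {
          cs <- nchar(query) - qe
          ce <- nchar(query) - qs
        } else {
          cs <- qs; ce <- qe
        }
        res[[length(res) + 1L]] <- data.frame(
          contig_id = query_id, cds_id = target_id,
          identity = ident, cds_start = ts, cds_end = te,
          contig_start = cs, contig_end = ce,
          strand = strand, length = len)
      }
    }
  }
  if (length(res) == 0L) {
    return(data.frame(contig_id = character(0), cds_id = character(0),
                      identity = numeric(0), cds_start = integer(0),
                      cds_end = integer(0), contig_start = integer(0),
                      contig_end = integer(0), strand = character(0),
                      length = integer(0)))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Reference-CDS recovery of an assembly
#'
#' Aligns every contig to every reference CDS it shares a canonical k-mer
#' with ([local_align()]), then reports per-CDS coverage as the union of
#' qualifying hit spans divided by the CDS length.
#'
#' @param x an [assembly()].
#' @param reference named character vector or [Biostrings::DNAStringSet] of
#'   reference CDS sequences (non-empty).
#' @param k seed k-mer length (default 31).
#' @param min_identity minimum hit identity (default 0.70).
#' @param xdrop X-drop parameter passed to [local_align()].
#' @param single_best_contig if `TRUE`, coverage of a CDS uses only its
#'   single best-covering contig instead of the union over all contigs.
#' @return list with `coverage` (named numeric, detected CDS only),
#'   `detected` and `full95` (character vectors of CDS ids; `full95` means
#'   coverage >= 0.95), `pct_contigs_with_hit` (two decimals), `hits` (the
#'   full hit table) and `n_contigs`.
#' @export
cds_recovery <- function(x, reference, k = 31L, min_identity = 0.70,
                         xdrop = 20, single_best_contig = FALSE) {
  stopifnot(is(x, "assembly"))
  if (is(reference, "DNAStringSet")) reference <- as.character(reference)
  stopifnot(length(reference) > 0L, !is.null(names(reference)))
  reference <- vapply(reference, close_alphabet, character(1))
  # candidate pairing by shared canonical k-mers
  ref_index <- new.env(hash = TRUE, parent = emptyenv())
  for (ci in seq_along(reference)) {
    for (km in unique(canonical_kmers(reference[[ci]], k))) {
      ref_index[[km]] <- c(ref_index[[km]], ci)
    }
  }
  contigs <- contig_strings(x)
  hits <- list()
  with_hit <- logical(length(contigs))
  for (qi in seq_along(contigs)) {
    ck <- unique(canonical_kmers(contigs[[qi]], k))
    cand <- unique(unlist(lapply(ck, function(km) {
      if (!is.null(ref_index[[km]])) ref_index[[km]] else integer(0)
    })))
    for (ci in cand) {
      h <- local_align(contigs[[qi]], reference[[ci]], k = k,
                       min_identity = min_identity, xdrop = xdrop,
                       query_id = names(contigs)[qi],
                       target_id = names(reference)[ci])
      if (nrow(h) > 0L) {
        hits[[length(hits) + 1L]] <- h
        with_hit[qi] <- TRUE
      }
    }
  }
  hit_tab <- if (length(hits)) do.call(rbind, hits) else
    data.frame(contig_id = character(0), cds_id = character(0),
               identity = numeric(0), cds_start = integer(0),
               cds_end = integer(0), contig_start = integer(0),
               contig_end = integer(0), strand = character(0),
               length = integer(0))
  coverage <- numeric(0)
  if (nrow(hit_tab) > 0L) {
    for (cid in unique(hit_tab$cds_id)) {
      sub <- hit_tab[hit_tab$cds_id == cid, , drop = FALSE]
      clen <- nchar(reference[[cid]])
      cov_of <- function(rows) {
        rng <- IRanges::reduce(IRanges::IRanges(start = rows$cds_start + 1L,
                                                end = rows$cds_end))
        sum(IRanges::width(rng)) / clen
      }
      coverage[cid] <- if (single_best_contig) {
        max(vapply(split(sub, sub$contig_id), cov_of, numeric(1)))
      } else {
        cov_of(sub)
      }
    }
  }
  detected <- names(coverage)
  list(coverage = coverage,
       detected = detected,
       full95 = detected[coverage >= 0.95],
       pct_contigs_with_hit = if (length(contigs) == 0L) 0 else
         round_half_up(100 * sum(with_hit) / length(contigs), 2),
       hits = hit_tab,
       n_contigs = length(contigs))
}

#' Write a CDS recovery report
#'
#' @param rec value of [cds_recovery()].
#' @param hits_tsv path for the hit table TSV, or `NULL`.
#' @param json path for the JSON summary, or `NULL`.
#' @return the report, invisibly.
#' @export
write_cds_report <- function(rec, hits_tsv = NULL, json = NULL) {
  if (!is.null(hits_tsv)) write_tsv(rec$hits, hits_tsv)
  if (!is.null(json)) {
    write_json_report(list(n_detected = length(rec$detected),
                           n_full95 = length(rec$full95),
                           pct_contigs_with_hit = rec$pct_contigs_with_hit,
                           coverage = as.list(rec$coverage)), json)
  }
  invisible(rec)
}
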