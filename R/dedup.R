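#' Concatenate assemblies into one candidate meta-assembly
#'
#' Contig ids are prefixed with `"<source_label>|"` so ids stay unique; each
#' contig remembers its source assembly.
#'
#' @param assemblies list of [assembly()] objects (at least one).
#' @param label label of the merged assembly.
#' @return an [assembly()] with `sum(n_contigs)` contigs.
#' @export
merge_assemblies <- function(assemblies, label = "meta") {
  stopifnot(length(assemblies) >= 1L)
  seqs <- character(0)
  src <- character(0)
  for (a in assemblies) {
    stopifnot(is(a, "assembly"))
    s <- contig_strings(a)
    names(s) <- paste0(a$label, "|", names(s))
    seqs <- c(seqs, s)
    src <- c(src, a$source)
  }
  dup <- names(seqs)[duplicated(names(seqs))]
  if (length(dup) > 0L) {
    stop("contig id collision after prefixing: ",
         paste(unique(dup), collapse = ", "))
  }
  assembly(seqs, label, source = src)
}

# All-substring relation via a Biostrings PDict with a trusted-band prefix.
# Returns, for each contig (subject), the integer indices of contigs whose
# sequence occurs within it.  Patterns whose trusted band would contain an N
# are located with a plain fixed-string fallback.
.containment_hits <- function(seqs, patterns) {
  n <- length(seqs)
  subj <- Biostrings::DNAStringSet(seqs)
  tb <- min(31L, min(nchar(patterns)))
  band <- substr(patterns, 1L, tb)
  ok <- !grepl("N", band, fixed = TRUE)
  hits <- vector("list", n)
  if (any(ok)) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(patterns[ok]),
                            tb.start = 1L, tb.width = tb)
    idx_ok <- which(ok)
    raw <- Biostrings::vwhichPDict(pd, subj)
    hits <- lapply(raw, function(h) idx_ok[h])
  }
  if (any(!ok)) {
    for (j in which(!ok)) {
      found <- which(vapply(seqs, function(s) {
        grepl(patterns[j], s, fixed = TRUE)
      }, logical(1)))
      for (i in found) hits[[i]] <- c(hits[[i]], j)
    }
  }
  hits
}

#' Remove substring-redundant contigs
#'
#' Redundancy reduction: every contig whose sequence is a substring of at
#' least one other contig in the set is removed (exact duplicates collapse
#' to one survivor).  With `consider_revcomp = TRUE` (default) containment
#' of a contig's reverse complement also counts, since de novo contigs are
#' strand-ambiguous.  Deterministic tie-breaks: among identical sequences
#' the lexicographically smallest id survives; the reported container of a
#' removed contig is the retained contig with the longest sequence (ties:
#' smallest id).  Retained contigs keep their input order.
#'
#' The containment relation is computed with an Aho-Corasick-style
#' dictionary scan ([Biostrings::PDict]) rather than all-pairs search, so
#' the common case is far below quadratic in the number of contigs; every
#' removed/container pair is re-verified by fixed-string matching.
#'
#' @param x an [assembly()].
#' @param consider_revcomp also treat reverse-complement containment as
#'   redundancy (default `TRUE`).
#' @return list with `assembly` (the non-redundant assembly, label
#'   preserved) and `report`, a list with `retained` (ids), `removed`
#'   (named character vector: removed id -> container id), `n_before`,
#'   `n_after`, and `reduction_pct` (percentage of contigs retained, one
#'   decimal, as in [reduction_percent()]).
#' @export
remove_redundant <- function(x, consider_revcomp = TRUE) {
  stopifnot(is(x, "assembly"))
  n <- n_contigs(x)
  if (n <= 1L) {
    report <- list(retained = contig_ids(x),
                   removed = stats::setNames(character(0), character(0)),
                   n_before = n, n_after = n,
                   reduction_pct = if (n > 0L) 100 else NA_real_)
    return(list(assembly = x, report = report))
  }
  ids <- contig_ids(x)
  seqs <- unname(contig_strings(x))
  len <- nchar(seqs)

  contained_in <- .containment_hits(seqs, seqs)  # subject i -> patterns in i
  if (consider_revcomp) {
    rc_hits <- .containment_hits(revcomp(seqs), seqs)
    contained_in <- mapply(function(a, b) unique(c(a, b)), contained_in,
                           rc_hits, SIMPLIFY = FALSE)
  }
  # invert: containers[[j]] = contigs i whose sequence contains contig j
  containers <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in contained_in[[i]]) {
      if (j != i) containers[[j]] <- c(containers[[j]], i)
    }
  }
  # greedy: longest first (ties: smallest id) is retained unless an already
  # retained contig contains it
  ord <- order(-len, ids)
  retained <- logical(n)
  container_of <- integer(n)  # 0 = retained
  for (j in ord) {
    cand <- containers[[j]]
    cand <- cand[retained[cand]]
    if (length(cand) == 0L) {
      retained[j] <- TRUE
    } else {
      cand <- cand[order(-len[cand], ids[cand])]
      container_of[j] <- cand[1L]
    }
  }
  # verification: each removed sequence really occurs in its container
  rem <- which(!retained)
  for (j in rem) {
    i <- container_of[j]
    hit <- grepl(seqs[j], seqs[i], fixed = TRUE) ||
      (consider_revcomp && grepl(revcomp(seqs[j]), seqs[i], fixed = TRUE))
    if (!hit) stop("internal error: containment verification failed for ",
                   ids[j])
  }
  keep_idx <- which(retained)
  out <- assembly(stats::setNames(seqs[keep_idx], ids[keep_idx]), x$label,
                  source = x$source[keep_idx])
  report <- list(retained = ids[keep_idx],
                 removed = stats::setNames(ids[container_of[rem]], ids[rem]),
                 n_before = n,
                 n_after = length(keep_idx),
                 reduction_pct = reduction_percent(n, length(keep_idx)))
  list(assembly = out, report = report)
}

#' Percentage of contigs retained after redundancy removal
#'
#' `100 * n_after / n_before`, rounded half away from zero to one decimal —
#' the "reduced to X % of initial size" figure of a meta-assembly report.
#'
#' @param n_before,n_after contig counts before and after removal.
#' @return percentage with one decimal.
#' @export
#' @examples
#' reduction_percent(169232, 68414)  # 40.4
reduction_percent <- function(n_before, n_after) {
  if (n_before <= 0) stop("n_before must be positive")
  stopifnot(n_after >= 0, n_after <= n_before)
  round_half_up(100 * n_after / n_before, 1)
}

#' Drop contigs without a sufficiently long ORF
#'
#' Coding-only filter used ahead of redundancy removal when only contigs
#' containing open reading frames should be considered.
#'
#' @param x an [assembly()].
#' @param min_aa minimum protein length in residues (default 30).
#' @return an [assembly()] containing only contigs with at least one
#'   complete ORF of `min_aa` residues or more.
#' @export
coding_filter <- function(x, min_aa = 30L) {
  stopifnot(is(x, "assembly"))
  keep <- vapply(seq_len(n_contigs(x)), function(i) {
    !is.null(longest_orf(as.character(x$contigs[[i]]), min_aa = min_aa))
  }, logical(1))
  s <- contig_strings(x)[keep]
  assembly(s, x$label, source = x$source[keep])
}

#' Write a redundancy report
#'
#' @param report the `report` element of [remove_redundant()]'s value.
#' @param tsv path for a two-column removed/container TSV, or `NULL`.
#' @param json path for a JSON summary, or `NULL`.
#' @return the report, invisibly.
#' @export
write_redundancy_report <- function(report, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) {
    write_tsv(data.frame(removed_id = names(report$removed),
                         container_id = unname(report$removed)), tsv)
  }
  if (!is.null(json)) {
    write_json_report(list(n_before = report$n_before,
                           n_after = report$n_after,
                           reduction_pct = report$reduction_pct,
                           n_removed = length(report$removed)), json)
  }
  invisible(report)
}
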