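#' Compute the seven quality metrics for a set of assemblies
#'
#' Metrics depending on a missing input are dropped with a warning:
#' `markers_recovered` needs `markers`; `pct_contigs_with_cds_hit`,
#' `cds_detected` and `cds_full95` need `reference`; `pct_reads_mapped`
#' needs `reads`.  N50 and median contig length are always available.
#' Marker recovery is scored through the CDS-coverage engine: a marker
#' counts as complete when covered to at least 95 percent and as fragmented
#' when detected below that, and the metric is the sum of both classes.
#'
#' @param assemblies named list of [assembly()] objects (names default to
#'   the assembly labels).
#' @param reference optional named character vector/`DNAStringSet` of
#'   reference CDS.
#' @param markers optional named character vector/`DNAStringSet` of marker
#'   genes.
#' @param reads optional read set (see [map_rate()]).
#' @param k k-mer length for alignment seeding and pseudo-alignment
#'   (default 31).
#' @param min_identity minimum alignment identity (default 0.70).
#' @param min_frac minimum present-k-mer fraction for read mapping
#'   (default 0.5).
#' @return list with `matrix` (a [metric_matrix()] of raw values) and
#'   `detected_cds` (named list label -> character vector of detected CDS
#'   ids, for overlap decomposition; `NULL` without a reference).
#' @export
assembly_metrics <- function(assemblies, reference = NULL, markers = NULL,
                             reads = NULL, k = 31L, min_identity = 0.70,
                             min_frac = 0.5) {
  stopifnot(length(assemblies) >= 1L)
  labels <- names(assemblies)
  if (is.null(labels)) {
    labels <- vapply(assemblies, function(a) a$label, character(1))
  }
  stopifnot(!anyDuplicated(labels))
  cols <- DEFAULT_METRICS
  missing_cols <- c(
    if (is.null(markers)) "markers_recovered",
    if (is.null(reference)) c("pct_contigs_with_cds_hit", "cds_detected",
                              "cds_full95"),
    if (is.null(reads)) "pct_reads_mapped")
  if (length(missing_cols) > 0L) {
    warning("dropping metric(s) with missing inputs: ",
            paste(missing_cols, collapse = ", "))
    cols <- setdiff(cols, missing_cols)
  }
  raw <- matrix(NA_real_, nrow = length(assemblies), ncol = length(cols),
                dimnames = list(labels, cols))
  detected_cds <- if (is.null(reference)) NULL else
    stats::setNames(vector("list", length(assemblies)), labels)
  for (j in seq_along(assemblies)) {
    a <- assemblies[[j]]
    st <- length_stats(a)
    raw[j, "n50"] <- st$n50
    raw[j, "median_len"] <- st$median_len
    if (!is.null(reference)) {
      rec <- cds_recovery(a, reference, k = k, min_identity = min_identity)
      raw[j, "pct_contigs_with_cds_hit"] <- rec$pct_contigs_with_hit
      raw[j, "cds_detected"] <- length(rec$detected)
      raw[j, "cds_full95"] <- length(rec$full95)
      detected_cds[[j]] <- rec$detected
    }
    if (!is.null(markers)) {
      mk <- cds_recovery(a, markers, k = k, min_identity = min_identity)
      raw[j, "markers_recovered"] <- length(mk$detected)
    }
    if (!is.null(reads)) {
      idx <- build_index(a, k = k)
      raw[j, "pct_reads_mapped"] <- map_rate(reads, idx,
                                             min_frac = min_frac)$pct_mapped
    }
  }
  list(matrix = metric_matrix(raw), detected_cds = detected_cds)
}

#' Build a non-redundant meta-assembly from candidate assemblies
#'
#' Concatenates the candidate assemblies, optionally keeps only contigs
#' with an ORF of at least `min_aa` residues, and removes every contig that
#' is a substring of another (see [remove_redundant()]).
#'
#' @param assemblies list of at least two [assembly()] objects.
#' @param label meta-assembly label (default "meta").
#' @param coding_only apply the ORF filter before redundancy removal
#'   (default `FALSE`).
#' @param consider_revcomp count reverse-complement containment as
#'   redundancy (default `TRUE`).
#' @param min_aa ORF threshold for `coding_only` (default 30).
#' @param out_dir if non-`NULL`, write `meta.fasta`, `redundancy.tsv` and
#'   `redundancy.json` there.
#' @return list with `assembly` (the meta-assembly) and `report` (see
#'   [remove_redundant()]).
#' @export
run_meta <- function(assemblies, label = "meta", coding_only = FALSE,
                     consider_revcomp = TRUE, min_aa = 30L, out_dir = NULL) {
  if (length(assemblies) < 2L) {
    stop("meta-assembly needs at least 2 input assemblies")
  }
  merged <- merge_assemblies(assemblies, label = label)
  if (coding_only) merged <- coding_filter(merged, min_aa = min_aa)
  res <- remove_redundant(merged, consider_revcomp = consider_revcomp)
  message(sprintf("meta-assembly: %d -> %d contigs (%.1f%% of initial)",
                  res$report$n_before, res$report$n_after,
                  res$report$reduction_pct))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(res$assembly, file.path(out_dir, "meta.fasta"))
    write_redundancy_report(res$report,
                            tsv = file.path(out_dir, "redundancy.tsv"),
                            json = file.path(out_dir, "redundancy.json"))
  }
  res
}

#' Score, normalize, rank and overlap-decompose a set of assemblies
#'
#' Computes the available quality metrics per assembly
#' ([assembly_metrics()]), min-max normalizes them, ranks assemblies by the
#' summed normalized score, and decomposes the detected-CDS sets into
#' exclusive overlap regions.
#'
#' @inheritParams assembly_metrics
#' @param out_dir if non-`NULL`, write `metrics.tsv` (raw and normalized),
#'   `rank.json` and `overlap.json` there.
#' @return list with `matrix` (normalized [metric_matrix()]), `rank`
#'   ([rank_assemblies()]) and `overlap` ([overlap_sets()] of the
#'   detected-CDS lists, `NULL` without a reference or with more than six
#'   assemblies).
#' @export
run_evaluate <- function(assemblies, reference = NULL, markers = NULL,
                         reads = NULL, k = 31L, min_identity = 0.70,
                         min_frac = 0.5, out_dir = NULL) {
  am <- assembly_metrics(assemblies, reference = reference,
                         markers = markers, reads = reads, k = k,
                         min_identity = min_identity, min_frac = min_frac)
  if (ncol(am$matrix$raw) == 0L) stop("no metric computable from the inputs")
  m <- normalize_metrics(am$matrix)
  rk <- rank_assemblies(m)
  ov <- NULL
  if (!is.null(am$detected_cds) && length(am$detected_cds) <= 6L) {
    ov <- overlap_sets(am$detected_cds)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tab <- data.frame(assembly = rownames(m$raw), m$raw,
                      stats::setNames(as.data.frame(m$normalized),
                                      paste0("norm_", colnames(m$normalized))),
                      sum_normalized = rk$sums, check.names = FALSE)
    write_tsv(tab, file.path(out_dir, "metrics.tsv"))
    write_json_report(list(schema_version = 1L,
                           sums = as.list(rk$sums), order = rk$order),
                      file.path(out_dir, "rank.json"))
    if (!is.null(ov)) {
      write_json_report(list(schema_version = 1L,
                             set_labels = ov$set_labels,
                             region_counts = as.list(ov$region_counts),
                             n_union = ov$n_union),
                        file.path(out_dir, "overlap.json"))
    }
  }
  list(matrix = m, rank = rk, overlap = ov)
}
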