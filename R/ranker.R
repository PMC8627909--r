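#' The seven default assembly-quality metrics, in reporting order
#'
#' N50; median contig length; marker genes recovered (complete plus
#' fragmented); percentage of contigs with homology to a reference CDS;
#' number of reference CDS detected; number of CDS covered to at least 95
#' percent; percentage of library reads pseudo-aligned back to the assembly.
#' All are scored higher-is-better.
#'
#' @export
DEFAULT_METRICS <- c("n50", "median_len", "markers_recovered",
                     "pct_contigs_with_cds_hit", "cds_detected",
                     "cds_full95", "pct_reads_mapped")

#' Construct a metric matrix
#'
#' Holds the raw metric values of k assemblies and, after
#' [normalize_metrics()], their min-max-normalized counterparts.
#'
#' @param raw numeric matrix, rows = assemblies (rownames = labels),
#'   columns = metrics (colnames = metric names).
#' @param direction named character vector per metric, `"higher"` (default)
#'   or `"lower"`, saying which direction is better.
#' @return object of class `"metric_matrix"`: list with `raw`,
#'   `normalized` (`NULL` until normalized), `direction`, `assembly_labels`,
#'   `metric_names`.
#' @export
metric_matrix <- function(raw, direction = NULL) {
  raw <- as.matrix(raw)
  stopifnot(!is.null(rownames(raw)), !is.null(colnames(raw)),
            nrow(raw) >= 1L)
  if (is.null(direction)) {
    direction <- stats::setNames(rep("higher", ncol(raw)), colnames(raw))
  }
  stopifnot(all(colnames(raw) %in% names(direction)),
            all(direction %in% c("higher", "lower")))
  structure(list(raw = raw, normalized = NULL,
                 direction = direction[colnames(raw)],
                 assembly_labels = rownames(raw),
                 metric_names = colnames(raw)),
            class = "metric_matrix")
}

#' Min-max normalize every metric column to [0, 1]
#'
#' For a higher-is-better metric i with raw values \eqn{R^i_j} over the k
#' assemblies, the normalized value is
#' \eqn{N^i_j = (R^i_j - \min_j R^i_j) / (\max_j R^i_j - \min_j R^i_j)}, so
#' the worst assembly scores 0 and the best 1; lower-is-better metrics are
#' flipped to \eqn{1 - N^i_j}.  A degenerate column (all values equal,
#' including the single-assembly case) normalizes to 1 for every assembly: a
#' constant column cannot change the ranking and should not penalize anyone.
#'
#' @param m a [metric_matrix()].
#' @return the matrix with `normalized` filled.
#' @export
normalize_metrics <- function(m) {
  stopifnot(is(m, "metric_matrix"))
  raw <- m$raw
  bad <- which(!is.finite(raw), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-finite raw value for metric '%s', assembly '%s'",
                 colnames(raw)[bad[1, 2]], rownames(raw)[bad[1, 1]]))
  }
  norm <- raw
  for (i in seq_len(ncol(raw))) {
    v <- raw[, i]
    rng <- max(v) - min(v)
    if (rng == 0) {
      norm[, i] <- 1
    } else {
      n <- (v - min(v)) / rng
      norm[, i] <- if (m$direction[i] == "lower") 1 - n else n
    }
  }
  m$normalized <- norm
  m
}

#' Rank assemblies by summed normalized metrics
#'
#' All normalized parameters are summed per assembly; assemblies are sorted
#' by decreasing sum (ties broken by label).  The assembly with the highest
#' sum is considered to have the highest quality.
#'
#' @param m a [metric_matrix()] with `normalized` filled (a raw-only matrix
#'   is normalized first).
#' @return list with `sums` (named numeric, in input label order) and
#'   `order` (labels by decreasing sum).
#' @export
rank_assemblies <- function(m) {
  stopifnot(is(m, "metric_matrix"))
  if (is.null(m$normalized)) m <- normalize_metrics(m)
  sums <- rowSums(m$normalized)
  ord <- names(sums)[order(-sums, names(sums))]
  list(sums = sums, order = ord)
}

#' Exclusive set-overlap decomposition (Venn regions)
#'
#' For m labelled sets (m <= 6) counts, for every non-empty subset of
#' labels, the items belonging to exactly that subset — the exclusive
#' regions of a Venn diagram.
#'
#' @param lists named list of character/atomic vectors (the sets).
#' @return list with `set_labels`, `region_counts` (named integer vector;
#'   names join member labels with `"&"`), `n_union`, `in_all`,
#'   `in_exactly_one`, and `pairwise` (matrix of pairwise intersection
#'   sizes).
#' @export
#' @examples
#' overlap_sets(list(X = c("a", "b"), Y = c("b", "c")))$region_counts
overlap_sets <- function(lists) {
  m <- length(lists)
  if (m < 1L) stop("at least one set required")
  if (m > 6L) stop("at most 6 sets supported; use a tabular summary instead")
  labels <- names(lists)
  stopifnot(!is.null(labels), all(nzchar(labels)), !anyDuplicated(labels))
  lists <- lapply(lists, unique)
  universe <- unique(unlist(lists, use.names = FALSE))
  member <- vapply(lists, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, labels))
  if (length(universe) == 0L) member <- matrix(logical(0), ncol = m,
                                               dimnames = list(NULL, labels))
  key <- apply(member, 1L, function(r) paste(labels[r], collapse = "&"))
  subsets <- unlist(lapply(seq_len(m), function(sz) {
    utils::combn(labels, sz, paste, collapse = "&", simplify = FALSE)
  }))
  counts <- stats::setNames(integer(length(subsets)), subsets)
  tab <- table(key)
  counts[names(tab)] <- as.integer(tab)
  pairwise <- matrix(0L, m, m, dimnames = list(labels, labels))
  for (a in seq_len(m)) {
    for (b in seq_len(m)) {
      pairwise[a, b] <- length(intersect(lists[[a]], lists[[b]]))
    }
  }
  n_member <- if (nrow(member)) rowSums(member) else integer(0)
  list(set_labels = labels,
       region_counts = counts,
       n_union = length(universe),
       in_all = sum(n_member == m),
       in_exactly_one = sum(n_member == 1L),
       pairwise = pairwise)
}

#' Plot a proportional-free Venn diagram of up to three sets
#'
#' Base-graphics circles annotated with the exclusive region counts of
#' [overlap_sets()].  For four or more sets no figure is drawn; use the
#' `region_counts` table instead.
#'
#' @param ov an [overlap_sets()] result with at most 3 sets.
#' @return invisibly, `ov`.
#' @export
plot_overlap <- function(ov) {
  m <- length(ov$set_labels)
  if (m > 3L) stop("figure supported for at most 3 sets; see region_counts")
  centers <- list(matrix(c(0.5, 0.5), ncol = 2),
                  matrix(c(0.38, 0.62, 0.5, 0.5), ncol = 2),
                  matrix(c(0.38, 0.62, 0.5, 0.5, 0.5, 0.72), ncol = 2,
                         byrow = FALSE))[[m]]
  graphics::plot.new()
  graphics::plot.window(c(0, 1), c(0, 1), asp = 1)
  th <- seq(0, 2 * pi, length.out = 200)
  for (i in seq_len(m)) {
    graphics::lines(centers[i, 1] + 0.28 * cos(th),
                    centers[i, 2] + 0.28 * sin(th))
    graphics::text(centers[i, 1], centers[i, 2] + 0.32 * sign(centers[i, 2] - 0.45),
                   ov$set_labels[i], font = 2)
  }
  # region label positions chosen per m; approximate but readable
  regions <- names(ov$region_counts)
  pos <- switch(as.character(m),
    "1" = matrix(c(0.5, 0.5), ncol = 2),
    "2" = matrix(c(0.28, 0.5, 0.72, 0.5, 0.5, 0.5), ncol = 2, byrow = TRUE),
    "3" = matrix(c(0.24, 0.42, 0.76, 0.42, 0.5, 0.85, 0.5, 0.38,
                   0.35, 0.62, 0.65, 0.62, 0.5, 0.55), ncol = 2, byrow = TRUE))
  for (r in seq_along(regions)) {
    graphics::text(pos[r, 1], pos[r, 2], ov$region_counts[r])
  }
  invisible(ov)
}
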