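#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero (so 24.35 ->
#' 24.4), unlike [round()]'s round-half-even.  Used everywhere a percentage
#' or mean is reported at fixed precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector of the same length.
#' @export
#' @examples
#' round_half_up(c(0.25, -0.25), 1)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed, runs `code`, then restores the previous global RNG
#' state, so generators are reproducible without clobbering the caller's
#' random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

#' Reverse-complement a nucleotide string
#'
#' Plain character-level reverse complement over the closed alphabet
#' {A,C,G,T,N}.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

# Uppercase and close the alphabet to {A,C,G,T,N}: IUPAC ambiguity codes
# other than N become N (downstream k-mer machinery needs a closed alphabet).
close_alphabet <- function(x) {
  x <- toupper(x)
  bad <- grepl("[^ACGTNRYSWKMBDHVU]", x)
  if (any(bad)) {
    stop("non-nucleotide characters in sequence(s): ",
         paste(head(which(bad), 3), collapse = ", "))
  }
  x <- chartr("U", "T", x)
  chartr("RYSWKMBDHV", "NNNNNNNNNN", x)
}

# Extract all k-mers of a single sequence string (character vector, possibly
# empty when nchar(x) < k).
kmers_of <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  substring(x, starts, starts + k - 1L)
}

# Canonical k-mers of a sequence: for each position the lexicographic min of
# the forward k-mer and its reverse complement; k-mers containing N dropped.
canonical_kmers <- function(x, k) {
  fwd <- kmers_of(x, k)
  if (length(fwd) == 0L) return(character(0))
  rc_seq <- revcomp(x)
  rc <- rev(kmers_of(rc_seq, k))  # rc[i] = revcomp of fwd[i]
  can <- pmin(fwd, rc)
  can[!grepl("N", can, fixed = TRUE)]
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
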