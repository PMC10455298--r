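## Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of nucleotide strings
#'
#' Vectorised reverse complement over `A`, `C`, `G`, `T`, `N`.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of the same length.
#' @examples
#' revcomp(c("ACGT", "AACCN"))
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- character(length(x))
  ok <- !is.na(x) & nzchar(x)
  out[!ok] <- x[!ok]
  if (any(ok)) {
    out[ok] <- vapply(
      strsplit(chartr("ACGTN", "TGCAN", x[ok]), "", fixed = TRUE),
      function(b) paste(rev(b), collapse = ""),
      character(1)
    )
  }
  out
}

#' Enumerate the k-mers of a sequence
#'
#' Returns every window of `k` consecutive bases of `x` (top strand,
#' overlapping), in positional order.
#'
#' @param x A single nucleotide string.
#' @param k Window length in nt.
#' @param unique_only Drop duplicate k-mers?
#' @return Character vector of k-mers (empty if `nchar(x) < k`).
#' @export
kmers <- function(x, k = 12L, unique_only = FALSE) {
  stopifnot(is.character(x), length(x) == 1L, k >= 1L)
  n <- nchar(x)
  if (n < k) return(character(0))
  out <- substring(x, 1:(n - k + 1L), k:n)
  if (unique_only) unique(out) else out
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## sample one element of x (safe for length-1 vectors, unlike sample())
sample1 <- function(x) x[sample.int(length(x), 1L)]

## sub-seed derivation: keeps every derived seed a valid 32-bit integer
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single value in [0, 1].", name))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}
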