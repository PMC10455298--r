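## Core tabular containers: a read set is a plain tibble (one row per read),
## a genome is a named character vector (one element per replicon / FASTA
## record). Keeping both as ordinary R objects lets every downstream verb
## compose with dplyr.

READ_SET_PROVENANCE <- c("cellular", "secretome", "synthetic", "control")

#' Construct a read set
#'
#' A read set is a tibble with one row per read and columns `id`, `sequence`,
#' `quality` (Phred+33 string or `NA`) and `provenance`. All package verbs
#' take and return this shape, so pipelines chain with the pipe. Extra
#' columns (e.g. simulation ground truth) are carried along untouched.
#'
#' @param sequence Character vector of read sequences (`A`/`C`/`G`/`T`/`N`;
#'   lower case is upcased).
#' @param id Read identifiers; defaults to `read_1 ... read_n`.
#' @param quality Optional Phred+33 quality strings, same lengths as the
#'   sequences.
#' @param provenance One of `"cellular"`, `"secretome"`, `"synthetic"`,
#'   `"control"`; recycled to the number of reads.
#' @return A tibble of class `trf_read_set`.
#' @examples
#' read_set(c("ACGTACGTACGT", "TTGCA"), provenance = "synthetic")
#' @export
read_set <- function(sequence, id = NULL,
                     quality = NULL, provenance = "synthetic") {
  stopifnot(is.character(sequence))
  n <- length(sequence)
  if (is.null(id)) id <- sprintf("read_%d", seq_len(n))
  if (is.null(quality)) quality <- rep(NA_character_, n)
  provenance <- rep(provenance, length.out = n)
  bad <- !provenance %in% READ_SET_PROVENANCE
  if (any(bad)) {
    abort(sprintf("Unknown provenance: %s", paste(unique(provenance[bad]), collapse = ", ")))
  }
  sequence <- toupper(sequence)
  if (any(!nzchar(sequence) | is.na(sequence))) {
    abort("Read sequences must be non-empty.")
  }
  has_q <- !is.na(quality)
  if (any(nchar(quality[has_q]) != nchar(sequence[has_q]))) {
    abort("Quality strings must have the same length as their sequences.")
  }
  out <- tibble(
    id = as.character(id),
    sequence = sequence,
    quality = as.character(quality),
    provenance = provenance
  )
  class(out) <- c("trf_read_set", class(out))
  out
}

as_read_set <- function(x) {
  if (inherits(x, "trf_read_set")) return(x)
  if (is.data.frame(x)) {
    if (!all(c("id", "sequence") %in% names(x))) {
      abort("A read set needs at least `id` and `sequence` columns.")
    }
    if (!"quality" %in% names(x)) x$quality <- NA_character_
    if (!"provenance" %in% names(x)) x$provenance <- "synthetic"
    out <- as_tibble(x)
    class(out) <- unique(c("trf_read_set", class(out)))
    return(out)
  }
  if (is.character(x)) return(read_set(x))
  abort("Cannot interpret this object as a read set.")
}

## restore the read-set class after dplyr verbs strip attributes
restore_read_set <- function(x) {
  class(x) <- unique(c("trf_read_set", class(x)))
  x
}

#' Construct a genome
#'
#' A genome is a named character vector of nucleotide sequences, one element
#' per replicon (chromosome or plasmid). Each record is scanned separately by
#' the matching verbs, so no phantom matches can span record junctions.
#'
#' @param sequence Character vector of replicon sequences.
#' @param id Record identifiers; defaults to `chr_1 ... chr_n`.
#' @return A named character vector of class `trf_genome`.
#' @examples
#' genome("ACGTACGTACGTACGT", id = "toy")
#' @export
genome <- function(sequence, id = NULL) {
  stopifnot(is.character(sequence), length(sequence) >= 1L)
  sequence <- toupper(sequence)
  if (is.null(id)) {
    id <- if (!is.null(names(sequence))) names(sequence) else sprintf("chr_%d", seq_along(sequence))
  }
  out <- setNames(sequence, as.character(id))
  class(out) <- c("trf_genome", "character")
  out
}

as_genome <- function(x, id = "genome") {
  if (inherits(x, "trf_genome")) return(x)
  if (is.character(x)) {
    return(genome(unclass(x), id = if (is.null(names(x))) {
      if (length(x) == 1L) id else sprintf("%s_%d", id, seq_along(x))
    } else names(x)))
  }
  if (inherits(x, "DNAStringSet")) {
    return(genome(as.character(x)))
  }
  abort("Cannot interpret this object as a genome.")
}

## a list of genomes (for verbs that scan several species at once)
as_genome_list <- function(x) {
  if (inherits(x, "trf_genome")) return(list(x))
  if (is.character(x)) return(list(as_genome(x)))
  if (is.list(x)) return(lapply(x, as_genome))
  abort("Supply a genome or a list of genomes.")
}

#' @export
print.trf_genome <- function(x, ...) {
  cat(sprintf("<genome: %d record(s), %s bp total>\n",
              length(x), format(sum(nchar(x)), big.mark = ",")))
  for (i in seq_along(x)) {
    cat(sprintf("  %s: %d bp  %s...\n", names(x)[i], nchar(x[[i]]),
                substr(x[[i]], 1, 24)))
  }
  invisible(x)
}
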