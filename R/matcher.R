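## Dual-genome read classification: exhaustive substring matching with a
## bounded number of mismatches against two genomes, and the exclusive
## HOST_ONLY / ALIEN_ONLY / COMMON / UNMATCHED partition.

CLASS_CATEGORIES <- c("HOST_ONLY", "ALIEN_ONLY", "COMMON", "UNMATCHED")

#' Match a read against a genome with bounded mismatches
#'
#' Returns every position, on either strand of every genome record, where
#' the Hamming distance between the read and the genome window does not
#' exceed `max_mismatch`. Bottom-strand hits are found by matching the
#' reverse complement of the read and are reported in top-strand
#' coordinates (0-based, position of the leftmost matched base). `N` in the
#' read or genome always counts as a mismatch.
#'
#' @param read A single read sequence.
#' @param g A genome (named character vector; each record scanned
#'   separately).
#' @param max_mismatch Maximum Hamming distance, 0-3.
#' @return A tibble with columns `genome_id`, `position`, `strand`,
#'   `mismatches`, one row per hit.
#' @examples
#' match_read("ACGG", genome("AAACGGTT"), max_mismatch = 0)
#' @export
match_read <- function(read, g, max_mismatch = 0L) {
  stopifnot(is.character(read), length(read) == 1L)
  read <- toupper(read)
  g <- as_genome(g)
  max_mismatch <- assert_count(max_mismatch, "max_mismatch")
  if (max_mismatch > 3L) abort("`max_mismatch` must be 0-3.")
  if (nchar(read) > max(nchar(g))) {
    warn("Read is longer than every genome record; no match possible.")
  }
  rc <- revcomp(read)
  out <- purrr::map_dfr(seq_along(g), function(i) {
    fwd <- cpp_scan_mismatch(g[[i]], read, max_mismatch)
    rev <- cpp_scan_mismatch(g[[i]], rc, max_mismatch)
    dplyr::bind_rows(
      tibble(genome_id = names(g)[i], position = fwd[, 1],
             strand = "+", mismatches = fwd[, 2]),
      tibble(genome_id = names(g)[i], position = rev[, 1],
             strand = "-", mismatches = rev[, 2])
    )
  })
  dplyr::arrange(out, .data$genome_id, .data$position, .data$strand)
}

## TRUE per read if it matches `g` on either strand within max_mismatch
has_genome_match <- function(sequences, g, max_mismatch) {
  g <- as_genome(g)
  recs <- unclass(g)
  cpp_any_match(sequences, recs, max_mismatch) |
    cpp_any_match(revcomp(sequences), recs, max_mismatch)
}

#' Classify reads against a host and an alien genome
#'
#' Partitions a read set into the four exclusive categories used when
#' tracing alien RNA in co-culture experiments: `HOST_ONLY` (a hit in the
#' host genome and none in the alien), `ALIEN_ONLY` (the converse),
#' `COMMON` (hits in both -- orthologous or conserved sequence) and
#' `UNMATCHED`. A read counts once per genome regardless of how many
#' positions or strands it hits. The same `max_mismatch` applies to both
#' genomes.
#'
#' @param reads A read-set tibble.
#' @param host,alien Genomes.
#' @param max_mismatch Maximum Hamming distance, 0-3 (0 reproduces the
#'   exact-match classification used for category percentages).
#' @return An object of class `trf_classification`: a list with `reads`
#'   (per-read tibble with a `category` column), `summary` (per-category
#'   `count` and `percent`), `denominator` and `max_mismatch`. [tidy()]
#'   returns the per-read table, [glance()] the category percentages as one
#'   row, and [autoplot()] draws the category bars.
#' @export
classify_reads <- function(reads, host, alien, max_mismatch = 0L) {
  reads <- as_read_set(reads)
  max_mismatch <- assert_count(max_mismatch, "max_mismatch")
  if (max_mismatch > 3L) abort("`max_mismatch` must be 0-3.")
  in_host <- has_genome_match(reads$sequence, host, max_mismatch)
  in_alien <- has_genome_match(reads$sequence, alien, max_mismatch)
  category <- dplyr::case_when(
    in_host & in_alien ~ "COMMON",
    in_host ~ "HOST_ONLY",
    in_alien ~ "ALIEN_ONLY",
    TRUE ~ "UNMATCHED"
  )
  per_read <- dplyr::mutate(
    as_tibble(reads),
    category = factor(category, levels = CLASS_CATEGORIES)
  )
  denom <- nrow(per_read)
  summary <- tibble(category = factor(CLASS_CATEGORIES, levels = CLASS_CATEGORIES)) |>
    dplyr::left_join(dplyr::count(per_read, .data$category, name = "count"),
                     by = "category") |>
    dplyr::mutate(
      count = dplyr::coalesce(.data$count, 0L),
      percent = 100 * .data$count / denom
    )
  structure(
    list(reads = per_read, summary = summary,
         denominator = denom, max_mismatch = max_mismatch),
    class = "trf_classification"
  )
}

#' @export
print.trf_classification <- function(x, ...) {
  cat(sprintf("<read classification: %d reads, max mismatches %d>\n",
              x$denominator, x$max_mismatch))
  print(x$summary)
  invisible(x)
}

#' Remove reads resembling the host genome
#'
#' Drops every read with at least one hit to the host genome within
#' `max_mismatch` (default 1: removes exact matches and single-mismatch
#' reads, the background created by sequencing errors and strain SNPs).
#' The survivors are the candidates for alien origin or permutation
#' analysis.
#'
#' @inheritParams classify_reads
#' @return The surviving reads, order preserved.
#' @export
remove_host_like <- function(reads, host, max_mismatch = 1L) {
  reads <- as_read_set(reads)
  max_mismatch <- assert_count(max_mismatch, "max_mismatch")
  keep <- !has_genome_match(reads$sequence, host, max_mismatch)
  restore_read_set(reads[keep, , drop = FALSE])
}
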