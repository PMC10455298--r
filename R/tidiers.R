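## broom-style verbs for the package's result objects.

#' Tidy a read classification
#'
#' @param x A `trf_classification` from [classify_reads()].
#' @param ... Unused.
#' @return The per-read tibble (`id`, `sequence`, ..., `category`).
#' @export
tidy.trf_classification <- function(x, ...) {
  x$reads
}

#' One-row summary of a read classification
#'
#' @param x A `trf_classification`.
#' @param ... Unused.
#' @return A one-row tibble with the denominator, `max_mismatch`, and the
#'   count and percentage of every category.
#' @export
glance.trf_classification <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    x$summary,
    names_from = "category",
    values_from = c("count", "percent"),
    names_glue = "{tolower(category)}_{.value}"
  )
  dplyr::bind_cols(
    tibble(n_reads = x$denominator, max_mismatch = x$max_mismatch),
    wide
  )
}

#' Tidy a permutation scan
#'
#' @param x A `permutation_scan` from [detect_permutations()].
#' @param ... Unused.
#' @return The hit tibble, one row per read x locus.
#' @export
tidy.permutation_scan <- function(x, ...) {
  x$hits
}

#' One-row summary of a permutation scan
#'
#' @param x A `permutation_scan`.
#' @param ... Unused.
#' @return The summary tibble: unmapped reads, permuted reads, unique
#'   oligos, frequency, percent and display scale.
#' @export
glance.permutation_scan <- function(x, ...) {
  x$summary
}

#' Tidy an end profile
#'
#' @param x An `end_profile` from [profile_ends()].
#' @param ... Unused.
#' @return A long tibble: `position`, `base`, `end` (`"5p"`/`"3p"`),
#'   `count`, `pct`.
#' @export
tidy.end_profile <- function(x, ...) {
  dplyr::bind_rows(
    tibble(position = x$position, base = x$base, end = "5p",
           count = x$count5, pct = x$pct5),
    tibble(position = x$position, base = x$base, end = "3p",
           count = x$count3, pct = x$pct3)
  )
}

#' One-row summary of an end profile
#'
#' @param x An `end_profile`.
#' @param ... Unused.
#' @return A one-row tibble: `trf_id`, profiled reads, unplaced and
#'   out-of-range counts, ambiguous placements, and the modal 5'/3'
#'   positions.
#' @export
glance.end_profile <- function(x, ...) {
  tibble(
    trf_id = attr(x, "trf_id"),
    n_reads = attr(x, "n_reads"),
    n_unplaced = attr(x, "n_unplaced"),
    n_out_of_range = attr(x, "n_out_of_range"),
    n_ambiguous = attr(x, "n_ambiguous"),
    mode5 = if (any(x$count5 > 0)) x$position[which.max(x$count5)] else NA_integer_,
    mode3 = if (any(x$count3 > 0)) x$position[which.max(x$count3)] else NA_integer_
  )
}
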