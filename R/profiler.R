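## Marker-12-mer tRF tracing and 5'/3' read-end profiling: identify the
## reads belonging to a specific tRNA fragment via k-mers unique to its
## sequence context (absent from the host genome on both strands), then
## count where along the reference each read starts and ends.

#' Derive marker k-mers for a tRF
#'
#' Returns the k-mers of the tRF sequence context (top strand) that occur
#' nowhere in the excluded genome on either strand. Reads containing such a
#' marker cannot derive from the excluded genome, so markers assign reads to
#' the tRF.
#'
#' @param trf_context Nucleotide string of the tRF and its context.
#' @param excluded Genome the markers must be absent from (typically the
#'   host).
#' @param k Marker length in nt (default 12).
#' @param trf_id Label carried into downstream profiles.
#' @return A list of class `marker_set` with fields `trf_id`, `k` and
#'   `markers` (character vector). Warns when no marker survives (the tRF is
#'   untraceable against this genome).
#' @export
derive_markers <- function(trf_context, excluded, k = 12L, trf_id = "tRF") {
  stopifnot(is.character(trf_context), length(trf_context) == 1L)
  trf_context <- toupper(trf_context)
  k <- assert_count(k, "k", min = 1L)
  if (nchar(trf_context) < k) {
    abort(sprintf("`trf_context` is shorter than k = %d.", k))
  }
  excluded <- as_genome(excluded)
  candidate <- kmers(trf_context, k, unique_only = TRUE)
  excluded_k <- unique(unlist(lapply(unclass(excluded), kmers, k = k)))
  ## present on the bottom strand <=> reverse complement present on top
  banned <- union(excluded_k, revcomp(excluded_k))
  markers <- setdiff(candidate, banned)
  if (!length(markers)) {
    warn(sprintf("No marker %d-mers for '%s': every window also occurs in the excluded genome.",
                 k, trf_id))
  }
  structure(list(trf_id = trf_id, k = k, markers = markers),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker set '%s': %d unique %d-mers>\n",
              x$trf_id, length(x$markers), x$k))
  invisible(x)
}

#' Collect the reads carrying a tRF marker
#'
#' Retains reads containing at least one marker k-mer as a substring.
#'
#' @param reads A read-set tibble.
#' @param markers A [derive_markers()] result.
#' @return The collected reads, order preserved.
#' @export
collect_trf_reads <- function(reads, markers) {
  reads <- as_read_set(reads)
  stopifnot(inherits(markers, "marker_set"))
  if (!length(markers$markers)) abort("Empty marker set; nothing can be collected.")
  keep <- vapply(reads$sequence, function(s) {
    any(kmers(s, markers$k, unique_only = TRUE) %in% markers$markers)
  }, logical(1), USE.NAMES = FALSE)
  restore_read_set(reads[keep, , drop = FALSE])
}

#' Profile read 5'- and 3'-ends along a reference tRF
#'
#' For every read whose length lies in `[min_len, max_len]` and which occurs
#' verbatim in the reference, increments the 5' counter at the read's
#' (leftmost) start position and the 3' counter at its last base
#' (0-based, closed coordinate). Reads not found in the reference --
#' sequencing errors, chimeras -- are excluded from the profile and counted
#' as unplaced; reads with several exact occurrences are placed leftmost and
#' flagged ambiguous.
#'
#' @param trf_reads Read-set tibble (typically from [collect_trf_reads()]).
#' @param reference The reference tRF sequence.
#' @param min_len,max_len Inclusive length window (defaults 12 and 50 nt,
#'   i.e. 39 length groups).
#' @param trf_id Profile label.
#' @return A tibble of class `end_profile` with one row per reference
#'   position: `position`, `base`, `count5`, `pct5`, `count3`, `pct3`.
#'   Attributes: `trf_id`, `reference`, `n_reads` (profiled), `n_unplaced`,
#'   `n_out_of_range`, `n_ambiguous`. [autoplot()] draws the two end
#'   distributions.
#' @export
profile_ends <- function(trf_reads, reference, min_len = 12L, max_len = 50L,
                         trf_id = "tRF") {
  trf_reads <- as_read_set(trf_reads)
  stopifnot(is.character(reference), length(reference) == 1L)
  reference <- toupper(reference)
  L <- nchar(reference)
  len <- nchar(trf_reads$sequence)
  in_range <- len >= min_len & len <= max_len
  seqs <- trf_reads$sequence[in_range]
  start <- vapply(seqs, function(s) {
    r <- regexpr(s, reference, fixed = TRUE)
    if (r > 0) as.integer(r) - 1L else NA_integer_
  }, integer(1), USE.NAMES = FALSE)
  placed <- !is.na(start)
  ambiguous <- vapply(which(placed), function(i) {
    ## a second occurrence after the leftmost one?
    s <- seqs[i]
    regexpr(s, substr(reference, start[i] + 2L, L), fixed = TRUE) > 0
  }, logical(1))
  end5 <- start[placed]
  end3 <- end5 + nchar(seqs[placed]) - 1L
  counts5 <- tabulate(end5 + 1L, nbins = L)
  counts3 <- tabulate(end3 + 1L, nbins = L)
  n_reads <- sum(placed)
  pct <- function(x) if (n_reads > 0) 100 * x / n_reads else rep(0, L)
  out <- tibble(
    position = 0:(L - 1L),
    base = strsplit(reference, "", fixed = TRUE)[[1]],
    count5 = counts5, pct5 = pct(counts5),
    count3 = counts3, pct3 = pct(counts3)
  )
  class(out) <- c("end_profile", class(out))
  attr(out, "trf_id") <- trf_id
  attr(out, "reference") <- reference
  attr(out, "n_reads") <- n_reads
  attr(out, "n_unplaced") <- sum(!placed)
  attr(out, "n_out_of_range") <- sum(!in_range)
  attr(out, "n_ambiguous") <- sum(ambiguous)
  out
}

## local maxima of a nonnegative vector above a floor
find_peaks <- function(x, min_value) {
  n <- length(x)
  if (n == 0) return(integer(0))
  left <- c(-Inf, x[-n])
  right <- c(x[-1], -Inf)
  which(x >= min_value & x > left & x >= right)
}

#' Compare two end profiles
#'
#' Reports, per position and per end, the percentage difference between two
#' profiles of the same reference (e.g. culture medium vs intracellular),
#' flags positions whose difference exceeds `threshold`, and tabulates the
#' peaks (local maxima at or above `min_peak_pct`) of both profiles.
#'
#' @param a,b `end_profile` objects over the same reference.
#' @param threshold Percentage-point difference that flags a position.
#' @param min_peak_pct Minimum percentage for a position to qualify as a
#'   peak.
#' @return A list of class `profile_comparison` with tibbles `deltas`
#'   (`position`, `end`, `pct_a`, `pct_b`, `delta`, `flagged`) and `peaks`
#'   (`profile`, `end`, `position`, `pct`).
#' @export
compare_profiles <- function(a, b, threshold = 1, min_peak_pct = 5) {
  stopifnot(inherits(a, "end_profile"), inherits(b, "end_profile"))
  if (!identical(attr(a, "reference"), attr(b, "reference"))) {
    abort("Profiles were computed over different references.")
  }
  deltas <- dplyr::bind_rows(
    tibble(position = a$position, end = "5p",
           pct_a = a$pct5, pct_b = b$pct5),
    tibble(position = a$position, end = "3p",
           pct_a = a$pct3, pct_b = b$pct3)
  ) |>
    dplyr::mutate(
      delta = .data$pct_b - .data$pct_a,
      flagged = abs(.data$delta) > threshold
    )
  peak_rows <- function(prof, label) {
    dplyr::bind_rows(
      tibble(profile = label, end = "5p",
             position = prof$position[find_peaks(prof$pct5, min_peak_pct)],
             pct = prof$pct5[find_peaks(prof$pct5, min_peak_pct)]),
      tibble(profile = label, end = "3p",
             position = prof$position[find_peaks(prof$pct3, min_peak_pct)],
             pct = prof$pct3[find_peaks(prof$pct3, min_peak_pct)])
    )
  }
  peaks <- dplyr::bind_rows(
    peak_rows(a, attr(a, "trf_id")),
    peak_rows(b, attr(b, "trf_id"))
  )
  structure(list(deltas = deltas, peaks = peaks), class = "profile_comparison")
}
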