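## Quality control for small RNA-seq read sets: per-read Phred filtering,
## residual adapter removal, background (medium) subtraction, length
## selection and fixed end trimming, applied in that order by run_qc().

#' Quality-control parameters
#'
#' Bundles the thresholds used by the QC verbs. The defaults reproduce the
#' processing used for Ion Torrent small RNA libraries in this workflow:
#' keep a read when at least 90% of its bases reach Phred 20, drop reads
#' sharing >= 13 consecutive nt with an adapter, keep 16-50 nt reads, and
#' shave 1 nt from the 5' end plus 3 nt from the 3' end (removing ligation
#' artifacts and short poly-A tails), which maps the 16-50 nt range onto
#' 12-46 nt.
#'
#' @param quality_cutoff Phred score a base must reach (default 20).
#' @param min_fraction_at_cutoff Minimum fraction of bases at or above the
#'   cutoff for a read to survive (default 0.90).
#' @param adapter_seqs Character vector of adapter sequences.
#' @param adapter_min_match Minimum number of consecutive adapter nt that
#'   marks a read as contaminated (default 13).
#' @param length_min,length_max Inclusive length window in nt (defaults 16
#'   and 50).
#' @param trim5,trim3 Bases removed from the 5' and 3' ends (defaults 1
#'   and 3).
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(quality_cutoff = 20, min_fraction_at_cutoff = 0.90,
                      adapter_seqs = character(), adapter_min_match = 13L,
                      length_min = 16L, length_max = 50L,
                      trim5 = 1L, trim3 = 3L) {
  if (min_fraction_at_cutoff <= 0 || min_fraction_at_cutoff > 1) {
    abort("`min_fraction_at_cutoff` must be in (0, 1].")
  }
  adapter_min_match <- assert_count(adapter_min_match, "adapter_min_match", min = 1L)
  if (length_min > length_max) abort("`length_min` must be <= `length_max`.")
  structure(
    list(
      quality_cutoff = quality_cutoff,
      min_fraction_at_cutoff = min_fraction_at_cutoff,
      adapter_seqs = toupper(adapter_seqs),
      adapter_min_match = adapter_min_match,
      length_min = as.integer(length_min),
      length_max = as.integer(length_max),
      trim5 = as.integer(trim5),
      trim3 = as.integer(trim3)
    ),
    class = "qc_params"
  )
}

phred_scores <- function(quality) {
  lapply(quality, function(q) utf8ToInt(q) - 33L)
}

#' Filter reads on per-base quality
#'
#' Keeps exactly the reads in which the fraction of bases at or above
#' `quality_cutoff` reaches `min_fraction_at_cutoff`.
#'
#' @param reads A read-set tibble; every read must carry qualities.
#' @param params A [qc_params()] object.
#' @return The surviving reads, order preserved.
#' @export
quality_filter <- function(reads, params = qc_params()) {
  reads <- as_read_set(reads)
  if (anyNA(reads$quality)) {
    abort("quality_filter() requires per-base qualities on every read.")
  }
  frac <- vapply(phred_scores(reads$quality), function(s) {
    mean(s >= params$quality_cutoff)
  }, numeric(1))
  restore_read_set(reads[frac >= params$min_fraction_at_cutoff, , drop = FALSE])
}

adapter_windows <- function(adapter_seqs, w) {
  short <- nchar(adapter_seqs) < w
  if (any(short)) {
    abort(sprintf("Adapter(s) shorter than adapter_min_match = %d nt.", w))
  }
  unique(unlist(lapply(adapter_seqs, kmers, k = w)))
}

#' Remove residual adapter contamination
#'
#' A read is contaminated when any window of at least `adapter_min_match`
#' consecutive nucleotides from an adapter occurs verbatim in the read
#' (scanning every window is equivalent to scanning the windows of exactly
#' that length). By default a contaminated read is dropped whole; with
#' `clip = TRUE` the read is instead truncated at the first adapter
#' occurrence and kept if anything remains.
#'
#' @inheritParams quality_filter
#' @param clip Clip at the adapter instead of dropping the read.
#' @return The surviving (or clipped) reads.
#' @export
strip_residual_adapters <- function(reads, params = qc_params(), clip = FALSE) {
  reads <- as_read_set(reads)
  if (!length(params$adapter_seqs)) {
    abort("`params$adapter_seqs` must be non-empty.")
  }
  win <- adapter_windows(params$adapter_seqs, params$adapter_min_match)
  first_hit <- vapply(reads$sequence, function(s) {
    hits <- vapply(win, function(w) {
      r <- regexpr(w, s, fixed = TRUE)
      if (r > 0) as.integer(r) else NA_integer_
    }, integer(1))
    if (all(is.na(hits))) NA_integer_ else min(hits, na.rm = TRUE)
  }, integer(1), USE.NAMES = FALSE)
  if (!clip) {
    return(restore_read_set(reads[is.na(first_hit), , drop = FALSE]))
  }
  hit <- !is.na(first_hit)
  reads$sequence[hit] <- substr(reads$sequence[hit], 1L, first_hit[hit] - 1L)
  has_q <- hit & !is.na(reads$quality)
  reads$quality[has_q] <- substr(reads$quality[has_q], 1L, first_hit[has_q] - 1L)
  restore_read_set(reads[nzchar(reads$sequence), , drop = FALSE])
}

#' Subtract background reads
#'
#' Removes reads whose sequence occurs verbatim in a control set (e.g.
#' reads sequenced from uninoculated growth medium), preserving the order of
#' the survivors. Matching is exact sequence identity.
#'
#' @inheritParams quality_filter
#' @param control Read set of background sequences.
#' @return The surviving reads.
#' @export
subtract_background <- function(reads, control) {
  reads <- as_read_set(reads)
  control <- as_read_set(control)
  restore_read_set(reads[!reads$sequence %in% control$sequence, , drop = FALSE])
}

#' Select reads by length
#'
#' @inheritParams quality_filter
#' @param min_nt,max_nt Inclusive length bounds.
#' @return Reads with `min_nt <= length <= max_nt`.
#' @export
length_filter <- function(reads, min_nt = 16L, max_nt = 50L) {
  reads <- as_read_set(reads)
  len <- nchar(reads$sequence)
  restore_read_set(reads[len >= min_nt & len <= max_nt, , drop = FALSE])
}

#' Trim fixed numbers of bases from both ends
#'
#' Removes `trim5` leading and `trim3` trailing bases from every read
#' (qualities trimmed in lockstep). Reads too short to survive the trim are
#' dropped; their count is reported with a message and recorded in the
#' `n_dropped_short` attribute.
#'
#' @inheritParams quality_filter
#' @param trim5,trim3 Bases to remove from the 5' and 3' ends.
#' @return The trimmed reads.
#' @export
trim_ends <- function(reads, trim5 = 1L, trim3 = 3L) {
  reads <- as_read_set(reads)
  len <- nchar(reads$sequence)
  keep <- len > trim5 + trim3
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    inform(sprintf("trim_ends(): dropped %d read(s) shorter than trim5 + trim3 + 1.", n_drop))
  }
  out <- reads[keep, , drop = FALSE]
  len <- len[keep]
  out$sequence <- substr(out$sequence, trim5 + 1L, len - trim3)
  has_q <- !is.na(out$quality)
  out$quality[has_q] <- substr(out$quality[has_q], trim5 + 1L, len[has_q] - trim3)
  out <- restore_read_set(out)
  attr(out, "n_dropped_short") <- n_drop
  out
}

#' Run the full QC pipeline
#'
#' Applies, in order: quality filter, adapter removal, background
#' subtraction, length filter and end trimming. Stages whose inputs are
#' absent (no qualities, no adapters, no control set) are skipped and noted
#' in the report. The per-stage report is attached as the `qc_report`
#' attribute and retrievable with [qc_report()].
#'
#' @inheritParams quality_filter
#' @param control Optional background read set.
#' @param clip Passed to [strip_residual_adapters()].
#' @return The surviving reads with a `qc_report` attribute.
#' @export
run_qc <- function(reads, params = qc_params(), control = NULL, clip = FALSE) {
  reads <- as_read_set(reads)
  stages <- character(0); n_in <- integer(0); n_out <- integer(0)
  note <- function(stage, before, after) {
    stages <<- c(stages, stage)
    n_in <<- c(n_in, before)
    n_out <<- c(n_out, after)
  }
  cur <- reads
  if (!anyNA(cur$quality)) {
    n0 <- nrow(cur); cur <- quality_filter(cur, params); note("quality", n0, nrow(cur))
  } else {
    note("quality (skipped: no qualities)", nrow(cur), nrow(cur))
  }
  if (length(params$adapter_seqs)) {
    n0 <- nrow(cur); cur <- strip_residual_adapters(cur, params, clip = clip)
    note("adapter", n0, nrow(cur))
  } else {
    note("adapter (skipped: no adapters)", nrow(cur), nrow(cur))
  }
  if (!is.null(control)) {
    n0 <- nrow(cur); cur <- subtract_background(cur, control)
    note("background", n0, nrow(cur))
  } else {
    note("background (skipped: no control)", nrow(cur), nrow(cur))
  }
  n0 <- nrow(cur)
  cur <- length_filter(cur, params$length_min, params$length_max)
  note("length", n0, nrow(cur))
  n0 <- nrow(cur)
  cur <- withCallingHandlers(
    trim_ends(cur, params$trim5, params$trim3),
    message = function(m) invokeRestart("muffleMessage")
  )
  note("trim", n0, nrow(cur))
  attr(cur, "qc_report") <- tibble(stage = stages, reads_in = n_in, reads_out = n_out)
  cur
}

#' @rdname run_qc
#' @param x A read set returned by [run_qc()].
#' @export
qc_report <- function(x) {
  rep <- attr(x, "qc_report")
  if (is.null(rep)) abort("No `qc_report` attribute; was this produced by run_qc()?")
  rep
}
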