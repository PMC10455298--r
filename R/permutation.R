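## Detection of circularly permuted reads: reads whose sequence is a
## rotation of a contiguous genomic segment, the footprint left when a
## linear fragment circularises and the ring is re-opened at a new site.
## The two-step procedure first discards every read that matches a genome
## verbatim, then, for each survivor, anchors the read's first 12-mer in the
## genome, extends the match to the maximal prefix, and requires the
## remaining 3' segment of the read to sit immediately upstream of the
## anchor with no other deviation from the genomic sequence. Both genome
## strands are scanned; bottom-strand coordinates are reported on the top
## strand.

#' Remove reads that match a genome exactly
#'
#' Drops every read occurring verbatim, on either strand, in any record of
#' any supplied genome. The survivor count -- the denominator of the
#' permutation frequency -- is recorded in the `n_unmapped` attribute.
#'
#' @param reads A read-set tibble.
#' @param genomes A genome or list of genomes.
#' @return The unmatched reads with attribute `n_unmapped`.
#' @export
remove_exact_matches <- function(reads, genomes) {
  reads <- as_read_set(reads)
  genomes <- as_genome_list(genomes)
  recs <- unlist(lapply(genomes, unclass), use.names = FALSE)
  texts <- c(recs, revcomp(recs))
  keep <- !cpp_contains(reads$sequence, texts)
  out <- restore_read_set(reads[keep, , drop = FALSE])
  attr(out, "n_unmapped") <- nrow(out)
  out
}

## run one arm of the scan on an oriented sequence; returns hit rows or NULL
## (plain loop: this sits inside per-read loops over large read sets)
permutation_arm_hits <- function(oriented, g, k, min_transfer, strand) {
  out <- NULL
  for (i in seq_along(g)) {
    h <- cpp_permutation_arm(g[[i]], oriented, k, min_transfer)
    if (nrow(h)) {
      rows <- tibble(
        genome_id = names(g)[i],
        strand = strand,
        anchor = h[, 1],
        matched_prefix = h[, 2],
        relocated_len = h[, 3],
        locus_start = h[, 1] - h[, 3],
        locus_end = h[, 1] + h[, 2],
        ligation_site = h[, 1]
      )
      out <- if (is.null(out)) rows else dplyr::bind_rows(out, rows)
    }
  }
  out
}

#' Test one read for circular permutation
#'
#' For each genome position where the read's first 12-mer (`k`-mer) matches
#' exactly, the match is extended to the maximal prefix length `m`; the
#' read is a permutation hit when its remaining `s = length - m` 3' bases
#' (at least `min_transfer` nt) exactly match the genome immediately
#' upstream of the anchor. The same test is applied to the reverse
#' complement of the read (bottom-strand arm), with coordinates reported on
#' the top strand. Reads deviating from the genome anywhere besides the
#' single junction yield no hit; all qualifying anchors (paralogous loci)
#' are returned.
#'
#' @param read A single read sequence.
#' @param g A genome.
#' @param k Anchor length in nt (default 12).
#' @param min_transfer Minimum relocated-segment length in nt; the
#'   procedure supports 4, analyses here default to 5.
#' @return A tibble of hits (`genome_id`, `strand`, `anchor`,
#'   `matched_prefix`, `relocated_len`, `locus_start`, `locus_end`,
#'   `ligation_site`), empty when the read is not a permutation.
#' @export
find_permutation <- function(read, g, k = 12L, min_transfer = 5L) {
  stopifnot(is.character(read), length(read) == 1L)
  read <- toupper(read)
  g <- as_genome(g)
  k <- assert_count(k, "k", min = 1L)
  min_transfer <- assert_count(min_transfer, "min_transfer", min = 1L)
  if (nchar(read) < k + min_transfer) {
    inform(sprintf("Read shorter than k + min_transfer = %d nt; skipped.", k + min_transfer))
    return(empty_hits())
  }
  out <- dplyr::bind_rows(
    permutation_arm_hits(read, g, k, min_transfer, "+"),
    permutation_arm_hits(revcomp(read), g, k, min_transfer, "-")
  )
  if (!nrow(out)) empty_hits() else out
}

empty_hits <- function() {
  tibble(
    genome_id = character(), strand = character(), anchor = integer(),
    matched_prefix = integer(), relocated_len = integer(),
    locus_start = integer(), locus_end = integer(), ligation_site = integer()
  )
}

## rebuild the oriented read from the genome; internal consistency check
## applied to every emitted hit
assert_reconstruction <- function(hits, genomes_by_id) {
  if (!nrow(hits)) return(invisible(TRUE))
  for (i in seq_len(nrow(hits))) {
    g <- genomes_by_id[[hits$genome_id[i]]]
    p <- hits$anchor[i]; m <- hits$matched_prefix[i]; s <- hits$relocated_len[i]
    rebuilt <- paste0(substr(g, p + 1L, p + m), substr(g, p - s + 1L, p))
    oriented <- if (hits$strand[i] == "+") hits$read_seq[i] else revcomp(hits$read_seq[i])
    if (!identical(rebuilt, oriented)) {
      abort("Internal error: permutation hit fails genome reconstruction.")
    }
  }
  invisible(TRUE)
}

#' Detect circularly permuted reads in a read set
#'
#' Runs the full two-step procedure: [remove_exact_matches()] against all
#' supplied genomes, then [find_permutation()] on every surviving read.
#' Identical read sequences hitting multiple loci (paralogous genes) are
#' counted once in the read-level tallies while every locus is listed; the
#' `copies` column of the hit table gives the number of identical reads
#' supporting each hit.
#'
#' @inheritParams remove_exact_matches
#' @param k Anchor length in nt.
#' @param min_transfer Minimum relocated-segment length in nt.
#' @return An object of class `permutation_scan`: a list with `hits` (one
#'   row per read x locus, columns `read_id`, `read_seq`, `genome_id`,
#'   `strand`, `anchor`, `matched_prefix`, `relocated_len`, `locus_start`,
#'   `locus_end`, `ligation_site`, `copies`) and `summary` (see
#'   [permutation_frequency()]; plus the read-length distribution and a
#'   per-locus table keyed by genome and ligation site). [tidy()] returns
#'   the hits, [glance()] the one-row summary.
#' @export
detect_permutations <- function(reads, genomes, k = 12L, min_transfer = 5L) {
  reads <- as_read_set(reads)
  genomes <- as_genome_list(genomes)
  unmapped <- remove_exact_matches(reads, genomes)
  n_unmapped <- attr(unmapped, "n_unmapped")
  genomes_by_id <- list()
  for (g in genomes) for (i in seq_along(g)) genomes_by_id[[names(g)[i]]] <- g[[i]]

  min_len <- k + min_transfer
  candidates <- unmapped[nchar(unmapped$sequence) >= min_len, , drop = FALSE]
  rc_seqs <- revcomp(candidates$sequence)
  hit_list <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    per_genome <- vector("list", 2L * length(genomes))
    for (j in seq_along(genomes)) {
      per_genome[[2L * j - 1L]] <-
        permutation_arm_hits(candidates$sequence[i], genomes[[j]], k, min_transfer, "+")
      per_genome[[2L * j]] <-
        permutation_arm_hits(rc_seqs[i], genomes[[j]], k, min_transfer, "-")
    }
    per_genome <- per_genome[!vapply(per_genome, is.null, logical(1))]
    if (length(per_genome)) {
      h <- dplyr::bind_rows(per_genome)
      h$read_id <- candidates$id[i]
      h$read_seq <- candidates$sequence[i]
      hit_list[[i]] <- h
    }
  }
  hits <- dplyr::bind_rows(hit_list)
  if (nrow(hits)) {
    hits <- dplyr::relocate(hits, "read_id", "read_seq")
    copies <- dplyr::count(dplyr::distinct(hits, .data$read_id, .data$read_seq),
                           .data$read_seq, name = "copies")
    hits <- dplyr::left_join(hits, copies, by = "read_seq")
    assert_reconstruction(hits, genomes_by_id)
  } else {
    hits <- dplyr::mutate(empty_hits(), read_id = character(),
                          read_seq = character(), copies = integer())
    hits <- dplyr::relocate(hits, "read_id", "read_seq")
  }
  n_permuted_reads <- dplyr::n_distinct(hits$read_id)
  n_unique_oligos <- dplyr::n_distinct(hits$read_seq)
  summary <- permutation_frequency(n_permuted_reads, n_unmapped)
  summary$n_unique_oligos <- n_unique_oligos
  length_distribution <- if (nrow(hits)) {
    dplyr::count(dplyr::distinct(hits, .data$read_id, .data$read_seq),
                 length = nchar(.data$read_seq), name = "n_reads")
  } else {
    tibble(length = integer(), n_reads = integer())
  }
  loci <- if (nrow(hits)) {
    hits |>
      dplyr::group_by(.data$genome_id, .data$ligation_site) |>
      dplyr::summarise(
        strand = paste(sort(unique(.data$strand)), collapse = "/"),
        n_reads = dplyr::n_distinct(.data$read_id),
        n_oligos = dplyr::n_distinct(.data$read_seq),
        .groups = "drop"
      )
  } else {
    tibble(genome_id = character(), ligation_site = integer(),
           strand = character(), n_reads = integer(), n_oligos = integer())
  }
  structure(
    list(hits = hits, summary = summary,
         length_distribution = length_distribution, loci = loci),
    class = "permutation_scan"
  )
}

#' @export
print.permutation_scan <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<permutation scan: %d permuted read(s) (%d unique oligo(s)) among %d unmapped>\n",
              s$n_permuted_reads, s$n_unique_oligos, s$n_unmapped))
  cat(sprintf("  frequency %.3g  (%.3g%%, display x100: %.3g)\n",
              s$frequency, s$percent, s$display_scale))
  invisible(x)
}

#' Permutation frequency of a dataset
#'
#' The deduplicated permuted-read count over the number of unmapped reads,
#' also expressed as a percentage and on the display scale conventionally
#' used for these rare events (percentage multiplied by 100).
#'
#' @param n_permuted_reads Deduplicated permuted-read count.
#' @param n_unmapped Reads that survived exact-match removal.
#' @return A one-row tibble: `n_unmapped`, `n_permuted_reads`, `frequency`,
#'   `percent`, `display_scale`. When `n_unmapped` is zero the ratios are
#'   reported as missing.
#' @examples
#' permutation_frequency(5, 1000)  # frequency 0.005, percent 0.5, display 50
#' @export
permutation_frequency <- function(n_permuted_reads, n_unmapped) {
  n_permuted_reads <- assert_count(n_permuted_reads, "n_permuted_reads")
  n_unmapped <- assert_count(n_unmapped, "n_unmapped")
  if (n_unmapped == 0L) {
    inform("No unmapped reads: permutation frequency undefined.")
    freq <- NA_real_
  } else {
    freq <- n_permuted_reads / n_unmapped
  }
  tibble(
    n_unmapped = n_unmapped,
    n_permuted_reads = n_permuted_reads,
    frequency = freq,
    percent = 100 * freq,
    display_scale = 100 * 100 * freq
  )
}

#' Export permutation loci as BED6
#'
#' Writes one line per hit: 0-based half-open locus, name = read id,
#' score = copies, strand.
#'
#' @param scan A `permutation_scan` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_permutation_bed <- function(scan, path) {
  stopifnot(inherits(scan, "permutation_scan"))
  h <- scan$hits
  bed <- data.frame(
    chrom = h$genome_id, start = h$locus_start, end = h$locus_end,
    name = h$read_id, score = h$copies, strand = h$strand
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
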