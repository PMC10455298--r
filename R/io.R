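## FASTA/FASTQ input and output (via Biostrings) plus the plain-text TSV
## side-channels used for ground truth and filter reports.

parse_header_meta <- function(headers) {
  ## headers look like "id key=value key=value"; the first token is the id
  parts <- strsplit(headers, " ", fixed = TRUE)
  id <- vapply(parts, `[[`, character(1), 1L)
  meta <- lapply(parts, function(p) {
    kv <- p[-1][grepl("=", p[-1], fixed = TRUE)]
    if (!length(kv)) return(list())
    key <- sub("=.*$", "", kv)
    val <- sub("^[^=]*=", "", kv)
    setNames(as.list(val), key)
  })
  list(id = id, meta = meta)
}

apply_header_meta <- function(out, meta) {
  keys <- unique(unlist(lapply(meta, names)))
  for (k in setdiff(keys, c("id", "sequence", "quality"))) {
    out[[k]] <- vapply(meta, function(m) {
      if (is.null(m[[k]])) NA_character_ else m[[k]]
    }, character(1))
  }
  out
}

format_headers <- function(reads) {
  extra <- setdiff(names(reads), c("id", "sequence", "quality"))
  hdr <- reads$id
  for (k in extra) {
    v <- reads[[k]]
    if (!is.atomic(v)) next
    keep <- !is.na(v)
    hdr[keep] <- paste0(hdr[keep], " ", k, "=", as.character(v[keep]))
  }
  hdr
}

#' Read and write sequence files
#'
#' Thin wrappers around Biostrings that convert between files and the
#' package's tibble read sets. Sequences are upcased on input; the read id,
#' sequence, qualities and any `key=value` tokens carried on the header line
#' (e.g. `provenance`, simulation `origin` labels) round-trip losslessly.
#'
#' @param path File to read or write.
#' @param provenance Default provenance for records without a
#'   `provenance=` header token.
#' @return `read_fasta()` / `read_fastq()` return a read-set tibble;
#'   the writers return `path` invisibly.
#' @name sequence_io
NULL

#' @rdname sequence_io
#' @export
read_fasta <- function(path, provenance = "synthetic") {
  ss <- Biostrings::readDNAStringSet(path, format = "fasta")
  h <- parse_header_meta(names(ss))
  out <- read_set(unname(as.character(ss)), id = h$id, provenance = provenance)
  restore_read_set(apply_header_meta(out, h$meta))
}

#' @rdname sequence_io
#' @export
read_fastq <- function(path, provenance = "synthetic") {
  parsed <- tryCatch({
    ss <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
    list(seq = unname(as.character(ss)),
         qual = unname(as.character(S4Vectors::mcols(ss)$qualities)),
         header = names(ss))
  }, error = function(e) {
    abort(sprintf("Malformed FASTQ in '%s': %s", path, conditionMessage(e)))
  })
  bad <- which(nchar(parsed$qual) != nchar(parsed$seq))
  if (length(bad)) {
    abort(sprintf("Malformed FASTQ record %d in '%s': quality length differs from sequence length.",
                  bad[1], path))
  }
  h <- parse_header_meta(parsed$header)
  out <- read_set(parsed$seq, id = h$id, quality = parsed$qual,
                  provenance = provenance)
  restore_read_set(apply_header_meta(out, h$meta))
}

#' @rdname sequence_io
#' @param reads A read-set tibble.
#' @export
write_fasta <- function(reads, path) {
  reads <- as_read_set(reads)
  ss <- Biostrings::DNAStringSet(reads$sequence)
  names(ss) <- format_headers(reads)
  Biostrings::writeXStringSet(ss, path, format = "fasta")
  invisible(path)
}

#' @rdname sequence_io
#' @param default_quality Phred+33 character used for every base of reads
#'   that carry no qualities (default `"I"`, Phred 40).
#' @export
write_fastq <- function(reads, path, default_quality = "I") {
  reads <- as_read_set(reads)
  q <- reads$quality
  miss <- is.na(q)
  q[miss] <- strrep(default_quality, nchar(reads$sequence[miss]))
  ss <- Biostrings::DNAStringSet(reads$sequence)
  names(ss) <- format_headers(reads)
  Biostrings::writeXStringSet(ss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(q))
  invisible(path)
}

#' @rdname sequence_io
#' @param g A genome (named character vector).
#' @export
write_genome_fasta <- function(g, path) {
  g <- as_genome(g)
  ss <- Biostrings::DNAStringSet(unclass(g))
  names(ss) <- names(g)
  Biostrings::writeXStringSet(ss, path, format = "fasta")
  invisible(path)
}

#' @rdname sequence_io
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fasta")
  genome(toupper(as.character(ss)), id = sub(" .*$", "", names(ss)))
}

#' Write or read a plain TSV table
#'
#' Used for ground-truth tables, per-read classifications and filter
#' reports.
#'
#' @param x A data frame.
#' @param path File path.
#' @return `write_tsv_table()` returns `path` invisibly; `read_tsv_table()`
#'   returns a tibble.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE))
}
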