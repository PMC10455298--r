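## Independent oracles used throughout the suite. They deliberately share no
## code with the package internals: pure-R window scans, Biostrings counting
## and rotation enumeration via base-R string search.

rc1 <- function(x) {
  ## local reverse complement, independent of trftracer::revcomp
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE)[[1]]),
        collapse = "")
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

## brute-force Hamming scan of one read against one sequence (top strand):
## data frame of (position 0-based, mismatches) for all windows within max_mm
oracle_hamming_scan <- function(read, seq, max_mm) {
  rb <- strsplit(read, "", fixed = TRUE)[[1]]
  gb <- strsplit(seq, "", fixed = TRUE)[[1]]
  l <- length(rb); L <- length(gb)
  pos <- integer(0); mm <- integer(0)
  if (l <= L) {
    for (p in 0:(L - l)) {
      d <- sum(rb != gb[(p + 1):(p + l)] | rb == "N" | gb[(p + 1):(p + l)] == "N")
      if (d <= max_mm) { pos <- c(pos, p); mm <- c(mm, d) }
    }
  }
  data.frame(position = pos, mismatches = mm)
}

## both-strand oracle mirroring match_read()'s output shape
oracle_match_read <- function(read, seq, max_mm) {
  fwd <- oracle_hamming_scan(read, seq, max_mm)
  rev <- oracle_hamming_scan(rc1(read), seq, max_mm)
  out <- rbind(
    if (nrow(fwd)) cbind(fwd, strand = "+") else NULL,
    if (nrow(rev)) cbind(rev, strand = "-") else NULL
  )
  if (is.null(out)) return(data.frame(position = integer(0),
                                      mismatches = integer(0),
                                      strand = character(0)))
  out[order(out$position, out$strand), c("position", "strand", "mismatches")]
}

## Biostrings-based has-a-hit oracle (either strand of any record)
oracle_has_match_biostrings <- function(read, subjects, max_mm) {
  any(vapply(subjects, function(s) {
    Biostrings::countPattern(read, s, max.mismatch = max_mm) > 0 ||
      Biostrings::countPattern(rc1(read), s, max.mismatch = max_mm) > 0
  }, logical(1)))
}

## ---- rotation oracles for the permutation detector ----------------------

## fully naive oracle: enumerate every genomic window of the oriented read's
## length and every rotation point; keep maximal-prefix junctions only.
## Returns a data frame (anchor, matched_prefix, relocated_len) per arm.
oracle_rotation_windows <- function(oriented, seq, k, min_transfer) {
  l <- nchar(oriented); L <- nchar(seq)
  anchor <- integer(0); m_out <- integer(0); s_out <- integer(0)
  if (l >= k + min_transfer && l <= L) {
    for (a in 0:(L - l)) {
      win <- substr(seq, a + 1, a + l)
      for (s in min_transfer:(l - k)) {
        rot <- paste0(substr(win, s + 1, l), substr(win, 1, s))
        if (rot != oriented) next
        p <- a + s; m <- l - s
        ## junction must be forced: prefix not extendable past m
        if (p + m < L &&
            substr(seq, p + m + 1, p + m + 1) == substr(oriented, m + 1, m + 1)) next
        anchor <- c(anchor, p); m_out <- c(m_out, m); s_out <- c(s_out, s)
      }
    }
  }
  data.frame(anchor = anchor, matched_prefix = m_out, relocated_len = s_out)
}

## faster oracle used at acceptance scale: for each rotation point, rebuild
## the un-rotated genomic segment and locate it with gregexpr()
oracle_rotation_segments <- function(oriented, seq, k, min_transfer) {
  l <- nchar(oriented); L <- nchar(seq)
  anchor <- integer(0); m_out <- integer(0); s_out <- integer(0)
  if (l >= k + min_transfer && l <= L) {
    for (s in min_transfer:(l - k)) {
      m <- l - s
      segment <- paste0(substr(oriented, m + 1, l), substr(oriented, 1, m))
      occ <- gregexpr(segment, seq, fixed = TRUE)[[1]]
      if (occ[1] == -1) next
      for (a in as.integer(occ) - 1L) {
        p <- a + s
        if (p + m < L &&
            substr(seq, p + m + 1, p + m + 1) == substr(oriented, m + 1, m + 1)) next
        anchor <- c(anchor, p); m_out <- c(m_out, m); s_out <- c(s_out, s)
      }
    }
  }
  data.frame(anchor = anchor, matched_prefix = m_out, relocated_len = s_out)
}

## full per-read oracle decision mirroring detect_permutations() on a
## single-record genome: exact-match removal, then both arms
oracle_detect_read <- function(read, seq, k, min_transfer,
                               segment_oracle = oracle_rotation_segments) {
  if (grepl(read, seq, fixed = TRUE) || grepl(rc1(read), seq, fixed = TRUE)) {
    return(NULL)  # removed at step 1
  }
  plus <- segment_oracle(read, seq, k, min_transfer)
  minus <- segment_oracle(rc1(read), seq, k, min_transfer)
  out <- rbind(
    if (nrow(plus)) cbind(plus, strand = "+") else NULL,
    if (nrow(minus)) cbind(minus, strand = "-") else NULL
  )
  if (is.null(out) || !nrow(out)) return(data.frame(
    anchor = integer(0), matched_prefix = integer(0),
    relocated_len = integer(0), strand = character(0)
  ))
  out[order(out$strand, out$anchor, out$matched_prefix), ]
}

## random Phred+33 quality string
random_quality <- function(len, min_q = 2, max_q = 40) {
  intToUtf8(33L + sample(min_q:max_q, len, replace = TRUE))
}
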