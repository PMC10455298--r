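## Synthetic-data generator: toy genome pairs with planted orthologous
## blocks, endonuclease-style tRF fragmentation, circularly permuted reads,
## dual-origin read mixtures and spike-in sets -- all with ground truth, so
## every downstream stage of the pipeline can be checked against a known
## answer.

#' Simulation configuration
#'
#' Collects the parameters of the synthetic co-culture experiment: two
#' random genomes sharing a configurable number of identical (orthologous)
#' blocks, and a read set drawn from host-unique, alien-unique and shared
#' regions with substitution errors and library artifacts.
#'
#' Default rates mirror a co-culture small RNA-seq experiment: an alien-only
#' read fraction of 0.012% (the level measured inside host cells co-cultured
#' with a secreting species), a shared/orthologous fraction of 2% (the
#' ectopic cross-mapping level of such libraries), a 0.1% per-base
#' substitution rate covering sequencing errors and strain SNPs, and a 0.4%
#' chance of a single 3' exonucleolytic truncation.
#'
#' @param seed Integer seed; the whole simulation is deterministic given the
#'   configuration and seed.
#' @param host_length,alien_length Genome lengths in bp.
#' @param n_shared_blocks,shared_block_length Number and size (bp) of
#'   identical blocks planted in both genomes.
#' @param n_reads Number of reads drawn by [simulate_mixture()].
#' @param read_length_range Inclusive read-length range in nt, within
#'   12-50.
#' @param error_rate Per-base substitution probability.
#' @param frac_alien,frac_common,frac_permuted Fractions of reads drawn from
#'   alien-unique regions, shared blocks, and injected as circular
#'   permutations of host segments; the remainder is host-unique.
#' @param exo_trim_prob Probability of one extra 1-nt 3' truncation in
#'   [simulate_trf_fragments()].
#' @param polya_ext_len Bases of a literal `"AAA"` poly-A-like tail appended
#'   at the 3' end of every mixture read (0-3 nt; models bacterial
#'   polyadenylation remnants).
#' @param lig_ext_len Random bases prepended at the 5' end of every mixture
#'   read (models ligation artifacts).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       host_length = 5000L, alien_length = 5000L,
                       n_shared_blocks = 2L, shared_block_length = 100L,
                       n_reads = 10000L,
                       read_length_range = c(16L, 50L),
                       error_rate = 0.001,
                       frac_alien = 0.00012,
                       frac_common = 0.02,
                       frac_permuted = 0,
                       exo_trim_prob = 0.004,
                       polya_ext_len = 0L,
                       lig_ext_len = 0L) {
  seed <- assert_count(seed, "seed")
  host_length <- assert_count(host_length, "host_length", min = 1L)
  alien_length <- assert_count(alien_length, "alien_length", min = 1L)
  n_shared_blocks <- assert_count(n_shared_blocks, "n_shared_blocks")
  shared_block_length <- assert_count(shared_block_length, "shared_block_length", min = 1L)
  n_reads <- assert_count(n_reads, "n_reads", min = 1L)
  stopifnot(length(read_length_range) == 2L)
  read_length_range <- as.integer(read_length_range)
  if (read_length_range[1] < 12L || read_length_range[2] > 50L ||
      read_length_range[1] > read_length_range[2]) {
    abort("`read_length_range` must be within [12, 50].")
  }
  assert_fraction(error_rate, "error_rate")
  assert_fraction(frac_alien, "frac_alien")
  assert_fraction(frac_common, "frac_common")
  assert_fraction(frac_permuted, "frac_permuted")
  if (frac_alien + frac_common > 1) {
    abort("`frac_alien + frac_common` must be <= 1.")
  }
  if (frac_alien + frac_common + frac_permuted > 1) {
    abort("Origin fractions must leave a non-negative host fraction.")
  }
  assert_fraction(exo_trim_prob, "exo_trim_prob")
  polya_ext_len <- assert_count(polya_ext_len, "polya_ext_len")
  if (polya_ext_len > 3L) abort("`polya_ext_len` must be 0-3 nt (a literal 'AAA' tail).")
  lig_ext_len <- assert_count(lig_ext_len, "lig_ext_len")
  structure(
    list(
      seed = seed, host_length = host_length, alien_length = alien_length,
      n_shared_blocks = n_shared_blocks,
      shared_block_length = shared_block_length,
      n_reads = n_reads, read_length_range = read_length_range,
      error_rate = error_rate, frac_alien = frac_alien,
      frac_common = frac_common, frac_permuted = frac_permuted,
      exo_trim_prob = exo_trim_prob,
      polya_ext_len = polya_ext_len, lig_ext_len = lig_ext_len
    ),
    class = "sim_config"
  )
}

## non-overlapping 0-based block starts on a genome of length L
sample_block_starts <- function(L, n_blocks, block_len) {
  if (n_blocks == 0L) return(integer(0))
  for (i in 1:1000) {
    st <- sort(sample.int(L - block_len + 1L, n_blocks) - 1L)
    if (n_blocks == 1L || all(diff(st) >= block_len)) return(st)
  }
  abort("Could not place non-overlapping shared blocks; genomes too small.")
}

## is occurrence [p, p+k) fully inside one of the intervals [s, s+len)?
inside_any <- function(p, k, starts, len) {
  any(p >= starts & p + k <= starts + len)
}

## mutate one outside-block base of the occurrence so the two genomes stop
## sharing this 12-mer
mutate_occurrence <- function(seq, p, k, starts, len) {
  cand <- setdiff(seq.int(p, p + k - 1L),
                  unlist(lapply(starts, function(s) seq.int(s, s + len - 1L))))
  i <- cand[ceiling(length(cand) / 2)]
  old <- substr(seq, i + 1L, i + 1L)
  substr(seq, i + 1L, i + 1L) <- sample1(setdiff(DNA_BASES, old))
  seq
}

#' Generate a toy host/alien genome pair
#'
#' Draws two uniform-random genomes and plants `n_shared_blocks` identical
#' blocks in both (the toy analogue of orthologous sequence). Outside the
#' shared blocks the two genomes are guaranteed to share no 12-mer: any
#' chance collision is removed by resampling a base of the offending window,
#' so a read of >= 12 nt drawn outside a block can never exactly match the
#' other genome.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `host` and `alien` (genomes) and
#'   `shared_intervals`, a tibble of 0-based block coordinates
#'   (`block`, `host_start`, `alien_start`, `length`).
#' @export
make_toy_genomes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  k <- 12L
  nb <- cfg$n_shared_blocks
  bl <- cfg$shared_block_length
  if (nb > 0L && (nb * bl > cfg$host_length || nb * bl > cfg$alien_length)) {
    abort("Shared blocks exceed a genome length; enlarge the genomes or shrink the blocks.")
  }
  withr::with_seed(cfg$seed, {
    host <- random_dna(cfg$host_length)
    alien <- random_dna(cfg$alien_length)
    h_starts <- sample_block_starts(cfg$host_length, nb, bl)
    a_starts <- sample_block_starts(cfg$alien_length, nb, bl)
    if (nb > 0L) {
      for (b in seq_len(nb)) {
        blk <- random_dna(bl)
        substr(host, h_starts[b] + 1L, h_starts[b] + bl) <- blk
        substr(alien, a_starts[b] + 1L, a_starts[b] + bl) <- blk
      }
    }
    ## remove chance 12-mer collisions outside the shared blocks
    for (iter in 1:200) {
      shared <- intersect(kmers(host, k, unique_only = TRUE),
                          kmers(alien, k, unique_only = TRUE))
      fixed <- TRUE
      for (km in shared) {
        for (p in cpp_find_occurrences(host, km)) {
          if (!inside_any(p, k, h_starts, bl)) {
            host <- mutate_occurrence(host, p, k, h_starts, bl)
            fixed <- FALSE
          }
        }
        for (p in cpp_find_occurrences(alien, km)) {
          if (!inside_any(p, k, a_starts, bl)) {
            alien <- mutate_occurrence(alien, p, k, a_starts, bl)
            fixed <- FALSE
          }
        }
      }
      if (fixed) break
    }
    if (!fixed) abort("Failed to separate the genomes' 12-mer sets; genomes too large for toy mode.")
    list(
      host = genome(host, id = "host"),
      alien = genome(alien, id = "alien"),
      shared_intervals = tibble(
        block = seq_len(nb),
        host_start = as.integer(h_starts),
        alien_start = as.integer(a_starts),
        length = rep(as.integer(bl), nb)
      )
    )
  })
}

#' Endonucleolytic cut model for a reference tRF
#'
#' Describes fixed 5'- and 3'-cleavage sites along a reference tRF as
#' weighted positions (0-based; the 3' coordinate is the last base of the
#' fragment, closed). Weights are normalised to sum to one per end.
#'
#' @param five_prime_sites,three_prime_sites Either a named numeric vector
#'   (`names` = 0-based positions, values = weights) or a data frame with
#'   columns `position` and `weight`.
#' @return A list of class `cut_model` with tibbles `five_prime` and
#'   `three_prime`.
#' @examples
#' cut_model(c(`0` = 0.6, `4` = 0.3, `8` = 0.1), c(`29` = 1))
#' @export
cut_model <- function(five_prime_sites, three_prime_sites) {
  norm_end <- function(x, which) {
    if (is.data.frame(x)) {
      pos <- as.integer(x$position); w <- as.numeric(x$weight)
    } else {
      pos <- as.integer(names(x)); w <- as.numeric(x)
    }
    if (any(is.na(pos)) || any(pos < 0L)) {
      abort(sprintf("%s positions must be non-negative integers.", which))
    }
    if (any(w < 0) || sum(w) <= 0) {
      abort(sprintf("%s weights must be non-negative with a positive sum.", which))
    }
    tibble(position = pos, weight = w / sum(w))
  }
  structure(
    list(
      five_prime = norm_end(five_prime_sites, "5'"),
      three_prime = norm_end(three_prime_sites, "3'")
    ),
    class = "cut_model"
  )
}

#' Simulate endonucleolytic tRF fragments
#'
#' Draws `n` fragments of `trf`, each delimited by a 5' site and a 3' site
#' sampled from the cut model (pairs with 5' >= 3' are excluded by joint
#' sampling over the valid grid). With probability `exo_trim_prob` a
#' fragment additionally loses its last base, modelling a single
#' exonucleolytic nibble.
#'
#' @param trf Reference tRF sequence (single nucleotide string).
#' @param cuts A [cut_model()] whose positions lie within `trf`.
#' @param n Number of fragments.
#' @param exo_trim_prob Probability of the extra 1-nt 3' truncation.
#' @param seed Integer seed.
#' @return A read-set tibble with truth columns `cut5`, `cut3` (the sampled
#'   0-based sites) and `exo_trimmed`.
#' @export
simulate_trf_fragments <- function(trf, cuts, n, exo_trim_prob = 0, seed = 1L) {
  stopifnot(is.character(trf), length(trf) == 1L, inherits(cuts, "cut_model"))
  n <- assert_count(n, "n", min = 1L)
  assert_fraction(exo_trim_prob, "exo_trim_prob")
  L <- nchar(trf)
  if (any(cuts$five_prime$position >= L) || any(cuts$three_prime$position >= L)) {
    abort("Cut-site positions must lie within the reference tRF.")
  }
  grid <- tidyr::expand_grid(
    p5 = cuts$five_prime$position,
    p3 = cuts$three_prime$position
  )
  w <- outer(cuts$five_prime$weight, cuts$three_prime$weight)
  grid$w <- as.vector(t(w))
  grid <- grid[grid$p5 < grid$p3 & grid$w > 0, , drop = FALSE]
  if (!nrow(grid)) {
    abort("Invalid cut model: every weighted 5' site is at or beyond every 3' site.")
  }
  withr::with_seed(seed, {
    i <- sample.int(nrow(grid), n, replace = TRUE, prob = grid$w)
    trimmed <- stats::runif(n) < exo_trim_prob
    p5 <- grid$p5[i]
    p3 <- grid$p3[i]
    end <- ifelse(trimmed, p3 - 1L, p3)
    out <- read_set(substr(rep(trf, n), p5 + 1L, end + 1L),
                    id = sprintf("frag_%d", seq_len(n)),
                    provenance = "synthetic")
    out$cut5 <- as.integer(p5)
    out$cut3 <- as.integer(p3)
    out$exo_trimmed <- trimmed
    restore_read_set(out)
  })
}

#' Inject circularly permuted reads with ground truth
#'
#' Builds reads that are rotations of contiguous genomic segments:
#' for a segment `g[a : a+L)` and a rotation offset `s`, the oriented read
#' is `g[a+s : a+L) + g[a : a+s)`. Draws whose read occurs verbatim in the
#' genome (degenerate rotations, repeats) are resampled, as are draws where
#' the matched prefix could be extended past the junction -- both would make
#' the read undetectable or ambiguous by construction rather than by the
#' detector's fault.
#'
#' @param g Genome to permute (single- or multi-record).
#' @param n Number of permuted reads.
#' @param total_len_range Read length range in nt (max 50).
#' @param relocated_len_range Range of the rotation offset (relocated
#'   segment length) in nt; its minimum must leave a >= 12 nt anchor, i.e.
#'   `total_len_range[1] - relocated_len_range[1] >= 12`.
#' @param strand_mix Fraction of reads sequenced from the bottom strand.
#' @param seed Integer seed.
#' @return A list with `reads` (read-set tibble, `origin = "permuted"`) and
#'   `truth`, a tibble of the true permutation records (`read_id`,
#'   `read_seq`, `genome_id`, `strand`, `anchor`, `matched_prefix`,
#'   `relocated_len`, `locus_start`, `locus_end`, `ligation_site`).
#' @export
inject_permuted_reads <- function(g, n, total_len_range = c(17L, 50L),
                                  relocated_len_range = c(5L, 12L),
                                  strand_mix = 0.5, seed = 1L) {
  g <- as_genome(g)
  n <- assert_count(n, "n", min = 1L)
  assert_fraction(strand_mix, "strand_mix")
  k <- 12L
  total_len_range <- as.integer(total_len_range)
  relocated_len_range <- as.integer(relocated_len_range)
  if (relocated_len_range[2] >= total_len_range[1]) {
    abort("`relocated_len_range` maximum must be below `total_len_range` minimum.")
  }
  if (total_len_range[2] > 50L) abort("`total_len_range` maximum must be <= 50 nt.")
  if (total_len_range[1] - relocated_len_range[1] < k) {
    abort("Shortest reads must keep a >= 12 nt anchor: total min - relocated min >= 12.")
  }
  recs <- unclass(g)
  rc_recs <- revcomp(recs)
  rec_len <- nchar(recs)
  if (max(total_len_range) > max(rec_len)) {
    abort("Genome records shorter than the longest requested read.")
  }
  withr::with_seed(seed, {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in 1:1000) {
        ri <- sample.int(length(recs), 1L, prob = rec_len)
        Lg <- rec_len[ri]
        Lr <- sample1(seq.int(total_len_range[1], min(total_len_range[2], Lg)))
        s_max <- min(relocated_len_range[2], Lr - k)
        s <- sample1(seq.int(relocated_len_range[1], s_max))
        a <- sample.int(Lg - Lr + 1L, 1L) - 1L
        gseq <- recs[[ri]]
        oriented <- paste0(substr(gseq, a + s + 1L, a + Lr),
                           substr(gseq, a + 1L, a + s))
        ## junction must be a real deviation: prefix not extendable past m
        if (a + Lr < Lg &&
            substr(gseq, a + Lr + 1L, a + Lr + 1L) == substr(gseq, a + 1L, a + 1L)) next
        ## the read (either orientation) must not occur verbatim anywhere
        if (any(cpp_contains(c(oriented, revcomp(oriented)), c(recs, rc_recs)))) next
        ok <- TRUE
        break
      }
      if (!ok) abort("Could not place a permuted read; relax the ranges or enlarge the genome.")
      minus <- stats::runif(1) < strand_mix
      rows[[i]] <- tibble(
        read_id = sprintf("perm_%d", i),
        read_seq = if (minus) revcomp(oriented) else oriented,
        genome_id = names(recs)[ri],
        strand = if (minus) "-" else "+",
        anchor = a + s,
        matched_prefix = Lr - s,
        relocated_len = s,
        locus_start = a,
        locus_end = a + Lr,
        ligation_site = a + s
      )
    }
    truth <- dplyr::bind_rows(rows)
    reads <- read_set(truth$read_seq, id = truth$read_id, provenance = "synthetic")
    reads$origin <- "permuted"
    list(reads = restore_read_set(reads), truth = truth)
  })
}

## sample a (start, length, sequence) for one read from `seq`, with the
## window required to avoid `avoid` intervals ([start, start+len) 0-based)
## or to sit inside one of `inside` intervals
sample_window <- function(seq, len_range, avoid = NULL, inside = NULL) {
  Lg <- nchar(seq)
  for (try in 1:1000) {
    l <- sample1(seq.int(len_range[1], len_range[2]))
    if (!is.null(inside)) {
      b <- sample.int(nrow(inside), 1L)
      l <- min(l, inside$length[b])
      off <- sample.int(inside$length[b] - l + 1L, 1L) - 1L
      st <- inside$start[b] + off
      return(list(start = st, len = l, seq = substr(seq, st + 1L, st + l)))
    }
    st <- sample.int(Lg - l + 1L, 1L) - 1L
    if (!is.null(avoid) && nrow(avoid) &&
        any(st < avoid$start + avoid$length & st + l > avoid$start)) next
    return(list(start = st, len = l, seq = substr(seq, st + 1L, st + l)))
  }
  abort("Could not sample a read window; genome too crowded with shared blocks.")
}

apply_substitutions <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  lens <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), lens, error_rate)
  idx <- which(n_err > 0L)
  for (i in idx) {
    pos <- sample.int(lens[i], n_err[i])
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (p in pos) ch[p] <- sample1(setdiff(DNA_BASES, ch[p]))
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate a dual-origin read mixture
#'
#' Draws `cfg$n_reads` reads from the host-unique regions, the alien-unique
#' regions and the shared blocks of a toy genome pair, in the configured
#' proportions, optionally injecting circularly permuted host reads. Each
#' read is sampled from a random strand, then per-base substitution errors,
#' a 5' ligation extension (`lig_ext_len` random nt) and a 3' poly-A-like
#' tail (`polya_ext_len` nt of `"AAA"`) are applied. The true origin of
#' every read is recorded in the `origin` column
#' (`host` / `alien` / `common` / `permuted`).
#'
#' @param host,alien Single-record genomes from [make_toy_genomes()].
#' @param shared_intervals The block-coordinate tibble from
#'   [make_toy_genomes()].
#' @param cfg The [sim_config()] used to build the genomes.
#' @param provenance Provenance label for the reads (default `"cellular"`).
#' @return A read-set tibble with the `origin` truth column.
#' @export
simulate_mixture <- function(host, alien, shared_intervals, cfg,
                             provenance = "cellular") {
  stopifnot(inherits(cfg, "sim_config"))
  host <- as_genome(host); alien <- as_genome(alien)
  if (length(host) != 1L || length(alien) != 1L) {
    abort("simulate_mixture() expects single-record toy genomes.")
  }
  h_seq <- host[[1]]; a_seq <- alien[[1]]
  h_blocks <- tibble(start = shared_intervals$host_start,
                     length = shared_intervals$length)
  a_blocks <- tibble(start = shared_intervals$alien_start,
                     length = shared_intervals$length)
  n <- cfg$n_reads
  withr::with_seed(derive_seed(cfg$seed, 1L), {
    origin <- sample(
      c("host", "alien", "common", "permuted"), n, replace = TRUE,
      prob = c(1 - cfg$frac_alien - cfg$frac_common - cfg$frac_permuted,
               cfg$frac_alien, cfg$frac_common, cfg$frac_permuted)
    )
    seqs <- character(n)
    for (i in seq_len(n)) {
      w <- switch(origin[i],
        host = sample_window(h_seq, cfg$read_length_range, avoid = h_blocks),
        alien = sample_window(a_seq, cfg$read_length_range, avoid = a_blocks),
        common = sample_window(h_seq, cfg$read_length_range, inside = h_blocks),
        permuted = NULL
      )
      if (!is.null(w)) seqs[i] <- w$seq
    }
    n_perm <- sum(origin == "permuted")
    if (n_perm > 0L) {
      inj <- inject_permuted_reads(
        host, n_perm,
        total_len_range = c(max(17L, cfg$read_length_range[1]),
                            cfg$read_length_range[2]),
        seed = derive_seed(cfg$seed, 2L)
      )
      seqs[origin == "permuted"] <- inj$reads$sequence
    }
    ## random sequencing strand for genome-derived reads
    flip <- stats::runif(n) < 0.5 & origin != "permuted"
    seqs[flip] <- revcomp(seqs[flip])
    seqs <- apply_substitutions(seqs, cfg$error_rate)
    if (cfg$lig_ext_len > 0L) {
      ext <- vapply(seq_len(n), function(i) random_dna(cfg$lig_ext_len), character(1))
      seqs <- paste0(ext, seqs)
    }
    if (cfg$polya_ext_len > 0L) {
      seqs <- paste0(seqs, substr("AAA", 1L, cfg$polya_ext_len))
    }
    out <- read_set(seqs, id = sprintf("mix_%d", seq_len(n)),
                    provenance = provenance)
    out$origin <- origin
    restore_read_set(out)
  })
}

#' Simulate a spike-in experiment
#'
#' Mixes reads sampled from known spike oligo sequences (with probability
#' `spike_molar_fraction`) into a background read set, labelling the true
#' origin of every read, so spike-in based concentration estimates can be
#' verified against the configured truth.
#'
#' @param background Read-set tibble to sample background reads from (with
#'   replacement).
#' @param spike_seqs Character vector of spike oligo sequences.
#' @param spike_molar_fraction Probability that a read comes from a spike
#'   (in `[0, 1)`; read counts are assumed proportional to molarity).
#' @param n Number of reads.
#' @param seed Integer seed.
#' @return A read-set tibble with truth columns `origin`
#'   (`"spike"` / `"background"`) and `spike_index`.
#' @export
simulate_spikein <- function(background, spike_seqs, spike_molar_fraction,
                             n, seed = 1L) {
  background <- as_read_set(background)
  if (!length(spike_seqs)) abort("`spike_seqs` must be non-empty.")
  if (!is.numeric(spike_molar_fraction) || spike_molar_fraction < 0 ||
      spike_molar_fraction >= 1) {
    abort("`spike_molar_fraction` must be in [0, 1).")
  }
  n <- assert_count(n, "n", min = 1L)
  spike_seqs <- toupper(spike_seqs)
  withr::with_seed(seed, {
    is_spike <- stats::runif(n) < spike_molar_fraction
    spike_i <- ifelse(is_spike,
                      sample.int(length(spike_seqs), n, replace = TRUE),
                      NA_integer_)
    bg_i <- sample.int(nrow(background), n, replace = TRUE)
    seqs <- ifelse(is_spike, spike_seqs[spike_i], background$sequence[bg_i])
    out <- read_set(seqs, id = sprintf("spk_%d", seq_len(n)),
                    provenance = "secretome")
    out$origin <- ifelse(is_spike, "spike", "background")
    out$spike_index <- spike_i
    restore_read_set(out)
  })
}
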