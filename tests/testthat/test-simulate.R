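toy_cfg <- function(...) {
  sim_config(seed = 101, host_length = 2000, alien_length = 2000,
             n_shared_blocks = 2, shared_block_length = 100,
             n_reads = 400, error_rate = 0, exo_trim_prob = 0, ...)
}

test_that("toy genomes contain the shared blocks verbatim and share no 12-mer elsewhere", {
  cfg <- toy_cfg()
  tg <- make_toy_genomes(cfg)
  h <- tg$host[[1]]; a <- tg$alien[[1]]
  iv <- tg$shared_intervals
  expect_equal(nrow(iv), 2)
  for (b in seq_len(nrow(iv))) {
    expect_equal(
      substr(h, iv$host_start[b] + 1, iv$host_start[b] + iv$length[b]),
      substr(a, iv$alien_start[b] + 1, iv$alien_start[b] + iv$length[b])
    )
  }
  ## every shared 12-mer occurs only inside the planted blocks
  shared <- intersect(kmers(h, 12, unique_only = TRUE),
                      kmers(a, 12, unique_only = TRUE))
  inside <- function(p, starts, len) any(p >= starts & p + 12 <= starts + len)
  for (km in shared) {
    occ_h <- as.integer(gregexpr(km, h, fixed = TRUE)[[1]]) - 1L
    occ_a <- as.integer(gregexpr(km, a, fixed = TRUE)[[1]]) - 1L
    expect_true(all(vapply(occ_h, inside, logical(1), iv$host_start, iv$length)))
    expect_true(all(vapply(occ_a, inside, logical(1), iv$alien_start, iv$length)))
  }
})

test_that("genomes with no shared blocks share no 12-mer at all", {
  cfg <- sim_config(seed = 5, host_length = 3000, alien_length = 3000,
                    n_shared_blocks = 0)
  tg <- make_toy_genomes(cfg)
  expect_length(
    intersect(kmers(tg$host[[1]], 12, unique_only = TRUE),
              kmers(tg$alien[[1]], 12, unique_only = TRUE)),
    0
  )
})

test_that("toy genome generation is deterministic and validates sizing", {
  cfg <- toy_cfg()
  tg1 <- make_toy_genomes(cfg)
  tg2 <- make_toy_genomes(cfg)
  expect_identical(tg1, tg2)
  ## byte-identical FASTA output
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(tg1$host, f1); write_genome_fasta(tg2$host, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(
    make_toy_genomes(sim_config(host_length = 150, alien_length = 5000,
                                n_shared_blocks = 2, shared_block_length = 100)),
    "exceed"
  )
})

test_that("sim_config rejects invalid fractions and ranges", {
  expect_error(sim_config(frac_alien = 0.7, frac_common = 0.5), "<= 1")
  expect_error(sim_config(read_length_range = c(8, 50)), "12")
  expect_error(sim_config(read_length_range = c(16, 60)), "12, 50")
  expect_error(sim_config(error_rate = 1.5), "error_rate")
  expect_error(sim_config(polya_ext_len = 5), "AAA")
})

test_that("tRF fragment simulation honours degenerate cut models", {
  withr::local_seed(3)
  trf <- random_seq(30)
  ## one 5' site at 0, one 3' site at the last base, no trimming -> all reads == trf
  cm <- cut_model(c(`0` = 1), stats::setNames(1, nchar(trf) - 1))
  fr <- simulate_trf_fragments(trf, cm, n = 50, exo_trim_prob = 0, seed = 2)
  expect_true(all(fr$sequence == trf))

  ## exo_trim_prob = 1 -> all reads are trf minus its last base
  fr1 <- simulate_trf_fragments(trf, cm, n = 50, exo_trim_prob = 1, seed = 2)
  expect_true(all(fr1$sequence == substr(trf, 1, nchar(trf) - 1)))
  expect_true(all(fr1$exo_trimmed))

  ## inverted model: every 5' site at/after every 3' site
  bad <- cut_model(c(`20` = 1), c(`5` = 1))
  expect_error(simulate_trf_fragments(trf, bad, 10), "Invalid cut model")
  expect_error(simulate_trf_fragments(trf, cut_model(c(`0` = 1), c(`99` = 1)), 10),
               "within")
})

test_that("empirical cut-site frequencies converge to the model weights", {
  withr::local_seed(8)
  trf <- random_seq(40)
  w5 <- c(`0` = 0.6, `5` = 0.3, `9` = 0.1)
  cm <- cut_model(w5, stats::setNames(1, 39))
  n <- 10000
  fr <- simulate_trf_fragments(trf, cm, n = n, exo_trim_prob = 0, seed = 12)
  obs <- table(factor(fr$cut5, levels = c(0, 5, 9))) / n
  for (i in seq_along(w5)) {
    sd_i <- sqrt(w5[i] * (1 - w5[i]) / n)
    expect_lt(abs(obs[i] - w5[i]), 3 * sd_i)
  }
})

test_that("injected permuted reads match their truth records by construction", {
  cfg <- toy_cfg()
  tg <- make_toy_genomes(cfg)
  g <- tg$host[[1]]
  inj <- inject_permuted_reads(tg$host, 50, seed = 9)
  expect_equal(nrow(inj$reads), 50)
  expect_equal(nrow(inj$truth), 50)
  for (i in seq_len(50)) {
    tr <- inj$truth[i, ]
    oriented <- paste0(
      substr(g, tr$anchor + 1, tr$anchor + tr$matched_prefix),
      substr(g, tr$locus_start + 1, tr$locus_start + tr$relocated_len)
    )
    expect_equal(tr$locus_end - tr$locus_start, nchar(tr$read_seq))
    expect_equal(tr$anchor, tr$locus_start + tr$relocated_len)
    if (tr$strand == "+") {
      expect_equal(tr$read_seq, oriented)
    } else {
      expect_equal(tr$read_seq, rc1(oriented))
    }
    ## never a verbatim genome substring (would be removed at step 1)
    expect_false(grepl(tr$read_seq, g, fixed = TRUE))
    expect_false(grepl(rc1(tr$read_seq), g, fixed = TRUE))
  }

  all_top <- inject_permuted_reads(tg$host, 20, strand_mix = 0, seed = 4)
  expect_true(all(all_top$truth$strand == "+"))

  expect_error(
    inject_permuted_reads(tg$host, 5, total_len_range = c(17, 50),
                          relocated_len_range = c(5, 20)),
    "below"
  )
})

test_that("mixture reads are verbatim host substrings when error-free and unextended", {
  cfg <- toy_cfg()
  cfg$frac_alien <- 0; cfg$frac_common <- 0
  tg <- make_toy_genomes(cfg)
  mix <- simulate_mixture(tg$host, tg$alien, tg$shared_intervals, cfg)
  g <- tg$host[[1]]
  expect_true(all(vapply(mix$sequence, function(s) {
    grepl(s, g, fixed = TRUE) || grepl(rc1(s), g, fixed = TRUE)
  }, logical(1))))
})

test_that("an all-common mixture classifies as COMMON at zero mismatches", {
  cfg <- toy_cfg()
  cfg$frac_common <- 1; cfg$frac_alien <- 0
  tg <- make_toy_genomes(cfg)
  mix <- simulate_mixture(tg$host, tg$alien, tg$shared_intervals, cfg)
  cl <- classify_reads(mix, tg$host, tg$alien, max_mismatch = 0)
  expect_equal(unname(cl$summary$count[cl$summary$category == "COMMON"]),
               nrow(mix))
})

test_that("mixture composition matches the configured fractions within 3 binomial SDs", {
  cfg <- sim_config(seed = 77, host_length = 3000, alien_length = 3000,
                    n_shared_blocks = 2, shared_block_length = 120,
                    n_reads = 10000, error_rate = 0,
                    frac_alien = 0.05, frac_common = 0.10)
  tg <- make_toy_genomes(cfg)
  mix <- simulate_mixture(tg$host, tg$alien, tg$shared_intervals, cfg)
  n <- nrow(mix)
  for (cat in c("alien", "common")) {
    p <- if (cat == "alien") cfg$frac_alien else cfg$frac_common
    obs <- mean(mix$origin == cat)
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("mixture extensions and determinism behave as configured", {
  cfg <- toy_cfg(polya_ext_len = 3, lig_ext_len = 1)
  tg <- make_toy_genomes(toy_cfg())
  mix <- simulate_mixture(tg$host, tg$alien, tg$shared_intervals, cfg)
  expect_true(all(substr(mix$sequence, nchar(mix$sequence) - 2,
                         nchar(mix$sequence)) == "AAA"))
  expect_true(all(nchar(mix$sequence) >= cfg$read_length_range[1] + 4))
  mix2 <- simulate_mixture(tg$host, tg$alien, tg$shared_intervals, cfg)
  expect_identical(mix, mix2)
})

test_that("spike-in simulation hits the configured molar fraction and labels survive FASTQ", {
  withr::local_seed(55)
  background <- read_set(vapply(sample(17:30, 500, TRUE), random_seq, character(1)),
                         provenance = "secretome")
  spikes <- vapply(rep(40, 4), random_seq, character(1))
  n <- 10000
  sp <- simulate_spikein(background, spikes, spike_molar_fraction = 0.5,
                         n = n, seed = 6)
  n_spike <- sum(sp$origin == "spike")
  expect_lt(abs(n_spike - n / 2), 3 * sqrt(n * 0.25))

  none <- simulate_spikein(background, spikes, spike_molar_fraction = 0,
                           n = 100, seed = 6)
  expect_equal(sum(none$origin == "spike"), 0)

  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(head(sp, 50), fq)
  back <- read_fastq(fq)
  expect_equal(back$origin, head(sp, 50)$origin)

  expect_error(simulate_spikein(background, character(0), 0.5, 10), "non-empty")
  expect_error(simulate_spikein(background, spikes, 1, 10), "\\[0, 1\\)")
})
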