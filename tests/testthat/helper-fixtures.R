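## construct a genome + rotated read where the junction is guaranteed to be
## detectable (prefix not extendable, read not verbatim in the genome)
make_rotation_case <- function(seed, L_genome = 100, a = 10, len = 30, s = 12) {
  withr::with_seed(seed, {
    repeat {
      g_seq <- random_seq(L_genome)
      oriented <- paste0(substr(g_seq, a + s + 1, a + len),
                         substr(g_seq, a + 1, a + s))
      extendable <- a + len < L_genome &&
        substr(g_seq, a + len + 1, a + len + 1) == substr(g_seq, a + 1, a + 1)
      verbatim <- grepl(oriented, g_seq, fixed = TRUE) ||
        grepl(rc1(oriented), g_seq, fixed = TRUE)
      if (!extendable && !verbatim) return(list(g = genome(g_seq, id = "g"),
                                                g_seq = g_seq,
                                                read = oriented))
    }
  })
}
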