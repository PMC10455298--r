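---
title: "Tracing alien tRNA fragments in co-culture small RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing alien tRNA fragments in co-culture small RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trftracer)
library(dplyr)
```

## The problem

When two bacterial species share a growth medium, each secretes short RNA
fragments — prominently tRNA-derived fragments (tRFs) — and some of those
fragments end up inside the cells of the other species. Quantifying this
traffic from small RNA-seq data raises four computational problems that
`trftracer` addresses as one pipeline:

1. **Dual-genome classification.** A read isolated from host cells must be
   assigned to the host genome, the co-cultured ("alien") genome, both
   (orthologous or conserved sequence), or neither. Because the interesting
   alien signal is orders of magnitude below the host background
   (on the order of 0.01% of reads), the assignment has to be exhaustive and
   exact, with a controlled mismatch tolerance to separate true alien reads
   from host reads carrying sequencing errors or strain SNPs.
2. **tRF tracing and end profiling.** Individual tRFs are traced with marker
   12-mers — windows of the tRF sequence context absent from the host genome
   on both strands — and the positional distribution of read 5′- and 3′-ends
   along the tRF distinguishes endonucleolytic cleavage (sharp, reproducible
   end peaks) from exonucleolytic decay (diffuse end erosion).
3. **Circular-permutation detection.** A read whose sequence is a rotation
   of a contiguous genomic segment is the footprint of a transient circular
   isoform: the linear fragment self-ligated and the ring was re-opened at a
   new site. These reads fail ordinary exact mapping and need a dedicated
   two-step search.
4. **Derived quantities.** Penetration efficiency, spike-in based absolute
   concentration, permutation frequencies, replicate means with standard
   errors, two-group tests with Bonferroni correction, and growth-curve
   areas.

Every stage is driven by a synthetic-data generator that produces toy
genomes and read sets with recorded ground truth, so the whole pipeline is
verifiable end to end without any external download.

## Read classification with bounded mismatches

`match_read()` reports every position on either strand of every genome
record where the Hamming distance between read and genome window is at most
`max_mismatch` (0–3). Coordinates are 0-based, top-strand throughout;
bottom-strand hits are found by scanning the reverse complement of the read
and reported in top-strand coordinates. `N` counts as a mismatch against
everything. Each FASTA record (chromosome, plasmid) is scanned separately,
so no match can span a record junction.

`classify_reads()` partitions a read set into `HOST_ONLY`, `ALIEN_ONLY`,
`COMMON` and `UNMATCHED`; a read counts once per genome however many
positions it hits. The same mismatch radius applies to both genomes.
`remove_host_like()` implements the complementary operation used before
tRF tracing: dropping every read within one mismatch of the host genome
(its exact matches plus the error/SNP halo).

The scanning core is a plain exhaustive window comparison with early exit,
written in C++. At the problem sizes this package targets (toy genomes of a
few kilobases, up to a few hundred thousand short reads) an index-free scan
is fast enough and keeps the contract — the *complete* hit list — trivially
auditable; the test suite checks it against both a pure-R Hamming scan and
Biostrings pattern counting.

```{r classify-demo}
cfg <- sim_config(seed = 42, host_length = 2000, alien_length = 2000,
                  n_reads = 2000, frac_alien = 0.01, frac_common = 0.02)
tg <- make_toy_genomes(cfg)
mix <- simulate_mixture(tg$host, tg$alien, tg$shared_intervals, cfg)
cl <- classify_reads(mix, tg$host, tg$alien, max_mismatch = 0)
glance(cl)
```

## Marker 12-mers and end profiles

`derive_markers()` returns the k-mers (default k = 12) of a tRF's sequence
context that occur nowhere in an excluded genome, on either strand. Twelve
is the shortest window that is effectively unique against a bacterial
genome: a 4.6-Mb genome contains about 4.6 million 12-mer windows against
4^12 ≈ 16.8 million possibilities, so most foreign 12-mers are absent, while
anything much shorter would be saturated. Reads carrying a marker are
collected by `collect_trf_reads()` and profiled by `profile_ends()`:
each read of length 12–50 nt (39 length groups) found verbatim in the
reference increments a 5′ counter at its start and a 3′ counter at its last
base (closed coordinate).

Three deliberate choices:

* **Exact placement, not alignment.** Reads are exact subfragments of the
  reference by construction of the assay; exact leftmost placement keeps
  the computation trivially checkable. Reads not found verbatim (sequencing
  errors, chimeras) are excluded from the profile denominators and counted
  separately (`n_unplaced`), so percentages describe the cleanly placed
  population.
* **Leftmost placement for repeats.** A read occurring several times in the
  reference is placed at its leftmost occurrence and flagged
  (`n_ambiguous`); for tRF-scale references repeats are rare and no
  placement rule can be justified from the data itself.
* **Closed 3′ coordinate.** The 3′-end position is the read's last base,
  matching how adjacent cleavage positions are described for end peaks.

`compare_profiles()` reports per-position percentage differences between
two profiles of the same reference (e.g. culture medium vs intracellular)
and tabulates peaks — local maxima above a percentage floor.

## The circular-permutation detector

For each read that survives exact-match removal against every supplied
genome, the detector:

1. anchors the read's first 12-mer at every exact genomic occurrence
   (both strands; the bottom-strand arm runs the same test on the reverse
   complement and converts coordinates to the top strand);
2. extends the anchor to the **maximal** matching prefix of length *m*;
3. accepts the read iff its remaining *s* = length − *m* bases (at least
   `min_transfer` nt) match the genome *immediately upstream* of the anchor,
   with no other deviation anywhere.

An accepted read reconstructs exactly as `g[p : p+m) + g[p−s : p)`; this
identity is asserted on every emitted hit. The locus `[p−s, p+m)` has the
read's length; the anchor *p* is reported as the ligation site, with the
locus left border also emitted, since both coordinate conventions occur in
practice for describing the junction. The maximal-prefix rule is the only
consistent one: accepting a junction at a shorter prefix would posit a
genomic deviation at a position where the genome actually matches the read.

Parameters: the anchor length stays at 12 for the same uniqueness reasons
as the markers. The minimum relocated-segment length defaults to 5 nt, the
setting used for transcriptome surveys; 4 nt is the procedural floor, and
both are exposed (`min_transfer`). Genome ends are linear — no hit may wrap
around a replicon boundary; circular-replicon (origin-spanning) detection
is out of scope.

Counting follows the read-level convention: identical read sequences
hitting multiple loci (paralogous genes) are counted once in the permuted
read tally, while all loci are listed and each hit carries the number of
identical supporting reads (`copies`). The frequency is the deduplicated
permuted-read count over the reads that survived exact-match removal
(`n_unmapped`), reported also as a percentage and on a ×100 display scale,
the convention used for plotting these rare events.

Two detector subtleties worth knowing:

* **Rotation ambiguity in repeats.** If the base preceding a permuted locus
  equals the base closing it, the rotation point is not unique: the same
  read reconstructs from two loci shifted by one base. The maximal-prefix
  rule picks one deterministically, but the mirror-image scan (on the
  reverse-complemented genome) may legitimately pick the other. Reported
  ligation sites are therefore exact only up to the length of the repeated
  run at the junction.
* **Directionality of the anchor.** Because the anchor is the *first*
  12-mer of the (oriented) read, a hit whose relocated segment is shorter
  than 12 nt is visible from one strand orientation only — which is why
  both genome strands must be scanned to collect all permuted reads.

```{r perm-demo}
g <- tg$host
inj <- inject_permuted_reads(g, 25, seed = 7)
scan <- detect_permutations(inj$reads, g)
glance(scan)
```

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
verified; its defaults are fixed once and encode the co-culture experiment
it emulates:

* **Genomes** are uniform-random over `{A,C,G,T}` (no `N`), sharing
  `n_shared_blocks` identical planted blocks — the toy analogue of
  orthologous sequence. Outside the blocks the two genomes are guaranteed
  to share no 12-mer: chance collisions are removed by mutating one base of
  the offending window. This makes truth labels exact: a ≥ 12-nt read drawn
  outside a block can never exactly match the other genome. The guarantee
  is what makes the toy classifier truth exact, and it limits genome sizes
  to the few-kilobase scale (the expected number of chance 12-mer
  collisions grows with the product of genome lengths).
* **Mixtures** draw reads of 16–50 nt from host-unique, alien-unique and
  shared regions at configured fractions, from a random strand, then apply
  per-base substitutions, an optional 5′ ligation extension (random bases)
  and an optional 3′ poly-A-like tail (a literal `"AAA"` truncated to the
  configured length, mirroring bacterial polyadenylation remnants). The
  default composition is the co-culture condition: alien-only fraction
  0.012% (the level measured inside host cells co-cultured with a secreting
  species), shared fraction 2% (the ectopic cross-mapping level of such
  libraries), substitution rate 0.1% per base — the per-base error/SNP rate
  is not something the source datasets report, so this is fixed once at a
  typical small RNA-seq order of magnitude.
* **tRF fragments** are cut at weighted 5′/3′ sites (`cut_model()`), the
  endonuclease picture: fixed ends with site preferences. Invalid pairs
  (5′ at or beyond 3′) are excluded by joint sampling over the valid site
  grid. A single optional 1-nt 3′ truncation (default probability 0.004,
  the order of the rare 3′ nibbling seen for synthetic oligos) models
  exonucleolysis.
* **Permuted reads** are true rotations of genomic segments with recorded
  anchor, prefix and relocated lengths. Draws are rejected when the read
  occurs verbatim in the genome (it would be removed at step 1 through no
  fault of the detector) or when the junction is not forced (the genome
  base one past the locus equals the locus's first base, in which case the
  maximal-prefix rule would rightly explain the read differently). Both
  rejections remove only constructions that are undetectable *by
  construction*, so recovery of the remaining truth records is a fair test
  of the detector.
* **Spike-ins** mix reads from known oligo sequences into a background at a
  molar fraction, assuming read counts proportional to molarity.

What the generator does **not** emulate: platform-specific homopolymer
indel errors (substitutions only), quality-value structure (uniform
qualities unless supplied), RNA secondary structure, any sequence
composition bias, and realistic genome repeat content. Passing tests
therefore demonstrate the correctness of the *computations* under the
stated statistical structure, not robustness to every artifact of real
libraries.

## Quality control

`run_qc()` applies, in this fixed order: per-read quality filtering (keep a
read when ≥ 90% of bases reach Phred 20), residual-adapter removal (drop a
read sharing ≥ 13 consecutive nt with an adapter; every adapter window of
that length is scanned, and a `clip` mode truncates instead of dropping),
background subtraction (exact sequence identity against a control set, e.g.
medium-only libraries), length selection (16–50 nt inclusive) and fixed end
trimming (1 nt from the 5′ end, 3 nt from the 3′ end — removing ligation
artifacts and short poly-A tails and mapping 16–50 nt reads onto
12–46 nt). Adapter and background matching are exact because no mismatch
tolerance can be justified for either; all filters are idempotent, and the
per-stage report is attached to the result (`qc_report()`).

## Derived quantities and statistics

* `penetration_efficiency(n_inside, n_outside)` =
  `100 · n_inside / (n_inside + n_outside)` — the percentage of imported
  molecules among all recovered ones; scale-invariant by construction.
* `estimate_concentration()` treats oligos added at a known total molar
  concentration as calibration spikes:
  `conc = spike_total_conc · (n_total − n_spike) / n_spike`, the simplest
  model consistent with read counts proportional to molar abundance. With
  four 1-µM oligos the default total is 4 µM and the estimate is returned
  in µM.
* `aggregate_percentages()` gives mean and SEM = sd/√n across replicates.
* `compare_groups()` is a two-sided two-sample t-test with
  `p_adjusted = min(1, p·m)` (Bonferroni). Welch is the default because
  replicate counts are small and variances unknown; `var_equal = TRUE`
  restores the pooled Student test. At very small group sizes (n ≈ 5) the
  Welch degrees-of-freedom approximation makes the test slightly
  conservative, while the pooled test holds its nominal size;
  size-calibration checks in the test suite therefore use the pooled form. When both groups are
  constant, p = 1 for equal means and p = 0 otherwise, by convention.
* `growth_auc()` integrates optical density over a time interval with the
  trapezoid rule, linearly interpolating interval endpoints that fall
  between samples; it is exactly additive over adjacent intervals.

## Problem sizes used in the checks

The verification suite runs entirely on synthetic data at desk scale: toy
genome pairs of 2–5 kb, read sets of 10,000–50,000, 500 injected
permutations for recovery rates, 10,000 fragments per end-profile recovery,
10⁵ reads per spike-in calibration and 10,000 Monte-Carlo replicates for
test-size calibration. These sizes give three-binomial-SD resolution on
every recovered fraction while keeping each check in seconds to a few
minutes on one core. The headline quantities of a real co-culture study
(alien-read percentages, penetration efficiencies, permutation counts
across whole transcriptomes) depend on the deposited sequencing libraries
and are not reproduced here; the synthetic conditions are set to the same
rates so the recovered values land in the same ranges.

## Known limitations

* The exhaustive scanner is deliberately index-free; for genomes beyond a
  few megabases or read sets beyond ~10⁶ a seeded index would be needed.
* The shared-block uniqueness repair limits toy genomes to the kilobase
  scale (see above).
* No gapped alignment anywhere: mismatches only in classification, and no
  mismatches, indels or non-template bases at permutation junctions —
  a read touched by both a rotation and a sequencing error is invisible to
  the detector, so real-data permutation frequencies are lower bounds.
* Circular replicons are treated as linear; origin-spanning loci are not
  detected.
* Spike-in calibration assumes equal capture efficiency for spikes and
  endogenous RNA; ligation and size biases of real libraries violate this
  to an unknown degree, which is why such estimates are order-of-magnitude
  calibrations rather than measurements.
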