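## Derived quantities and statistical comparisons: penetration efficiency,
## spike-in concentration, replicate aggregation with SEM, two-group tests
## with Bonferroni correction, growth-curve areas.

#' Penetration efficiency of an oligonucleotide
#'
#' The percentage of imported molecules: reads found inside cells over the
#' total found inside and outside.
#'
#' @param n_inside,n_outside Read counts inside cells and in the culture
#'   medium; vectors are recycled pairwise.
#' @return Percentage(s); `NA` where both counts are zero.
#' @examples
#' penetration_efficiency(1, 999)  # 0.1
#' @export
penetration_efficiency <- function(n_inside, n_outside) {
  stopifnot(is.numeric(n_inside), is.numeric(n_outside),
            all(n_inside >= 0, na.rm = TRUE), all(n_outside >= 0, na.rm = TRUE))
  total <- n_inside + n_outside
  out <- ifelse(total > 0, 100 * n_inside / total, NA_real_)
  if (any(total == 0, na.rm = TRUE)) {
    inform("penetration_efficiency(): zero total count; reported as NA.")
  }
  out
}

#' Estimate extracellular RNA concentration from spike-ins
#'
#' Oligos added at a known total molar concentration act as calibration
#' spikes: assuming read counts proportional to molar abundance, the
#' concentration of the remaining (non-spike) RNA is
#' `spike_total_conc * (n_total_reads - n_spike_reads) / n_spike_reads`.
#'
#' @param n_spike_reads Reads mapped to the spike oligos.
#' @param n_total_reads Total quality-controlled reads in the dataset.
#' @param spike_total_conc Combined molar concentration of all spikes
#'   (default 4, e.g. four oligos at 1 uM each; the estimate is returned in
#'   the same unit).
#' @return Estimated concentration; `NA` when `n_spike_reads` is zero.
#' @examples
#' estimate_concentration(500, 1000, spike_total_conc = 4)  # 4
#' @export
estimate_concentration <- function(n_spike_reads, n_total_reads,
                                   spike_total_conc = 4) {
  stopifnot(is.numeric(n_spike_reads), is.numeric(n_total_reads),
            is.numeric(spike_total_conc), all(spike_total_conc > 0))
  if (any(n_spike_reads > n_total_reads)) {
    abort("`n_spike_reads` cannot exceed `n_total_reads`.")
  }
  out <- ifelse(n_spike_reads > 0,
                spike_total_conc * (n_total_reads - n_spike_reads) / n_spike_reads,
                NA_real_)
  if (any(n_spike_reads == 0)) {
    inform("estimate_concentration(): zero spike reads; reported as NA.")
  }
  out
}

#' Aggregate replicate percentages
#'
#' Mean and standard error of the mean (`sd / sqrt(n)`) across replicates,
#' the form behind every "x +/- y %" summary.
#'
#' @param values Numeric vector of replicate measurements.
#' @return A one-row tibble: `mean`, `sem`, `n`. With a single replicate the
#'   SEM is `NA`.
#' @examples
#' aggregate_percentages(c(0, 2))  # mean 1, sem 1
#' @export
aggregate_percentages <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1L)
  n <- length(values)
  tibble(
    mean = mean(values),
    sem = if (n >= 2L) sd(values) / sqrt(n) else NA_real_,
    n = n
  )
}

#' Two-group comparison with Bonferroni correction
#'
#' Two-sided two-sample t-test (Welch by default; `var_equal = TRUE`
#' restores the pooled test) with
#' `p_adjusted = min(1, p * n_comparisons)`. When both groups are constant,
#' the convention is `p = 1` for equal means (no evidence of a difference)
#' and `p = 0` otherwise.
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @param n_comparisons Number of simultaneous comparisons for the
#'   Bonferroni correction.
#' @param var_equal Assume equal variances (pooled t-test)?
#' @return A one-row tibble: `t`, `p`, `p_adjusted`, `method`.
#' @examples
#' compare_groups(c(1, 2, 3), c(2, 3, 4), n_comparisons = 2)
#' @export
compare_groups <- function(a, b, n_comparisons = 1L, var_equal = FALSE) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 2L, length(b) >= 2L)
  n_comparisons <- assert_count(n_comparisons, "n_comparisons", min = 1L)
  res <- tryCatch(
    t.test(a, b, var.equal = var_equal),
    error = function(e) NULL
  )
  if (is.null(res)) {
    ## degenerate variance: both groups essentially constant
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      tt <- 0; pp <- 1
    } else {
      tt <- sign(mean(a) - mean(b)) * Inf; pp <- 0
    }
  } else {
    tt <- unname(res$statistic); pp <- res$p.value
  }
  tibble(
    t = tt,
    p = pp,
    p_adjusted = min(1, pp * n_comparisons),
    method = if (var_equal) "pooled t-test" else "Welch t-test"
  )
}

#' Bonferroni-adjust a p value
#'
#' @param p P value(s).
#' @param n_comparisons Number of simultaneous comparisons.
#' @return `min(1, p * n_comparisons)`, elementwise.
#' @examples
#' bonferroni(0.040, 2)  # 0.080
#' @export
bonferroni <- function(p, n_comparisons) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1, na.rm = TRUE))
  pmin(1, p * n_comparisons)
}

#' Construct a growth curve
#'
#' @param times Time points in hours, strictly increasing.
#' @param od Optical densities (e.g. at 650 nm), non-negative.
#' @param label Curve label.
#' @return A tibble of class `growth_curve` with columns `time_h`, `od`,
#'   `label`.
#' @export
growth_curve <- function(times, od, label = "culture") {
  stopifnot(is.numeric(times), is.numeric(od), length(times) == length(od))
  if (any(diff(times) <= 0)) abort("`times` must be strictly increasing.")
  if (any(od < 0)) abort("`od` must be non-negative.")
  out <- tibble(time_h = as.numeric(times), od = as.numeric(od),
                label = label)
  class(out) <- c("growth_curve", class(out))
  out
}

#' Area under a growth curve
#'
#' Trapezoidal integral of optical density over a time interval, with
#' linear interpolation where the interval endpoints fall between sampled
#' time points. Additive over adjacent intervals.
#'
#' @param curve A [growth_curve()] (or any tibble with `time_h` and `od`).
#' @param interval `c(t0, t1)` in hours; defaults to the full sampled
#'   range.
#' @return Area in OD x hours (0 for an empty interval).
#' @examples
#' gc <- growth_curve(0:10, rep(1, 11))
#' growth_auc(gc)  # 10
#' @export
growth_auc <- function(curve, interval = NULL) {
  stopifnot(is.data.frame(curve), all(c("time_h", "od") %in% names(curve)))
  t <- curve$time_h; y <- curve$od
  if (is.null(interval)) interval <- range(t)
  stopifnot(length(interval) == 2L)
  t0 <- interval[1]; t1 <- interval[2]
  if (t0 > t1) abort("`interval` must satisfy t0 <= t1.")
  if (t0 < min(t) || t1 > max(t)) {
    abort("`interval` must lie within the sampled time range.")
  }
  if (t0 == t1) return(0)
  inner <- t > t0 & t < t1
  grid_t <- c(t0, t[inner], t1)
  grid_y <- c(approx(t, y, xout = t0)$y, y[inner], approx(t, y, xout = t1)$y)
  pracma::trapz(grid_t, grid_y)
}
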