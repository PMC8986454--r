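#' Per-patient Echo minus fiducial-point differences
#'
#' For each valve event, repeated sonogram measures (times from R) are
#' averaged and the detected fiducial latency subtracted.  A negative
#' difference means the real valve event precedes the SCG fiducial point.
#'
#' @param echo_measures named list mapping events (`MC`, `AO`, `AC`, `MO`)
#'   to numeric vectors of echo-derived times-from-R in ms (all accepted
#'   images and beats pooled).
#' @param fp_latencies named vector of detected fiducial latencies in ms
#'   from R (NA for undetected points).
#' @return named numeric vector of per-event differences in ms; events
#'   without a valid measure or without a detected fiducial are absent.
#' @examples
#' patient_differences(list(AO = c(78, 82)), c(AO = 90))
#' @export
patient_differences <- function(echo_measures, fp_latencies) {
  out <- numeric(0)
  for (ev in intersect(FP_EVENTS, names(echo_measures))) {
    m <- echo_measures[[ev]]
    m <- m[is.finite(m)]
    fp <- fp_latencies[[ev]]
    if (!length(m) || is.null(fp) || !is.finite(fp)) next
    out[ev] <- mean(m) - fp
  }
  out
}

#' Group mean and sample SD per valve event
#'
#' @param diff_table data frame of per-patient differences with columns
#'   among `MC`, `AO`, `AC`, `MO` (NA allowed).
#' @return data frame with one row per event: `event`, `n`, `mean`, `sd`
#'   (sample SD, n-1 denominator).
#' @export
group_stats <- function(diff_table) {
  evs <- intersect(FP_EVENTS, names(diff_table))
  do.call(rbind, lapply(evs, function(ev) {
    x <- diff_table[[ev]]
    x <- x[is.finite(x)]
    if (length(x) < 2) {
      stopf("group statistics need at least 2 patients for event %s (got %d)", ev, length(x))
    }
    data.frame(event = ev, n = length(x), mean = mean(x), sd = sd(x))
  }))
}

#' 95% reference range for one valve event
#'
#' Exact mode computes `mean +/- 1.96 * SD` from the healthy-subject
#' summary statistics.  Printed mode substitutes the rounded ranges of the
#' published benchmark table (whose rounding is not exactly `1.96 * SD`),
#' for reproduction of the published within-range counts.
#'
#' @param event one of `"MC"`, `"AO"`, `"AC"`, `"MO"`.
#' @param mode `"exact"` or `"printed"`.
#' @param stats healthy-subject reference statistics, as from
#'   [healthy_reference()]; used by the exact mode.
#' @return numeric `c(lo, hi)`; a zero-width range (SD 0) carries the
#'   attribute `degenerate = TRUE`.
#' @examples
#' reference_range("MC")             # 4 +/- 1.96 * 11
#' reference_range("MC", "printed")  # 4 +/- 22
#' @export
reference_range <- function(event, mode = c("exact", "printed"),
                            stats = healthy_reference()) {
  mode <- match.arg(mode)
  event <- match.arg(event, FP_EVENTS)
  if (mode == "printed") {
    pr <- printed_reference_ranges()
    row <- pr[pr$event == event, ]
    rng <- c(row$center - row$halfwidth, row$center + row$halfwidth)
  } else {
    row <- stats[stats$event == event, ]
    if (!nrow(row)) stopf("no reference statistics for event %s", event)
    rng <- c(row$mean_ms - 1.96 * row$sd_ms, row$mean_ms + 1.96 * row$sd_ms)
  }
  if (diff(rng) == 0) attr(rng, "degenerate") <- TRUE
  rng
}

#' Count differences inside a reference range
#'
#' @param x numeric differences (non-finite values are dropped).
#' @param range numeric `c(lo, hi)`.
#' @param inclusive include both bounds (default; a difference sitting
#'   exactly on a bound counts as within).
#' @return integer count.
#' @export
count_within_range <- function(x, range, inclusive = TRUE) {
  x <- x[is.finite(x)]
  if (inclusive) sum(x >= range[1] & x <= range[2])
  else sum(x > range[1] & x < range[2])
}

#' Welch two-sample t test from summary statistics
#'
#' Unequal-variance t test with Welch-Satterthwaite degrees of freedom,
#' computed from group means, SDs and sizes (no raw data needed).
#'
#' @param mean1,sd1,n1 first group summary (n1 >= 2, sd1 > 0).
#' @param mean2,sd2,n2 second group summary.
#' @return an object of class `htest` with `statistic` (t), `parameter`
#'   (df) and `p.value` (two-sided).
#' @examples
#' welch_test(-17.1, 26.2, 20, 4, 11, 41)
#' @export
welch_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stopf("both groups need n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stopf("both SDs must be positive")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  structure(list(statistic = c(t = t), parameter = c(df = df), p.value = p,
                 estimate = c(`mean difference` = mean1 - mean2),
                 method = "Welch two-sample t test (summary statistics)",
                 data.name = sprintf("group1 (n=%d) vs group2 (n=%d)", n1, n2)),
            class = "htest")
}

#' Two-sided F test for equality of SDs from summary statistics
#'
#' The statistic is the larger sample variance over the smaller; the
#' two-sided p value doubles the upper tail (capped at 1).  Degrees of
#' freedom are ordered with the larger-variance group first.
#'
#' @param sd1,n1 first group SD and size.
#' @param sd2,n2 second group SD and size.
#' @return an object of class `htest`.
#' @examples
#' f_test_variances(26.2, 20, 11, 41)
#' @export
f_test_variances <- function(sd1, n1, sd2, n2) {
  if (n1 < 2 || n2 < 2) stopf("both groups need n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stopf("both SDs must be positive")
  v1 <- sd1^2
  v2 <- sd2^2
  if (v1 >= v2) {
    f <- v1 / v2; df <- c(df1 = n1 - 1, df2 = n2 - 1)
  } else {
    f <- v2 / v1; df <- c(df1 = n2 - 1, df2 = n1 - 1)
  }
  p <- if (f == 1) 1 else min(1, 2 * pf(f, df[1], df[2], lower.tail = FALSE))
  structure(list(statistic = c(F = f), parameter = df, p.value = p,
                 method = "Two-sided F test of SDs (summary statistics)",
                 data.name = sprintf("sd1=%g (n=%d) vs sd2=%g (n=%d)", sd1, n1, sd2, n2)),
            class = "htest")
}

#' G test of independence (likelihood-ratio chi-square)
#'
#' `G = 2 * sum(observed * log(observed / expected))` with expected counts
#' from the marginals; zero cells contribute nothing.  The p value uses the
#' chi-square distribution with `(r - 1) * (c - 1)` degrees of freedom.
#' No correction is applied by default; the Williams correction is
#' available as an option.
#'
#' @param tab matrix of non-negative integer counts; every row and column
#'   marginal must be positive.
#' @param correction `"none"` (default) or `"williams"`.
#' @return an object of class `htest`.
#' @examples
#' g_test_independence(matrix(c(26, 8, 27, 22), 2, byrow = TRUE))
#' @export
g_test_independence <- function(tab, correction = c("none", "williams")) {
  correction <- match.arg(correction)
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) stopf("counts must be non-negative integers")
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) stopf("every row and column marginal must be positive")
  n <- sum(tab)
  expected <- outer(rs, cs) / n
  pos <- tab > 0
  g <- 2 * sum(tab[pos] * log(tab[pos] / expected[pos]))
  if (correction == "williams") {
    q <- 1 + ((n * sum(1 / rs) - 1) * (n * sum(1 / cs) - 1)) /
      (6 * n * (nrow(tab) - 1) * (ncol(tab) - 1))
    g <- g / q
  }
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  p <- pchisq(g, df, lower.tail = FALSE)
  structure(list(statistic = c(G = g), parameter = c(df = df), p.value = p,
                 method = sprintf("G test of independence (%s correction)", correction),
                 data.name = sprintf("%dx%d contingency table, n=%d", nrow(tab), ncol(tab), n)),
            class = "htest")
}

#' Prevalence of the traditional waveform by stratum
#'
#' @param cohort data frame with one row per patient and columns
#'   `waveform_class` (`"T"` / `"NT"`) plus the stratifier column.
#' @param by stratifier column name, e.g. `"diagnosis"` or `"ef_band"`.
#'   Patients with a missing stratum are reported in an `"unavailable"`
#'   row.
#' @param levels optional stratum ordering for the output.
#' @return data frame with columns `stratum`, `n_patients`,
#'   `n_traditional`, `prevalence` (exact fraction) and `prevalence_pct`
#'   (rounded to integer percent for display).
#' @examples
#' prevalence_table(study_cohort(), by = "diagnosis")
#' @export
prevalence_table <- function(cohort, by = "diagnosis", levels = NULL) {
  if (!nrow(cohort)) {
    return(data.frame(stratum = character(0), n_patients = integer(0),
                      n_traditional = integer(0), prevalence = numeric(0),
                      prevalence_pct = numeric(0)))
  }
  if (!by %in% names(cohort)) stopf("cohort has no column `%s`", by)
  if (!"waveform_class" %in% names(cohort)) stopf("cohort has no column `waveform_class`")
  strata <- as.character(cohort[[by]])
  strata[is.na(strata) | strata == ""] <- "unavailable"
  if (is.null(levels)) {
    levels <- unique(strata[strata != "unavailable"])
    if ("unavailable" %in% strata) levels <- c(levels, "unavailable")
  }
  out <- do.call(rbind, lapply(levels, function(s) {
    sel <- strata == s
    n <- sum(sel)
    nt <- sum(sel & cohort$waveform_class == "T")
    data.frame(stratum = s, n_patients = n, n_traditional = nt,
               prevalence = if (n > 0) nt / n else NA_real_,
               prevalence_pct = if (n > 0) round(100 * nt / n) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
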