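#' Detect R peaks in an ECG channel
#'
#' The ECG is conditioned with a zero-phase 0.5--40 Hz Butterworth filter,
#' candidate local maxima above an adaptive amplitude threshold are
#' collected, a 200 ms refractory period is enforced (keeping the larger
#' peak on conflicts), and each detection is snapped to the local maximum
#' of the raw ECG.
#'
#' @param ecg numeric ECG samples.
#' @param sampling_rate sampling rate in Hz.
#' @param refractory_ms minimum separation between accepted R peaks.
#' @param threshold_frac detection threshold as a fraction of the 99.9th
#'   amplitude percentile of the conditioned ECG.
#' @return a `beat_series` object: list with `r_times` (ms from record
#'   start, strictly increasing), `rr` (first differences, ms), `quality`
#'   (per-beat, initialised to `"good"`), `q_times` (filled by
#'   [detect_q_points()]), and `sampling_rate`.  A flat or peak-free signal
#'   yields an empty series, not an error.
#' @examples
#' rec <- generate_record(synth_config(duration = 10, seed = 1))
#' detect_r_peaks(rec$record$ecg, rec$record$sampling_rate)$r_times[1:3]
#' @export
detect_r_peaks <- function(ecg, sampling_rate, refractory_ms = 200,
                           threshold_frac = 0.5) {
  if (length(ecg) < 2 * sampling_rate) {
    stopf("need at least 2 s of ECG (got %.2f s)", length(ecg) / sampling_rate)
  }
  empty <- structure(list(r_times = numeric(0), rr = numeric(0),
                          quality = character(0), q_times = NULL,
                          sampling_rate = sampling_rate),
                     class = "beat_series")
  if (diff(range(ecg)) == 0) return(empty)
  z <- bandpass_filter(ecg, sampling_rate,
                       filter_spec(0.5, min(40, sampling_rate / 2 - 1), 3))
  thr <- threshold_frac * quantile(z, 0.999, names = FALSE)
  if (thr <= 0) return(empty)
  n <- length(z)
  cand <- which(z[-c(1, n)] > z[-c(n - 1, n)] & z[-c(1, n)] >= z[-c(1, 2)]) + 1L
  cand <- cand[z[cand] > thr]
  if (!length(cand)) return(empty)
  # greedy refractory resolution, strongest candidates first
  refr <- refractory_ms / 1000 * sampling_rate
  cand <- cand[order(z[cand], decreasing = TRUE)]
  accepted <- integer(0)
  for (i in cand) {
    if (!length(accepted) || all(abs(accepted - i) >= refr)) accepted <- c(accepted, i)
  }
  accepted <- sort(accepted)
  # snap to the raw-ECG local maximum within +/- 10 ms
  w <- max(1L, as.integer(round(0.010 * sampling_rate)))
  idx <- vapply(accepted, function(i) {
    lo <- max(1L, i - w); hi <- min(length(ecg), i + w)
    lo + which.max(ecg[lo:hi]) - 1L
  }, integer(1))
  idx <- sort(unique(idx))
  r_times <- (idx - 1L) / sampling_rate * 1000
  structure(list(r_times = r_times, rr = diff(r_times),
                 quality = rep("good", length(r_times)),
                 q_times = NULL, sampling_rate = sampling_rate),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats", length(x$r_times)))
  if (length(x$rr)) cat(sprintf(", mean RR %.0f ms", mean(x$rr)))
  tab <- table(x$quality)
  if (length(tab)) cat(" [", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "]")
  cat("\n")
  invisible(x)
}

#' Detect Q points preceding each R peak
#'
#' The Q point is taken as the ECG minimum in the window
#' `[R - 60 ms, R - 4 ms]`.  Beats whose window extends before the record
#' start get a missing Q; a Q found exactly at a window edge (e.g. on a
#' monotone segment) is flagged low-confidence.
#'
#' @param ecg numeric ECG samples (same channel used for R detection).
#' @param r_times R-peak times in ms from record start.
#' @param sampling_rate sampling rate in Hz.
#' @param window search window in ms relative to R (default `c(-60, -4)`).
#' @return data frame with one row per beat: `q_time_ms` (NA when the
#'   window is truncated) and `low_confidence`.
#' @export
detect_q_points <- function(ecg, r_times, sampling_rate, window = c(-60, -4)) {
  out <- data.frame(q_time_ms = rep(NA_real_, length(r_times)),
                    low_confidence = rep(FALSE, length(r_times)))
  for (k in seq_along(r_times)) {
    lo <- round((r_times[k] + window[1]) / 1000 * sampling_rate) + 1L
    hi <- round((r_times[k] + window[2]) / 1000 * sampling_rate) + 1L
    if (lo < 1L || hi > length(ecg) || hi <= lo) next
    seg <- ecg[lo:hi]
    j <- which.min(seg)
    out$q_time_ms[k] <- (lo + j - 2L) / sampling_rate * 1000
    out$low_confidence[k] <- j == 1L || j == length(seg)
  }
  out
}

#' Flag per-beat quality
#'
#' A beat is flagged `"ectopic"` when its incoming RR interval is more than
#' 20% shorter than the running median (window 5) of the RR series -- the
#' premature-beat signature; the compensatory pause that follows is a
#' consequence of the ectopy and the beat terminating it is still sinus.
#' A beat is flagged `"noisy"` when the SCG RMS over its analysis window
#' exceeds 3 times the median per-beat RMS.
#'
#' @param series a `beat_series` from [detect_r_peaks()].
#' @param scg the (filtered) SCG channel at the series' sampling rate.
#' @param window_ms per-beat analysis window in ms relative to R.
#' @param rr_tol fractional RR shortening that marks ectopy (default 0.2).
#' @param rms_factor multiple of the median beat RMS that marks noise.
#' @return the series with `quality` updated.
#' @export
flag_beat_quality <- function(series, scg, window_ms = c(-100, 600),
                              rr_tol = 0.2, rms_factor = 3) {
  stopifnot(inherits(series, "beat_series"))
  nb <- length(series$r_times)
  if (!nb) stopf("cannot flag an empty beat series")
  fs <- series$sampling_rate
  quality <- rep("good", nb)

  if (nb >= 3) {
    med <- runmed(series$rr, k = min(5L, length(series$rr) - !(length(series$rr) %% 2)),
                  endrule = "median")
    short <- series$rr < (1 - rr_tol) * med
    quality[which(short) + 1L] <- "ectopic"
  }

  rms <- vapply(seq_len(nb), function(k) {
    lo <- max(1L, round((series$r_times[k] + window_ms[1]) / 1000 * fs) + 1L)
    hi <- min(length(scg), round((series$r_times[k] + window_ms[2]) / 1000 * fs) + 1L)
    if (hi <= lo) return(NA_real_)
    sqrt(mean(scg[lo:hi]^2))
  }, numeric(1))
  med_rms <- median(rms, na.rm = TRUE)
  if (is.finite(med_rms) && med_rms > 0) {
    noisy <- !is.na(rms) & rms > rms_factor * med_rms
    quality[noisy & quality == "good"] <- "noisy"
  }
  series$quality <- quality
  series
}

#' Select the analysis window of good beats
#'
#' Returns the longest contiguous run of at least `min_beats` good-quality
#' beats (the earliest on ties): the more beats enter the ensemble
#' average, the stronger the noise suppression.  When no such run exists
#' but at least one good beat does, the single-beat fallback engages: the
#' good beat whose incoming RR is closest to the median RR is returned
#' alone (averaging a single sinus beat avoids smearing by irregular
#' beats).
#'
#' @param series a flagged `beat_series`.
#' @param min_beats minimum run length (default 6).
#' @return list with `indices` (beat indices into the series) and
#'   `single_beat` flag.
#' @export
select_window <- function(series, min_beats = 6) {
  stopifnot(inherits(series, "beat_series"))
  good <- series$quality == "good"
  if (!any(good)) stopf("no usable beats: every beat is flagged ectopic or noisy")
  r <- rle(good)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= min_beats)
  if (length(ok)) {
    pick <- ok[which.max(r$lengths[ok])]   # longest; which.max ties -> earliest
    s <- starts[pick]
    return(list(indices = s:(s + r$lengths[pick] - 1L), single_beat = FALSE))
  }
  # fallback: most representative single good beat
  rr_in <- c(series$rr[1], series$rr)[seq_along(series$r_times)]
  med <- median(series$rr)
  cand <- which(good)
  best <- cand[which.min(abs(rr_in[cand] - med))]
  list(indices = best, single_beat = TRUE)
}

#' Ensemble-average SCG beats synchronized at the R peak
#'
#' Per-beat segments over `window_ms` relative to each R peak are averaged
#' sample-wise.  Segments truncated by the record edges contribute nothing
#' to the samples they miss (the mean at each time point runs over the
#' beats that cover it).
#'
#' @param scg the (filtered) SCG channel.
#' @param series a `beat_series` at the same sampling rate.
#' @param indices beats to average; defaults to [select_window()] on the
#'   series.
#' @param window_ms averaging window in ms relative to R; must contain 0.
#' @return an `scg_average_beat`: list with `time_ms` (relative to R),
#'   `samples`, `n_beats_used`, `mean_rr` (ms) and `sampling_rate`.
#' @examples
#' rec <- generate_record(synth_config(duration = 10, seed = 1))
#' bs <- detect_r_peaks(rec$record$ecg, 200)
#' avg <- ensemble_average(bandpass_filter(rec$record$scg, 200), bs)
#' @export
ensemble_average <- function(scg, series, indices = NULL,
                             window_ms = c(-100, 600)) {
  stopifnot(inherits(series, "beat_series"))
  if (window_ms[1] > 0 || window_ms[2] < 0) stopf("`window_ms` must contain 0 (the R instant)")
  if (is.null(indices)) indices <- select_window(series)$indices
  if (!length(indices)) stopf("no beats selected for averaging")
  fs <- series$sampling_rate
  k_lo <- round(window_ms[1] / 1000 * fs)
  k_hi <- round(window_ms[2] / 1000 * fs)
  offs <- k_lo:k_hi
  n <- length(scg)
  acc <- numeric(length(offs))
  cnt <- integer(length(offs))
  for (b in indices) {
    ridx <- round(series$r_times[b] / 1000 * fs) + 1L
    pos <- ridx + offs
    ok <- pos >= 1L & pos <= n
    acc[ok] <- acc[ok] + scg[pos[ok]]
    cnt[ok] <- cnt[ok] + 1L
  }
  if (!any(cnt > 0)) stopf("averaging window lies outside the record for every selected beat")
  samples <- ifelse(cnt > 0, acc / pmax(cnt, 1L), NA_real_)
  mean_rr <- if (length(indices) >= 2) {
    mean(diff(series$r_times[sort(indices)]))
  } else if (length(series$rr)) median(series$rr) else NA_real_
  structure(list(time_ms = offs / fs * 1000, samples = samples,
                 n_beats_used = length(indices), mean_rr = mean_rr,
                 sampling_rate = fs),
            class = "scg_average_beat")
}

#' @export
print.scg_average_beat <- function(x, ...) {
  cat(sprintf("<scg_average_beat> %d beats averaged, window %g..%g ms, mean RR %.0f ms\n",
              x$n_beats_used, min(x$time_ms), max(x$time_ms), x$mean_rr))
  invisible(x)
}

#' @export
plot.scg_average_beat <- function(x, ...) {
  graphics::plot(x$time_ms, x$samples, type = "l",
                 xlab = "time from R peak [ms]", ylab = "SCG [a.u.]", ...)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  invisible(x)
}
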