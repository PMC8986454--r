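#' Default fiducial-point search windows
#'
#' Literature-informed windows in ms from the R peak: MC 10--60, AO
#' 45--160, AC 250--450, MO from 20 to 180 ms after the detected AC.  The
#' diastolic windows (AC, and the AC fallback for MO) scale with the mean
#' RR interval (factor `mean_rr / 1000`, clipped to `[0.7, 1.3]`), since
#' diastolic events shift with heart rate while systolic ones barely do.
#'
#' @param mean_rr mean RR in ms, or `NULL` for no scaling.
#' @return named list of `c(lo, hi)` windows; `MO` holds offsets relative
#'   to the detected AC.
#' @export
default_fp_windows <- function(mean_rr = NULL) {
  f <- 1
  if (!is.null(mean_rr) && is.finite(mean_rr)) {
    f <- min(1.3, max(0.7, mean_rr / 1000))
  }
  list(MC = c(10, 60), AO = c(45, 160), AC = f * c(250, 450), MO = c(20, 180))
}

# Topographic prominence of the local maximum at index i of y: height above
# the higher of the two key saddles (walk outward until a strictly higher
# sample or the signal edge).
peak_prominence <- function(y, i) {
  h <- y[i]
  left_min <- h
  j <- i - 1L
  while (j >= 1L && y[j] <= h) {
    if (y[j] < left_min) left_min <- y[j]
    j <- j - 1L
  }
  right_min <- h
  j <- i + 1L
  while (j <= length(y) && y[j] <= h) {
    if (y[j] < right_min) right_min <- y[j]
    j <- j + 1L
  }
  h - max(left_min, right_min)
}

local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

#' Detect the four fiducial points on an averaged SCG beat
#'
#' Each fiducial point is the local extremum of greatest topographic
#' prominence inside its search window (a per-point polarity switch allows
#' conventions that place a point on a valley).  The search is sequential:
#' AO is searched after the detected MC, MO after the detected AC.  A point
#' is "found" when its prominence reaches `prominence_frac` of the beat's
#' peak-to-peak amplitude; ties break toward the earlier extremum.
#'
#' @param beat an `scg_average_beat` from [ensemble_average()].
#' @param windows list as from [default_fp_windows()]; `NULL` uses the
#'   defaults scaled by the beat's mean RR.
#' @param prominence_frac detection threshold as a fraction of the beat
#'   peak-to-peak amplitude (default 0.10).
#' @param polarity named vector of +1 / -1 per point (default all +1,
#'   peaks).
#' @return a `fiducial_set`: lists `latencies` (ms from R, NA when not
#'   found), `prominences`, `found_flags`, `search_windows_used`.
#' @examples
#' rec <- generate_record(synth_config(duration = 10, noise_sd = 0, seed = 1))
#' bs <- detect_r_peaks(rec$record$ecg, 200)
#' avg <- ensemble_average(bandpass_filter(rec$record$scg, 200), bs)
#' detect_fiducials(avg)$latencies
#' @export
detect_fiducials <- function(beat, windows = NULL, prominence_frac = 0.10,
                             polarity = c(MC = 1, AO = 1, AC = 1, MO = 1)) {
  stopifnot(inherits(beat, "scg_average_beat"))
  if (is.null(windows)) windows <- default_fp_windows(beat$mean_rr)
  polarity <- check_fp_names(polarity, "polarity")
  t <- beat$time_ms
  y <- beat$samples
  ok <- is.finite(y)
  t <- t[ok]; y <- y[ok]
  p2p <- diff(range(y))

  lat <- prom <- structure(rep(NA_real_, 4), names = FP_EVENTS)
  found <- structure(rep(FALSE, 4), names = FP_EVENTS)
  used <- list()

  find_in <- function(win, pol) {
    if (win[1] < min(t) || win[2] > max(t)) {
      stopf("averaged beat (%g..%g ms) does not cover the search window %g..%g ms",
            min(t), max(t), win[1], win[2])
    }
    sel <- which(t >= win[1] & t <= win[2])
    # prominence confined to the window (edges act as signal boundaries),
    # so remote valleys elsewhere on the beat cannot inflate small ripples
    seg <- pol * y[sel]
    cand <- local_maxima(seg)
    if (!length(cand)) return(NULL)
    pr <- vapply(cand, function(i) peak_prominence(seg, i), numeric(1))
    best <- cand[which.max(pr)]       # which.max ties -> earliest
    list(lat = t[sel[best]], prom = max(pr))
  }

  if (p2p > 0) {
    # MC
    w <- windows$MC; used$MC <- w
    r <- find_in(w, polarity["MC"])
    if (!is.null(r)) { lat["MC"] <- r$lat; prom["MC"] <- r$prom }
    # AO: starts after the detected MC
    w <- windows$AO
    if (is.finite(lat["MC"])) w[1] <- max(w[1], lat["MC"] + 2)
    used$AO <- w
    r <- find_in(w, polarity["AO"])
    if (!is.null(r)) { lat["AO"] <- r$lat; prom["AO"] <- r$prom }
    # AC
    w <- windows$AC
    if (is.finite(lat["AO"])) w[1] <- max(w[1], lat["AO"] + 2)
    used$AC <- w
    r <- find_in(w, polarity["AC"])
    if (!is.null(r)) { lat["AC"] <- r$lat; prom["AC"] <- r$prom }
    # MO: relative to the detected AC (fall back to the AC window bounds)
    anchor <- if (is.finite(lat["AC"])) lat["AC"] else NA
    w <- if (is.finite(anchor)) anchor + windows$MO
         else c(windows$AC[1] + windows$MO[1], windows$AC[2] + windows$MO[2])
    w[2] <- min(w[2], max(t))
    used$MO <- w
    if (w[2] > w[1]) {
      r <- find_in(w, polarity["MO"])
      if (!is.null(r)) { lat["MO"] <- r$lat; prom["MO"] <- r$prom }
    }
    found <- is.finite(prom) & prom >= prominence_frac * p2p
    lat[!found] <- NA_real_
  } else {
    used <- windows
  }

  structure(list(latencies = lat, prominences = prom, found_flags = found,
                 search_windows_used = used,
                 prominence_frac = prominence_frac, p2p = p2p),
            class = "fiducial_set")
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat("<fiducial_set>\n")
  for (ev in FP_EVENTS) {
    cat(sprintf("  %s: %s\n", ev,
                if (isTRUE(x$found_flags[[ev]])) sprintf("%.1f ms (prominence %.3g)",
                                                         x$latencies[[ev]], x$prominences[[ev]])
                else "not found"))
  }
  invisible(x)
}

#' Classify an averaged waveform as traditional or non-traditional
#'
#' A waveform is traditional (T) when all four fiducial points were found
#' *and* their latencies are properly ordered `MC < AO < AC < MO`;
#' otherwise it is non-traditional (NT).  Per-point availability is passed
#' through so that partial fiducial sets remain usable for a subset of the
#' cardiac time intervals.  This is an explicit algorithmic surrogate for
#' the expert visual call that is standard in the field; provenance notes
#' record it.
#'
#' @param fps a `fiducial_set` from [detect_fiducials()].
#' @return a `waveform_class`: list with `label` ("T"/"NT"),
#'   `per_point_availability`, and `note`.
#' @export
classify_waveform <- function(fps) {
  stopifnot(inherits(fps, "fiducial_set"))
  avail <- fps$found_flags
  note <- "algorithmic surrogate for expert visual classification"
  label <- "NT"
  if (all(avail)) {
    if (all(diff(fps$latencies[FP_EVENTS]) > 0) && fps$latencies["MC"] > 0) {
      label <- "T"
    } else {
      note <- paste(note, "; ordering violation MC<AO<AC<MO", sep = "")
    }
  }
  structure(list(label = label, per_point_availability = avail, note = note),
            class = "waveform_class")
}

#' Compute cardiac time intervals from a fiducial set
#'
#' PEP (pre-ejection period) = Q-to-R interval + R-to-AO latency; IVCT
#' (isovolumic contraction time) = AO - MC; LVET (left-ventricular
#' ejection time) = AC - AO; IVRT (isovolumic relaxation time) = MO - AC.
#' Intervals with a missing endpoint are NA.
#'
#' @param fps a `fiducial_set`.
#' @param q_to_r time from the Q wave to the R peak in ms (>= 0); NA gives
#'   a missing PEP.
#' @return named numeric vector `c(PEP, IVCT, LVET, IVRT)` in ms.
#' @examples
#' \dontrun{compute_ctis(fps, q_to_r = 20)}
#' @export
compute_ctis <- function(fps, q_to_r = NA_real_) {
  stopifnot(inherits(fps, "fiducial_set"))
  if (is.finite(q_to_r) && q_to_r < 0) stopf("`q_to_r` must be >= 0 ms")
  l <- fps$latencies
  c(PEP  = unname(l["AO"] + q_to_r),
    IVCT = unname(l["AO"] - l["MC"]),
    LVET = unname(l["AC"] - l["AO"]),
    IVRT = unname(l["MO"] - l["AC"]))
}
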