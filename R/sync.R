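#' Align a sonogram RR sequence to the device RR series
#'
#' Exhaustively scans every admissible start index and scores each
#' placement by the mean absolute difference between the sonogram RR
#' intervals and the device RR intervals it would overlap.  The placement
#' of minimum cost wins (ties to the earliest index).  The match is
#' accepted only when the cost is at or below `tolerance` and the margin to
#' the second-best placement is at least `min_margin` -- a perfectly
#' regular device rhythm yields zero margin and is rejected as ambiguous.
#'
#' @param sono_rrs RR intervals read off the sonogram, ms (length >= 2).
#' @param device_rrs device RR series, ms (at least as long).
#' @param tolerance maximum acceptable cost in ms (default 15, comfortably
#'   above the 2.64 ms sonogram pixel pitch plus reading jitter).
#' @param min_margin minimum cost margin to the runner-up in ms.
#' @param search_center optional beat index around which to search (the
#'   rough event-button synchronization).
#' @param search_radius admissible deviation from `search_center`, beats.
#' @return an `alignment_result`: `start_index` (index into the device
#'   beat series of the first displayed beat), `cost`, `margin`
#'   (`Inf` when a single placement is admissible), `accepted`.
#' @examples
#' dev <- c(900, 950, 1000, 870, 920, 980)
#' align_rr_sequences(c(1000, 870, 920), dev)
#' @export
align_rr_sequences <- function(sono_rrs, device_rrs, tolerance = 15,
                               min_margin = 10, search_center = NULL,
                               search_radius = NULL) {
  m <- length(sono_rrs)
  n <- length(device_rrs)
  if (m < 2) stopf("`sono_rrs` must contain at least 2 intervals")
  if (n < m) stopf("device RR series (%d) shorter than the sonogram sequence (%d)", n, m)
  starts <- seq_len(n - m + 1L)
  if (!is.null(search_center)) {
    r <- if (is.null(search_radius)) Inf else search_radius
    starts <- starts[abs(starts - search_center) <= r]
    if (!length(starts)) stopf("no admissible start index within the search radius")
  }
  costs <- vapply(starts, function(s) {
    mean(abs(sono_rrs - device_rrs[s:(s + m - 1L)]))
  }, numeric(1))
  o <- order(costs)
  best <- o[1]
  cost <- costs[best]
  margin <- if (length(costs) > 1) costs[o[2]] - cost else Inf
  structure(list(start_index = starts[best], cost = cost, margin = margin,
                 accepted = cost <= tolerance && margin >= min_margin),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> start %d, cost %.2f ms, margin %s, %s\n",
              x$start_index, x$cost,
              if (is.finite(x$margin)) sprintf("%.2f ms", x$margin) else "inf",
              if (x$accepted) "accepted" else "REJECTED (ambiguous or poor match)"))
  invisible(x)
}

#' Map annotated event times onto the device timeline
#'
#' Beat `i` of the sonogram corresponds to device beat
#' `start_index + i - 1`; the event time from record start is that beat's
#' R time plus the annotated time-from-R.
#'
#' @param annotation an [echo_annotation()].
#' @param alignment an accepted `alignment_result`.
#' @param series the device `beat_series`.
#' @return numeric vector of global event times (ms from record start),
#'   one per annotated beat.
#' @export
map_annotation_times <- function(annotation, alignment, series) {
  stopifnot(inherits(annotation, "echo_annotation"),
            inherits(alignment, "alignment_result"),
            inherits(series, "beat_series"))
  if (!alignment$accepted) {
    stopf("alignment not accepted (cost %.2f ms, margin %s): refusing to map ambiguous timing",
          alignment$cost,
          if (is.finite(alignment$margin)) sprintf("%.2f ms", alignment$margin) else "inf")
  }
  k <- alignment$start_index + seq_along(annotation$event_times_from_r) - 1L
  if (max(k) > length(series$r_times)) {
    stopf("alignment maps beyond the end of the device beat series")
  }
  series$r_times[k] + annotation$event_times_from_r
}
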