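# shared helpers for building small fixtures in code

# beat series at exact sample positions (r_times in ms)
make_series <- function(r_times, fs, quality = NULL) {
  structure(list(
    r_times = r_times, rr = diff(r_times),
    quality = quality %||% rep("good", length(r_times)),
    q_times = NULL, sampling_rate = fs
  ), class = "beat_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# averaged-beat container from raw samples on a -100..600 ms axis
make_avg_beat <- function(samples, fs = 1000, window = c(-100, 600), mean_rr = 1000) {
  offs <- seq(round(window[1] / 1000 * fs), round(window[2] / 1000 * fs))
  stopifnot(length(samples) == length(offs))
  structure(list(time_ms = offs / fs * 1000, samples = samples,
                 n_beats_used = 1L, mean_rr = mean_rr, sampling_rate = fs),
            class = "scg_average_beat")
}

# a fiducial_set with given latencies, everything found
make_fps <- function(latencies) {
  found <- !is.na(latencies)
  structure(list(latencies = latencies,
                 prominences = ifelse(found, 1, NA_real_),
                 found_flags = found,
                 search_windows_used = list(),
                 prominence_frac = 0.1, p2p = 2),
            class = "fiducial_set")
}

# fast small traditional record for pipeline-level tests
quick_record <- function(seed, duration = 30, ...) {
  generate_record(synth_config(duration = duration, seed = seed, ...))
}
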