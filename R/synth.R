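#' Configuration for the synthetic ECG+SCG generator
#'
#' Bundles every knob of the synthetic two-channel record generator.  The
#' defaults emulate a bedside acquisition in a cardiac population: a 5-min
#' recording digitized at 200 Hz on a 14-bit converter, a mean RR interval
#' of 900 ms with moderate sinus variability, and an SCG beat built from
#' Gaussian-windowed cosine bumps placed at the valve-event latencies
#' (mitral closure MC, aortic opening AO, aortic closure AC, mitral
#' opening MO).
#'
#' @param sampling_rate acquisition rate in Hz (default 200).
#' @param duration record length in seconds (default 300, i.e. 5 min).
#' @param mean_rr mean sinus RR interval in ms.
#' @param rr_sd SD of the sinus RR intervals in ms; draws are truncated to
#'   `[0.5, 1.5] * mean_rr`.
#' @param ectopic_rate per-beat probability of an ectopic event.  An event
#'   replaces one sinus RR by a premature `0.6 * RR` interval followed by a
#'   compensatory `1.4 * RR` interval.
#' @param morphology `"traditional"` (all four fiducial bumps present) or
#'   `"non_traditional"` (one to three bumps suppressed plus in-band
#'   distortion noise).
#' @param fp_latencies named vector `c(MC=, AO=, AC=, MO=)` of bump centers
#'   in ms after the R peak.  Must be strictly increasing for traditional
#'   morphology.
#' @param fp_amplitudes named vector of bump amplitudes (arbitrary units).
#' @param fp_width_ms full width of the Gaussian bump envelope in ms
#'   (interpreted as two envelope SDs).
#' @param carrier_hz carrier frequency of the bump oscillation, inside the
#'   5--40 Hz analysis band.
#' @param noise_sd white measurement noise SD, as a fraction of the clean
#'   SCG peak-to-peak amplitude.
#' @param resp_mod_depth depth in `[0, 1)` of the sinusoidal respiratory
#'   amplitude modulation of the SCG.
#' @param resp_period respiratory period in seconds.
#' @param quantization_bits ADC resolution (default 14); `NULL` disables
#'   quantization.
#' @param nt_suppressed for non-traditional morphology, which fiducial
#'   bumps to suppress (subset of `c("MC","AO","AC","MO")`); `NULL` picks
#'   1--3 at random.
#' @param nt_noise_frac amplitude of the non-traditional 5--40 Hz
#'   distortion noise, as a fraction of the clean beat amplitude.
#' @param q_offset_ms Q-wave position in ms before the R peak.
#' @param seed integer seed making every generated record reproducible.
#'
#' @return an object of class `synth_config` (a validated list).
#' @examples
#' cfg <- synth_config(duration = 10, mean_rr = 1000, rr_sd = 0, seed = 1)
#' @export
synth_config <- function(sampling_rate = 200,
                         duration = 300,
                         mean_rr = 900,
                         rr_sd = 40,
                         ectopic_rate = 0,
                         morphology = c("traditional", "non_traditional"),
                         fp_latencies = c(MC = 30, AO = 80, AC = 380, MO = 460),
                         fp_amplitudes = c(MC = 0.8, AO = 1.0, AC = 0.7, MO = 0.5),
                         fp_width_ms = 20,
                         carrier_hz = 15,
                         noise_sd = 0.02,
                         resp_mod_depth = 0.2,
                         resp_period = 4,
                         quantization_bits = 14,
                         nt_suppressed = NULL,
                         nt_noise_frac = 0.5,
                         q_offset_ms = 20,
                         seed = NULL) {
  morphology <- match.arg(morphology)
  if (!is_scalar_number(mean_rr) || mean_rr <= 0) {
    stopf("`mean_rr` must be a positive finite number")
  }
  if (!is_scalar_number(rr_sd) || rr_sd < 0) stopf("`rr_sd` must be >= 0")
  if (!is_scalar_number(ectopic_rate) || ectopic_rate < 0 || ectopic_rate > 1) {
    stopf("`ectopic_rate` must lie in [0, 1]")
  }
  if (!is_scalar_number(sampling_rate) || sampling_rate <= 80) {
    stopf("`sampling_rate` must exceed 80 Hz (twice the 40 Hz analysis band)")
  }
  if (!is_scalar_number(duration) || duration < 3 * mean_rr / 1000) {
    stopf("`duration` must cover at least 3 beats (>= %.2f s)", 3 * mean_rr / 1000)
  }
  fp_latencies <- check_fp_names(fp_latencies, "fp_latencies")
  fp_amplitudes <- check_fp_names(fp_amplitudes, "fp_amplitudes")
  if (morphology == "traditional") {
    if (any(diff(fp_latencies) <= 0) || fp_latencies[1] <= 0) {
      stopf("traditional morphology requires 0 < MC < AO < AC < MO latencies")
    }
  }
  if (!is_scalar_number(resp_mod_depth) || resp_mod_depth < 0 || resp_mod_depth >= 1) {
    stopf("`resp_mod_depth` must lie in [0, 1)")
  }
  if (!is.null(nt_suppressed)) {
    if (!all(nt_suppressed %in% FP_EVENTS)) stopf("`nt_suppressed` must be a subset of MC, AO, AC, MO")
  }
  structure(list(
    sampling_rate = sampling_rate, duration = duration,
    mean_rr = mean_rr, rr_sd = rr_sd, ectopic_rate = ectopic_rate,
    morphology = morphology,
    fp_latencies = fp_latencies, fp_amplitudes = fp_amplitudes,
    fp_width_ms = fp_width_ms, carrier_hz = carrier_hz,
    noise_sd = noise_sd, resp_mod_depth = resp_mod_depth,
    resp_period = resp_period, quantization_bits = quantization_bits,
    nt_suppressed = nt_suppressed, nt_noise_frac = nt_noise_frac,
    q_offset_ms = q_offset_ms, seed = seed
  ), class = "synth_config")
}

# RR generation without seeding (callers wrap in with_seed so that
# generate_rr_series() and generate_record() share one stream).
rr_series_impl <- function(config) {
  total_ms <- config$duration * 1000
  cap <- 2L * as.integer(ceiling(total_ms / (0.5 * config$mean_rr))) + 4L
  rr <- numeric(cap)
  label <- character(cap)
  m <- 0L
  t <- 0
  while (t < total_ms) {
    v <- rnorm(1, config$mean_rr, config$rr_sd)
    while (v < 0.5 * config$mean_rr || v > 1.5 * config$mean_rr) {
      v <- rnorm(1, config$mean_rr, config$rr_sd)
    }
    if (runif(1) < config$ectopic_rate) {
      rr[m + 1:2] <- c(0.6 * v, 1.4 * v)
      label[m + 1:2] <- c("ectopic", "sinus")
      m <- m + 2L
      t <- t + 2 * v
    } else {
      m <- m + 1L
      rr[m] <- v
      label[m] <- "sinus"
      t <- t + v
    }
  }
  data.frame(rr_ms = rr[seq_len(m)], label = label[seq_len(m)],
             stringsAsFactors = FALSE)
}

#' Generate a synthetic RR-interval series
#'
#' Sinus intervals are drawn from a normal law truncated to
#' `[0.5, 1.5] * mean_rr`.  Each ectopic event replaces one interval with a
#' premature `0.6 * RR` interval followed by a compensatory `1.4 * RR`
#' interval; the beat terminating the premature interval is labelled
#' `"ectopic"`.
#'
#' @param config a [synth_config()].
#' @return data frame with columns `rr_ms` and `label` (`"sinus"` /
#'   `"ectopic"`, the label of the beat *terminating* each interval).
#' @examples
#' generate_rr_series(synth_config(duration = 5, mean_rr = 1000, rr_sd = 0))
#' @export
generate_rr_series <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, rr_series_impl(config))
}

gauss_bump <- function(t_ms, center_ms, sd_ms) {
  exp(-((t_ms - center_ms)^2) / (2 * sd_ms^2))
}

# Zero-mean Gaussian-windowed cosine (Morlet-style) bump with unit peak at
# the center.  The admissibility correction removes the envelope's DC /
# low-frequency mass, keeping the bump band-limited around the carrier so
# the 5-40 Hz analysis filter does not ring into neighbouring search
# windows.  Its unique global maximum sits exactly at center_ms.
scg_bump <- function(t_ms, center_ms, sd_ms, carrier_hz) {
  tau <- (t_ms - center_ms) / 1000
  kappa <- exp(-(2 * pi * carrier_hz * sd_ms / 1000)^2 / 2)
  (cos(2 * pi * carrier_hz * tau) - kappa) *
    gauss_bump(t_ms, center_ms, sd_ms) / (1 - kappa)
}

# One ECG complex added in place around each R time (all in ms).
ecg_template <- function(t_ms, r_ms, ectopic = FALSE, q_offset = 20) {
  if (ectopic) {
    # ventricular-style beat: no P, wider and slightly smaller QRS, no Q dip
    0.9 * gauss_bump(t_ms, r_ms, 12) -
      0.30 * gauss_bump(t_ms, r_ms + 40, 12) +
      0.25 * gauss_bump(t_ms, r_ms + 260, 50)
  } else {
    0.15 * gauss_bump(t_ms, r_ms - 160, 25) -
      0.15 * gauss_bump(t_ms, r_ms - q_offset, 5) +
      1.00 * gauss_bump(t_ms, r_ms, 7) -
      0.25 * gauss_bump(t_ms, r_ms + 30, 8) +
      0.35 * gauss_bump(t_ms, r_ms + 250, 45)
  }
}

#' Generate one synthetic two-channel record with ground truth
#'
#' The ECG channel carries one stylized PQRST complex per beat, with the R
#' wave as the unique per-beat maximum and the Q wave `q_offset_ms` before
#' R.  The SCG channel carries, per beat, a sum of Gaussian-windowed cosine
#' bumps centered at the configured fiducial latencies (traditional
#' morphology), or a version with one to three bumps suppressed plus
#' beat-to-beat 5--40 Hz distortion noise (non-traditional).  Respiratory
#' amplitude modulation, white measurement noise, and ADC quantization are
#' applied on top.
#'
#' @param config a [synth_config()].
#' @param patient_id identifier stored in the record.
#' @param metadata named list stored in the record (e.g. `diagnosis`,
#'   `ejection_fraction`).
#' @return list with elements `record` (a [signal_record()]) and `truth`
#'   (class `scg_ground_truth`: `r_times` ms, `q_offsets` ms-before-R,
#'   `valve_times` per-beat matrix, `beat_labels`, `true_class`,
#'   `suppressed` fiducials for non-traditional records).
#' @examples
#' rec <- generate_record(synth_config(duration = 10, seed = 1))
#' length(rec$truth$r_times)
#' @export
generate_record <- function(config, patient_id = "synthetic", metadata = list()) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    rrdf <- rr_series_impl(config)
    fs <- config$sampling_rate
    n <- round(config$duration * fs)
    t_ms <- (seq_len(n) - 1) / fs * 1000

    lead_ms <- 400
    r_times <- lead_ms + c(0, cumsum(rrdf$rr_ms))
    labels <- c("sinus", rrdf$label)          # beat k terminates interval k-1
    keep <- r_times <= (config$duration * 1000 - 100)
    r_times <- r_times[keep]
    labels <- labels[keep]
    if (length(r_times) < 3) stopf("duration too short: fewer than 3 beats fit the record")

    # index window of samples within [lo_ms, hi_ms] of a center time
    span_idx <- function(c_ms, lo_ms, hi_ms) {
      lo <- max(1L, as.integer(ceiling((c_ms + lo_ms) / 1000 * fs)) + 1L)
      hi <- min(n, as.integer(floor((c_ms + hi_ms) / 1000 * fs)) + 1L)
      if (hi < lo) integer(0) else lo:hi
    }
    ecg <- numeric(n)
    for (k in seq_along(r_times)) {
      # each complex is negligible beyond ~350 ms of its R peak
      idx <- span_idx(r_times[k], -350, 450)
      ecg[idx] <- ecg[idx] + ecg_template(t_ms[idx], r_times[k],
                                          ectopic = labels[k] == "ectopic",
                                          q_offset = config$q_offset_ms)
    }

    suppressed <- character(0)
    if (config$morphology == "non_traditional") {
      suppressed <- config$nt_suppressed
      if (is.null(suppressed)) {
        suppressed <- sample(FP_EVENTS, sample(1:3, 1))
      }
    }
    amps <- config$fp_amplitudes
    amps[suppressed] <- 0
    sd_ms <- config$fp_width_ms / 2
    scg <- numeric(n)
    for (k in seq_along(r_times)) {
      if (labels[k] != "sinus") next   # ectopic beats carry no organized SCG pattern
      for (ev in FP_EVENTS) {
        if (amps[ev] == 0) next
        c_ms <- r_times[k] + config$fp_latencies[ev]
        idx <- span_idx(c_ms, -5 * sd_ms, 5 * sd_ms)
        if (!length(idx)) next
        scg[idx] <- scg[idx] +
          amps[ev] * scg_bump(t_ms[idx], c_ms, sd_ms, config$carrier_hz)
      }
    }
    beat_amp <- max(abs(scg), max(config$fp_amplitudes))
    if (config$morphology == "non_traditional" && config$nt_noise_frac > 0) {
      wn <- rnorm(n)
      colored <- bandpass_filter(wn, fs, filter_spec(5, min(40, fs / 2 - 1), 3))
      colored <- colored / stats::sd(colored) * (config$nt_noise_frac * beat_amp / 2)
      scg <- scg + colored
    }

    # respiratory amplitude modulation, then additive white noise
    scg <- scg * (1 + config$resp_mod_depth * sin(2 * pi * t_ms / 1000 / config$resp_period))
    p2p <- diff(range(scg))
    if (config$noise_sd > 0 && p2p > 0) {
      scg <- scg + rnorm(n, 0, config$noise_sd * p2p)
    }

    ecg <- quantize_signal(ecg, config$quantization_bits)
    scg <- quantize_signal(scg, config$quantization_bits)

    valve_times <- matrix(NA_real_, nrow = length(r_times), ncol = 4,
                          dimnames = list(NULL, FP_EVENTS))
    for (ev in FP_EVENTS) {
      if (amps[ev] > 0) valve_times[labels == "sinus", ev] <- config$fp_latencies[ev]
    }
    truth <- structure(list(
      r_times = r_times,
      q_offsets = ifelse(labels == "sinus", config$q_offset_ms, NA_real_),
      valve_times = valve_times,
      beat_labels = labels,
      true_class = if (config$morphology == "traditional") "T" else "NT",
      suppressed = suppressed,
      config = config
    ), class = "scg_ground_truth")

    list(
      record = signal_record(ecg, scg, fs, patient_id = patient_id, metadata = metadata),
      truth = truth
    )
  })
}

#' Generate a sonogram-style annotation from ground truth
#'
#' Emulates an M-mode ultrasound still frame: a contiguous run of
#' `n_beats` sinus beats is selected, and both the displayed RR intervals
#' and the per-beat valve-event times from R are reported with optional
#' reading jitter and quantization to the sonogram pixel pitch.
#'
#' @param truth ground truth from [generate_record()].
#' @param event which valve event the image annotates (`"MC"`, `"AO"`,
#'   `"AC"`, `"MO"`).
#' @param n_beats number of beats displayed; must lie in `[3, 5]` unless
#'   `allow_any_n = TRUE`.
#' @param jitter_sd SD in ms of the Gaussian measurement jitter added to
#'   every reported time.
#' @param pixel_ms image resolution; all reported times are rounded to the
#'   nearest multiple (default 2.64 ms per pixel).
#' @param start_beat index of the first displayed beat; `NULL` picks a
#'   random eligible run.
#' @param image_id identifier for the image.
#' @param allow_any_n permit `n_beats` outside `[3, 5]`.
#' @param seed optional seed for the jitter / run choice.
#' @return an [echo_annotation()]; the true first-beat index is attached as
#'   attribute `"true_start"`.
#' @examples
#' rec <- generate_record(synth_config(duration = 10, seed = 1))
#' generate_echo_annotation(rec$truth, "AO", n_beats = 4, jitter_sd = 0)
#' @export
generate_echo_annotation <- function(truth, event = "AO", n_beats = 4,
                                     jitter_sd = 1, pixel_ms = 2.64,
                                     start_beat = NULL, image_id = "img1",
                                     allow_any_n = FALSE, seed = NULL) {
  stopifnot(inherits(truth, "scg_ground_truth"))
  event <- match.arg(event, FP_EVENTS)
  if (!allow_any_n && (n_beats < 3 || n_beats > 5)) {
    stopf("`n_beats` must lie in [3, 5] (got %d); a sonogram frame shows 3-5 beats", n_beats)
  }
  nb <- length(truth$r_times)
  sinus <- truth$beat_labels == "sinus" & !is.na(truth$valve_times[, event])
  # eligible starts: n_beats consecutive sinus beats with the event defined
  ok <- vapply(seq_len(nb - n_beats + 1),
               function(s) all(sinus[s:(s + n_beats - 1)]), logical(1))
  if (!any(ok)) stopf("ground truth has no run of %d consecutive sinus beats", n_beats)
  with_seed(seed, {
    start <- if (is.null(start_beat)) {
      cand <- which(ok)
      cand[sample.int(length(cand), 1)]
    } else {
      if (start_beat > length(ok) || !ok[start_beat]) {
        stopf("`start_beat` %d does not begin a run of %d sinus beats", start_beat, n_beats)
      }
      start_beat
    }
    beats <- start:(start + n_beats - 1)
    rr_true <- diff(truth$r_times)[start:(start + n_beats - 2)]
    ev_true <- truth$valve_times[beats, event]
    snap <- function(x) round((x + rnorm(length(x), 0, jitter_sd)) / pixel_ms) * pixel_ms
    ann <- echo_annotation(
      patient_id = "synthetic", event = event,
      rr_sequence = snap(rr_true),
      event_times_from_r = snap(ev_true),
      image_id = image_id
    )
    attr(ann, "true_start") <- start
    ann
  })
}

#' Generate a synthetic patient cohort
#'
#' Each patient is assigned a diagnosis group by the given mix, then a
#' traditional / non-traditional waveform class by an independent draw at
#' the group's prevalence.  Per-patient physiology (mean RR, fiducial
#' latencies and amplitudes, noise, respiration) is sampled within
#' realistic ranges; diastolic latencies scale with the RR interval.  An
#' ejection fraction is drawn per group (and missing for a small fraction
#' of patients, as typical of retrospective clinical records).
#'
#' @param n_patients number of patients (> 0).
#' @param group_mix named proportions over diagnosis groups, summing to 1.
#'   Defaults mirror a rehabilitation cohort of myocardial-infarction (MI),
#'   heart-failure (HF) and heart-transplant (TX) patients.
#' @param t_prevalence named per-group probability of a traditional
#'   waveform.
#' @param duration,sampling_rate record parameters passed to every patient.
#' @param ef_missing_rate probability that ejection fraction is unavailable.
#' @param seed cohort-level seed; per-patient seeds are derived from it.
#' @return list of per-patient lists `(record, truth, metadata)` where
#'   `metadata` holds `diagnosis`, `ejection_fraction` and `true_class`.
#' @examples
#' coh <- generate_cohort(3, duration = 10, seed = 1)
#' vapply(coh, function(p) p$metadata$diagnosis, "")
#' @export
generate_cohort <- function(n_patients,
                            group_mix = c(MI = 34 / 90, HF = 49 / 90, TX = 7 / 90),
                            t_prevalence = c(MI = 26 / 34, HF = 27 / 49, TX = 3 / 7),
                            duration = 300, sampling_rate = 200,
                            ef_missing_rate = 5 / 90, seed = NULL) {
  if (!is_scalar_number(n_patients) || n_patients <= 0) {
    stopf("`n_patients` must be a positive number")
  }
  if (any(group_mix < 0)) stopf("`group_mix` proportions must be non-negative")
  if (abs(sum(group_mix) - 1) > 1e-8) stopf("`group_mix` proportions must sum to 1")
  if (any(t_prevalence < 0 | t_prevalence > 1)) stopf("`t_prevalence` values must lie in [0, 1]")
  if (!all(names(group_mix) %in% names(t_prevalence))) {
    stopf("`t_prevalence` must name every group in `group_mix`")
  }
  ef_params <- list(MI = c(43, 8), HF = c(30, 7), TX = c(57, 6))
  with_seed(seed, {
    groups <- sample(names(group_mix), n_patients, replace = TRUE, prob = group_mix)
    seeds <- sample.int(.Machine$integer.max - 1L, n_patients)
    lapply(seq_len(n_patients), function(i) {
      g <- groups[i]
      is_t <- runif(1) < t_prevalence[g]
      mean_rr <- runif(1, 750, 1100)
      rrf <- mean_rr / 1000
      mc <- runif(1, 20, 42)
      ao <- runif(1, max(mc + 25, 60), 110)
      # diastolic events scale with RR; MO sits beyond the scaled AC search
      # window so each search window contains exactly one true event
      ac <- rrf * runif(1, 400, 430)
      mo <- ac + runif(1, 60, min(120, 585 - ac))
      ef <- if (runif(1) < ef_missing_rate) NA_real_ else {
        p <- ef_params[[if (g %in% names(ef_params)) g else "HF"]]
        min(70, max(15, rnorm(1, p[1], p[2])))
      }
      cfg <- synth_config(
        sampling_rate = sampling_rate, duration = duration,
        mean_rr = mean_rr, rr_sd = runif(1, 20, 60),
        ectopic_rate = if (runif(1) < 4 / 90) 0.2 else 0.005,
        morphology = if (is_t) "traditional" else "non_traditional",
        fp_latencies = c(MC = mc, AO = ao, AC = ac, MO = mo),
        fp_amplitudes = c(MC = runif(1, 0.6, 1.2), AO = runif(1, 0.6, 1.2),
                          AC = runif(1, 0.6, 1.2), MO = runif(1, 0.6, 1.2)),
        noise_sd = runif(1, 0.01, 0.08),
        resp_mod_depth = runif(1, 0.1, 0.3),
        resp_period = runif(1, 3, 5),
        seed = seeds[i]
      )
      pid <- sprintf("S%03d", i)
      out <- generate_record(cfg, patient_id = pid,
                             metadata = list(diagnosis = g, ejection_fraction = ef))
      out$metadata <- list(patient_id = pid, diagnosis = g,
                           ejection_fraction = ef,
                           true_class = out$truth$true_class)
      out
    })
  })
}
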