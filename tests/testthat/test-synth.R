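test_that("RR series honours the zero-variance and forced-ectopy cases", {
  cfg <- synth_config(duration = 5, mean_rr = 1000, rr_sd = 0, seed = 1)
  rr <- generate_rr_series(cfg)
  expect_equal(rr$rr_ms, rep(1000, 5))
  expect_true(all(rr$label == "sinus"))

  cfg <- synth_config(duration = 10, mean_rr = 1000, rr_sd = 0,
                      ectopic_rate = 1, seed = 1)
  rr <- generate_rr_series(cfg)
  expect_equal(rr$rr_ms, rep(c(600, 1400), length.out = nrow(rr)))
  expect_equal(rr$label, rep(c("ectopic", "sinus"), length.out = nrow(rr)))
})

test_that("sinus RR intervals follow the configured law of large numbers", {
  cfg <- synth_config(duration = 8000, mean_rr = 800, rr_sd = 40, seed = 7)
  rr <- generate_rr_series(cfg)
  expect_gt(nrow(rr), 9000)
  expect_lt(abs(mean(rr$rr_ms) - 800), 3 * 40 / sqrt(nrow(rr)))
  expect_true(all(rr$rr_ms >= 0.5 * 800 & rr$rr_ms <= 1.5 * 800))
})

test_that("invalid generator parameters are rejected", {
  expect_error(synth_config(mean_rr = -5), "mean_rr")
  expect_error(synth_config(mean_rr = Inf), "mean_rr")
  expect_error(synth_config(ectopic_rate = 1.5), "ectopic_rate")
  expect_error(synth_config(duration = 1, mean_rr = 1000), "3 beats")
  expect_error(synth_config(fp_latencies = c(MC = 80, AO = 30, AC = 380, MO = 460)),
               "MC < AO")
  expect_error(synth_config(sampling_rate = 50), "sampling_rate")
})

test_that("noise-free traditional records place SCG extrema at the valve latencies", {
  lat <- c(MC = 30, AO = 80, AC = 380, MO = 460)
  cfg <- synth_config(duration = 10, mean_rr = 1000, rr_sd = 10,
                      noise_sd = 0, resp_mod_depth = 0,
                      fp_latencies = lat, seed = 3)
  out <- generate_record(cfg)
  rec <- out$record
  fs <- rec$sampling_rate
  dt <- 1000 / fs
  for (k in 2:5) {
    r <- out$truth$r_times[k]
    for (ev in names(lat)) {
      c_ms <- r + lat[[ev]]
      idx <- round((c_ms + c(-20, 20)) / dt)
      seg <- rec$scg[idx[1]:idx[2]]
      peak_ms <- (idx[1] + which.max(seg) - 2) * dt
      # quantized 14-bit signal: extremum within one sample of the center
      expect_lt(abs(peak_ms - c_ms), dt + 1e-9)
    }
  }
  # R is the unique per-beat ECG maximum
  for (k in 2:5) {
    r <- out$truth$r_times[k]
    idx <- round((r + c(-300, 300)) / dt)
    seg <- rec$ecg[idx[1]:idx[2]]
    peak_ms <- (idx[1] + which.max(seg) - 2) * dt
    expect_lt(abs(peak_ms - r), dt + 1e-9)
  }
})

test_that("quantization limits the number of distinct sample values", {
  out <- generate_record(synth_config(duration = 20, seed = 5,
                                      quantization_bits = 14))
  expect_lte(length(unique(out$record$scg)), 2^14)
  expect_lte(length(unique(out$record$ecg)), 2^14)
  out8 <- generate_record(synth_config(duration = 20, seed = 5,
                                       quantization_bits = 8))
  expect_lte(length(unique(out8$record$scg)), 2^8)
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- synth_config(duration = 15, ectopic_rate = 0.05, seed = 99)
  a <- generate_record(cfg)
  b <- generate_record(cfg)
  expect_identical(a$record$ecg, b$record$ecg)
  expect_identical(a$record$scg, b$record$scg)
  expect_identical(a$truth$r_times, b$truth$r_times)
  c1 <- generate_cohort(4, duration = 10, seed = 17)
  c2 <- generate_cohort(4, duration = 10, seed = 17)
  expect_identical(c1[[3]]$record$scg, c2[[3]]$record$scg)
  expect_identical(lapply(c1, `[[`, "metadata"), lapply(c2, `[[`, "metadata"))
})

test_that("echo annotations quantize to the sonogram pixel pitch", {
  out <- generate_record(synth_config(duration = 10, mean_rr = 1000, rr_sd = 0,
                                      seed = 2))
  ann <- generate_echo_annotation(out$truth, "AO", n_beats = 4, jitter_sd = 0,
                                  pixel_ms = 2.64, start_beat = 2)
  # true AO = 80 ms -> 30 pixels -> 79.2 ms
  expect_equal(ann$event_times_from_r, rep(79.2, 4))
  expect_equal(length(ann$rr_sequence), 3)
  expect_equal(ann$rr_sequence, rep(round(1000 / 2.64) * 2.64, 3))

  fine <- generate_echo_annotation(out$truth, "AO", n_beats = 4, jitter_sd = 0,
                                   pixel_ms = 1e-9, start_beat = 2)
  expect_equal(fine$event_times_from_r, rep(80, 4), tolerance = 1e-6)

  expect_error(generate_echo_annotation(out$truth, "AO", n_beats = 6), "\\[3, 5\\]")
  expect_silent(generate_echo_annotation(out$truth, "AO", n_beats = 6,
                                         allow_any_n = TRUE, start_beat = 2))
})

test_that("cohort generation respects the group mix and prevalence contracts", {
  expect_error(generate_cohort(0), "n_patients")
  expect_error(generate_cohort(5, group_mix = c(MI = 0.5, HF = 0.2, TX = 0.2)),
               "sum to 1")
  expect_error(generate_cohort(5, group_mix = c(MI = 0.7, HF = 0.7, TX = -0.4)),
               "non-negative")

  coh <- generate_cohort(10, t_prevalence = c(MI = 1, HF = 1, TX = 1),
                         duration = 10, seed = 4)
  expect_true(all(vapply(coh, function(p) p$truth$true_class, "") == "T"))

  # realized traditional count behaves binomially around the configured mix
  coh <- generate_cohort(90, duration = 10, seed = 21)
  n_t <- sum(vapply(coh, function(p) p$truth$true_class, "") == "T")
  p_t <- sum(c(34, 49, 7) / 90 * c(26 / 34, 27 / 49, 3 / 7))
  expect_gte(n_t, qbinom(0.005, 90, p_t))
  expect_lte(n_t, qbinom(0.995, 90, p_t))
  groups <- vapply(coh, function(p) p$metadata$diagnosis, "")
  expect_true(all(groups %in% c("MI", "HF", "TX")))
})

test_that("non-traditional records suppress the configured fiducial bumps", {
  cfg <- synth_config(duration = 10, morphology = "non_traditional",
                      nt_suppressed = c("AO", "AC"), nt_noise_frac = 0,
                      noise_sd = 0, resp_mod_depth = 0, seed = 6)
  out <- generate_record(cfg)
  expect_identical(out$truth$true_class, "NT")
  expect_setequal(out$truth$suppressed, c("AO", "AC"))
  expect_true(all(is.na(out$truth$valve_times[, "AO"])))
  sinus <- out$truth$beat_labels == "sinus"
  expect_true(all(is.finite(out$truth$valve_times[sinus, "MC"])))
})
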