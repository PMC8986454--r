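test_that("R peaks are recovered exactly on clean synthetic ECG", {
  out <- generate_record(synth_config(duration = 30, noise_sd = 0, seed = 8))
  rec <- out$record
  bs <- detect_r_peaks(rec$ecg, rec$sampling_rate)
  expect_equal(length(bs$r_times), length(out$truth$r_times))
  dt <- 1000 / rec$sampling_rate
  expect_true(all(abs(bs$r_times - out$truth$r_times) <= dt + 1e-9))
})

test_that("flat or empty signals yield empty beat series, not errors", {
  bs <- detect_r_peaks(rep(0, 1000), 200)
  expect_equal(length(bs$r_times), 0)
  expect_error(detect_r_peaks(rep(0, 100), 200), "at least 2 s")
})

test_that("R detection stays above 99% sensitivity and precision in noise", {
  out <- generate_record(synth_config(duration = 280, mean_rr = 900,
                                      noise_sd = 0, seed = 12))
  truth <- out$truth$r_times
  expect_gte(length(truth), 300)
  noisy <- withr::with_seed(13, out$record$ecg + rnorm(length(out$record$ecg), 0, 0.10))
  bs <- detect_r_peaks(noisy, out$record$sampling_rate)
  # match detections to truth within 50 ms
  hits <- vapply(truth, function(r) any(abs(bs$r_times - r) < 50), logical(1))
  sens <- mean(hits)
  prec <- mean(vapply(bs$r_times, function(d) any(abs(truth - d) < 50), logical(1)))
  expect_gte(sens, 0.99)
  expect_gte(prec, 0.99)
})

test_that("Q points are found at the configured offset before R", {
  out <- generate_record(synth_config(duration = 20, noise_sd = 0, seed = 9))
  ecg <- resample_signal(out$record$ecg, 200, 1000)
  bs <- detect_r_peaks(ecg, 1000)
  q <- detect_q_points(ecg, bs$r_times, 1000)
  off <- bs$r_times - q$q_time_ms
  expect_true(all(abs(off - 20) <= 2, na.rm = TRUE))
  expect_true(any(is.finite(off)))
})

test_that("Q handling covers truncated windows and monotone segments", {
  # first R at 30 ms: the 60 ms search window precedes the record start
  ecg <- exp(-((0:999) - 30)^2 / 50) + exp(-((0:999) - 500)^2 / 50) -
    0.3 * exp(-((0:999) - 480)^2 / 8)
  q <- detect_q_points(ecg, c(30, 500), 1000)
  expect_true(is.na(q$q_time_ms[1]))
  expect_false(is.na(q$q_time_ms[2]))

  mono <- seq(0, 1, length.out = 1000)
  qm <- detect_q_points(mono, 500, 1000)
  expect_true(qm$low_confidence[1])
})

test_that("beat quality flags track ectopy and noise bursts", {
  series <- make_series(seq(0, 9000, by = 1000), 200)
  flagged <- flag_beat_quality(series, rnorm(2001), window_ms = c(-100, 600))
  expect_true(all(flagged$quality == "good"))

  out <- generate_record(synth_config(duration = 240, ectopic_rate = 0.1, seed = 15))
  bs <- detect_r_peaks(out$record$ecg, 200)
  bs <- flag_beat_quality(bs, bandpass_filter(out$record$scg, 200))
  truth_lab <- ifelse(out$truth$beat_labels == "ectopic", "ectopic", "good")
  n <- min(length(bs$quality), length(truth_lab))
  flag_ect <- bs$quality[seq_len(n)] == "ectopic"
  true_ect <- truth_lab[seq_len(n)] == "ectopic"
  expect_gte(mean(flag_ect == true_ect), 0.95)
  expect_gt(sum(true_ect), 10)  # the record really contains ectopy

  # a 10x noise burst on one beat flags it noisy
  fs <- 200
  scg <- rep(sin(2 * pi * 15 * (0:(10 * fs - 1)) / fs) * 0.1, 1)
  r_times <- seq(500, 9500, by = 1000)
  burst <- round((r_times[4] + 50) / 1000 * fs):round((r_times[4] + 250) / 1000 * fs)
  scg[burst] <- scg[burst] + withr::with_seed(2, rnorm(length(burst), 0, 1))
  series <- make_series(r_times, fs)
  flagged <- flag_beat_quality(series, scg)
  expect_equal(flagged$quality[4], "noisy")
  expect_true(all(flagged$quality[-4] == "good"))
})

test_that("window selection takes the longest good run or falls back to one beat", {
  s <- make_series(seq(0, 9000, by = 1000), 200)
  w <- select_window(s)
  expect_equal(w$indices, 1:10)
  expect_false(w$single_beat)

  # two eligible runs: the longer one wins even when it comes later
  two <- make_series(seq(0, 16000, by = 1000), 200,
                     quality = c(rep("good", 6), "ectopic", rep("good", 9), "noisy"))
  w2 <- select_window(two)
  expect_equal(w2$indices, 8:16)

  alt <- make_series(seq(0, 9000, by = 1000), 200,
                     quality = rep(c("good", "ectopic"), 5))
  w <- select_window(alt)
  expect_true(w$single_beat)
  expect_length(w$indices, 1)
  expect_equal(alt$quality[w$indices], "good")

  bad <- make_series(seq(0, 9000, by = 1000), 200, quality = rep("noisy", 10))
  expect_error(select_window(bad), "no usable beats")
})

test_that("ensemble averaging reproduces identical beats and is order-invariant", {
  fs <- 1000
  template <- sin(2 * pi * 15 * seq(-0.1, 0.6, by = 1 / fs)) *
    exp(-((seq(-0.1, 0.6, by = 1 / fs)) - 0.1)^2 / 0.01)
  n_b <- 8
  scg <- numeric(n_b * 1000 + 2000)
  r_times <- (seq_len(n_b) - 1) * 1000 + 500
  for (r in r_times) {
    idx <- round(r * fs / 1000) + seq(-100, 600) + 1
    scg[idx] <- scg[idx] + template
  }
  series <- make_series(r_times, fs)
  avg <- ensemble_average(scg, series)
  expect_equal(avg$n_beats_used, n_b)
  expect_equal(avg$samples, template, tolerance = 1e-12)
  expect_true(0 %in% avg$time_ms)

  perm <- ensemble_average(scg, series, indices = sample(seq_len(n_b)))
  expect_equal(perm$samples, avg$samples)

  one <- ensemble_average(scg, series, indices = 3)
  expect_equal(one$samples, template, tolerance = 1e-12)
  expect_equal(one$n_beats_used, 1)
})

test_that("averaging K noisy beats reduces noise by about sqrt(K)", {
  withr::with_seed(31, {
    fs <- 1000
    sigma <- 0.3
    K <- 6
    scg <- numeric(K * 1000 + 2000)
    r_times <- (seq_len(K) - 1) * 1000 + 500
    for (r in r_times) {
      idx <- round(r * fs / 1000) + seq(-100, 600) + 1
      scg[idx] <- scg[idx] + rnorm(701, 0, sigma)
    }
    series <- make_series(r_times, fs)
    avg <- ensemble_average(scg, series)
    resid_sd <- sd(avg$samples[1:500])
    expect_lt(abs(resid_sd - sigma / sqrt(K)), 0.25 * sigma / sqrt(K))
  })
})

test_that("averaging excludes truncated segments per sample", {
  fs <- 1000
  scg <- rep(1, 3000)
  # first beat's window starts before the record: its leading samples drop out
  series <- make_series(c(50, 1050, 2050), fs)
  avg <- ensemble_average(scg, series, indices = 1:3)
  expect_true(all(is.finite(avg$samples)))
  expect_equal(unique(avg$samples), 1)
  expect_error(ensemble_average(rep(1, 100), make_series(5000, fs), indices = 1),
               "outside the record")
})
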