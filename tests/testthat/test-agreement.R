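test_that("patient differences average repeated measures with the stated sign", {
  expect_equal(patient_differences(list(AO = c(78, 82)), c(AO = 90)), c(AO = -10))
  expect_equal(unname(patient_differences(list(MC = 30), c(MC = 30))), 0)
  # events without measures or without a detected fiducial are absent
  d <- patient_differences(list(AO = c(80), AC = numeric(0)),
                           c(AO = 85, AC = NA, MO = 400))
  expect_named(d, "AO")
})

test_that("group statistics match a two-pass oracle on the packaged differences", {
  d <- echo_fp_differences()
  gs <- group_stats(d)
  for (ev in c("MC", "AO", "AC", "MO")) {
    x <- d[[ev]]
    m <- sum(x) / length(x)
    s <- sqrt(sum((x - m)^2) / (length(x) - 1))
    expect_equal(gs$mean[gs$event == ev], m, tolerance = 1e-9)
    expect_equal(gs$sd[gs$event == ev], s, tolerance = 1e-9)
    expect_equal(gs$n[gs$event == ev], 20)
  }
  same <- data.frame(MC = rep(5, 4))
  gs0 <- group_stats(same)
  expect_equal(gs0$sd, 0)
  expect_error(group_stats(data.frame(MC = 1)), "at least 2")
})

test_that("reference ranges come in exact and printed modes", {
  expect_equal(reference_range("MC"), c(4 - 1.96 * 11, 4 + 1.96 * 11))
  expect_equal(reference_range("MC", "printed"), c(-18, 26))
  expect_equal(reference_range("MO", "printed"), c(-44, 30))
  degen <- reference_range("MC", stats = data.frame(event = "MC", mean_ms = 5,
                                                    sd_ms = 0, n = 10))
  expect_equal(unname(degen[1]), unname(degen[2]))
  expect_true(isTRUE(attr(degen, "degenerate")))
})

test_that("within-range counting is inclusive at both bounds", {
  d <- echo_fp_differences()
  expect_equal(count_within_range(d$MC, c(-18, 26)), 10)
  # AO holds the boundary case: -25 sits exactly on the printed bound
  expect_equal(count_within_range(d$AO, c(-25, 19)), 18)
  expect_equal(count_within_range(d$AO, c(-25, 19), inclusive = FALSE), 17)
  expect_equal(count_within_range(numeric(0), c(-1, 1)), 0)
  # partition property: within + outside = n
  for (ev in c("MC", "AO", "AC", "MO")) {
    rng <- reference_range(ev, "printed")
    inside <- count_within_range(d[[ev]], rng)
    outside <- sum(d[[ev]] < rng[1] | d[[ev]] > rng[2])
    expect_equal(inside + outside, length(d[[ev]]))
  }
})

test_that("the Welch test reproduces the known significance pattern", {
  gs <- group_stats(echo_fp_differences())
  href <- healthy_reference()
  p <- vapply(c("MC", "AO", "AC", "MO"), function(ev) {
    g <- gs[gs$event == ev, ]
    h <- href[href$event == ev, ]
    welch_test(g$mean, g$sd, g$n, h$mean_ms, h$sd_ms, h$n)$p.value
  }, numeric(1))
  expect_lt(p[["MC"]], 0.05)
  expect_gt(p[["AO"]], 0.05)
  expect_gt(p[["AC"]], 0.05)
  expect_gt(p[["MO"]], 0.05)

  eq <- welch_test(5, 2, 10, 5, 2, 10)
  expect_equal(unname(eq$statistic), 0)
  expect_equal(eq$p.value, 1)
  # invariance under group swap
  a <- welch_test(-17.1, 26.2, 20, 4, 11, 41)
  b <- welch_test(4, 11, 41, -17.1, 26.2, 20)
  expect_equal(a$p.value, b$p.value)
  expect_error(welch_test(1, 2, 1, 0, 2, 10), "n >= 2")
})

test_that("the F test flags wider dispersion for every valve event", {
  gs <- group_stats(echo_fp_differences())
  href <- healthy_reference()
  for (ev in c("MC", "AO", "AC", "MO")) {
    g <- gs[gs$event == ev, ]
    h <- href[href$event == ev, ]
    res <- f_test_variances(g$sd, g$n, h$sd_ms, h$n)
    expect_lt(res$p.value, 0.05)
    swap <- f_test_variances(h$sd_ms, h$n, g$sd, g$n)
    expect_equal(res$p.value, swap$p.value)
    expect_gte(unname(res$statistic), 1)
  }
  eq <- f_test_variances(3, 10, 3, 15)
  expect_equal(unname(eq$statistic), 1)
  expect_equal(eq$p.value, 1)
})

test_that("the G test matches its closed form and handles degenerate tables", {
  res <- g_test_independence(matrix(c(26, 8, 27, 22), 2, byrow = TRUE))
  expect_lt(res$p.value, 0.05)
  # closed-form oracle
  tab <- matrix(c(26, 8, 27, 22), 2, byrow = TRUE)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(unname(res$statistic), 2 * sum(tab * log(tab / e)), tolerance = 1e-12)

  prop <- matrix(c(10, 20, 5, 10), 2, byrow = TRUE)  # identical row proportions
  expect_equal(unname(g_test_independence(prop)$statistic), 0, tolerance = 1e-12)
  expect_equal(g_test_independence(prop)$p.value, 1)
  expect_equal(unname(g_test_independence(matrix(10, 2, 2))$statistic), 0)

  expect_error(g_test_independence(matrix(c(0, 0, 1, 2), 2)), "marginal")
  expect_error(g_test_independence(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
  w <- g_test_independence(tab, correction = "williams")
  expect_lt(unname(w$statistic), unname(res$statistic))
})

test_that("prevalence tables stratify with exact internal fractions", {
  coh <- study_cohort()
  by_dx <- prevalence_table(coh, by = "diagnosis", levels = c("MI", "HF", "TX"))
  expect_equal(by_dx$n_patients, c(34, 49, 7))
  expect_equal(by_dx$n_traditional, c(26, 27, 3))
  expect_equal(by_dx$prevalence_pct, c(76, 55, 43))
  expect_equal(by_dx$prevalence, c(26 / 34, 27 / 49, 3 / 7))

  by_ef <- prevalence_table(coh, by = "ef_band",
                            levels = c(">50%", "40-50%", "<40%", "unavailable"))
  expect_equal(by_ef$n_patients[1:3], c(13, 21, 52))
  expect_equal(by_ef$n_traditional[1:3], c(8, 14, 31))

  empty <- prevalence_table(coh[0, ], by = "diagnosis")
  expect_equal(nrow(empty), 0)
})
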