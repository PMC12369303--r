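test_that("spike metrics follow the reciprocal-ISI definitions", {
  m <- spike_metrics(c(1.0, 1.1, 1.2, 1.3), c(0, 2))
  expect_identical(m$count, 4L)
  expect_equal(m$mean_if, 10)
  expect_equal(m$peak_if, 10)

  m2 <- spike_metrics(c(0, 0.5, 0.6), c(-0.1, 1))
  expect_equal(m2$mean_if, mean(c(2, 10)))
  expect_equal(m2$peak_if, 10)

  # the minimum-two-spikes rule: frequencies undefined below two spikes
  m1 <- spike_metrics(0.7, c(0, 2))
  expect_identical(m1$count, 1L)
  expect_true(is.na(m1$mean_if) && is.na(m1$peak_if))

  # the alternative span definition stays available
  ms <- spike_metrics(c(0, 0.5, 0.6), c(0, 1), method = "span")
  expect_equal(ms$mean_if, 2 / 0.6)

  expect_error(spike_metrics(c(1, 2), c(2, 1)), "t0 < t1")
})

test_that("regular trains give mean_if = peak_if = 1/delta exactly", {
  for (delta in c(0.02, 0.1, 0.25)) {
    tt <- seq(0.5, 2.5, by = delta)
    m <- spike_metrics(tt, c(0, 3))
    expect_equal(m$mean_if, 1 / delta, tolerance = 1e-12)
    expect_equal(m$peak_if, 1 / delta, tolerance = 1e-12)
  }
})

test_that("mean reciprocal ISI dominates the span rate (Jensen)", {
  withr::with_seed(42, {
    for (i in 1:25) {
      tt <- cumsum(stats::rexp(sample(3:30, 1), rate = 20))
      m <- spike_metrics(tt, range(tt) + c(-1, 1) * 1e-9)
      span_rate <- (m$count - 1) / (max(tt) - min(tt))
      expect_gte(m$mean_if, span_rate - 1e-9)
    }
  })
})

test_that("conduction velocity is distance over latency with guards", {
  expect_equal(conduction_velocity(0.060, 0.055), 0.060 / 0.055)
  expect_equal(conduction_velocity(0.35, 0.010), 35)
  expect_error(conduction_velocity(0.35, 0), "positive")
  expect_error(conduction_velocity(-1, 0.01), "positive")
})

test_that("fibre classification follows polarity plus velocity/delay", {
  expect_identical(classify_fibre("down", 1.09), "C")
  expect_identical(classify_fibre("up", 34.9), "A_beta")
  expect_identical(classify_fibre("up", 10), "other")
  expect_identical(classify_fibre("down", NA, response_delay = 0.3), "C")
  expect_identical(classify_fibre("down", NA, response_delay = 0.01), "other")
  expect_error(classify_fibre("down"), "provide")
})

test_that("the 50%-criterion threshold rule matches hand-worked cases", {
  r <- estimate_mech_threshold(tibble::tibble(
    force = c(4, 4, 0.7, 0.7, 0.4, 0.4, 0.4, 0.2, 0.2),
    response = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)))
  expect_equal(r$threshold, 0.4)
  expect_identical(r$confidence, "confirmed")

  none <- estimate_mech_threshold(tibble::tibble(
    force = c(4, 4, 0.7), response = c(FALSE, FALSE, FALSE)))
  expect_false(none$responsive)
  expect_true(is.na(none$threshold))

  single <- estimate_mech_threshold(tibble::tibble(force = 0.4,
                                                   response = TRUE))
  expect_equal(single$threshold, 0.4)
  expect_identical(single$confidence, "low")

  expect_error(estimate_mech_threshold(tibble::tibble(force = 0.5,
                                                      response = TRUE)),
               "standard monofilament")
  expect_error(estimate_mech_threshold(tibble::tibble()), "non-empty")
  # named-list interface
  r2 <- estimate_mech_threshold(list(`4` = c(TRUE, TRUE),
                                     `0.7` = c(FALSE, FALSE)))
  expect_equal(r2$threshold, 4)
})

test_that("unit classification requires the CT and HFA criteria", {
  ct <- list(fibre_class = "C", mech_threshold = 0.4, adaptation = "unknown",
             brush_responsive = TRUE)
  expect_identical(classify_unit(ct, FALSE), "CT")
  hfa <- list(fibre_class = "A_beta", mech_threshold = 4, adaptation = "RA",
              brush_responsive = TRUE)
  expect_identical(classify_unit(hfa, TRUE), "HFA")
  sa <- list(fibre_class = "A_beta", mech_threshold = 4, adaptation = "SA",
             brush_responsive = TRUE)
  expect_identical(classify_unit(sa, TRUE), "other")
  high <- list(fibre_class = "C", mech_threshold = 10, adaptation = "unknown",
               brush_responsive = TRUE)
  expect_identical(classify_unit(high, TRUE), "other")
  expect_error(classify_unit(list(fibre_class = "C"), TRUE), "missing")
  # pure function: identical inputs, identical outputs
  expect_identical(classify_unit(ct, FALSE), classify_unit(ct, FALSE))
})

test_that("the gap rule terminates the after-discharge scan", {
  # stray spike beyond the gap excluded; duration runs to the last spike
  # of the discharge itself
  ad <- detect_after_discharge(c(seq(0.1, 2.0, by = 0.1), 30), 0,
                               gap_rule = 2)
  expect_equal(ad$duration, 2.0)
  expect_identical(ad$count, 20L)

  none <- detect_after_discharge(c(0.2, 0.4), 1.0, gap_rule = 2)
  expect_equal(none$duration, 0)
  expect_true(is.na(none$mean_if))

  # the scan starts at stimulus end: a lone late spike is not a discharge
  late <- detect_after_discharge(5, 0, gap_rule = 2)
  expect_equal(late$duration, 0)
})

test_that("spike detection recovers ground truth at SNR 8", {
  eps <- stimulus_epochs("brush", 0.5, 2.5)
  tr <- gen_neural_trace(ct_unit_spec(), eps, noise_sd = 5, seed = 12,
                         amplitude = 40)
  st <- detect_spikes(tr)
  truth <- tr$truth$spike_times
  expect_identical(length(st$times), length(truth))
  expect_lt(max(abs(st$times - truth)), 0.5e-3)
})

test_that("pure noise yields no detections at five noise SDs", {
  tr <- gen_neural_trace(ct_unit_spec(), NULL, noise_sd = 5, seed = 3,
                         duration = 2)
  st <- detect_spikes(tr, threshold = 25)
  expect_length(st$times, 0)
})

test_that("template matching rejects non-spike artefacts", {
  eps <- stimulus_epochs("brush", 0.5, 2.5)
  tr <- gen_neural_trace(ct_unit_spec(), eps, noise_sd = 0, seed = 9)
  # inject a square pulse (correlation with the biphasic template is low)
  i0 <- round(2.8 * tr$sampling_rate)
  tr$samples[i0:(i0 + 50)] <- 60
  st <- detect_spikes(tr)
  expect_identical(length(st$times), length(tr$truth$spike_times))
  cand <- attr(st, "candidates")
  expect_true(any(!cand$matched))
  expect_false(any(abs(st$times - 2.8) < 0.005))
})

test_that("detection is near-perfect on noiseless traces across seeds", {
  eps <- stimulus_epochs("hair_deflection", 0.5, 2.5)
  hits <- 0; total <- 0; detected <- 0
  for (s in 1:8) {
    tr <- gen_neural_trace(ct_unit_spec(), eps, noise_sd = 0, seed = s)
    st <- detect_spikes(tr)
    truth <- tr$truth$spike_times
    total <- total + length(truth)
    detected <- detected + length(st$times)
    hits <- hits + sum(vapply(st$times, function(t)
      any(abs(truth - t) < 0.5e-3), logical(1)))
  }
  expect_gte(hits / total, 0.99)        # recall
  expect_gte(hits / detected, 0.99)     # precision
})

test_that("detected after-discharge duration tracks the drawn truth", {
  pl <- simulate_pluck_trials(120, seed = 8)
  expect_gt(stats::cor(pl$true_duration, pl$detected_duration), 0.99)
  expect_lt(mean(abs(pl$detected_duration - pl$true_duration)), 0.2)
})

test_that("staircase threshold estimates recover the true threshold", {
  th <- simulate_threshold_units(60, seed = 4)
  expect_gt(mean(th$est_threshold == th$true_threshold, na.rm = TRUE), 0.9)
})
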