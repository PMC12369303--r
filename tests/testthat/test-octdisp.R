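test_that("surface segmentation is exact on noiseless trials", {
  p <- oct_protocol()
  flat <- gen_oct_trial(p, "idle", seed = 1, displacement = 0, noise_sd = 0)
  trk <- segment_surface(flat)
  expect_true(all(trk$valid))
  expect_lt(diff(range(trk$depth)), 1e-9)

  step <- gen_oct_trial(p, "mono_4.0", seed = 1, displacement = 60.93,
                        noise_sd = 0)
  trk2 <- segment_surface(step)
  # the tracked step equals the rendered step outside the smoothing window
  expect_equal(max(trk2$depth) - min(trk2$depth), 60.93, tolerance = 1e-9)
})

test_that("occluded A-lines are flagged invalid", {
  p <- small_oct_protocol()
  tri <- gen_oct_trial(p, "mono_0.4", seed = 2, noise_sd = 0,
                       artefact = "beam_crossing")
  trk <- segment_surface(tri)
  occ <- tri$truth$occlusion
  tt <- (seq_along(trk$valid) - 0.5) / trk$aline_rate
  inside <- tt > occ[1] + 0.01 & tt < occ[2] - 0.01
  expect_true(all(!trk$valid[inside]))
  expect_true(mean(!trk$valid) > 0.05)
})

test_that("event detection finds steps to within a millisecond", {
  p <- oct_protocol()
  mono <- gen_oct_trial(p, "mono_0.4", seed = 1, displacement = 17.09,
                        noise_sd = 0)
  trk <- segment_surface(mono)
  expect_lt(abs(detect_event(trk, "contact") - 1.5), 1e-3)

  hair <- gen_oct_trial(p, "hair_release", seed = 1, displacement = 8.14,
                        noise_sd = 0)
  expect_lt(abs(detect_event(segment_surface(hair), "release") - 1.5), 1e-3)

  idle <- gen_oct_trial(p, "idle", seed = 1, displacement = 0, noise_sd = 0)
  expect_error(detect_event(segment_surface(idle), "contact"),
               class = "cthair_no_event")

  # two steps: the larger one wins
  n <- 3 * 2000
  d <- rep(300, n)
  d[(1.0 * 2000):n] <- 310
  d[(2.0 * 2000):n] <- 340
  expect_equal(detect_event(make_track(d), "contact"), 2.0,
               tolerance = 2e-3)
})

test_that("windowed displacement is exact for arbitrary noiseless steps", {
  p <- oct_protocol()
  withr::with_seed(31, {
    for (i in 1:5) {
      amp <- stats::runif(1, 1, 90)
      tri <- gen_oct_trial(p, "mono_0.7", seed = i, displacement = amp,
                           noise_sd = 0)
      trk <- segment_surface(tri)
      ev <- detect_event(trk, "contact")
      expect_lt(abs(displacement_windows(trk, ev) - amp), 0.01)
    }
  })
})

test_that("displacement is invariant to a constant depth offset", {
  n <- 3 * 2000
  d <- rep(300, n); d[3001:n] <- 317.09
  t1 <- make_track(d); t2 <- make_track(d + 123.4)
  expect_equal(displacement_windows(t1, 1.5),
               displacement_windows(t2, 1.5), tolerance = 1e-12)
  expect_equal(displacement_idle(t1), displacement_idle(t2),
               tolerance = 1e-12)
})

test_that("window guards and validity rules raise errors", {
  n <- 3 * 2000
  trk <- make_track(rep(300, n))
  expect_error(displacement_windows(trk, 0.1), "outside")
  trk$valid[2600:3400] <- FALSE
  expect_error(displacement_windows(trk, 1.5), "50%")
  short <- make_track(rep(300, 1500))
  expect_error(displacement_idle(short), "insufficient")
})

test_that("noisy steps are recovered to sub-tenth-micron accuracy", {
  # with 1 um per-A-line track noise at 10 kHz, each 200 ms window mean
  # has SE 1/sqrt(2000), so the combined displacement SE is ~0.032 um
  fs <- 10000; n <- 3 * fs
  d0 <- rep(300, n); d0[(1.5 * fs + 1):n] <- 300 + 60.93
  err <- vapply(1:5, function(s) {
    withr::with_seed(s, d <- d0 + stats::rnorm(n, 0, 1))
    displacement_windows(make_track(d, fs), 1.5) - 60.93
  }, numeric(1))
  expect_lt(max(abs(err)), 3 * sqrt(2) / sqrt(2000))

  # full image pipeline: intensity noise, segmentation, event detection
  p <- oct_protocol()
  est <- vapply(1:3, function(s) {
    tri <- gen_oct_trial(p, "mono_4.0", seed = s, displacement = 60.93)
    trk <- segment_surface(tri)
    displacement_windows(trk, detect_event(trk, "contact"))
  }, numeric(1))
  expect_lt(max(abs(est - 60.93)), 0.1)
})

test_that("idle windows follow closed forms for drift and sinusoids", {
  fs <- 2000; n <- 3 * fs
  tt <- (seq_len(n) - 0.5) / fs
  drift <- make_track(300 + 4.08 * tt, fs)
  expect_equal(displacement_idle(drift), 2.04, tolerance = 1e-9)

  amp <- 5; f <- 1.2
  hb <- make_track(300 + amp * sin(2 * pi * f * tt), fs)
  # closed-form difference of consecutive 500 ms window means
  wmean <- function(t0) -amp / (2 * pi * f * 0.5) *
    (cos(2 * pi * f * (t0 + 0.5)) - cos(2 * pi * f * t0))
  expected <- abs(wmean(0.5) - wmean(0))
  expect_equal(displacement_idle(hb), expected, tolerance = 1e-3)
  expect_lt(displacement_idle(hb), amp)
})

test_that("artefact screening rejects the injected artefact trials", {
  p <- small_oct_protocol(artefact_fraction = 0)
  clean <- purrr::map(1:6, function(i)
    segment_surface(gen_oct_trial(p, "mono_0.7", seed = i)))
  r0 <- reject_trials(clean)
  expect_equal(r0$fraction, 0)

  occ <- segment_surface(gen_oct_trial(p, "mono_0.7", seed = 1,
                                       artefact = "beam_crossing"))
  hb <- segment_surface(gen_oct_trial(p, "mono_0.7", seed = 2,
                                      artefact = "heartbeat"))
  mo <- segment_surface(gen_oct_trial(p, "idle", seed = 3,
                                      artefact = "motion"))
  r <- reject_trials(list(occ, hb, mo))
  expect_identical(r$log$reason, c("beam-crossing", "heartbeat", "motion"))
  expect_equal(r$fraction, 1)
})

test_that("top-k selection keeps the largest displacements deterministically", {
  withr::with_seed(2, {
    m <- tibble::tibble(condition = "mono_4.0",
                        displacement = sample(seq(1, 45)),
                        loc_row = rep(1:9, 5), loc_col = rep(1:5, 9),
                        replicate = 1:45)
  })
  top <- select_top(m, k = 10)
  expect_equal(sort(top$displacement), 36:45, ignore_attr = TRUE)
  expect_gte(min(top$displacement),
             max(setdiff(m$displacement, top$displacement)))

  expect_warning(out <- select_top(m[1:8, ], k = 10), "fewer than")
  expect_identical(nrow(out), 8L)

  # deterministic tie-break at the k-th value
  mt <- tibble::tibble(condition = "c", displacement = rep(c(5, 1), c(12, 4)),
                       loc_row = 1:16, loc_col = 1, replicate = 1)
  t1 <- select_top(mt, 10); t2 <- select_top(mt, 10)
  expect_identical(t1, t2)
  expect_identical(t1$loc_row, 1:10)
  expect_error(select_top(mt[0, ]), "no displacement")
})

test_that("condition comparison flags separated groups and guards input", {
  withr::with_seed(5, {
    cmp <- compare_conditions(list(a = c(1, 1, 1) + stats::rnorm(3, 0, 1e-3),
                                   b = c(100, 100, 100) + stats::rnorm(3, 0, 1e-3)))
  })
  expect_true(all(cmp$pairwise$significant))
  expect_true(all(cmp$pairwise$p_adj >= 0 & cmp$pairwise$p_adj <= 1))
  expect_true(all(cmp$summary$ci_lwr <= cmp$summary$mean &
                    cmp$summary$mean <= cmp$summary$ci_upr))
  expect_error(compare_conditions(list(a = c(1, 2))), "at least 2 conditions")
  expect_error(compare_conditions(list(a = 1, b = 2)), "at least 2 values")
  expect_error(compare_conditions(list(a = c(1, 1, 1), b = c(2, 2, 2))),
               class = "cthair_degenerate_variance")
  gl <- glance(cmp)
  expect_identical(gl$n_conditions, 2L)
  td <- tidy(cmp)
  expect_identical(nrow(td), 1L)
})

test_that("Tukey adjusted p agrees with a max-t permutation oracle", {
  withr::with_seed(77, {
    values <- c(stats::rnorm(3, 0), stats::rnorm(3, 1.5), stats::rnorm(3, 0.5))
  })
  groups <- rep(c("a", "b", "c"), each = 3)
  cmp <- compare_conditions(tibble::tibble(condition = groups,
                                           displacement = values))
  perm <- tukey_perm_oracle(values, groups, n_perm = 4000, seed = 3)
  tuk <- cmp$pairwise$p_adj
  names(tuk) <- cmp$pairwise$contrast
  for (k in names(perm)) {
    k_rev <- paste(rev(strsplit(k, "-")[[1]]), collapse = "-")
    p_t <- if (k %in% names(tuk)) tuk[[k]] else tuk[[k_rev]]
    expect_lt(abs(p_t - perm[[k]]), 0.15)
  }
})
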