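test_that("epoch validation enforces ordering, overlap and force rules", {
  expect_error(stimulus_epochs("brush", 2, 1), "t_start < t_end")
  expect_error(stimulus_epochs("monofilament", 0, 1), "force > 0")
  expect_error(
    stimulus_epochs(c("brush", "brush"), c(0, 1), c(2, 3)), "overlap")
  ep <- stimulus_epochs("monofilament", 0, 0.5, force = 4)
  expect_equal(ep$force, 4)
})

test_that("unit specs enforce conduction-velocity ranges by fibre class", {
  expect_error(unit_spec("C", conduction_velocity = 5), "< 2")
  expect_error(unit_spec("A_beta", conduction_velocity = 10), "> 30")
  expect_identical(ct_unit_spec()$polarity, "down")
  expect_identical(hfa_unit_spec()$polarity, "up")
})

test_that("noiseless traces reproduce their own ground truth exactly", {
  eps <- stimulus_epochs("brush", 0.5, 2.5)
  tr <- gen_neural_trace(ct_unit_spec(), eps, noise_sd = 0, seed = 7)
  st <- detect_spikes(tr)
  expect_identical(length(st$times), length(tr$truth$spike_times))
  expect_equal(st$times, tr$truth$spike_times, tolerance = 1e-12)
  # C spikes lead downward
  expect_identical(st$polarity, "down")
  # a-beta template leads upward
  trb <- gen_neural_trace(hfa_unit_spec(), eps, noise_sd = 0, seed = 7)
  expect_gt(max(trb$samples), abs(min(trb$samples)) - 1e-9)
})

test_that("traces are seed-reproducible and noise_sd is validated", {
  eps <- stimulus_epochs("brush", 0.5, 1.5)
  a <- gen_neural_trace(ct_unit_spec(), eps, noise_sd = 4, seed = 3)
  b <- gen_neural_trace(ct_unit_spec(), eps, noise_sd = 4, seed = 3)
  expect_identical(a$samples, b$samples)
  expect_error(gen_neural_trace(ct_unit_spec(), eps, noise_sd = -1),
               "non-negative")
  # empty epoch list: idle-only trace is allowed
  idle <- gen_neural_trace(ct_unit_spec(), NULL, noise_sd = 2, seed = 1)
  expect_length(idle$truth$spike_times, 0)
})

test_that("A-beta units produce no spikes after a pluck epoch ends", {
  eps <- stimulus_epochs("pluck", 0.5, 1.5)
  for (s in 1:5) {
    tr <- gen_neural_trace(hfa_unit_spec(), eps, noise_sd = 0, seed = s)
    expect_true(all(tr$truth$spike_times <= 1.5 + 0.003))
  }
})

test_that("after-discharge durations match the configured distribution", {
  # empirical mean of drawn durations within 3 SEM of the configured mean
  # of the truncated-normal draw (truncation slightly raises it)
  pl <- simulate_pluck_trials(600, seed = 5)
  trunc_mean <- 7.1 + 3.2 * stats::dnorm(-7.1 / 3.2) /
    (1 - stats::pnorm(-7.1 / 3.2))
  sem <- 3.2 / sqrt(600)
  expect_lt(abs(mean(pl$true_duration) - trunc_mean), 3 * sem)
})

test_that("the default OCT protocol lays out 45 trials per condition", {
  plan <- oct_trial_plan(oct_protocol(), seed = 1)
  expect_identical(nrow(plan), 270L)
  expect_true(all(table(plan$condition) == 45))
  # artefact tagging hits the configured fraction exactly in count
  expect_equal(sum(plan$artefact != "none"), round(0.23 * 270))
})

test_that("gen_oct_protocol generates one trial per plan row", {
  p <- oct_protocol(grid_dim = c(1, 1), trials_per_location = 1,
                    aline_rate = 500, n_depth = 60, artefact_fraction = 0)
  trials <- gen_oct_protocol(p, seed = 2)
  expect_length(trials, length(p$conditions))
  expect_setequal(vapply(trials, function(t) t$condition, character(1)),
                  p$conditions)
})

test_that("different seeds change noise but not ground-truth displacement", {
  p <- small_oct_protocol(artefact_fraction = 0)
  a <- gen_oct_trial(p, "mono_0.7", c(2, 1), 2, seed = 1)
  b <- gen_oct_trial(p, "mono_0.7", c(2, 1), 2, seed = 99)
  expect_identical(a$truth$displacement, b$truth$displacement)
  expect_false(identical(a$intensity, b$intensity))
  # same seed: bit-identical
  a2 <- gen_oct_trial(p, "mono_0.7", c(2, 1), 2, seed = 1)
  expect_identical(a$intensity, a2$intensity)
})

test_that("noiseless OCT trials reproduce the specified surface profile", {
  p <- oct_protocol()
  idle <- gen_oct_trial(p, "idle", seed = 1, displacement = 0, noise_sd = 0)
  trk <- segment_surface(idle)
  expect_lt(diff(range(trk$depth)), 1e-9)
  mono <- gen_oct_trial(p, "mono_4.0", seed = 1, displacement = 60.93,
                        noise_sd = 0)
  s <- mono$truth$surface
  expect_equal(max(s) - min(s), 60.93, tolerance = 1e-12)
  expect_error(gen_oct_trial(p, "not_a_condition", seed = 1),
               "unknown condition")
})

test_that("tip scenarios derive per-frame steps from the calibration", {
  sc <- tip_scenario(speed = 0.8, fps = 60, calibration = 465)
  step <- sqrt(sum(diff(sc$trajectory[1:2, ])^2))
  expect_equal(step, 0.8 * 465 / 60, tolerance = 1e-12)
  expect_error(tip_scenario(trajectory = cbind(x = c(1, 500), y = c(5, 5))),
               "exits")
})

test_that("stationary tip videos are identical frames up to noise", {
  sc <- tip_scenario(trajectory = cbind(x = rep(60, 4), y = rep(60, 4)),
                     frame_size = c(120, 160))
  vid <- gen_tip_video(sc, seed = 2, noise_sd = 0)
  expect_identical(vid$frames[[1]], vid$frames[[4]])
  vid_n <- gen_tip_video(sc, seed = 2, noise_sd = 0.02)
  expect_false(identical(vid_n$frames[[1]], vid_n$frames[[2]]))
  expect_lt(max(abs(vid_n$frames[[1]] - vid_n$frames[[2]])), 0.25)
})

test_that("serialisation round-trips traces, trials and frame stacks", {
  eps <- stimulus_epochs("brush", 0.2, 0.8)
  tr <- gen_neural_trace(ct_unit_spec(), eps, noise_sd = 2, seed = 5,
                         duration = 1)
  pre <- file.path(withr::local_tempdir(), "trace")
  write_neural_trace(tr, pre)
  tr2 <- read_neural_trace(pre)
  expect_equal(tr2$samples, tr$samples)
  expect_equal(tr2$truth$spike_times, tr$truth$spike_times)
  expect_equal(tr2$epochs$kind, tr$epochs$kind)

  p <- small_oct_protocol()
  trial <- gen_oct_trial(p, "mono_0.4", seed = 3)
  pre2 <- file.path(withr::local_tempdir(), "oct")
  write_oct_mmode(trial, pre2)
  trial2 <- read_oct_mmode(pre2)
  expect_equal(dim(trial2$intensity), dim(trial$intensity))
  expect_equal(trial2$truth$displacement, trial$truth$displacement)
  expect_lt(max(abs(trial2$intensity -
                      pmin(pmax(trial$intensity, 0), 1))), 1e-6)

  sc <- tip_scenario(n_frames = 3, frame_size = c(60, 90),
                     start = c(20, 30))
  vid <- gen_tip_video(sc, seed = 1)
  pre3 <- file.path(withr::local_tempdir(), "vid")
  write_frame_stack(vid, pre3)
  vid2 <- read_frame_stack(pre3)
  expect_length(vid2$frames, 3)
  expect_lt(max(abs(vid2$frames[[2]] - vid$frames[[2]])), 1e-4)
  expect_equal(vid2$truth$x, vid$truth$x)
})
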