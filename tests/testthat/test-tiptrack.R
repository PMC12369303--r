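# analytic wedge polygon (closed, ordered) used by the locate_tip tests
wedge_polygon <- function(apex = c(60, 40), angle_deg = 20, len = 40,
                          pts_per_edge = 20) {
  h <- angle_deg / 2 * pi / 180
  t_in <- seq(len, len / pts_per_edge, length.out = pts_per_edge)
  upper <- cbind(apex[1] - t_in * cos(h), apex[2] - t_in * sin(h))
  t_out <- rev(t_in)
  lower <- cbind(apex[1] - t_out * cos(h), apex[2] + t_out * sin(h))
  # base sampled at the same ~2 px spacing as the edges
  step <- len / pts_per_edge
  ys <- seq(apex[2] + len * sin(h) - step, apex[2] - len * sin(h) + step,
            by = -step)
  base <- cbind(rep(apex[1] - len * cos(h), length(ys)), ys)
  rbind(upper, matrix(apex, 1), lower, base)
}

test_that("instrument segmentation isolates the dark wedge", {
  sc <- tip_scenario(trajectory = cbind(x = rep(120, 2), y = rep(60, 2)),
                     frame_size = c(120, 180))
  vid <- gen_tip_video(sc, seed = 2, noise_sd = 0)
  fr <- vid$frames[[1]]
  mask <- segment_instrument(fr)
  truth <- fr < 0.45
  iou <- sum(mask & truth) / sum(mask | truth)
  expect_gt(iou, 0.9)

  expect_error(segment_instrument(matrix(0.5, 50, 50)),
               class = "cthair_no_instrument")

  # two dark blobs: the larger is retained
  f2 <- matrix(0.8, 60, 60)
  f2[5:10, 5:10] <- 0.1
  f2[30:55, 30:55] <- 0.1
  m2 <- segment_instrument(f2)
  expect_false(m2[7, 7])
  expect_true(m2[40, 40])
})

test_that("morphological refinement removes salt noise and holes", {
  mask <- matrix(FALSE, 60, 60)
  mask[20:40, 15:45] <- TRUE
  noisy <- mask
  noisy[5, 5] <- TRUE                     # 1 px salt (separate component)
  noisy[30, 30] <- FALSE                  # small hole
  out <- refine_mask(noisy, 1, 2)
  expect_false(out[5, 5])
  expect_true(out[30, 30])

  # open-close filtering is idempotent
  once <- refine_mask(noisy, 2, 2)
  twice <- refine_mask(once, 2, 2)
  expect_identical(once, twice)
})

test_that("contour extraction simplifies to polygon corners", {
  mask <- matrix(FALSE, 50, 50)
  mask[10:40, 12:38] <- TRUE
  ctr <- extract_contour(mask, tolerance = 1)
  expect_lte(nrow(ctr), 6)
  expect_gte(nrow(ctr), 4)
  # corners present
  corners <- rbind(c(12, 10), c(38, 10), c(12, 40), c(38, 40))
  for (k in seq_len(4)) {
    d <- sqrt((ctr[, 1] - corners[k, 1])^2 + (ctr[, 2] - corners[k, 2])^2)
    expect_lte(min(d), 1.5)
  }
  # tolerance zero keeps every boundary pixel
  ctr0 <- extract_contour(mask, tolerance = 0)
  expect_gte(nrow(ctr0), 2 * (31 + 27) - 4)
  expect_error(extract_contour(matrix(FALSE, 5, 5)), "empty mask")
})

test_that("tip localisation picks the apex and honours the search radius", {
  poly <- wedge_polygon(apex = c(60, 40), angle_deg = 20)
  tip <- locate_tip(poly, span = 3)
  expect_lt(sqrt(sum((tip - c(60, 40))^2)), 1.01)

  # uniform curvature (circle): tie-break by proximity to the previous tip
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  circ <- cbind(50 + 20 * cos(th), 50 + 20 * sin(th))
  prev <- c(72, 50)
  tip_c <- locate_tip(circ, prev_tip = prev, search_radius = 1e9)
  d_all <- sqrt((circ[, 1] - prev[1])^2 + (circ[, 2] - prev[2])^2)
  expect_equal(sqrt(sum((tip_c - prev)^2)), min(d_all), tolerance = 1e-9)

  # search radius excludes the sharper apex: the in-radius base corner wins
  near_corner <- c(60 - 40 * cos(10 * pi / 180), 40 + 40 * sin(10 * pi / 180))
  tip_near <- locate_tip(poly, prev_tip = near_corner, search_radius = 8)
  expect_lt(sqrt(sum((tip_near - near_corner)^2)), 1e-6)

  expect_error(locate_tip(poly, prev_tip = c(500, 500), search_radius = 5),
               class = "cthair_tracking_lost")
  expect_error(locate_tip(poly[1:3, ]), "at least 5")

  # with an unbounded radius the constrained result equals the free one
  free <- locate_tip(poly)
  constrained <- locate_tip(poly, prev_tip = c(60, 40), search_radius = 1e9)
  expect_equal(free, constrained)
})

test_that("tip speed converts steps through fps and calibration", {
  n <- 40
  pos <- tibble::tibble(x = 10 + (seq_len(n) - 1) * 6.2, y = rep(5, n))
  tj <- tip_speed(pos, fps = 60, calibration = 465, gaussian_sigma = 5)
  expect_equal(tj$mean_speed, 6.2 * 60 / 465, tolerance = 1e-9)
  sm <- tj$data$smoothed_speed[-1]
  expect_lt(diff(range(sm)), 1e-9)  # constant stays constant

  still <- tip_speed(tibble::tibble(x = rep(3, 5), y = rep(4, 5)))
  expect_equal(still$mean_speed, 0)
  expect_error(tip_speed(tibble::tibble(x = 1, y = 1)), "at least 2")
})

test_that("Gaussian smoothing preserves the mean and step midpoints", {
  withr::with_seed(11, raw <- stats::runif(80, 0.2, 1.4))
  pos_x <- cumsum(c(10, raw))
  tj <- tip_speed(tibble::tibble(x = pos_x, y = 0), fps = 60,
                  calibration = 465, gaussian_sigma = 5)
  sm <- tj$data$smoothed_speed[-1]; rw <- tj$data$raw_speed[-1]
  expect_lt(abs(mean(sm) - mean(rw)) / mean(rw), 0.02)

  # step-change speed profile crosses its midpoint at the change frame
  step_speed <- rep(c(2, 6), each = 30)
  smoothed <- cthair:::smooth_gaussian(step_speed, 5)
  expect_equal(smoothed[30], 4, tolerance = 0.15)
  expect_equal(smoothed[31], 4, tolerance = 0.15)
})

test_that("end-to-end tip tracking recovers position and speed", {
  vid <- gen_tip_video(tip_scenario(), seed = 13)
  pos <- track_tip(vid)
  err <- sqrt((pos$x - vid$truth$x)^2 + (pos$y - vid$truth$y)^2)
  expect_lte(max(err), 2)
  tj <- tip_speed(pos, fps = 60, calibration = 465, gaussian_sigma = 5)
  expect_lt(abs(tj$mean_speed - 0.8) / 0.8, 0.05)
  expect_false(any(pos$reseeded))
})
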