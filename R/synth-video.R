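#' Define a tip-video scenario
#'
#' Either supply a per-frame trajectory or let a constant-velocity one be
#' built from `speed` (cm/s), the frame rate and the pixel calibration:
#' the per-frame step is `speed * calibration / fps` px (6.2 px/frame at
#' 0.8 cm/s, 465 px/cm and 60 fps).
#'
#' @param trajectory Optional n x 2 matrix or tibble of per-frame (x, y)
#'   apex positions in px.
#' @param speed Constant speed in cm/s used when `trajectory` is `NULL`.
#' @param n_frames Number of frames when building a trajectory.
#' @param fps Frames per second.
#' @param calibration px/cm.
#' @param frame_size (rows, cols) in px.
#' @param start Starting apex (x, y) in px.
#' @param direction Unit-free motion direction (dx, dy); normalised.
#' @return A `tip_scenario` object.
#' @export
tip_scenario <- function(trajectory = NULL, speed = 0.8, n_frames = 30,
                         fps = 60, calibration = 465,
                         frame_size = c(160, 260),
                         start = c(30, 80), direction = c(1, 0.15)) {
  if (calibration <= 0) abort("calibration must be > 0")
  if (is.null(trajectory)) {
    step <- speed * calibration / fps
    dirn <- direction / sqrt(sum(direction^2))
    k <- seq_len(n_frames) - 1
    trajectory <- cbind(x = start[1] + k * step * dirn[1],
                        y = start[2] + k * step * dirn[2])
  } else {
    trajectory <- as.matrix(trajectory)[, 1:2, drop = FALSE]
    colnames(trajectory) <- c("x", "y")
  }
  margin <- 5
  if (any(trajectory[, 1] < margin) ||
      any(trajectory[, 1] > frame_size[2] - margin) ||
      any(trajectory[, 2] < margin) ||
      any(trajectory[, 2] > frame_size[1] - margin)) {
    abort("trajectory exits the frame bounds")
  }
  structure(
    list(trajectory = trajectory, fps = fps, calibration = calibration,
         frame_size = frame_size, speed = speed),
    class = "tip_scenario"
  )
}

# smooth light background texture: coarse noise bilinearly upsampled
background_texture <- function(nr, nc, base = 0.78, amplitude = 0.1,
                               grain = 10) {
  coarse <- matrix(stats::rnorm(ceiling(nr / grain + 2) *
                                  ceiling(nc / grain + 2)),
                   ceiling(nr / grain + 2), ceiling(nc / grain + 2))
  tex <- resize_bilinear(coarse, nr, nc)
  tex <- tex / max(abs(tex), 1e-9)
  pmin(pmax(base + amplitude * tex, 0), 1)
}

# render an anti-aliased dark wedge with apex at (ax, ay), axis pointing
# from the apex towards `axis_deg` (degrees), half-angle `half_deg`
render_wedge <- function(bg, ax, ay, axis_deg = 187, half_deg = 12,
                         dark = 0.08) {
  nr <- nrow(bg); nc <- ncol(bg)
  xg <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - ax
  yg <- matrix(seq_len(nr), nr, nc) - ay
  th <- axis_deg * pi / 180
  ux <- cos(th); uy <- sin(th)
  # signed distances to the two wedge edges (positive inside)
  h <- half_deg * pi / 180
  n1x <- -sin(th - h); n1y <- cos(th - h)
  n2x <- sin(th + h); n2y <- -cos(th + h)
  d1 <- xg * n1x + yg * n1y
  d2 <- xg * n2x + yg * n2y
  along <- xg * ux + yg * uy
  # per-pixel coverage approximation from the limiting edge distance
  dmin <- pmin(d1, d2, along + 0.5)
  cov <- pmin(pmax(dmin + 0.5, 0), 1)
  bg * (1 - cov) + dark * cov
}

#' Generate a synthetic instrument-tip video
#'
#' Renders a lightly textured skin-like background with a dark elongated
#' wedge whose anti-aliased apex follows the scenario trajectory, the
#' wedge body extending out of frame so the instrument always touches the
#' border. Optionally adds a dark hair strand. Per-frame ground truth is
#' retained.
#'
#' @param scenario A [tip_scenario()].
#' @param seed Integer seed (background texture and per-frame noise).
#' @param noise_sd Per-frame additive noise SD (intensity units).
#' @param apex_angle Full wedge apex angle in degrees.
#' @param axis_deg Wedge axis direction in degrees (from apex into the
#'   body).
#' @param hair Add a static dark hair strand.
#' @return A `frame_stack`: list of grayscale matrices, `fps`,
#'   `calibration` and `truth` (the trajectory tibble).
#' @export
gen_tip_video <- function(scenario, seed = 1, noise_sd = 0.01,
                          apex_angle = 40, axis_deg = 187, hair = FALSE) {
  nr <- scenario$frame_size[1]; nc <- scenario$frame_size[2]
  withr::with_seed(seed, {
    bg <- background_texture(nr, nc)
    if (hair) {
      xs <- seq_len(nc)
      yc <- nr * 0.55 + 8 * sin(xs / 40)
      for (j in xs) {
        rows <- round(yc[j]) + (-1:1)
        rows <- rows[rows >= 1 & rows <= nr]
        bg[rows, j] <- pmin(bg[rows, j], 0.25)
      }
    }
    frames <- purrr::map(seq_len(nrow(scenario$trajectory)), function(i) {
      fr <- render_wedge(bg, scenario$trajectory[i, 1],
                         scenario$trajectory[i, 2],
                         axis_deg = axis_deg, half_deg = apex_angle / 2)
      if (noise_sd > 0) {
        fr <- fr + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
      }
      pmin(pmax(fr, 0), 1)
    })
    structure(
      list(frames = frames, fps = scenario$fps,
           calibration = scenario$calibration,
           truth = tibble(frame = seq_len(nrow(scenario$trajectory)),
                          x = scenario$trajectory[, 1],
                          y = scenario$trajectory[, 2]),
           seed = seed),
      class = "frame_stack"
    )
  })
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("<frame_stack> %d frames of %d x %d px @ %g fps\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              x$fps))
  invisible(x)
}
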