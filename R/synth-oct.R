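#' Define an OCT M-mode stimulation protocol
#'
#' The default protocol reproduces the study design: six conditions (idle,
#' hair release and four monofilament forces), a 3 x 3 grid of locations
#' over 2 x 2 mm with five trials per location (45 trials per condition),
#' a 10 kHz A-line rate over 3 s, and ~5.5 um depth resolution. The
#' per-condition true surface displacements default to the reported group
#' means and the per-trial spread to the SDs implied by their 95%
#' confidence intervals; 23% of trials carry an injected artefact.
#'
#' @param conditions Character vector of condition labels.
#' @param grid_dim Location grid dimensions (rows, cols).
#' @param trials_per_location Replicates per (condition, location).
#' @param aline_rate A-line rate in Hz.
#' @param duration Recording length in s.
#' @param depth_resolution Depth sampling in um per sample.
#' @param n_depth Number of depth samples per A-line.
#' @param surface_depth Resting skin surface depth in um.
#' @param true_displacement Named vector, um per condition; for the idle
#'   condition this is the drift-induced difference between consecutive
#'   500 ms window means.
#' @param trial_sd Named vector, um: SD of the per-trial true displacement.
#' @param artefact_fraction Proportion of trials given an injected artefact.
#' @param noise_sd Additive intensity noise SD (0-1 scale).
#' @param event_time Monofilament contact / hair release time in s.
#' @param hold Monofilament indentation hold in s.
#' @return An `oct_protocol` object.
#' @export
oct_protocol <- function(conditions = c("idle", "hair_release", "mono_0.4",
                                        "mono_0.7", "mono_4.0", "mono_6.0"),
                         grid_dim = c(3, 3), trials_per_location = 5,
                         aline_rate = 10000, duration = 3,
                         depth_resolution = 5.5, n_depth = 120,
                         surface_depth = 330,
                         true_displacement = c(idle = 2.04,
                                               hair_release = 8.14,
                                               mono_0.4 = 17.09,
                                               mono_0.7 = 25.28,
                                               mono_4.0 = 60.93,
                                               mono_6.0 = 79.18),
                         trial_sd = c(idle = 1.59, hair_release = 3.72,
                                      mono_0.4 = 4.83, mono_0.7 = 6.05,
                                      mono_4.0 = 6.35, mono_6.0 = 10.46),
                         artefact_fraction = 0.23, noise_sd = 0.06,
                         event_time = 1.5, hold = 0.5) {
  if (aline_rate <= 0 || duration <= 0 || depth_resolution <= 0) {
    abort("aline_rate, duration and depth_resolution must be positive")
  }
  missing_td <- setdiff(conditions, names(true_displacement))
  if (length(missing_td) > 0) {
    abort(paste("true_displacement missing for:",
                paste(missing_td, collapse = ", ")))
  }
  if (any(true_displacement < 0)) abort("true_displacement must be >= 0")
  structure(
    list(conditions = conditions, grid_dim = grid_dim,
         trials_per_location = trials_per_location,
         aline_rate = aline_rate, duration = duration,
         depth_resolution = depth_resolution, n_depth = n_depth,
         surface_depth = surface_depth,
         true_displacement = true_displacement, trial_sd = trial_sd,
         artefact_fraction = artefact_fraction, noise_sd = noise_sd,
         event_time = event_time, hold = hold,
         edge_width = 3 * depth_resolution),
    class = "oct_protocol"
  )
}

# surface depth trajectory in um per A-line, plus ground-truth event time
oct_surface_trajectory <- function(protocol, condition, displacement, t) {
  s0 <- protocol$surface_depth
  ev <- protocol$event_time
  if (condition == "idle") {
    # linear drift calibrated so consecutive 500 ms window means differ by
    # exactly `displacement`
    list(s = s0 + (displacement / 0.5) * t, event = NA_real_)
  } else if (condition == "hair_release") {
    # bending pulls the peri-follicular surface deeper until the hair
    # releases from the hook at `ev` and the skin springs back
    ramp <- pmin(pmax((t - (ev - 0.7)) / 0.4, 0), 1)
    s <- s0 + displacement * ramp
    s[t >= ev] <- s0
    list(s = s, event = ev)
  } else if (grepl("^mono", condition)) {
    s <- s0 + displacement * as.numeric(t >= ev & t < ev + protocol$hold)
    list(s = s, event = ev)
  } else {
    abort(paste("unknown condition:", condition))
  }
}

#' Generate one synthetic OCT M-mode trial
#'
#' Renders a depth x time intensity matrix with dark air above a bright
#' skin band whose surface follows a condition-specific trajectory:
#' constant with slow drift (idle), a step of the true displacement at the
#' contact event with a 500 ms hold (monofilament), or a bending ramp with
#' a release event (hair). The surface edge is rendered as a linear
#' intensity ramp a few depth samples wide so that sub-sample segmentation
#' is exact on noiseless trials. Optional artefacts: a beam-crossing
#' occlusion band, a 1.2 Hz heartbeat oscillation, or gross motion drift.
#'
#' @param protocol An [oct_protocol()].
#' @param condition Condition label present in the protocol.
#' @param location Length-2 integer grid location.
#' @param replicate Trial replicate index.
#' @param seed Integer seed.
#' @param displacement True displacement in um; `NULL` draws from
#'   Normal(mean, sd) for the condition (truncated above zero).
#' @param noise_sd Intensity noise SD; `NULL` uses the protocol value, 0
#'   gives a noiseless trial.
#' @param artefact `"none"`, `"beam_crossing"`, `"heartbeat"` or
#'   `"motion"`.
#' @return An `oct_mmode` object with fields `intensity` (depth x time),
#'   `aline_rate`, `depth_resolution`, `condition`, `location`,
#'   `replicate` and `truth` (displacement, event time, surface
#'   trajectory, artefact).
#' @export
gen_oct_trial <- function(protocol, condition, location = c(1L, 1L),
                          replicate = 1L, seed = 1,
                          displacement = NULL, noise_sd = NULL,
                          artefact = c("none", "beam_crossing",
                                       "heartbeat", "motion")) {
  artefact <- match.arg(artefact)
  if (!condition %in% protocol$conditions) {
    abort(paste("unknown condition:", condition))
  }
  if (protocol$depth_resolution <= 0) abort("depth resolution must be > 0")
  noise_sd <- noise_sd %||% protocol$noise_sd

  if (is.null(displacement)) {
    # per-trial true displacement is part of the protocol's ground truth:
    # it is drawn from a stream keyed by (condition, location, replicate)
    # only, so different top-level seeds change the noise but never the
    # truth
    mu <- protocol$true_displacement[[condition]]
    sd <- protocol$trial_sd[[condition]] %||% 0
    if (sd > 0) {
      truth_seed <- child_seed(
        match(condition, protocol$conditions) * 100000 +
          location[1] * 1000 + location[2] * 100 + replicate, 7L)
      displacement <- withr::with_seed(
        truth_seed, rnorm_positive(1, mu, sd, floor = 0.1 * mu))
    } else {
      displacement <- mu
    }
  }

  withr::with_seed(seed, {
    n_t <- round(protocol$duration * protocol$aline_rate)
    t <- (seq_len(n_t) - 0.5) / protocol$aline_rate
    traj <- oct_surface_trajectory(protocol, condition, displacement, t)
    s <- traj$s

    if (artefact == "heartbeat") {
      s <- s + 6 * sin(2 * pi * 1.2 * t)
    } else if (artefact == "motion") {
      s <- s + 20 * t
    }

    dz <- protocol$depth_resolution
    z <- seq_len(protocol$n_depth) * dz
    w <- protocol$edge_width
    bg <- 0.05; skin <- 0.95
    frac <- (outer(z, s, `-`)) / w
    intensity <- bg + (skin - bg) * pmin(pmax(frac, 0), 1)

    occlusion <- NULL
    if (artefact == "beam_crossing") {
      occ_start <- stats::runif(1, 0.4, 0.8)
      occlusion <- c(occ_start, occ_start + 0.3)
      occ_idx <- which(t >= occlusion[1] & t <= occlusion[2])
      intensity[, occ_idx] <- bg
    }
    if (noise_sd > 0) {
      intensity <- intensity +
        matrix(stats::rnorm(length(intensity), 0, noise_sd),
               nrow(intensity), ncol(intensity))
    }

    structure(
      list(intensity = intensity,
           aline_rate = protocol$aline_rate,
           depth_resolution = dz,
           condition = condition,
           location = as.integer(location),
           replicate = as.integer(replicate),
           truth = list(displacement = displacement,
                        event_time = traj$event,
                        surface = s, artefact = artefact,
                        occlusion = occlusion),
           seed = seed),
      class = "oct_mmode"
    )
  })
}

#' @export
print.oct_mmode <- function(x, ...) {
  cat(sprintf(
    "<oct_mmode> %s, %d x %d (depth x A-lines) @ %g Hz, truth %.2f um%s\n",
    x$condition, nrow(x$intensity), ncol(x$intensity), x$aline_rate,
    x$truth$displacement,
    if (x$truth$artefact != "none") paste0(" [", x$truth$artefact, "]") else ""))
  invisible(x)
}

#' Lay out the trials of an OCT protocol
#'
#' Expands the protocol into one row per (condition, location, replicate),
#' assigns per-trial seeds from the top-level seed, and marks the trials
#' that receive an injected artefact (exactly
#' `round(artefact_fraction * n)` of them, types drawn uniformly).
#'
#' @param protocol An [oct_protocol()].
#' @param seed Integer seed.
#' @return A tibble with columns `condition`, `loc_row`, `loc_col`,
#'   `replicate`, `trial_seed`, `artefact`.
#' @export
oct_trial_plan <- function(protocol, seed = 1) {
  plan <- tidyr::expand_grid(
    condition = protocol$conditions,
    loc_row = seq_len(protocol$grid_dim[1]),
    loc_col = seq_len(protocol$grid_dim[2]),
    replicate = seq_len(protocol$trials_per_location)
  )
  n <- nrow(plan)
  withr::with_seed(seed, {
    n_art <- round(protocol$artefact_fraction * n)
    art_rows <- sample.int(n, n_art)
    types <- sample(c("beam_crossing", "heartbeat", "motion"),
                    n_art, replace = TRUE)
  })
  plan$artefact <- "none"
  plan$artefact[art_rows] <- types
  plan$trial_seed <- vapply(seq_len(n), function(i) child_seed(seed, i),
                            integer(1))
  plan
}

#' Generate a full synthetic OCT protocol
#'
#' One trial per (condition, location, replicate); with defaults this is
#' 45 trials per condition across 6 conditions. Different top-level seeds
#' change the noise but trial ground-truth structure (plan layout) is
#' drawn identically from the same seed stream. Note that a full-rate
#' default protocol holds 270 large matrices; for protocol-scale analysis
#' prefer the streaming [run_oct_pipeline()].
#'
#' @inheritParams oct_trial_plan
#' @param noise_sd Optional override of the protocol intensity noise.
#' @return A list of `oct_mmode` trials; the plan is attached as attribute
#'   `plan`.
#' @export
gen_oct_protocol <- function(protocol, seed = 1, noise_sd = NULL) {
  plan <- oct_trial_plan(protocol, seed)
  trials <- purrr::pmap(plan, function(condition, loc_row, loc_col,
                                       replicate, artefact, trial_seed) {
    gen_oct_trial(protocol, condition, c(loc_row, loc_col), replicate,
                  seed = trial_seed, noise_sd = noise_sd,
                  artefact = artefact)
  })
  attr(trials, "plan") <- plan
  trials
}
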