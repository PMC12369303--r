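#' Track the skin surface in an OCT M-mode trial
#'
#' For each A-line the surface is the first depth sample (probe side)
#' whose intensity exceeds the background mean plus `threshold_k`
#' background SDs, refined to sub-sample precision by linear interpolation
#' of the threshold crossing. The background statistics come from the
#' probe-side air margin (the top rows). The track is median-filtered over
#' `smooth_ms`; A-lines with no crossing are flagged invalid. On
#' effectively noiseless trials the threshold falls back to the midpoint
#' between background and peak intensity, which lies mid-ramp on the
#' rendered surface edge and makes the interpolated crossing exact.
#'
#' @param trial An `oct_mmode`.
#' @param threshold_k Threshold in background-noise SD multiples.
#' @param smooth_ms Median filter window in ms (1 ms = 10 A-lines at
#'   10 kHz).
#' @param bg_rows Number of probe-side rows used as the air background.
#' @return A `surface_track`: smoothed `depth` (um per A-line, `NA` where
#'   invalid), `raw_depth`, `valid` flags, `aline_rate` and the smoothing
#'   parameters used.
#' @export
segment_surface <- function(trial, threshold_k = 5, smooth_ms = 1,
                            bg_rows = 8) {
  m <- trial$intensity
  if (is.null(m) || length(m) == 0) abort("trial has an empty intensity matrix")
  nd <- nrow(m); nt <- ncol(m)
  dz <- trial$depth_resolution
  bgv <- m[seq_len(min(bg_rows, nd - 1L)), , drop = FALSE]
  bg_mean <- mean(bgv); bg_sd <- stats::sd(as.numeric(bgv))
  thr <- bg_mean + threshold_k * bg_sd
  if (!is.finite(thr) || thr <= bg_mean + 1e-9) {
    thr <- bg_mean + 0.5 * (max(m) - bg_mean)
  }

  # first above-threshold row per column, vectorised over A-lines
  acc <- rep(FALSE, nt)
  idx <- rep(NA_integer_, nt)
  for (k in seq_len(nd)) {
    new <- (m[k, ] >= thr) & !acc
    if (any(new)) idx[new] <- k
    acc <- acc | new
  }
  valid <- !is.na(idx) & idx > 1L
  depth <- rep(NA_real_, nt)
  if (any(valid)) {
    cols <- which(valid)
    below <- m[cbind(idx[cols] - 1L, cols)]
    above <- m[cbind(idx[cols], cols)]
    fr <- (thr - below) / (above - below)
    fr[!is.finite(fr)] <- 0
    depth[cols] <- (idx[cols] - 1L + pmin(pmax(fr, 0), 1)) * dz
  }
  raw_depth <- depth

  if (any(valid)) {
    k <- max(1L, round(smooth_ms / 1000 * trial$aline_rate))
    if (k %% 2L == 0L) k <- k + 1L
    if (k >= 3L && sum(valid) >= k) {
      filled <- depth
      if (any(!valid)) {
        filled <- stats::approx(which(valid), depth[valid], xout = seq_len(nt),
                                rule = 2)$y
      }
      sm <- stats::runmed(filled, k, endrule = "keep")
      depth <- ifelse(valid, sm, NA_real_)
    }
  }

  structure(
    list(depth = depth, raw_depth = raw_depth, valid = valid,
         aline_rate = trial$aline_rate, depth_resolution = dz,
         threshold = thr, threshold_k = threshold_k, smooth_ms = smooth_ms,
         condition = trial$condition, location = trial$location,
         replicate = trial$replicate, truth = trial$truth),
    class = "surface_track"
  )
}

#' @export
print.surface_track <- function(x, ...) {
  cat(sprintf("<surface_track> %d A-lines @ %g Hz, %.1f%% valid\n",
              length(x$depth), x$aline_rate, 100 * mean(x$valid)))
  invisible(x)
}

#' @export
tidy.surface_track <- function(x, ...) {
  tibble(time = (seq_along(x$depth) - 0.5) / x$aline_rate,
         depth = x$depth, valid = x$valid)
}

#' Detect the stimulus event in a surface track
#'
#' The event is the time of the maximum derivative of the smoothed track
#' in the direction selected by `kind`: `"contact"` looks for the largest
#' increase in depth (indentation pushes the surface away from the probe),
#' `"release"` for the largest decrease (the surface springs back when the
#' hair releases from the hook).
#'
#' @param track A `surface_track` with at least 1 s of data.
#' @param kind `"contact"` or `"release"`.
#' @param min_step Minimum derivative magnitude in um (per A-line step)
#'   considered an event; flat tracks raise a no-event error.
#' @return Event time in s.
#' @export
detect_event <- function(track, kind = c("contact", "release"),
                         min_step = 1, deriv_ms = 10) {
  kind <- match.arg(kind)
  d <- track$depth
  fs <- track$aline_rate
  if (sum(track$valid) < fs) abort("need at least 1 s of valid track data")
  filled <- d
  if (any(!track$valid)) {
    filled <- stats::approx(which(track$valid), d[track$valid],
                            xout = seq_along(d), rule = 2)$y
  }
  # difference of the mean depth over the h samples after vs before each
  # inter-sample boundary: a step keeps its full amplitude while per-line
  # noise is averaged down by sqrt(h)
  h <- max(1L, round(deriv_ms / 1000 * fs))
  cs <- c(0, cumsum(filled))
  n <- length(filled)
  b <- h:(n - h)   # boundary after sample b
  dv <- (cs[b + 1 + h] - cs[b + 1]) / h - (cs[b + 1] - cs[b + 1 - h]) / h
  if (kind == "release") dv <- -dv
  i <- which.max(dv)
  if (!is.finite(dv[i]) || dv[i] < min_step) {
    abort("no event found: track is flat", class = "cthair_no_event")
  }
  b[i] / fs
}

window_mean <- function(track, t0, t1) {
  fs <- track$aline_rate
  tt <- (seq_along(track$depth) - 0.5) / fs
  sel <- tt >= t0 & tt < t1
  if (!any(sel)) abort("window out of range")
  ok <- sel & track$valid & is.finite(track$depth)
  if (sum(ok) < 0.5 * sum(sel)) {
    abort("fewer than 50% of the window's A-lines are valid")
  }
  mean(track$depth[ok])
}

#' Windowed displacement around a stimulus event
#'
#' Averages the surface depth over a pre-event and a post-event window of
#' `window_ms` each, separated from the event by a small guard gap, and
#' returns the absolute difference of the two means (displacement
#' magnitude in um). Only valid A-lines contribute; each window must be at
#' least half valid.
#'
#' @param track A `surface_track`.
#' @param event Event time in s (from [detect_event()]).
#' @param window_ms Window length in ms (200 ms for stimulus events).
#' @param guard_ms Guard gap around the event excluded from both windows.
#' @return Displacement in um.
#' @export
displacement_windows <- function(track, event, window_ms = 200,
                                 guard_ms = 20) {
  w <- window_ms / 1000; g <- guard_ms / 1000
  dur <- length(track$depth) / track$aline_rate
  if (event - g - w < 0 || event + g + w > dur) {
    abort("event windows fall outside the recording")
  }
  pre <- window_mean(track, event - g - w, event - g)
  post <- window_mean(track, event + g, event + g + w)
  abs(post - pre)
}

#' Idle-condition displacement from consecutive windows
#'
#' With no stimulus event to anchor on, the idle displacement is the
#' absolute difference between the means of two consecutive windows of
#' `window_ms` each (500 ms by default, longer than the stimulus windows
#' to average over biological motion), placed at the start of the
#' recording.
#'
#' @param track A `surface_track`.
#' @param window_ms Window length in ms.
#' @param start Placement of the first window in s.
#' @return Displacement in um.
#' @export
displacement_idle <- function(track, window_ms = 500, start = 0) {
  w <- window_ms / 1000
  dur <- length(track$depth) / track$aline_rate
  if (start + 2 * w > dur) abort("insufficient data for two idle windows")
  m1 <- window_mean(track, start, start + w)
  m2 <- window_mean(track, start + w, start + 2 * w)
  abs(m2 - m1)
}

# heartbeat amplitude estimate over the pre-stimulus span: largest
# amplitude of a sinusoid fitted on a frequency grid across `band` (Hz)
# after linear detrending (a direct projection avoids the spectral leakage
# of FFT bins on sub-second spans)
heartbeat_amplitude <- function(track, band = c(0.8, 2), span_s = 0.8) {
  fs <- track$aline_rate
  n <- min(length(track$depth), round(span_s * fs))
  d <- track$depth[seq_len(n)]
  ok <- track$valid[seq_len(n)] & is.finite(d)
  if (sum(ok) < n / 2) return(Inf)
  tt <- (seq_len(n)[ok] - 0.5) / fs
  y <- d[ok]
  y <- y - stats::fitted(stats::lm(y ~ tt))
  amps <- vapply(seq(band[1], band[2], by = 0.05), function(f) {
    c1 <- cos(2 * pi * f * tt); s1 <- sin(2 * pi * f * tt)
    fit <- stats::lm(y ~ c1 + s1)
    sqrt(sum(stats::coef(fit)[2:3]^2))
  }, numeric(1))
  max(amps)
}

#' Screen trials for artefacts
#'
#' A trial is rejected when any criterion fires: beam-crossing occlusion
#' (more than `max_invalid_frac` invalid A-lines), heartbeat (amplitude of
#' the dominant 0.8-2 Hz component of the pre-event track exceeding
#' `heartbeat_limit`), or gross motion (absolute pre-event drift slope
#' exceeding `drift_limit`). Screening uses the pre-stimulus span (first
#' 0.8 s, before any bending or contact) so stimulus steps do not
#' masquerade as artefacts.
#'
#' @param tracks A list of `surface_track` objects, or a tibble with a
#'   `track` list-column (as produced by [run_oct_pipeline()] internals).
#' @param max_invalid_frac Maximum tolerated invalid A-line fraction.
#' @param heartbeat_limit um.
#' @param drift_limit um/s.
#' @return A list: `kept` (indices into the input), `log` (tibble with
#'   `trial`, `rejected`, `reason`) and `fraction` rejected.
#' @export
reject_trials <- function(tracks, max_invalid_frac = 0.05,
                          heartbeat_limit = 3, drift_limit = 15) {
  if (is.data.frame(tracks)) tracks <- tracks$track
  res <- purrr::imap(tracks, function(tr, i) {
    reason <- NA_character_
    if (mean(!tr$valid) > max_invalid_frac) {
      reason <- "beam-crossing"
    } else {
      hb <- heartbeat_amplitude(tr)
      if (hb > heartbeat_limit) {
        reason <- "heartbeat"
      } else {
        fs <- tr$aline_rate
        n <- min(length(tr$depth), round(0.8 * fs))
        ok <- tr$valid[seq_len(n)]
        x <- (seq_len(n)[ok] - 0.5) / fs
        slope <- stats::coef(stats::lm(tr$depth[seq_len(n)][ok] ~ x))[2]
        if (is.finite(slope) && abs(slope) > drift_limit) reason <- "motion"
      }
    }
    tibble(trial = i, rejected = !is.na(reason), reason = reason)
  })
  log <- bind_rows(res)
  list(kept = log$trial[!log$rejected], log = log,
       fraction = mean(log$rejected))
}

#' Select the highest displacements per condition
#'
#' Keeps the `k` largest displacements (per condition when several are
#' present), reflecting the rationale that manually positioned probes
#' capture the deformation best at only some locations. Ties at the k-th
#' value are broken deterministically by location then trial order. If
#' fewer than `k` trials survive, all are returned with a warning.
#'
#' @param measures Tibble with columns `condition`, `displacement` and
#'   (for tie-breaking) `loc_row`, `loc_col`, `replicate` if available.
#' @param k Number of trials to keep per condition.
#' @return The selected rows of `measures`.
#' @export
select_top <- function(measures, k = 10) {
  if (nrow(measures) == 0) abort("no displacement measures supplied")
  if (!"condition" %in% names(measures)) measures$condition <- "all"
  tie_cols <- intersect(c("loc_row", "loc_col", "replicate"), names(measures))
  out <- measures |>
    group_by(.data$condition) |>
    arrange(desc(.data$displacement),
            across(all_of(tie_cols)), .by_group = TRUE) |>
    slice_head(n = k) |>
    ungroup()
  short <- out |> count(.data$condition) |> filter(.data$n < k)
  if (nrow(short) > 0) {
    warn(paste0("fewer than k=", k, " trials survive for: ",
                paste(short$condition, collapse = ", ")))
  }
  out
}

#' Compare displacement across conditions with Tukey HSD
#'
#' Fits a one-way layout and runs Tukey's honestly significant difference
#' procedure (studentized range, family-wise alpha `alpha`) over all
#' pairwise condition contrasts, alongside per-condition means with
#' t-based 95% confidence intervals.
#'
#' @param measures Tibble with columns `condition` and `displacement`
#'   (um), or a named list mapping condition to displacement vectors.
#' @param alpha Family-wise error rate.
#' @return A `condition_comparison` object with `summary` (per-condition
#'   n, mean, CI), `pairwise` (adjusted p-values and significance flags)
#'   and the underlying `aov` fit. See [tidy.condition_comparison()].
#' @export
compare_conditions <- function(measures, alpha = 0.05) {
  if (is.list(measures) && !is.data.frame(measures)) {
    measures <- tibble(
      condition = rep(names(measures),
                      vapply(measures, length, integer(1))),
      displacement = unlist(measures, use.names = FALSE)
    )
  }
  counts <- table(measures$condition)
  if (length(counts) < 2) abort("need at least 2 conditions")
  if (any(counts < 2)) abort("need at least 2 values per condition")
  if (all(tapply(measures$displacement, measures$condition,
                 stats::var) < 1e-24)) {
    abort("zero within-group variance in every group",
          class = "cthair_degenerate_variance")
  }
  df <- data.frame(condition = factor(measures$condition),
                   displacement = measures$displacement)
  fit <- stats::aov(displacement ~ condition, data = df)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$condition
  pairwise <- tibble(
    contrast = rownames(tk),
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p_adj = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha
  )
  summary_tbl <- df |>
    group_by(condition = as.character(.data$condition)) |>
    summarise(
      n = n(),
      mean = mean(.data$displacement),
      sd = stats::sd(.data$displacement),
      ci_lwr = .data$mean - stats::qt(0.975, .data$n - 1) * .data$sd / sqrt(.data$n),
      ci_upr = .data$mean + stats::qt(0.975, .data$n - 1) * .data$sd / sqrt(.data$n),
      .groups = "drop"
    )
  structure(
    list(summary = summary_tbl, pairwise = pairwise, alpha = alpha,
         fit = fit),
    class = "condition_comparison"
  )
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("<condition_comparison> %d conditions, family-wise alpha %.2f\n",
              nrow(x$summary), x$alpha))
  print(x$summary)
  print(x$pairwise)
  invisible(x)
}

#' Tidy a condition comparison
#'
#' @param x A `condition_comparison`.
#' @param ... Unused.
#' @return The pairwise contrast tibble.
#' @export
tidy.condition_comparison <- function(x, ...) {
  x$pairwise
}

#' @export
glance.condition_comparison <- function(x, ...) {
  s <- summary(x$fit)[[1]]
  tibble(
    n_conditions = nrow(x$summary),
    n_total = sum(x$summary$n),
    statistic = s[["F value"]][1],
    p_value = s[["Pr(>F)"]][1],
    alpha = x$alpha,
    n_significant_pairs = sum(x$pairwise$significant)
  )
}
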