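#' Spike-train summary metrics
#'
#' Computes the spike count, mean instantaneous frequency and peak
#' instantaneous frequency over a response window. Instantaneous
#' frequencies are reciprocals of successive inter-spike intervals within
#' the window; the mean IF is their arithmetic mean and the peak IF their
#' maximum. With fewer than two spikes both frequencies are undefined and
#' reported as `NA` (the minimum-two-spikes rule: at least one interval is
#' needed to define an instantaneous frequency).
#'
#' @param train A `spike_train` or numeric vector of spike times (s).
#' @param window Length-2 numeric `(t0, t1)` with `t0 < t1`.
#' @param method `"reciprocal_isi"` (default): mean of `1/ISI`;
#'   `"span"`: `(n - 1) / (t_last - t_first)`, the alternative reading of a
#'   mean frequency between the first and last spike. Peak IF is always the
#'   maximum reciprocal ISI.
#' @return A one-row tibble: `count`, `mean_if`, `peak_if`, `t0`, `t1`,
#'   `method`.
#' @export
#' @examples
#' spike_metrics(c(1.0, 1.1, 1.2, 1.3), c(0, 2))
spike_metrics <- function(train, window,
                          method = c("reciprocal_isi", "span")) {
  method <- match.arg(method)
  times <- if (inherits(train, "spike_train")) train$times else as.numeric(train)
  if (length(window) != 2 || window[1] >= window[2]) {
    abort("window must be (t0, t1) with t0 < t1")
  }
  tt <- times[times >= window[1] & times <= window[2]]
  n <- length(tt)
  if (n < 2) {
    return(tibble(count = n, mean_if = NA_real_, peak_if = NA_real_,
                  t0 = window[1], t1 = window[2], method = method))
  }
  iff <- 1 / diff(tt)
  mean_if <- switch(method,
    reciprocal_isi = mean(iff),
    span = (n - 1) / (tt[n] - tt[1])
  )
  tibble(count = n, mean_if = mean_if, peak_if = max(iff),
         t0 = window[1], t1 = window[2], method = method)
}

#' Conduction velocity from distance and latency
#'
#' @param distance Conduction distance in m (> 0).
#' @param latency Response latency in s (> 0).
#' @return Velocity in m/s.
#' @export
conduction_velocity <- function(distance, latency) {
  if (!is.numeric(distance) || !is.numeric(latency) ||
      any(distance <= 0) || any(latency <= 0)) {
    abort("distance and latency must be positive")
  }
  distance / latency
}

#' Classify a fibre as C, A-beta or other
#'
#' C fibres spike downward and conduct below 2 m/s (or, when no electrical
#' conduction velocity is available, show a response delay of at least
#' 100 ms, the defining mechanical-latency signature of slow conduction);
#' A-beta fibres spike upward and conduct above 30 m/s. Everything else is
#' `"other"`.
#'
#' @param polarity `"up"` or `"down"`.
#' @param conduction_velocity m/s, or `NA` if not measured.
#' @param response_delay Mechanical response delay in s, or `NA`.
#' @return `"C"`, `"A_beta"` or `"other"`.
#' @export
classify_fibre <- function(polarity = c("down", "up"),
                           conduction_velocity = NA_real_,
                           response_delay = NA_real_) {
  polarity <- match.arg(polarity)
  if (is.na(conduction_velocity) && is.na(response_delay)) {
    abort("provide conduction_velocity or response_delay")
  }
  if (polarity == "down" &&
      ((!is.na(conduction_velocity) && conduction_velocity < 2) ||
       (!is.na(response_delay) && response_delay >= 0.1))) {
    return("C")
  }
  if (polarity == "up" && !is.na(conduction_velocity) &&
      conduction_velocity > 30) {
    return("A_beta")
  }
  "other"
}

#' Standard monofilament force set
#'
#' Nominal buckling forces (mN) of the Semmes-Weinstein monofilament kit,
#' spanning 0.08 to 3000 mN.
#'
#' @return Numeric vector of forces in mN.
#' @export
monofilament_forces <- function() {
  c(0.08, 0.2, 0.4, 0.7, 1.6, 4, 6, 10, 14, 20, 40, 60, 80, 100,
    150, 260, 600, 1000, 1800, 3000)
}

#' Estimate the mechanical threshold from monofilament responses
#'
#' Applies the 50%-criterion rule: the threshold is the lowest tested force
#' with a spike response on at least half of its trials, confirmed on
#' re-test (at least two positive trials at that force). A single-trial
#' candidate force is accepted but flagged low-confidence; if no force
#' qualifies the unit is flagged unresponsive.
#'
#' @param responses A tibble with columns `force` (mN, drawn from
#'   [monofilament_forces()]) and `response` (logical), one row per trial;
#'   or a named list mapping force to a logical vector of trial outcomes.
#' @return A one-row tibble: `threshold` (mN, `NA` if unresponsive),
#'   `responsive`, `confidence` (`"confirmed"` or `"low"`),
#'   `n_trials_at_threshold`.
#' @export
#' @examples
#' estimate_mech_threshold(tibble::tibble(
#'   force = c(4, 4, 0.7, 0.7, 0.4, 0.4, 0.4, 0.2, 0.2),
#'   response = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
#' ))
estimate_mech_threshold <- function(responses) {
  if (is.list(responses) && !is.data.frame(responses)) {
    responses <- tibble(
      force = rep(as.numeric(names(responses)),
                  vapply(responses, length, integer(1))),
      response = unlist(responses, use.names = FALSE)
    )
  }
  if (!all(c("force", "response") %in% names(responses)) ||
      nrow(responses) == 0) {
    abort("responses must be a non-empty tibble with columns force, response")
  }
  std <- monofilament_forces()
  ok <- vapply(responses$force,
               function(f) any(abs(f - std) / std < 0.01), logical(1))
  if (!all(ok)) {
    abort(paste0("forces must come from the standard monofilament set: ",
                 paste(unique(responses$force[!ok]), collapse = ", "),
                 " not recognised"))
  }
  by_force <- responses |>
    group_by(force = .data$force) |>
    summarise(n = n(), n_pos = sum(.data$response),
              prop = mean(.data$response), .groups = "drop") |>
    arrange(.data$force)
  eligible <- by_force |> filter(.data$prop >= 0.5)
  if (nrow(eligible) == 0) {
    return(tibble(threshold = NA_real_, responsive = FALSE,
                  confidence = NA_character_,
                  n_trials_at_threshold = NA_integer_))
  }
  thr_row <- eligible[1, ]
  tibble(
    threshold = thr_row$force,
    responsive = TRUE,
    confidence = if (thr_row$n_pos >= 2) "confirmed" else "low",
    n_trials_at_threshold = as.integer(thr_row$n)
  )
}

#' Classify a unit as CT, HFA or other
#'
#' A CT unit is a C fibre with a mechanical threshold of 4 mN or less that
#' responds to soft brushing; an HFA is an A-beta rapidly adapting unit
#' that responds to hair deflection.
#'
#' @param record A list or one-row data frame with fields `fibre_class`
#'   (`"C"`, `"A_beta"`, `"other"`), `mech_threshold` (mN), `adaptation`
#'   (`"RA"`, `"SA"`, `"unknown"`) and `brush_responsive` (logical).
#' @param hair_deflection_responsive Logical: did the unit respond to
#'   single-hair deflection?
#' @return `"CT"`, `"HFA"` or `"other"`.
#' @export
classify_unit <- function(record, hair_deflection_responsive) {
  need <- c("fibre_class", "mech_threshold", "adaptation", "brush_responsive")
  missing_f <- setdiff(need, names(record))
  if (length(missing_f) > 0) {
    abort(paste("record is missing fields:", paste(missing_f, collapse = ", ")))
  }
  if (record$fibre_class == "C" &&
      !is.na(record$mech_threshold) && record$mech_threshold <= 4 &&
      isTRUE(record$brush_responsive)) {
    return("CT")
  }
  if (record$fibre_class == "A_beta" && identical(record$adaptation, "RA") &&
      isTRUE(hair_deflection_responsive)) {
    return("HFA")
  }
  "other"
}

#' Quantify after-discharge following a stimulus
#'
#' Scans post-stimulus spikes in order and terminates the discharge at the
#' last spike before the first inter-spike gap exceeding `gap_rule`
#' (counting the gap from stimulus end to the first spike), or at the last
#' spike overall. Duration is that spike's time minus the stimulus end;
#' mean and peak IF are computed over the discharge window. With no
#' post-stimulus spikes the duration is zero and the frequencies are
#' absent.
#'
#' @param train A `spike_train` or numeric spike times (s).
#' @param stimulus_end Stimulus offset time in s.
#' @param gap_rule Maximum tolerated inter-spike gap in s (default 2 s,
#'   about ten times the typical inter-spike interval at the observed
#'   discharge rate).
#' @return A one-row tibble: `duration`, `count`, `mean_if`, `peak_if`,
#'   `gap_rule`.
#' @export
detect_after_discharge <- function(train, stimulus_end, gap_rule = 2) {
  times <- if (inherits(train, "spike_train")) train$times else as.numeric(train)
  post <- times[times > stimulus_end]
  if (length(post) == 0) {
    return(tibble(duration = 0, count = 0L, mean_if = NA_real_,
                  peak_if = NA_real_, gap_rule = gap_rule))
  }
  gaps <- diff(c(stimulus_end, post))
  first_big <- which(gaps > gap_rule)
  last_i <- if (length(first_big) == 0) length(post) else first_big[1] - 1L
  if (last_i == 0L) {
    return(tibble(duration = 0, count = 0L, mean_if = NA_real_,
                  peak_if = NA_real_, gap_rule = gap_rule))
  }
  end_t <- post[last_i]
  m <- spike_metrics(post[seq_len(last_i)], c(stimulus_end, end_t + 1e-9))
  tibble(duration = end_t - stimulus_end, count = m$count,
         mean_if = m$mean_if, peak_if = m$peak_if, gap_rule = gap_rule)
}
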