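#' Build a validated table of stimulus epochs
#'
#' Stimulus epochs annotate a neural trace with the periods during which a
#' mechanical stimulus was applied to the receptive field. Epochs are kept
#' as a tibble with one row per epoch so they compose naturally with the
#' rest of the pipeline.
#'
#' @param kind Character vector of epoch kinds; one of `"brush"`,
#'   `"hair_deflection"`, `"air_puff"`, `"monofilament"`, `"pluck"`, `"idle"`.
#' @param t_start,t_end Epoch boundaries in seconds.
#' @param force Monofilament force in mN (required and positive when
#'   `kind == "monofilament"`, `NA` otherwise).
#' @param velocity Nominal stimulus velocity in cm/s for brush and hair
#'   deflection epochs (optional).
#' @return A tibble with columns `kind`, `t_start`, `t_end`, `force`,
#'   `velocity`.
#' @export
#' @examples
#' stimulus_epochs("brush", 0.5, 2.5, velocity = 3)
stimulus_epochs <- function(kind, t_start, t_end, force = NA_real_,
                            velocity = NA_real_) {
  kinds <- c("brush", "hair_deflection", "air_puff", "monofilament",
             "pluck", "idle")
  kind <- match.arg(kind, kinds, several.ok = TRUE)
  ep <- tibble(
    kind = kind,
    t_start = as.numeric(t_start),
    t_end = as.numeric(t_end),
    force = as.numeric(force),
    velocity = as.numeric(velocity)
  )
  validate_epochs(ep)
  ep
}

validate_epochs <- function(epochs) {
  if (!all(c("kind", "t_start", "t_end") %in% names(epochs))) {
    abort("epochs must have columns kind, t_start, t_end")
  }
  if (any(!is.finite(epochs$t_start)) || any(!is.finite(epochs$t_end))) {
    abort("epoch boundaries must be finite")
  }
  if (any(epochs$t_end <= epochs$t_start)) {
    abort("each epoch must satisfy t_start < t_end")
  }
  mono <- epochs$kind == "monofilament"
  if (any(mono) && any(!is.finite(epochs$force[mono]) | epochs$force[mono] <= 0)) {
    abort("monofilament epochs require force > 0 (mN)")
  }
  if (nrow(epochs) > 1) {
    o <- order(epochs$t_start)
    if (any(epochs$t_start[o][-1] < epochs$t_end[o][-nrow(epochs)])) {
      abort("epochs must not overlap")
    }
  }
  invisible(epochs)
}

#' Specify a simulated afferent unit
#'
#' A unit spec holds the physiological ground truth for one simulated
#' afferent: fibre class, conduction velocity, mechanical threshold, the
#' target mean instantaneous frequency (IF) per stimulus kind, and the
#' after-discharge model. Spiking is a gamma renewal process: with ISI
#' shape `k`, the mean of reciprocal ISIs at renewal rate `r` equals
#' `r * k / (k - 1)`, so the generator uses rate `(k - 1) / k * mean_if`
#' to make the mean-IF target hold in expectation.
#'
#' @param fibre_class `"C"` or `"A_beta"`. C units must have conduction
#'   velocity below 2 m/s and spike downward first; A-beta units above
#'   30 m/s and upward first.
#' @param conduction_velocity Conduction velocity in m/s.
#' @param true_threshold Mechanical threshold in mN.
#' @param rate_presets Named list mapping stimulus kind to
#'   `list(mean_if = , shape = )`, mean IF in spikes/s.
#' @param after_discharge `NULL` (none), or
#'   `list(mean = , sd = , rate_initial = , rate_final = )`: duration drawn
#'   from Normal(mean, sd) with non-positive draws resampled; firing decays
#'   linearly from `rate_initial` to `rate_final` over the drawn duration.
#' @return A `unit_spec` object.
#' @export
unit_spec <- function(fibre_class = c("C", "A_beta"),
                      conduction_velocity = 1.09,
                      true_threshold = 0.7,
                      rate_presets = list(),
                      after_discharge = NULL) {
  fibre_class <- match.arg(fibre_class)
  if (fibre_class == "C" && conduction_velocity >= 2) {
    abort("C units must have conduction_velocity < 2 m/s")
  }
  if (fibre_class == "A_beta" && conduction_velocity <= 30) {
    abort("A_beta units must have conduction_velocity > 30 m/s")
  }
  for (p in rate_presets) {
    if (p$mean_if < 0) abort("rate preset mean_if must be >= 0")
  }
  structure(
    list(
      fibre_class = fibre_class,
      conduction_velocity = conduction_velocity,
      true_threshold = true_threshold,
      rate_presets = rate_presets,
      after_discharge = after_discharge,
      polarity = if (fibre_class == "C") "down" else "up"
    ),
    class = "unit_spec"
  )
}

#' Preset C-tactile (CT) unit
#'
#' Defaults reproduce the population means of the study conditions: soft
#' brushing at 21 spikes/s, single-hair deflection at 12 spikes/s, air puff
#' at 10 spikes/s, and a hair-plucking after-discharge lasting
#' Normal(7.1, 3.2) seconds with firing decaying from 12 to 3 spikes/s.
#'
#' @param mean_if_brush,mean_if_deflection,mean_if_air_puff Target mean IF
#'   (spikes/s) per stimulus kind.
#' @param isi_shape Gamma ISI shape parameter (regularity); 4 by default.
#' @param ad_mean,ad_sd After-discharge duration distribution (s).
#' @param conduction_velocity m/s, must be < 2.
#' @param true_threshold Mechanical threshold in mN.
#' @return A `unit_spec`.
#' @export
ct_unit_spec <- function(mean_if_brush = 21, mean_if_deflection = 12,
                         mean_if_air_puff = 10, isi_shape = 4,
                         ad_mean = 7.1, ad_sd = 3.2,
                         conduction_velocity = 1.09, true_threshold = 0.7) {
  unit_spec(
    fibre_class = "C",
    conduction_velocity = conduction_velocity,
    true_threshold = true_threshold,
    rate_presets = list(
      brush = list(mean_if = mean_if_brush, shape = isi_shape),
      hair_deflection = list(mean_if = mean_if_deflection, shape = isi_shape),
      air_puff = list(mean_if = mean_if_air_puff, shape = isi_shape),
      monofilament = list(mean_if = 30, shape = isi_shape),
      pluck = list(mean_if = 20, shape = isi_shape)
    ),
    after_discharge = list(mean = ad_mean, sd = ad_sd,
                           rate_initial = 12, rate_final = 3)
  )
}

#' Preset hair follicle afferent (HFA) unit
#'
#' A-beta rapidly adapting unit responding to brushing (31 spikes/s), hair
#' deflection (12 spikes/s) and air puffs (26 spikes/s), with no
#' after-discharge following plucking.
#'
#' @inheritParams ct_unit_spec
#' @param mean_if_air_puff Target mean IF for air puff (spikes/s).
#' @return A `unit_spec`.
#' @export
hfa_unit_spec <- function(mean_if_brush = 31, mean_if_deflection = 12,
                          mean_if_air_puff = 26, isi_shape = 4,
                          conduction_velocity = 34.9, true_threshold = 4) {
  unit_spec(
    fibre_class = "A_beta",
    conduction_velocity = conduction_velocity,
    true_threshold = true_threshold,
    rate_presets = list(
      brush = list(mean_if = mean_if_brush, shape = isi_shape),
      hair_deflection = list(mean_if = mean_if_deflection, shape = isi_shape),
      air_puff = list(mean_if = mean_if_air_puff, shape = isi_shape),
      monofilament = list(mean_if = 40, shape = isi_shape),
      pluck = list(mean_if = 30, shape = isi_shape)
    ),
    after_discharge = NULL
  )
}

#' Stereotyped extracellular spike waveform
#'
#' A 3 ms biphasic template whose leading phase is the larger one and whose
#' polarity encodes the fibre class: downward-leading for C fibres,
#' upward-leading for A-beta, matching the recording convention in which C
#' and A-beta spikes deflect in opposite directions. The template peak
#' (largest absolute sample) defines the spike time.
#'
#' @param sampling_rate Hz.
#' @param polarity `"down"` or `"up"`.
#' @param duration_ms Template length in ms.
#' @return Numeric vector with attribute `peak_index`.
#' @export
spike_template <- function(sampling_rate = 20000, polarity = c("down", "up"),
                           duration_ms = 3) {
  polarity <- match.arg(polarity)
  n <- max(8L, round(duration_ms / 1000 * sampling_rate))
  t <- seq(0, duration_ms / 1000, length.out = n)
  # damped single-cycle sine: dominant first phase, weaker rebound
  w <- sin(2 * pi * t / (duration_ms / 1000)) * exp(-t / (duration_ms / 1000 / 2.2))
  w <- w / max(abs(w))
  if (polarity == "down") w <- -w
  structure(w, peak_index = which.max(abs(w)))
}

# Homogeneous gamma renewal spike times within [t0, t1) at mean-IF target m.
renewal_spikes <- function(t0, t1, mean_if, shape = 4) {
  if (mean_if <= 0) return(numeric(0))
  rate <- mean_if * (shape - 1) / shape
  n_guess <- max(10, ceiling((t1 - t0) * rate * 2 + 20))
  isi <- stats::rgamma(n_guess, shape = shape, rate = shape * rate)
  tt <- t0 + cumsum(isi)
  while (sum(isi) < (t1 - t0)) {
    isi2 <- stats::rgamma(n_guess, shape = shape, rate = shape * rate)
    tt <- c(tt, tt[length(tt)] + cumsum(isi2))
    isi <- c(isi, isi2)
  }
  tt[tt < t1]
}

# After-discharge spike times on [0, d]: linearly decaying-rate renewal
# process via time rescaling, terminated by a final spike at d itself (the
# discharge is modelled as ending with its last action potential).
discharge_spikes <- function(d, rate_initial, rate_final, shape = 4) {
  if (d <= 0) return(numeric(0))
  r0 <- rate_initial * (shape - 1) / shape
  r1 <- rate_final * (shape - 1) / shape
  # integrated rate Lambda(t) = r0*t - (r0 - r1) * t^2 / (2d), t in [0, d]
  total <- (r0 + r1) * d / 2
  u <- cumsum(stats::rgamma(max(10, ceiling(total * 2 + 20)),
                            shape = shape, rate = shape))
  while (u[length(u)] < total) {
    u <- c(u, u[length(u)] +
             cumsum(stats::rgamma(20, shape = shape, rate = shape)))
  }
  u <- u[u < total]
  # invert Lambda: (r0 - r1)/(2d) t^2 - r0 t + u = 0
  a <- (r0 - r1) / (2 * d)
  tt <- if (abs(a) < 1e-12) u / r0 else (r0 - sqrt(pmax(r0^2 - 4 * a * u, 0))) / (2 * a)
  sort(unique(c(tt[tt > 0 & tt < d], d)))
}

#' Generate a synthetic extracellular voltage trace
#'
#' Emulates a single-unit microneurography recording: stimulus-locked gamma
#' renewal spiking at the unit's per-stimulus mean-IF targets, silence
#' outside epochs, an after-discharge following pluck epochs for units that
#' have one, a stereotyped biphasic waveform per spike (polarity by fibre
#' class), an optional conduction latency, and additive Gaussian noise.
#' Ground-truth spike times and the drawn after-discharge duration are
#' retained for downstream validation.
#'
#' @param spec A [unit_spec()].
#' @param epochs Epoch tibble from [stimulus_epochs()]; an empty tibble
#'   yields an idle-only trace.
#' @param noise_sd Additive Gaussian noise SD in uV (>= 0).
#' @param seed Integer seed; the trace is bit-reproducible given the seed.
#' @param sampling_rate Hz (20 kHz by default, the acquisition rate).
#' @param duration Trace length in s; `NULL` extends past the last epoch
#'   (and any after-discharge) automatically.
#' @param amplitude Spike waveform peak amplitude in uV.
#' @param conduction_distance Electrode-to-field distance in m; spikes are
#'   delayed by `conduction_distance / conduction_velocity`. Zero by
#'   default so that ground-truth timing is stimulus-locked.
#' @return A `neural_trace` object: `samples` (uV), `sampling_rate`,
#'   `epochs`, `truth` (spike times in s, after-discharge duration,
#'   template), and the generating `spec`.
#' @export
gen_neural_trace <- function(spec, epochs = NULL, noise_sd = 5, seed = 1,
                             sampling_rate = 20000, duration = NULL,
                             amplitude = 40, conduction_distance = 0) {
  if (!inherits(spec, "unit_spec")) abort("spec must be a unit_spec")
  if (!is_scalar_number(noise_sd) || noise_sd < 0) {
    abort("noise_sd must be a non-negative number")
  }
  if (is.null(epochs) || nrow(epochs) == 0) {
    epochs <- tibble(kind = character(), t_start = numeric(),
                     t_end = numeric(), force = numeric(),
                     velocity = numeric())
  } else {
    validate_epochs(epochs)
  }

  withr::with_seed(seed, {
    spike_times <- numeric(0)
    ad_duration <- NA_real_
    for (i in seq_len(nrow(epochs))) {
      kind <- epochs$kind[i]
      if (kind == "idle") next
      preset <- spec$rate_presets[[kind]]
      if (is.null(preset)) next
      st <- renewal_spikes(epochs$t_start[i], epochs$t_end[i],
                           preset$mean_if, preset$shape %||% 4)
      spike_times <- c(spike_times, st)
      if (kind == "pluck" && !is.null(spec$after_discharge)) {
        ad <- spec$after_discharge
        ad_duration <- rnorm_positive(1, ad$mean, ad$sd)
        ds <- discharge_spikes(ad_duration, ad$rate_initial, ad$rate_final)
        spike_times <- c(spike_times, epochs$t_end[i] + ds)
      }
    }
    latency <- if (conduction_distance > 0) {
      conduction_distance / spec$conduction_velocity
    } else 0
    spike_times <- sort(spike_times) + latency

    if (is.null(duration)) {
      last_t <- max(c(epochs$t_end, spike_times, 1))
      duration <- ceiling((last_t + 0.25) * 10) / 10
    }
    n <- round(duration * sampling_rate)
    tmpl <- spike_template(sampling_rate, spec$polarity)
    peak_i <- attr(tmpl, "peak_index")

    samples <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
    keep <- logical(length(spike_times))
    for (j in seq_along(spike_times)) {
      i0 <- round(spike_times[j] * sampling_rate) + 1L - (peak_i - 1L)
      i1 <- i0 + length(tmpl) - 1L
      if (i0 < 1L || i1 > n) next
      samples[i0:i1] <- samples[i0:i1] + amplitude * as.numeric(tmpl)
      keep[j] <- TRUE
    }
    # truth times snapped to the sample grid at which the peak was written
    truth_times <- (round(spike_times[keep] * sampling_rate)) / sampling_rate

    structure(
      list(
        samples = samples,
        sampling_rate = sampling_rate,
        duration = duration,
        epochs = epochs,
        truth = list(spike_times = truth_times,
                     after_discharge_duration = ad_duration,
                     template = tmpl, amplitude = amplitude,
                     latency = latency),
        spec = spec,
        noise_sd = noise_sd,
        seed = seed
      ),
      class = "neural_trace"
    )
  })
}

#' @export
print.neural_trace <- function(x, ...) {
  cat(sprintf(
    "<neural_trace> %.2f s @ %d Hz, %d epochs, %d truth spikes (%s unit)\n",
    x$duration, x$sampling_rate, nrow(x$epochs),
    length(x$truth$spike_times), x$spec$fibre_class))
  invisible(x)
}

#' @export
tidy.neural_trace <- function(x, ...) {
  tibble(
    time = (seq_along(x$samples) - 1) / x$sampling_rate,
    voltage = x$samples
  )
}
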