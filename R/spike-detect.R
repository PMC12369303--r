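#' Construct a spike train
#'
#' @param times Strictly increasing spike times in seconds.
#' @param polarity `"up"` or `"down"`: direction of the leading phase.
#' @param template Waveform used for template matching (may be `NULL`).
#' @param duration Trace duration the times must lie within (optional).
#' @return A `spike_train` object.
#' @export
spike_train <- function(times, polarity = c("down", "up"), template = NULL,
                        duration = NULL) {
  polarity <- match.arg(polarity)
  times <- as.numeric(times)
  if (length(times) > 1 && any(diff(times) <= 0)) {
    abort("spike times must be strictly increasing")
  }
  if (!is.null(duration) && length(times) > 0 &&
      (min(times) < 0 || max(times) > duration)) {
    abort("spike times must lie within the trace duration")
  }
  structure(
    list(times = times, polarity = polarity, template = template,
         duration = duration),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes, polarity %s\n",
              length(x$times), x$polarity))
  invisible(x)
}

#' @export
tidy.spike_train <- function(x, ...) {
  tibble(time = x$times)
}

# local maxima of |v| above thr, merged within a refractory distance,
# keeping the larger peak of any conflicting pair.
find_candidate_peaks <- function(v, thr, refr_samples) {
  a <- abs(v)
  above <- which(a > thr)
  if (length(above) == 0) return(integer(0))
  # local maxima among above-threshold samples
  n <- length(a)
  lm <- above[a[above] >= a[pmax(above - 1L, 1L)] &
                a[above] >= a[pmin(above + 1L, n)]]
  if (length(lm) == 0) return(integer(0))
  # greedy merge by descending amplitude
  ord <- lm[order(a[lm], decreasing = TRUE)]
  keep <- logical(0)
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0 || all(abs(kept - i) >= refr_samples)) {
      kept <- c(kept, i)
    }
  }
  sort(kept)
}

#' Detect spikes by threshold crossing and template matching
#'
#' Candidate events are threshold crossings of either polarity separated by
#' at least the refractory period; the matching template is the mean
#' waveform of candidates inside brush epochs (conventionally the cleanest
#' stimulus), and candidates are retained when their normalized
#' cross-correlation with the template reaches `match_threshold`. The spike
#' time is the time of the peak sample.
#'
#' @param trace A `neural_trace` (from [gen_neural_trace()] or
#'   [read_neural_trace()]).
#' @param threshold Detection threshold in uV; `NULL` uses five times a
#'   robust noise SD estimate (MAD), falling back to 20% of the largest
#'   absolute sample on effectively noiseless traces.
#' @param refractory Minimum event separation in seconds.
#' @param match_threshold Minimum normalized cross-correlation in \[-1, 1\].
#' @param template Optional pre-built waveform template (e.g. from a brush
#'   characterisation trace of the same unit, the convention used when a
#'   trace itself has no brush epoch); overrides in-trace template
#'   building.
#' @return A `spike_train`; attribute `candidates` holds a tibble of all
#'   candidate events with their correlations, and `template_source`
#'   records whether the template came from brush epochs, was supplied, or
#'   (flagged) fell back to the highest-amplitude candidate.
#' @export
detect_spikes <- function(trace, threshold = NULL, refractory = 0.002,
                          match_threshold = 0.8, template = NULL) {
  v <- trace$samples
  fs <- trace$sampling_rate
  tmpl_len <- max(8L, round(0.003 * fs))
  if (length(v) < tmpl_len) abort("trace shorter than one spike waveform")
  if (is.null(threshold)) {
    nsd <- stats::mad(v)
    threshold <- if (nsd > 1e-9) 5 * nsd else 0.2 * max(abs(v), 1e-12)
  }
  if (threshold <= 0) abort("threshold must be > 0")

  refr <- max(1L, round(refractory * fs))
  peaks <- find_candidate_peaks(v, threshold, refr)
  if (length(peaks) == 0) {
    return(spike_train(numeric(0), "down", NULL, trace$duration))
  }

  half <- tmpl_len %/% 2L
  ok <- peaks - half >= 1L & peaks + half <= length(v)
  peaks <- peaks[ok]
  wf <- t(vapply(peaks, function(p) v[(p - half):(p + half)],
                 numeric(2L * half + 1L)))

  if (!is.null(template)) {
    if (length(template) != ncol(wf)) {
      template <- stats::approx(seq_along(template), template,
                                n = ncol(wf))$y
    }
    template_source <- "supplied"
  } else {
    in_brush <- rep(FALSE, length(peaks))
    br <- trace$epochs[trace$epochs$kind == "brush", , drop = FALSE]
    if (nrow(br) > 0) {
      tt <- (peaks - 1) / fs
      for (i in seq_len(nrow(br))) {
        in_brush <- in_brush | (tt >= br$t_start[i] & tt <= br$t_end[i])
      }
    }
    if (any(in_brush)) {
      template <- colMeans(wf[in_brush, , drop = FALSE])
      template_source <- "brush_epochs"
    } else {
      template <- wf[which.max(abs(v[peaks])), ]
      template_source <- "highest_amplitude_candidate"
    }
  }

  cors <- suppressWarnings(apply(wf, 1, stats::cor, y = template))
  cors[is.na(cors)] <- 0
  matched <- cors >= match_threshold

  if (mean(!matched) > 0.5 && sum(!matched) >= 5) {
    warn("over half of the candidate events do not match the template; possible multi-unit recording")
  }

  times <- (peaks[matched] - 1) / fs
  pol <- if (length(times) > 0 && v[peaks[matched][which.max(abs(v[peaks[matched]]))]] < 0) {
    "down"
  } else "up"
  out <- spike_train(times, pol, template, trace$duration)
  attr(out, "candidates") <- tibble(
    time = (peaks - 1) / fs,
    amplitude = v[peaks],
    correlation = cors,
    matched = matched
  )
  attr(out, "template_source") <- template_source
  attr(out, "threshold") <- threshold
  out
}
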