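#' Study configuration
#'
#' Bundles the unit roster, per-population presets and analysis
#' parameters for an end-to-end simulated microneurography study. The
#' defaults reproduce the recorded study population: 15 CT units and 3
#' HFAs, CT brushing mean IF 21 +/- 6 spikes/s, hair deflection
#' 12 +/- 5 spikes/s, conduction velocities 1.09 +/- 0.31 m/s,
#' mechanical thresholds between 0.4 and 4 mN averaging 0.92 mN, and an
#' after-discharge of 7.1 +/- 3.2 s following plucking.
#'
#' @param n_ct,n_hfa Number of simulated CT and HFA units.
#' @param trials_per_stimulus Repeat trials per stimulus kind per unit.
#' @param ct_brush,ct_deflection,ct_air_puff `(mean, sd)` of the per-unit
#'   mean-IF targets, spikes/s.
#' @param ct_cv `(mean, sd)` of CT conduction velocities, m/s.
#' @param threshold_probs Probabilities over [ct_threshold_forces()].
#' @param ad_mean,ad_sd After-discharge duration distribution, s.
#' @param hfa_brush,hfa_deflection,hfa_air_puff HFA `(mean, sd)` presets.
#' @param noise_sd Trace noise SD, uV.
#' @param epoch Stimulus epoch `(t_start, t_end)` used for every kind, s.
#' @return A `study_config` list.
#' @export
study_config <- function(n_ct = 15, n_hfa = 3, trials_per_stimulus = 3,
                         ct_brush = c(21, 6), ct_deflection = c(12, 5),
                         ct_air_puff = c(10, 5), ct_cv = c(1.09, 0.31),
                         threshold_probs = c(6, 6, 2, 1) / 15,
                         ad_mean = 7.1, ad_sd = 3.2,
                         hfa_brush = c(31, 15), hfa_deflection = c(12, 7),
                         hfa_air_puff = c(26, 10),
                         noise_sd = 5, epoch = c(0.5, 2.5)) {
  structure(
    list(n_ct = n_ct, n_hfa = n_hfa,
         trials_per_stimulus = trials_per_stimulus,
         ct_brush = ct_brush, ct_deflection = ct_deflection,
         ct_air_puff = ct_air_puff, ct_cv = ct_cv,
         threshold_probs = threshold_probs,
         ad_mean = ad_mean, ad_sd = ad_sd,
         hfa_brush = hfa_brush, hfa_deflection = hfa_deflection,
         hfa_air_puff = hfa_air_puff,
         noise_sd = noise_sd, epoch = epoch),
    class = "study_config"
  )
}

#' Forces over which CT thresholds are distributed
#'
#' The monofilament forces (mN) spanned by the recorded CT population
#' (minimum 0.4, maximum 4.0 mN).
#'
#' @return Numeric vector of forces in mN.
#' @export
ct_threshold_forces <- function() c(0.4, 0.7, 1.6, 4)

# truncated-normal draw of a per-unit mean-IF target
draw_target <- function(n, mean_sd, floor = 2) {
  rnorm_positive(n, mean_sd[1], mean_sd[2], floor = floor)
}

#' Simulated monofilament staircase for one unit
#'
#' Descends the standard force set from a suprathreshold start, testing
#' `trials_per_force` indentations per force until a force fails the 50%
#' criterion, then estimates the threshold with
#' [estimate_mech_threshold()]. The response model is near-deterministic:
#' forces at or above the true threshold elicit a spike with probability
#' `p_hit`, weaker forces with probability `p_false`.
#'
#' @param true_threshold True threshold in mN.
#' @param seed Integer seed.
#' @param trials_per_force Indentations per tested force.
#' @param p_hit,p_false Response probabilities at/above and below
#'   threshold.
#' @param start_force First tested force in mN.
#' @return A one-row tibble from [estimate_mech_threshold()] plus
#'   `true_threshold`.
#' @export
simulate_monofilament_series <- function(true_threshold, seed = 1,
                                         trials_per_force = 3,
                                         p_hit = 0.97, p_false = 0.02,
                                         start_force = 4) {
  forces <- sort(monofilament_forces())
  i0 <- which(forces >= max(start_force, true_threshold))[1]
  withr::with_seed(seed, {
    rows <- list()
    test_force <- function(f) {
      p <- if (f >= true_threshold) p_hit else p_false
      stats::runif(trials_per_force) < p
    }
    # secure a suprathreshold response first, escalating if needed
    i <- i0
    repeat {
      resp <- test_force(forces[i])
      rows[[length(rows) + 1]] <- tibble(force = forces[i], response = resp)
      if (mean(resp) >= 0.5 || i >= min(length(forces), i0 + 3L)) break
      i <- i + 1L
    }
    # then descend until a force fails the 50% criterion
    if (mean(resp) >= 0.5) {
      for (j in rev(seq_len(i0 - 1))) {
        resp <- test_force(forces[j])
        rows[[length(rows) + 1]] <- tibble(force = forces[j],
                                           response = resp)
        if (mean(resp) < 0.5) break
      }
    }
    est <- estimate_mech_threshold(bind_rows(rows))
    est$true_threshold <- true_threshold
    est
  })
}

#' Simulate recovery of population mean instantaneous frequency
#'
#' Draws per-unit mean-IF targets from a population preset, generates
#' repeat stimulus trials per unit, runs spike detection and the metrics
#' on every trial, and averages within then across units: the full
#' trace-level pipeline behind the population summaries.
#'
#' @param n_units Number of simulated units.
#' @param n_trials Repeat trials per unit.
#' @param kind Stimulus kind (`"brush"`, `"hair_deflection"`, ...).
#' @param pop_mean,pop_sd Population mean and SD of the per-unit mean-IF
#'   target, spikes/s.
#' @param seed Integer seed.
#' @param noise_sd Trace noise SD, uV.
#' @param epoch Stimulus epoch `(t_start, t_end)`, s.
#' @return A tibble: `unit`, `target_if`, `est_mean_if`, `est_peak_if`.
#' @export
simulate_if_recovery <- function(n_units, n_trials, kind = "brush",
                                 pop_mean = 21, pop_sd = 6, seed = 1,
                                 noise_sd = 5, epoch = c(0.5, 2.5)) {
  targets <- withr::with_seed(child_seed(seed, 0L),
                              draw_target(n_units, c(pop_mean, pop_sd)))
  eps <- stimulus_epochs(kind, epoch[1], epoch[2])
  purrr::map_dfr(seq_len(n_units), function(u) {
    spec <- if (kind == "brush") {
      ct_unit_spec(mean_if_brush = targets[u])
    } else if (kind == "hair_deflection") {
      ct_unit_spec(mean_if_deflection = targets[u])
    } else {
      ct_unit_spec(mean_if_air_puff = targets[u])
    }
    # per-unit waveform template from a brush characterisation trace, as
    # in the recording convention
    tmpl <- if (kind == "brush") NULL else {
      chtr <- gen_neural_trace(spec, stimulus_epochs("brush", 0.5, 2.5),
                               noise_sd = noise_sd,
                               seed = child_seed(seed, u * 1000L))
      detect_spikes(chtr)$template
    }
    res <- purrr::map_dfr(seq_len(n_trials), function(tr) {
      trace <- gen_neural_trace(spec, eps, noise_sd = noise_sd,
                                seed = child_seed(seed, u * 1000L + tr))
      st <- detect_spikes(trace, template = tmpl)
      spike_metrics(st, epoch)
    })
    tibble(unit = u, target_if = targets[u],
           est_mean_if = mean(res$mean_if, na.rm = TRUE),
           est_peak_if = mean(res$peak_if, na.rm = TRUE))
  })
}

#' Simulate after-discharge trials following hair plucking
#'
#' Draws per-trial discharge durations from Normal(`ad_mean`, `ad_sd`)
#' (non-positive draws resampled), generates the decaying-rate discharge
#' spike train ending at the drawn duration, and runs the gap-rule
#' detector on each trial.
#'
#' @param n Number of trials.
#' @param seed Integer seed.
#' @param ad_mean,ad_sd Duration distribution, s.
#' @param gap_rule Detector gap rule, s.
#' @param rate_initial,rate_final Discharge firing rate bounds, spikes/s.
#' @param stimulus_end Pluck offset time, s.
#' @return A tibble: `trial`, `true_duration`, `detected_duration`,
#'   `mean_if`, `peak_if`.
#' @export
simulate_pluck_trials <- function(n = 500, seed = 1, ad_mean = 7.1,
                                  ad_sd = 3.2, gap_rule = 2,
                                  rate_initial = 12, rate_final = 3,
                                  stimulus_end = 1.5) {
  purrr::map_dfr(seq_len(n), function(i) {
    withr::with_seed(child_seed(seed, i), {
      d <- rnorm_positive(1, ad_mean, ad_sd)
      st <- stimulus_end + discharge_spikes(d, rate_initial, rate_final)
      ad <- detect_after_discharge(st, stimulus_end, gap_rule)
      tibble(trial = i, true_duration = d,
             detected_duration = ad$duration,
             mean_if = ad$mean_if, peak_if = ad$peak_if)
    })
  })
}

#' Simulate monofilament threshold estimation across units
#'
#' Draws true thresholds from a categorical distribution over the CT
#' force range and runs the staircase per unit.
#'
#' @param n Number of units.
#' @param seed Integer seed.
#' @param forces Candidate true thresholds, mN.
#' @param probs Probabilities over `forces` (default reproduces the
#'   recorded population: mean 0.92 mN over 0.4-4 mN).
#' @param trials_per_force Indentations per tested force.
#' @return A tibble: `unit`, `true_threshold`, `est_threshold`.
#' @export
simulate_threshold_units <- function(n = 400, seed = 1,
                                     forces = ct_threshold_forces(),
                                     probs = c(6, 6, 2, 1) / 15,
                                     trials_per_force = 3) {
  truths <- withr::with_seed(child_seed(seed, 0L),
                             sample(forces, n, replace = TRUE, prob = probs))
  purrr::map_dfr(seq_len(n), function(i) {
    est <- simulate_monofilament_series(truths[i],
                                        seed = child_seed(seed, i),
                                        trials_per_force = trials_per_force)
    tibble(unit = i, true_threshold = truths[i],
           est_threshold = est$threshold)
  })
}

#' Compare two groups of per-unit values
#'
#' Mann-Whitney U (exact two-sided p for combined n <= 20 without ties,
#' otherwise a tie/continuity-corrected normal approximation, flagged) or
#' a paired t test on per-unit differences.
#'
#' @param a,b Numeric vectors (equal length for the paired test).
#' @param method `"mann_whitney"` or `"paired_t"`.
#' @return A one-row tibble: `method`, `statistic`, `p_value`, `exact`.
#' @export
compare_groups <- function(a, b, method = c("mann_whitney", "paired_t")) {
  method <- match.arg(method)
  if (length(a) < 2 || length(b) < 2) abort("need at least 2 values per group")
  if (method == "mann_whitney") {
    has_ties <- anyDuplicated(c(a, b)) > 0
    want_exact <- (length(a) + length(b)) <= 20 && !has_ties
    res <- suppressWarnings(
      stats::wilcox.test(a, b, exact = want_exact, correct = TRUE)
    )
    tibble(method = method, statistic = unname(res$statistic),
           p_value = res$p.value, exact = want_exact)
  } else {
    if (length(a) != length(b)) abort("paired test requires equal lengths")
    d <- a - b
    if (all(abs(d - 0) < 1e-15) || stats::sd(d) < 1e-15) {
      return(tibble(method = method, statistic = 0, p_value = 1,
                    exact = NA))
    }
    res <- stats::t.test(a, b, paired = TRUE)
    tibble(method = method, statistic = unname(res$statistic),
           p_value = res$p.value, exact = NA)
  }
}

simulate_unit <- function(spec, config, seed, unit_id) {
  eps_for <- function(kind) stimulus_epochs(kind, config$epoch[1],
                                            config$epoch[2])
  # unit waveform template from a brush characterisation trace, reused for
  # matching on every other stimulus of the same unit
  chtr <- gen_neural_trace(spec, eps_for("brush"),
                           noise_sd = config$noise_sd,
                           seed = child_seed(seed, unit_id * 10000L + 99L))
  unit_tmpl <- detect_spikes(chtr)$template
  per_stim <- purrr::map_dfr(
    c("brush", "hair_deflection", "air_puff"), function(kind) {
      res <- purrr::map_dfr(seq_len(config$trials_per_stimulus), function(tr) {
        trace <- gen_neural_trace(
          spec, eps_for(kind), noise_sd = config$noise_sd,
          seed = child_seed(seed, unit_id * 10000L +
                              match(kind, c("brush", "hair_deflection",
                                            "air_puff")) * 100L + tr))
        st <- detect_spikes(trace, template = unit_tmpl)
        spike_metrics(st, config$epoch)
      })
      tibble(kind = kind,
             count = mean(res$count),
             mean_if = mean(res$mean_if, na.rm = TRUE),
             peak_if = mean(res$peak_if, na.rm = TRUE),
             responsive = mean(res$count >= 2) >= 0.5)
    })

  thr <- simulate_monofilament_series(
    spec$true_threshold, seed = child_seed(seed, unit_id * 10000L + 500L))

  pluck_eps <- stimulus_epochs("pluck", 0.5, 1.5)
  pluck_trace <- gen_neural_trace(
    spec, pluck_eps, noise_sd = config$noise_sd,
    seed = child_seed(seed, unit_id * 10000L + 600L))
  pluck_train <- detect_spikes(pluck_trace, template = unit_tmpl)
  ad <- detect_after_discharge(pluck_train, 1.5)

  polarity <- spec$polarity
  fibre <- classify_fibre(polarity,
                          conduction_velocity = spec$conduction_velocity)
  adaptation <- if (spec$fibre_class == "A_beta") "RA" else "unknown"
  g <- function(k, col) per_stim[[col]][per_stim$kind == k]
  record <- list(fibre_class = fibre, mech_threshold = thr$threshold,
                 adaptation = adaptation,
                 brush_responsive = g("brush", "responsive"))
  unit_type <- classify_unit(record, g("hair_deflection", "responsive"))

  tibble(
    unit = unit_id, true_class = spec$fibre_class,
    fibre_class = fibre, unit_type = unit_type,
    conduction_velocity = spec$conduction_velocity,
    mech_threshold = thr$threshold,
    true_threshold = spec$true_threshold,
    brush_mean_if = g("brush", "mean_if"),
    brush_peak_if = g("brush", "peak_if"),
    deflection_mean_if = g("hair_deflection", "mean_if"),
    deflection_peak_if = g("hair_deflection", "peak_if"),
    air_puff_mean_if = g("air_puff", "mean_if"),
    after_discharge_duration = ad$duration,
    after_discharge_mean_if = ad$mean_if,
    after_discharge_peak_if = ad$peak_if
  )
}

#' Run the full simulated microneurography pipeline
#'
#' Simulates the configured unit roster, and for every unit: trace
#' generation per stimulus trial, spike detection, metrics averaged over
#' repeat trials, monofilament threshold staircase, pluck after-discharge
#' and unit classification. Group summaries and the brushing-versus-
#' deflection comparison (Mann-Whitney first, paired t second) are
#' computed across CT units.
#'
#' @param config A [study_config()].
#' @param seed Integer seed.
#' @return A list: `units` (one row per unit), `group_stats` (per
#'   stimulus summaries by unit type) and `comparisons`.
#' @export
run_microneuro_pipeline <- function(config = study_config(), seed = 1) {
  n_total <- config$n_ct + config$n_hfa
  if (n_total == 0) {
    warn("empty unit roster; returning empty tables")
    return(list(units = tibble(), group_stats = tibble(),
                comparisons = tibble()))
  }
  draws <- withr::with_seed(child_seed(seed, 0L), {
    list(
      brush = draw_target(config$n_ct, config$ct_brush),
      defl = draw_target(config$n_ct, config$ct_deflection),
      air = draw_target(config$n_ct, config$ct_air_puff),
      cv = pmin(rnorm_positive(config$n_ct, config$ct_cv[1],
                               config$ct_cv[2], floor = 0.3), 1.99),
      thr = sample(ct_threshold_forces(), max(config$n_ct, 1),
                   replace = TRUE, prob = config$threshold_probs),
      h_brush = draw_target(config$n_hfa, config$hfa_brush),
      h_defl = draw_target(config$n_hfa, config$hfa_deflection),
      h_air = draw_target(config$n_hfa, config$hfa_air_puff)
    )
  })

  units <- list()
  for (u in seq_len(config$n_ct)) {
    spec <- ct_unit_spec(
      mean_if_brush = draws$brush[u], mean_if_deflection = draws$defl[u],
      mean_if_air_puff = draws$air[u], ad_mean = config$ad_mean,
      ad_sd = config$ad_sd, conduction_velocity = draws$cv[u],
      true_threshold = draws$thr[u])
    units[[length(units) + 1]] <- simulate_unit(spec, config, seed, u)
  }
  for (h in seq_len(config$n_hfa)) {
    spec <- hfa_unit_spec(
      mean_if_brush = draws$h_brush[h],
      mean_if_deflection = draws$h_defl[h],
      mean_if_air_puff = draws$h_air[h])
    units[[length(units) + 1]] <- simulate_unit(spec, config, seed,
                                                config$n_ct + h)
  }
  units <- bind_rows(units)

  group_stats <- units |>
    group_by(.data$unit_type) |>
    summarise(
      n = n(),
      brush_mean_if_mean = mean(.data$brush_mean_if, na.rm = TRUE),
      brush_mean_if_sd = stats::sd(.data$brush_mean_if),
      brush_peak_if_mean = mean(.data$brush_peak_if, na.rm = TRUE),
      deflection_mean_if_mean = mean(.data$deflection_mean_if, na.rm = TRUE),
      deflection_mean_if_sd = stats::sd(.data$deflection_mean_if),
      after_discharge_mean = mean(.data$after_discharge_duration),
      .groups = "drop"
    )

  ct <- units |> filter(.data$unit_type == "CT")
  comparisons <- if (nrow(ct) >= 2) {
    bind_rows(
      compare_groups(ct$brush_mean_if, ct$deflection_mean_if,
                     "mann_whitney"),
      compare_groups(ct$brush_mean_if, ct$deflection_mean_if, "paired_t")
    ) |> mutate(contrast = "brush_vs_deflection_mean_if", .before = 1)
  } else {
    tibble()
  }

  list(units = units, group_stats = group_stats, comparisons = comparisons)
}

#' Run the full synthetic OCT displacement pipeline
#'
#' Streams over the protocol's trial plan: generates each M-mode trial,
#' tracks the surface, screens for artefacts, applies the per-condition
#' displacement rule (consecutive idle windows, or event-anchored 200 ms
#' windows), selects the top displacements per condition, and compares
#' conditions with Tukey HSD. Trials are processed one at a time so the
#' full-rate default protocol stays within modest memory.
#'
#' @param protocol An [oct_protocol()].
#' @param seed Integer seed.
#' @param k_top Trials kept per condition after rejection.
#' @param noise_sd Optional override of the protocol intensity noise.
#' @return A list: `measures` (per-trial displacements and truth),
#'   `rejection` (log and fraction), `selected`, `comparison` (a
#'   `condition_comparison`, or `NULL` with fewer than two conditions).
#' @export
run_oct_pipeline <- function(protocol = oct_protocol(), seed = 1,
                             k_top = 10, noise_sd = NULL) {
  plan <- oct_trial_plan(protocol, seed)
  tracks <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    trial <- gen_oct_trial(protocol, plan$condition[i],
                           c(plan$loc_row[i], plan$loc_col[i]),
                           plan$replicate[i], seed = plan$trial_seed[i],
                           noise_sd = noise_sd,
                           artefact = plan$artefact[i])
    tracks[[i]] <- segment_surface(trial)
  }

  rej <- reject_trials(tracks)
  measures <- purrr::map_dfr(seq_len(nrow(plan)), function(i) {
    row <- tibble(
      trial = i, condition = plan$condition[i],
      loc_row = plan$loc_row[i], loc_col = plan$loc_col[i],
      replicate = plan$replicate[i], artefact = plan$artefact[i],
      true_displacement = tracks[[i]]$truth$displacement,
      rejected = !(i %in% rej$kept),
      reason = rej$log$reason[i],
      displacement = NA_real_
    )
    if (row$rejected) return(row)
    disp <- tryCatch({
      if (plan$condition[i] == "idle") {
        displacement_idle(tracks[[i]])
      } else {
        kind <- if (plan$condition[i] == "hair_release") "release" else "contact"
        ev <- detect_event(tracks[[i]], kind)
        displacement_windows(tracks[[i]], ev)
      }
    }, error = function(e) NA_real_)
    if (is.na(disp)) {
      row$rejected <- TRUE
      row$reason <- "no-event"
    } else {
      row$displacement <- disp
    }
    row
  })

  kept <- measures |> filter(!.data$rejected)
  selected <- select_top(kept, k = k_top)
  comparison <- if (length(unique(selected$condition)) >= 2 &&
                    all(table(selected$condition) >= 2)) {
    compare_conditions(selected)
  } else {
    warn("fewer than two comparable conditions; skipping comparison")
    NULL
  }

  list(measures = measures,
       rejection = list(log = rej$log, fraction = rej$fraction),
       selected = selected, comparison = comparison)
}
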