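#' Select the tracked remapping cell
#'
#' The recorded LIP(CD) cell is the one whose receptive field covers the
#' future-receptive-field stimulus after the saccade: its row index is the
#' post-saccadic steady-state argmax of the visual response to a persistent
#' stimulus at the FRF position, and its column index is the peak of the
#' anticipatory eye-position gain profile around saccade onset.
#'
#' @param config a [lip_config()].
#' @param ops optional [lip_operators()].
#' @return Integer `c(l, m)` with attributes `rf_center` and `eye_center`
#'   (degrees).
#' @export
select_remap_cell <- function(config = lip_config(), ops = NULL) {
  if (is.null(ops)) ops <- lip_operators(config)
  onset <- config$sim$settle + 300
  sac <- make_trajectory(config$remap$amplitude, onset, config = config)
  stim <- stimulus_set(config$remap$frf_position, config$sim$settle,
                       sac$offset + 320)
  trial <- simulate_trial(config, lip_ablation(), sac, stim,
                          t_end = sac$offset + 300, ops = ops,
                          snapshot_times = c(onset + 5, sac$offset + 280))
  peri <- trial$snapshots[[1]]
  post <- trial$snapshots[[2]]
  l <- which.max(rowSums(post$xb_cd))
  m <- which.max(drop(ops$Wfef %*% peri$xe_fef))
  structure(c(l, m),
            rf_center = ops$grid$centers[l],
            eye_center = ops$grid$centers[m])
}

#' Predictive-remapping paradigm
#'
#' For each flash time (relative to saccade onset) one deterministic trial is
#' simulated with a 100-ms probe at the cell's present receptive field and
#' one with the probe at its future receptive field (the pre-saccadic
#' fixation).  The tracked LIP(CD) cell's rate is averaged in the 50-350 ms
#' window after flash onset.  No endpoint scatter is applied.
#'
#' @param config a [lip_config()].
#' @param ablation a [lip_ablation()].
#' @param probes which probe positions to run (`"rf"`, `"frf"`).
#' @param ops optional [lip_operators()].
#' @return A tibble of class `lip_remap` with columns `flash_time` and one
#'   response column per probe; attributes `cell` (tracked indices),
#'   `cell_class`, and `config`.
#' @export
run_remapping <- function(config = lip_config(), ablation = lip_ablation(),
                          probes = c("rf", "frf"), ops = NULL) {
  if (is.null(ops)) ops <- lip_operators(config)
  rm <- config$remap
  onset <- config$sim$settle + 500
  if (any(rm$flash_times + onset < 0)) {
    abort("flash outside the simulation window")
  }
  sac <- make_trajectory(rm$amplitude, onset, config = config)
  cell <- select_remap_cell(config, ops)
  pos <- c(rf = rm$rf_position, frf = rm$frf_position)

  res <- tidyr::expand_grid(flash_time = rm$flash_times,
                            probe = probes)
  res$response <- purrr::pmap_dbl(res, function(flash_time, probe) {
    t_on <- onset + flash_time
    stim <- stimulus_set(pos[[probe]], t_on, t_on + rm$flash_duration)
    t_end <- max(sac$offset + 150, t_on + rm$window[2]) + 2
    trial <- simulate_trial(config, ablation, sac, stim, t_end = t_end,
                            ops = ops, track_cell = cell)
    win <- trial$time >= t_on + rm$window[1] &
      trial$time <= t_on + rm$window[2]
    mean(trial$cell[win])
  })
  out <- tidyr::pivot_wider(res, names_from = "probe",
                            values_from = "response")
  names(out)[names(out) == "rf"] <- "rf_response"
  names(out)[names(out) == "frf"] <- "frf_response"
  structure(out,
            class = c("lip_remap", class(out)),
            cell = cell,
            cell_class = if (isTRUE(config$circuit$gain_modulated)) {
              "gain_modulated"
            } else "purely_visual",
            ablation = ablation,
            config_hash = config_hash(config, ablation))
}

#' Onset of the predictive (FRF) response
#'
#' Earliest flash time at which the future-receptive-field response exceeds
#' a fraction (default 10%) of the curve's maximum.
#'
#' @param remap a [run_remapping()] result with an `frf_response` column.
#' @param frac threshold fraction of the curve maximum.
#' @return Flash time in ms relative to saccade onset (`NA` if never).
#' @export
remap_onset <- function(remap, frac = 0.1) {
  if (!"frf_response" %in% names(remap)) {
    abort("`remap` must contain an frf_response column")
  }
  thr <- frac * max(remap$frf_response)
  idx <- which(remap$frf_response >= thr)
  if (length(idx) == 0) return(NA_real_)
  min(remap$flash_time[idx])
}

#' One saccadic-suppression-of-displacement trial
#'
#' Full closed-loop simulation: the target is shown at the saccade goal for
#' 500 ms, the saccade is executed with sampled endpoint scatter, the target
#' is displaced 30 ms after saccade onset (in the blank condition it is
#' extinguished then and reappears displaced 250 ms later), and the
#' forward/backward report is produced by the accumulator readout.  Uses the
#' session RNG (scatter draw, Poisson spiking, tie-breaks); seed beforehand
#' for reproducibility.
#'
#' @param displacement target displacement in degrees.
#' @param condition `"normal"` or `"blank"`.
#' @param config a [lip_config()].
#' @param ablation a [lip_ablation()].
#' @param templates optional [build_templates()] (built on demand).
#' @param ops optional [lip_operators()].
#' @param scatter optional fixed endpoint error (degrees); drawn from
#'   [sample_scatter()] when `NULL`.
#' @return A one-row tibble: displacement, condition, outcome, forward flag,
#'   decision time, timeout flag, scatter and executed amplitude.
#' @export
run_ssd_trial <- function(displacement, condition = c("normal", "blank"),
                          config = lip_config(), ablation = lip_ablation(),
                          templates = NULL, ops = NULL, scatter = NULL) {
  condition <- match.arg(condition)
  if (is.null(ops)) ops <- lip_operators(config)
  target <- config$ssd$amplitude
  if (is.null(templates)) {
    templates <- build_templates(config, center = target,
                                 eye = target - config$saccade$undershoot_mean,
                                 variant = ablation$variant, ops = ops)
  }
  if (is.null(scatter)) scatter <- sample_scatter(1, config)

  onset <- config$sim$settle + config$ssd$target_lead
  sac <- make_trajectory(target, onset, scatter = scatter, config = config)
  blank <- condition == "blank"
  reappear <- onset + config$ssd$displacement_delay +
    if (blank) config$ssd$blank_gap else 0
  start <- accumulation_start(sac, reappear, config)
  t_end <- start + config$decision$timeout + 2
  stimuli <- ssd_stimuli(sac, config, displacement, blank, t_end + 1)

  trial <- simulate_trial(config, ablation, sac, stimuli, t_end = t_end,
                          ops = ops,
                          decision = list(templates = templates,
                                          c_pre = target, start = start))
  dec <- trial$decision
  tibble::tibble(displacement = displacement, condition = condition,
                 outcome = dec$outcome, forward = dec$outcome == "forward",
                 decision_time = dec$decision_time,
                 timed_out = dec$timed_out, scatter = scatter,
                 executed_amplitude = sac$executed_amplitude)
}

#' Saccadic-suppression-of-displacement experiment
#'
#' Runs `trials` seeded trials at every displacement of the configured
#' lattice, computes the percentage of forward reports per displacement and
#' fits a cumulative Gaussian by ordinary least squares.
#'
#' @param config a [lip_config()].
#' @param ablation a [lip_ablation()].
#' @param condition `"normal"` or `"blank"`.
#' @param trials trials per displacement (default `config$ssd$trials`).
#' @param seed optional integer seed for the whole experiment.
#' @param label optional condition label stored with the result.
#' @return An object of class `lip_psychometric`: the per-displacement curve
#'   (`displacement`, `pct_forward`, `n_trials`), the trial table, the fitted
#'   `mu` and `sigma` (degrees), and the condition/ablation metadata.
#' @export
run_ssd_experiment <- function(config = lip_config(),
                               ablation = lip_ablation(),
                               condition = c("normal", "blank"),
                               trials = NULL, seed = NULL, label = NULL) {
  condition <- match.arg(condition)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(trials)) trials <- config$ssd$trials
  ops <- lip_operators(config)
  templates <- build_templates(
    config, center = config$ssd$amplitude,
    eye = config$ssd$amplitude - config$saccade$undershoot_mean,
    variant = ablation$variant, ops = ops)
  grid <- tidyr::expand_grid(displacement = config$ssd$displacements,
                             trial = seq_len(trials))
  rows <- purrr::pmap(grid, function(displacement, trial) {
    run_ssd_trial(displacement, condition, config, ablation,
                  templates = templates, ops = ops)
  })
  trials_tbl <- dplyr::bind_rows(rows)
  curve <- dplyr::summarise(
    dplyr::group_by(trials_tbl, .data$displacement),
    pct_forward = 100 * mean(.data$forward),
    n_trials = dplyr::n(), .groups = "drop")
  fit <- fit_psychometric(curve$displacement, curve$pct_forward)
  structure(list(curve = curve, trials = trials_tbl,
                 mu = fit$mu, sigma = fit$sigma, fit = fit,
                 condition = condition, ablation = ablation,
                 n_trials = trials,
                 label = label %||% psychometric_label(ablation, condition)),
            class = "lip_psychometric")
}

psychometric_label <- function(ablation, condition) {
  base <- if (!ablation$corollary_discharge) {
    "no corollary discharge"
  } else if (!ablation$remapping_feedback) {
    "no remapping feedback"
  } else if (ablation$variant == "lateral") {
    "lateral variant"
  } else "full model"
  if (condition == "blank") paste(base, "(blank)") else base
}

#' @export
print.lip_psychometric <- function(x, ...) {
  cat(sprintf("<lip_psychometric> %s, %s condition\n", x$label, x$condition))
  cat(sprintf("  %d displacements x %d trials; mu = %.2f deg, sigma = %.2f deg\n",
              nrow(x$curve), x$n_trials, x$mu, x$sigma))
  invisible(x)
}

#' Cumulative-Gaussian psychometric fit
#'
#' Ordinary least-squares fit of `P(d) = 100 * Phi((d - mu) / sigma)` to the
#' percentage of forward reports; `mu` is the decision bias and `sigma` the
#' displacement uncertainty (both in degrees, `sigma > 0`).
#'
#' @param displacements displacement lattice (degrees); at least 4 distinct
#'   values.
#' @param pct_forward percentage of forward reports per displacement.
#' @return An object of class `lip_psychofit` with `mu`, `sigma`, `sse`,
#'   and `fitted` values.
#' @export
#' @examples
#' d <- seq(-4, 4, 0.5)
#' fit_psychometric(d, 100 * pnorm((d - 1) / 2))  # recovers mu 1, sigma 2
fit_psychometric <- function(displacements, pct_forward) {
  if (length(unique(displacements)) < 4) {
    abort("need at least 4 distinct displacements")
  }
  if (length(displacements) != length(pct_forward)) {
    abort("displacements and pct_forward lengths differ")
  }
  if (length(unique(pct_forward)) == 1) {
    abort(sprintf(
      "degenerate psychometric data (all responses %.1f%%): cannot fit",
      pct_forward[1]))
  }
  sse <- function(par) {
    mu <- par[1]
    sigma <- exp(par[2])
    sum((pct_forward - 100 * pnorm((displacements - mu) / sigma))^2)
  }
  p50 <- suppressWarnings(
    stats::approx(pct_forward, displacements, xout = 50, ties = mean)$y)
  mu0 <- if (is.finite(p50 %||% NA_real_)) p50 else 0
  best <- NULL
  for (s0 in c(0.5, 1, 2, 4)) {
    o <- optim(c(mu0, log(s0)), sse, method = "Nelder-Mead",
               control = list(maxit = 1000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  mu <- best$par[1]
  sigma <- exp(best$par[2])
  structure(list(mu = mu, sigma = sigma, sse = best$value,
                 displacements = displacements, pct_forward = pct_forward,
                 fitted = 100 * pnorm((displacements - mu) / sigma)),
            class = "lip_psychofit")
}

#' @export
print.lip_psychofit <- function(x, ...) {
  cat(sprintf("<lip_psychofit> mu = %.3f deg, sigma = %.3f deg (SSE %.1f)\n",
              x$mu, x$sigma, x$sse))
  invisible(x)
}

#' Run the full condition x ablation suite
#'
#' The four psychometric conditions (full model, no remapping feedback, no
#' corollary discharge, full model with a 250-ms blank) plus the
#' lateral-variant run, each as a seeded SSD experiment.
#'
#' @param config a [lip_config()].
#' @param seed master seed; each condition uses `seed + k`.
#' @param trials trials per displacement.
#' @param out_dir optional directory for a consolidated CSV (per-point
#'   curves) and JSON summary.
#' @return A tibble with one row per condition (`label`, `condition`,
#'   ablation flags, fitted `mu` and `sigma`) and a list column `result`
#'   holding the full `lip_psychometric` objects.
#' @export
run_ablation_suite <- function(config = lip_config(), seed = 1,
                               trials = NULL, out_dir = NULL) {
  specs <- list(
    list(abl = lip_ablation(), condition = "normal"),
    list(abl = lip_ablation(remapping_feedback = FALSE),
         condition = "normal"),
    list(abl = lip_ablation(corollary_discharge = FALSE),
         condition = "normal"),
    list(abl = lip_ablation(), condition = "blank"),
    list(abl = lip_ablation(variant = "lateral"), condition = "normal")
  )
  results <- purrr::imap(specs, function(s, k) {
    run_ssd_experiment(config, s$abl, s$condition, trials = trials,
                       seed = seed + k)
  })
  summary <- dplyr::bind_rows(purrr::map(results, glance))
  summary$result <- results
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    curves <- dplyr::bind_rows(purrr::map(results, tidy))
    write.csv(curves, file.path(out_dir, "ssd_curves.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, config_hash = config_hash(config),
           fits = summary[, setdiff(names(summary), "result")]),
      file.path(out_dir, "ssd_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  summary
}

`%||%` <- function(a, b) if (is.null(a)) b else a
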