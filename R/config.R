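#' Model configuration
#'
#' Builds the full set of constants controlling the simulator: map geometry,
#' time constants, connection-kernel widths and gains, input-signal timing,
#' saccade generation, the decision readout, and the two experimental
#' paradigms.  Every value can be overridden by passing a nested list, e.g.
#' `lip_config(cd = list(sigma_rise = 40))`.
#'
#' Key groups:
#' \describe{
#'   \item{grid}{`n` neurons per map dimension and visual-field extent `v`
#'     in degrees (centres span `[-v/2, v/2]`).}
#'   \item{tau}{leaky-integrator time constants in ms: `visual` for the
#'     input maps, `lip` for the LIP maps, `xh` for the intermediate
#'     (head-centred) cells, `dn` for the decision neurons.}
#'   \item{rf}{receptive-field width law `sigma0 + slope * |eccentricity|`
#'     (degrees).}
#'   \item{kernel}{`sigma_deg`: width (degrees) of the Gaussian input kernels
#'     feeding the 2-D maps; `sigma_diag`: width (grid-index units) of the
#'     diagonal kernels; `k_pc`, `k_cd`: peak gains of the diagonal readout
#'     from the two LIP maps.}
#'   \item{pc}{proprioceptive eye-position signal: spatial width `sigma`
#'     (degrees), update `delay` after saccade offset (ms) and `transition`
#'     duration (ms).}
#'   \item{cd}{corollary discharge: spatial width `sigma` (degrees) and the
#'     temporal envelope widths `sigma_rise` / `sigma_decay` (ms) around
#'     saccade onset.}
#'   \item{circuit}{`cd_ff_gain`: feedforward response gain of the LIP(CD)
#'     map; `fb_gain`: gain of the remapping feedback (intermediate
#'     cells x anticipatory eye position) into LIP(CD); `lat_gain`: gain of
#'     the direct lateral path used by the `"lateral"` variant;
#'     `gain_modulated`: whether the feedforward visual drive of LIP(CD) is
#'     gain-increased by the CD signal.}
#'   \item{decision}{template lattice step and half-width (degrees),
#'     accumulator threshold/baseline/timeout, Poisson bin count, and the
#'     accumulation start delays (ms) after saccade offset or stimulus
#'     reappearance.}
#'   \item{saccade}{main-sequence duration law `d0 + d1 * |amplitude|` and the
#'     endpoint scatter distribution (mean undershoot, SD, degrees).}
#'   \item{remap, ssd}{spatial/temporal layout of the predictive-remapping
#'     and saccadic-suppression-of-displacement paradigms.}
#' }
#'
#' @param ... named nested lists overriding defaults.
#' @return A nested list of class `lip_config`.
#' @export
#' @examples
#' cfg <- lip_config()
#' cfg$grid$n
#' small <- lip_config(grid = list(n = 21), ssd = list(trials = 5))
lip_config <- function(...) {
  defaults <- list(
    grid = list(n = 40L, v = 160),
    dt = 1,
    tau = list(visual = 10, lip = 10, xh = 10, dn = 50),
    rf = list(sigma0 = 4.0, slope = 0.05),
    attention = list(enabled = TRUE, gain = 0.1),
    kernel = list(sigma_deg = 6.0, sigma_diag = 15.0,
                  k_pc = 0.035, k_cd = 0.02),
    pc = list(sigma = 6.0, delay = 10, transition = 80),
    cd = list(sigma = 6.0, sigma_rise = 30, sigma_decay = 150),
    fef = list(gain = 2.0),
    circuit = list(fb_gain = 0.9, lat_gain = 0.9, cd_ff_gain = 0.25,
                   gain_modulated = TRUE),
    decision = list(template_step = 0.5, template_halfwidth = 12,
                    d_thresh = 0.6, baseline = 0.1, timeout = 100,
                    bins = 20L, s_max = 1, match_gain = 0.45,
                    offset_delay = 28, stim_delay = 60, settle = 250),
    saccade = list(d0 = 23, d1 = 2.7,
                   undershoot_mean = 0.52, undershoot_sd = 0.58),
    remap = list(amplitude = 14, flash_times = seq(-500, 100, by = 25),
                 flash_duration = 100, window = c(50, 350),
                 rf_position = -14, frf_position = 0,
                 onset_frac = 0.1),
    ssd = list(amplitude = 8, target_lead = 500, displacement_delay = 30,
               blank_gap = 250, displacements = seq(-4, 4, by = 0.5),
               trials = 20L),
    sim = list(settle = 200)
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      is.list(overrides[[1]])) {
    overrides <- overrides[[1]]
  }
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad) > 0) {
    abort(paste0("unknown lip_config group(s): ", paste(bad, collapse = ", ")))
  }
  cfg <- modifyList(defaults, overrides)
  validate_config(cfg)
  structure(cfg, class = c("lip_config", "list"))
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$grid$n >= 2, cfg$grid$v > 0,
    cfg$dt > 0,
    all(unlist(cfg$tau) > 0),
    cfg$dt <= min(unlist(cfg$tau)) / 5,
    cfg$rf$sigma0 > 0, cfg$rf$slope >= 0,
    cfg$kernel$sigma_deg > 0, cfg$kernel$sigma_diag > 0,
    cfg$kernel$k_pc > 0, cfg$kernel$k_cd > 0,
    cfg$pc$sigma > 0, cfg$pc$delay >= 0, cfg$pc$transition > 0,
    cfg$cd$sigma > 0, cfg$cd$sigma_rise > 0,
    cfg$cd$sigma_decay > cfg$cd$sigma_rise,
    cfg$decision$template_step > 0,
    cfg$decision$d_thresh > cfg$decision$baseline,
    cfg$decision$bins >= 1,
    cfg$saccade$d0 > 0, cfg$saccade$d1 >= 0,
    cfg$saccade$undershoot_sd > 0
  )
  invisible(cfg)
}

#' Ablation switches
#'
#' The three circuit manipulations studied with the model: disabling the
#' remapping feedback from the intermediate (head-centred) cells to LIP(CD),
#' disabling the corollary-discharge input altogether, and replacing the
#' intermediate cells by a direct lateral projection between the two LIP maps.
#'
#' @param remapping_feedback logical; feedback from intermediate cells to
#'   LIP(CD) (the substrate of predictive remapping).
#' @param corollary_discharge logical; the CD input.  When `FALSE` the
#'   anticipatory eye-position signal is silent, so the remapping feedback is
#'   inert as well.
#' @param variant `"intermediate"` (explicit head-centred cells) or
#'   `"lateral"` (direct LIP(PC) to LIP(CD) projection, no intermediate
#'   state and hence no recurrent stabilisation loop).
#' @return A list of class `lip_ablation`.
#' @export
#' @examples
#' lip_ablation()                              # full model
#' lip_ablation(remapping_feedback = FALSE)    # no predictive remapping
lip_ablation <- function(remapping_feedback = TRUE,
                         corollary_discharge = TRUE,
                         variant = c("intermediate", "lateral")) {
  variant <- match.arg(variant)
  structure(list(remapping_feedback = isTRUE(remapping_feedback),
                 corollary_discharge = isTRUE(corollary_discharge),
                 variant = variant),
            class = c("lip_ablation", "list"))
}

#' Hash of a configuration
#'
#' Stable hash used to key template caches and stamp run metadata.
#'
#' @param config a [lip_config()] object.
#' @param ... further objects folded into the hash (e.g. an ablation).
#' @return A character scalar.
#' @export
config_hash <- function(config, ...) {
  hash(list(unclass(config), lapply(list(...), unclass)))
}

#' Read / write a configuration as YAML
#'
#' @param path file path.
#' @param config a [lip_config()] object.
#' @return `read_config()` returns a `lip_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  lip_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
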