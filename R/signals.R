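#' Receptive-field width as a function of eccentricity
#'
#' Linear law `sigma(e) = sigma0 + slope * |e|`, clamped at the field edge:
#' eccentricities beyond `v/2` are treated as `v/2`.  Foveal width and slope
#' come from the configuration (`rf$sigma0`, `rf$slope`).
#'
#' @param eccentricity degrees (vectorised).
#' @param config a [lip_config()].
#' @return Width in degrees, strictly positive and non-decreasing in
#'   `|eccentricity|`.
#' @export
#' @examples
#' rf_width(0, lip_config())    # 4
#' rf_width(40, lip_config())   # 6
rf_width <- function(eccentricity, config = lip_config()) {
  e <- pmin(abs(eccentricity), config$grid$v / 2)
  config$rf$sigma0 + config$rf$slope * e
}

#' Stimulus set for a trial
#'
#' Builds the stimulus table used by the paradigm runners.  Positions are
#' head-centred; the retinal position at time `t` is
#' `position - eye_position(t)` and is computed by [retinal_drive()].
#'
#' @param position head-centred position in degrees.
#' @param onset,offset on/off times in ms (`offset > onset`).
#' @param intensity drive amplitude (> 0).
#' @return A tibble with one row per stimulus.
#' @export
stimulus_set <- function(position, onset, offset, intensity = 1) {
  s <- tibble::tibble(position = position, onset = onset, offset = offset,
                      intensity = intensity)
  if (any(s$offset <= s$onset)) abort("stimulus offset must exceed onset")
  if (any(s$intensity <= 0)) abort("stimulus intensity must be positive")
  s
}

#' Drive of the retinotopic input map
#'
#' Each retinal neuron `i` receives
#' `I_i = intensity * exp(-((pos - eye) - c_i)^2 / rf_width(c_i)^2)`
#' summed over the stimuli that are on at time `t`, gain-modulated by
#' attentional feedback from the LIP(PC) map through the saturating
#' nonlinearity `f(x) = gain * x / (1 + x)`:
#' `drive_i = I_i * (1 + f(fb_i))`.
#'
#' @param stimuli a [stimulus_set()] tibble (head-centred positions).
#' @param eye_position current eye position in degrees.
#' @param grid the retinal [make_grid()].
#' @param fb non-negative feedback vector (per retinal neuron), or `NULL`.
#' @param t time in ms.
#' @param config a [lip_config()].
#' @return Drive vector of length `grid$n`; all zero when no stimulus is on.
#' @export
retinal_drive <- function(stimuli, eye_position, grid, fb = NULL, t = 0,
                          config = lip_config()) {
  drive <- numeric(grid$n)
  if (!is.null(stimuli) && nrow(stimuli) > 0) {
    on <- stimuli$onset <= t & t < stimuli$offset
    if (any(on)) {
      w <- rf_width(grid$centers, config)
      for (k in which(on)) {
        retinal <- stimuli$position[k] - eye_position
        drive <- drive +
          stimuli$intensity[k] * exp(-((retinal - grid$centers) / w)^2)
      }
    }
  }
  if (!is.null(fb) && config$attention$enabled) {
    if (any(fb < 0)) abort("feedback rates must be non-negative")
    drive <- drive * (1 + config$attention$gain * fb / (1 + fb))
  }
  drive
}

# registered (proprioceptive) eye position at time t: holds the pre-saccadic
# value until saccade offset + delay, then moves linearly to the executed
# post-saccadic position over `transition` ms.
registered_eye <- function(t, saccade, config) {
  if (is.null(saccade)) return(rep(0, length(t)))
  t0 <- saccade$offset + config$pc$delay
  t1 <- t0 + config$pc$transition
  pre <- saccade$fixation
  post <- saccade$fixation + saccade$executed_amplitude
  frac <- pmin(pmax((t - t0) / (t1 - t0), 0), 1)
  pre + frac * (post - pre)
}

#' Drive of the proprioceptive eye-position map
#'
#' Gaussian activity profile (width `pc$sigma` degrees) centred on the
#' *registered* eye position, which stays at the pre-saccadic fixation until
#' `saccade$offset + pc$delay` ms and then shifts linearly to the executed
#' post-saccadic position over `pc$transition` ms — the late update of eye
#' position information in parietal cortex.
#'
#' @param t time in ms.
#' @param saccade a [make_trajectory()] event, or `NULL` during fixation.
#' @param grid the eye-position [make_grid()].
#' @param config a [lip_config()].
#' @return Drive vector of length `grid$n`.
#' @export
pc_eye_drive <- function(t, saccade, grid, config = lip_config()) {
  e <- registered_eye(t, saccade, config)
  exp(-((grid$centers - e) / config$pc$sigma)^2)
}

#' Temporal envelope of the corollary discharge
#'
#' Gaussian rise before saccade onset (width `sigma_rise` ms) and a slower
#' Gaussian decay after (width `sigma_decay` ms), peaking at 1 exactly at
#' saccade onset.
#'
#' @param t time in ms (vectorised).
#' @param onset saccade onset in ms.
#' @param config a [lip_config()].
#' @return Envelope values in `[0, 1]`.
#' @export
cd_envelope <- function(t, onset, config = lip_config()) {
  d <- t - onset
  s <- ifelse(d < 0, config$cd$sigma_rise, config$cd$sigma_decay)
  exp(-(d / s)^2)
}

#' Drive of the corollary-discharge map
#'
#' Gaussian spatial profile (width `cd$sigma` degrees) centred on the CD
#' displacement amplitude — the planned retinotopic saccade vector minus the
#' average undershoot — multiplied by the [cd_envelope()].
#'
#' @inheritParams pc_eye_drive
#' @param enabled set `FALSE` to silence the CD input (ablation).
#' @return Drive vector of length `grid$n`.
#' @export
cd_drive <- function(t, saccade, grid, config = lip_config(),
                     enabled = TRUE) {
  if (is.null(saccade) || !enabled) return(numeric(grid$n))
  env <- cd_envelope(t, saccade$onset, config)
  env * exp(-((grid$centers - saccade$cd_amplitude) / config$cd$sigma)^2)
}

#' Anticipatory eye-position signal from the FEF gain field
#'
#' Transforms eye displacement into eye position: the smoothed CD and
#' proprioceptive eye-position populations form a 2-D product map
#' (displacement x current position) whose diagonal sums yield a 1-D
#' population over the diagonal axis.  Its peak encodes
#' `current eye position + CD displacement`, i.e. the anticipated
#' post-saccadic eye position, and it inherits the CD temporal envelope
#' (silent whenever the CD is silent).
#'
#' @param cd rate vector of the CD map.
#' @param pc rate vector of the eye-position map.
#' @param ops model operators from [lip_operators()].
#' @return Drive vector over the `2n - 1` diagonal bins
#'   (positions `ops$diag_positions`).
#' @export
fef_transform <- function(cd, pc, ops) {
  if (length(cd) != length(pc)) abort("cd and pc must share a grid")
  cdk <- drop(ops$Wsm %*% cd)
  pck <- drop(ops$Wsm %*% pc)
  prod2d <- outer(cdk, pck)
  raw <- as.vector(rowsum(as.vector(prod2d), ops$diag_group))
  ops$fef_gain * raw / ops$norm_fef
}
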