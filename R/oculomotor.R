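#' Saccadic endpoint scatter
#'
#' Trial-to-trial endpoint error drawn from `N(mean, sd)` (defaults: mean
#' undershoot 0.52 deg, SD 0.58 deg).  The draw is *subtracted* from the
#' intended amplitude to obtain the executed amplitude.  The scatter arises on
#' the motor side, so it is not reflected in the CD signal; the CD amplitude
#' only discounts the average undershoot.
#'
#' @param n number of draws.
#' @param config a [lip_config()].
#' @return Signed endpoint errors in degrees.
#' @export
#' @examples
#' set.seed(1); mean(sample_scatter(1e4))  # ~0.52
sample_scatter <- function(n = 1, config = lip_config()) {
  rnorm(n, mean = config$saccade$undershoot_mean,
        sd = config$saccade$undershoot_sd)
}

#' Saccade event with a smooth trajectory
#'
#' Duration follows the main-sequence law `D = d0 + d1 * |amplitude|`
#' (defaults 23 ms + 2.7 ms/deg).  The eye-position profile is a smoothstep
#' sigmoid `3u^2 - 2u^3` between onset and offset, so velocity peaks at the
#' midpoint and vanishes at both endpoints.
#'
#' @param amplitude intended amplitude in degrees (non-zero).
#' @param onset saccade onset in ms.
#' @param fixation pre-saccadic fixation position in degrees.
#' @param scatter endpoint error in degrees (see [sample_scatter()]); the
#'   executed amplitude is `amplitude - scatter`.
#' @param config a [lip_config()].
#' @return An object of class `lip_saccade`: intended and executed amplitude,
#'   `onset`, `offset`, `duration`, `fixation`, and the CD amplitude
#'   `amplitude - undershoot_mean`.
#' @export
#' @examples
#' s <- make_trajectory(8, onset = 500)
#' s$duration          # 23 + 2.7*8 = 44.6
#' eye_position(s, c(0, 500, 600))
make_trajectory <- function(amplitude, onset, fixation = 0, scatter = 0,
                            config = lip_config()) {
  if (amplitude == 0) abort("saccade amplitude must be non-zero")
  duration <- config$saccade$d0 + config$saccade$d1 * abs(amplitude)
  structure(list(
    intended_amplitude = amplitude,
    executed_amplitude = amplitude - scatter,
    cd_amplitude = amplitude - sign(amplitude) *
      config$saccade$undershoot_mean,
    onset = onset,
    offset = onset + duration,
    duration = duration,
    fixation = fixation
  ), class = "lip_saccade")
}

#' Eye position along a saccade trajectory
#'
#' @param saccade a [make_trajectory()] event (or `NULL` for steady fixation
#'   at 0 deg).
#' @param t time in ms (vectorised).
#' @return Eye position in degrees.
#' @export
eye_position <- function(saccade, t) {
  if (is.null(saccade)) return(rep(0, length(t)))
  u <- pmin(pmax((t - saccade$onset) / saccade$duration, 0), 1)
  saccade$fixation + saccade$executed_amplitude * (3 * u^2 - 2 * u^3)
}

#' Trial event schedule for a paradigm
#'
#' Expands a paradigm definition into an ordered event table with exact ms
#' times.  For the SSD paradigm the target appears `target_lead` ms before
#' saccade onset and is displaced `displacement_delay` ms (default 30) after
#' onset; in the blank condition it is extinguished at that time instead and
#' reappears displaced after `blank_gap` ms (default 250).  For the remapping
#' paradigm a `flash_duration` ms flash is emitted at the requested time.
#'
#' @param paradigm `"ssd"` or `"remap"`.
#' @param saccade a [make_trajectory()] event.
#' @param config a [lip_config()].
#' @param displacement target displacement in degrees (SSD).
#' @param blank logical; SSD blanking condition.
#' @param flash_time flash onset relative to saccade onset in ms (remapping).
#' @param flash_position head-centred flash position in degrees (remapping).
#' @return A tibble with columns `time`, `event`, `position`, ordered by
#'   time.
#' @export
#' @examples
#' s <- make_trajectory(8, onset = 500)
#' schedule_events("ssd", s, displacement = 1)       # displacement at 530
#' schedule_events("ssd", s, displacement = 1, blank = TRUE)  # reappears 780
schedule_events <- function(paradigm = c("ssd", "remap"), saccade,
                            config = lip_config(), displacement = 0,
                            blank = FALSE, flash_time = 0,
                            flash_position = 0) {
  paradigm <- match.arg(paradigm)
  on <- saccade$onset
  if (paradigm == "ssd") {
    target <- saccade$fixation + saccade$intended_amplitude
    t_on <- on - config$ssd$target_lead
    t_disp <- on + config$ssd$displacement_delay
    if (t_on >= t_disp) {
      abort("target onset must precede the displacement event")
    }
    ev <- tibble::tibble(
      time = c(t_on, t_disp),
      event = c("target_on", if (blank) "target_off" else "displacement"),
      position = c(target, if (blank) NA_real_ else target + displacement)
    )
    if (blank) {
      ev <- dplyr::bind_rows(ev, tibble::tibble(
        time = t_disp + config$ssd$blank_gap,
        event = "reappearance",
        position = target + displacement
      ))
    }
  } else {
    t_on <- on + flash_time
    ev <- tibble::tibble(
      time = c(t_on, t_on + config$remap$flash_duration),
      event = c("flash_on", "flash_off"),
      position = c(flash_position, NA_real_)
    )
  }
  ev <- dplyr::bind_rows(
    ev,
    tibble::tibble(time = c(on, saccade$offset),
                   event = c("saccade_onset", "saccade_offset"),
                   position = NA_real_)
  )
  ev <- dplyr::arrange(ev, .data$time)
  if (anyDuplicated(ev[, c("time", "event")])) {
    abort("contradictory schedule: duplicated events at the same time")
  }
  ev
}

# stimulus table implied by an SSD schedule
ssd_stimuli <- function(saccade, config, displacement, blank, t_end) {
  target <- saccade$fixation + saccade$intended_amplitude
  t_on <- saccade$onset - config$ssd$target_lead
  t_disp <- saccade$onset + config$ssd$displacement_delay
  if (blank) {
    stimulus_set(
      position = c(target, target + displacement),
      onset = c(t_on, t_disp + config$ssd$blank_gap),
      offset = c(t_disp, t_end)
    )
  } else {
    stimulus_set(
      position = c(target, target + displacement),
      onset = c(t_on, t_disp),
      offset = c(t_disp, t_end)
    )
  }
}
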