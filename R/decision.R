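#' Input to the decision process
#'
#' With intermediate cells the decision input is the head-centred population
#' itself.  In the lateral variant an equivalent head-centred profile is read
#' out directly from the two LIP maps with the diagonal Gaussian kernels
#' (widths 15 index units, peak gains 0.035 and 0.02).
#'
#' @param state a [lip_state()].
#' @param variant `"intermediate"` or `"lateral"`.
#' @param ops [lip_operators()].
#' @return Numeric vector over the `2n - 1` head-centred bins.
#' @export
decision_input <- function(state, variant = "intermediate", ops) {
  if (variant == "intermediate") {
    state$xh
  } else {
    drive_xh(state$xb_pc, state$xb_cd, ops)
  }
}

# package-local template cache
the <- new.env(parent = emptyenv())
the$templates <- list()

#' Precalculated decision templates
#'
#' Expected decision-input pattern for a stimulus at each lattice position
#' `c` during steady fixation, on a 0.5-degree lattice.  Each
#' template is obtained by integrating the circuit to steady state with a
#' stimulus at `c` and recording the decision input; columns are normalised
#' to unit Euclidean norm (matched filters), which keeps the match argmax
#' aligned with the encoded position despite eccentricity-dependent
#' receptive-field widths.
#' Results are cached per configuration hash and variant.
#'
#' @param config a [lip_config()].
#' @param positions template positions in degrees (default: a lattice of
#'   half-width `decision$template_halfwidth` around `center` with step
#'   `decision$template_step`).
#' @param center lattice centre used when `positions` is `NULL`.
#' @param eye fixation eye position (degrees) at which the templates are
#'   recorded.  Displacement decisions rely on the post-saccadic view, so
#'   the SSD runners build their templates at the anticipated post-saccadic
#'   fixation.
#' @param variant `"intermediate"` or `"lateral"`.
#' @param ops optional [lip_operators()].
#' @param cache use the in-memory cache.
#' @return A list of class `lip_templates`: `matrix` (head-centred bins x
#'   positions), `positions`, `eye`, `variant`.
#' @export
build_templates <- function(config = lip_config(), positions = NULL,
                            center = 0, eye = 0, variant = "intermediate",
                            ops = NULL, cache = TRUE) {
  if (is.null(positions)) {
    hw <- config$decision$template_halfwidth
    positions <- seq(center - hw, center + hw,
                     by = config$decision$template_step)
  }
  key <- hash(list(unclass(config), positions, eye, variant))
  if (cache && !is.null(the$templates[[key]])) {
    return(the$templates[[key]])
  }
  if (is.null(ops)) ops <- lip_operators(config)
  settle <- config$decision$settle
  abl <- lip_ablation(variant = variant)
  sac <- if (eye != 0) {
    make_trajectory(eye, onset = -5000, scatter = 0, config = config)
  } else NULL
  tm <- matrix(0, ops$nd, length(positions))
  for (j in seq_along(positions)) {
    trial <- simulate_trial(config, abl, saccade = sac,
                            stimuli = stimulus_set(positions[j], 0,
                                                   settle + 1),
                            t_end = settle, ops = ops, record = "idp")
    tm[, j] <- trial$idp[, ncol(trial$idp)]
  }
  cs <- sqrt(colSums(tm^2))
  cs[cs == 0] <- 1
  tm <- sweep(tm, 2, cs, `/`)
  out <- structure(list(matrix = tm, positions = positions, eye = eye,
                        variant = variant, key = key),
                   class = "lip_templates")
  if (cache) the$templates[[key]] <- out
  out
}

#' Template matching by correlation
#'
#' `m_c = sum_j I_j t^c_j`: the dot product of the decision input with each
#' template (no mean-centering), scaled by `decision$match_gain`.
#'
#' @param idp decision-input vector.
#' @param templates a [build_templates()] object.
#' @param config a [lip_config()].
#' @return Named numeric vector of matches, one per template position.
#' @export
template_match <- function(idp, templates, config = lip_config()) {
  if (length(idp) != nrow(templates$matrix)) {
    abort("decision input length does not match the templates")
  }
  m <- config$decision$match_gain * drop(crossprod(templates$matrix, idp))
  names(m) <- templates$positions
  m
}

#' Poisson spike-train transform of a match value
#'
#' Over `bins` sub-steps the unit spikes (value `s_max`) iff
#' `m_c > R * s_max` with a fresh uniform `R` per sub-step; the mean over
#' sub-steps is returned.  Its expectation is `min(m_c / s_max, 1) * s_max`.
#' Vectorised over `m_c`; consumes the session RNG.
#'
#' @param m_c non-negative match value(s).
#' @param bins sub-steps per model time step.
#' @param s_max spike amplitude.
#' @return Averaged spike values, same length as `m_c`.
#' @export
poissonize <- function(m_c, bins = 20, s_max = 1) {
  if (any(m_c < 0)) abort("match values must be non-negative")
  nc <- length(m_c)
  r <- matrix(runif(bins * nc), bins, nc)
  s_max * colMeans(r < rep(m_c / s_max, each = bins))
}

#' Split matches into forward and backward evidence
#'
#' Using the pre-saccadic stimulus position `c_pre` as the decision border:
#' `m_f = sum_{c >= c_pre} m_c`, `m_b = sum_{c <= c_pre} m_c`.  The border
#' bin contributes to both sums.  An off-lattice `c_pre` is snapped to the
#' nearest template position with a warning.
#'
#' @param m match vector (named by position, as from [template_match()]).
#' @param positions template positions (degrees).
#' @param c_pre decision border (degrees).
#' @return Named list with `m_f`, `m_b`, and the snapped `c_pre`.
#' @export
split_evidence <- function(m, positions, c_pre) {
  j <- which.min(abs(positions - c_pre))
  if (abs(positions[j] - c_pre) > 1e-9) {
    warn(sprintf("c_pre = %g is off the template lattice; snapped to %g",
                 c_pre, positions[j]))
    c_pre <- positions[j]
  }
  list(m_f = sum(m[positions >= c_pre]),
       m_b = sum(m[positions <= c_pre]),
       c_pre = c_pre)
}

#' Competition between the decision inputs
#'
#' Mutual subtraction computed simultaneously from the pre-update values:
#' `m_f' = m_f - m_b`, `m_b' = m_b - m_f`, so `m_f' + m_b' = 0` always.
#'
#' @param m_f,m_b forward/backward evidence.
#' @return Named list with competed `m_f`, `m_b`.
#' @export
compete <- function(m_f, m_b) {
  list(m_f = m_f - m_b, m_b = m_b - m_f)
}

# fresh accumulator trace
decision_trace <- function(templates = NULL, c_pre = NA_real_,
                           config = lip_config()) {
  if (!is.null(templates) && !is.na(c_pre)) {
    pos <- templates$positions
    j <- which.min(abs(pos - c_pre))
    if (abs(pos[j] - c_pre) > 1e-9) {
      warn(sprintf("c_pre = %g is off the template lattice; snapped to %g",
                   c_pre, pos[j]))
    }
    c_pre <- pos[j]
  }
  structure(list(
    templates = templates, c_pre = c_pre,
    d_f = config$decision$baseline, d_b = config$decision$baseline,
    d_thresh = config$decision$d_thresh, tau = config$tau$dn,
    timeout = config$decision$timeout, elapsed = 0,
    d_f_path = numeric(0), d_b_path = numeric(0),
    done = FALSE, outcome = NA_character_, decision_time = NA_real_,
    timed_out = FALSE, start = 0, config = config
  ), class = "lip_decision")
}

#' Accumulate competed evidence in the decision neurons
#'
#' Pure integrators `d += (dt / tau_dn) * m`, floored at zero (firing-rate
#' semantics), both initialised at the 0.1 baseline.  The first accumulator
#' to reach the decision threshold wins; if neither crosses within the
#' 100-ms timeout the larger one wins, exact ties broken by a seeded coin
#' flip.
#'
#' @param trace a `lip_decision` trace (create one with
#'   `new_decision_trace()`).
#' @param m_f,m_b competed evidence values (from [compete()]).
#' @param dt step in ms.
#' @return The updated trace; once finished, fields `outcome` (`"forward"`
#'   or `"backward"`), `decision_time` (ms since accumulation start) and
#'   `timed_out` are set.
#' @export
accumulate <- function(trace, m_f, m_b, dt = 1) {
  if (trace$done) return(trace)
  trace$d_f <- max(trace$d_f + (dt / trace$tau) * m_f, 0)
  trace$d_b <- max(trace$d_b + (dt / trace$tau) * m_b, 0)
  trace$elapsed <- trace$elapsed + dt
  trace$d_f_path <- c(trace$d_f_path, trace$d_f)
  trace$d_b_path <- c(trace$d_b_path, trace$d_b)
  if (trace$d_f >= trace$d_thresh || trace$d_b >= trace$d_thresh) {
    trace$done <- TRUE
    trace$outcome <- if (trace$d_f >= trace$d_b) "forward" else "backward"
    trace$decision_time <- trace$elapsed
  } else if (trace$elapsed >= trace$timeout) {
    trace <- decision_finish(trace)
  }
  trace
}

#' @rdname accumulate
#' @export
new_decision_trace <- function(config = lip_config()) {
  decision_trace(config = config)
}

decision_finish <- function(trace) {
  trace$done <- TRUE
  trace$timed_out <- TRUE
  trace$decision_time <- trace$elapsed
  if (trace$d_f == trace$d_b) {
    trace$outcome <- if (runif(1) < 0.5) "forward" else "backward"
  } else {
    trace$outcome <- if (trace$d_f > trace$d_b) "forward" else "backward"
  }
  trace
}

# one inline decision update from a decision-input vector
decision_step <- function(trace, idp, dt = 1) {
  m <- template_match(idp, trace$templates, trace$config)
  sp <- poissonize(m, trace$config$decision$bins, trace$config$decision$s_max)
  ev <- split_evidence(sp, trace$templates$positions, trace$c_pre)
  cm <- compete(ev$m_f, ev$m_b)
  accumulate(trace, cm$m_f, cm$m_b, dt)
}

#' Start time of the evidence accumulation
#'
#' 28 ms after saccade offset when the displaced stimulus reappears during
#' the saccade (peri-saccadic detectability is suppressed, so the decision
#' relies on the post-saccadic view), and 60 ms after stimulus onset when it
#' reappears after saccade offset.  A reappearance exactly at saccade offset
#' counts as post-saccadic.
#'
#' @param saccade a [make_trajectory()] event.
#' @param reappearance_time time (ms) at which the displaced stimulus
#'   (re)appears.
#' @param config a [lip_config()].
#' @return Accumulation start time in ms.
#' @export
#' @examples
#' s <- make_trajectory(8, onset = 500)   # offset 544.6
#' accumulation_start(s, 530)             # peri-saccadic: offset + 28
#' accumulation_start(s, 780)             # post-saccadic: 780 + 60
accumulation_start <- function(saccade, reappearance_time,
                               config = lip_config()) {
  if (reappearance_time < saccade$offset) {
    saccade$offset + config$decision$offset_delay
  } else {
    reappearance_time + config$decision$stim_delay
  }
}
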