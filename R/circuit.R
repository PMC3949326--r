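#' Precomputed model operators
#'
#' Builds every connection matrix and index table the simulator needs:
#' normalised Gaussian input kernels (degree metric, width
#' `kernel$sigma_deg`), the diagonal-sum grouping of the 2-D maps, the
#' Eq.-style diagonal readout kernels into the head-centred axis (index
#' metric, width `kernel$sigma_diag`, peak gains `k_pc` / `k_cd`), the
#' smoothing kernel used by the remapping feedback, and the normalisation
#' constant of the FEF gain-field transform.
#'
#' @param config a [lip_config()].
#' @return A list of class `lip_operators`; fields include the retinal/eye
#'   grid (`grid`), the diagonal-axis positions (`diag_positions`, length
#'   `2n - 1`, spanning `[-v, v]`), and the weight matrices.
#' @export
lip_operators <- function(config = lip_config()) {
  n <- config$grid$n
  grid <- make_grid(n, config$grid$v)
  nd <- 2L * n - 1L
  # head-centred position of diagonal bin s (cells with l + m = s + 1):
  # centers[l] + centers[m] = -v + (s - 1) * spacing
  diag_positions <- seq(-config$grid$v, config$grid$v, length.out = nd)

  # normalised degree-space smoothing kernel (input bumps into the 2-D maps)
  Wsm <- gaussian_kernel(grid, grid, K = 1, sigma = config$kernel$sigma_deg,
                         normalize = TRUE)$matrix

  # diagonal-sum grouping: cell (l, m) belongs to bin l + m - 1
  IDX <- outer(seq_len(n), seq_len(n), `+`) - 1L
  diag_group <- as.vector(IDX)

  # Gaussian on the head-centred diagonal axis (Eq-style readout kernels);
  # sigma_diag is in degrees of head-centred position
  G79 <- exp(-outer(diag_positions, diag_positions, `-`)^2 /
               config$kernel$sigma_diag^2)
  Wg_pc <- config$kernel$k_pc * G79
  Wg_cd <- config$kernel$k_cd * G79
  Whs <- G79 / rowSums(G79)          # normalised smoothing for feedback

  # fef (diagonal axis) onto the eye-position columns of LIP(CD), degrees
  dfe <- outer(grid$centers, diag_positions, `-`)
  Wfef <- exp(-dfe^2 / config$kernel$sigma_deg^2)
  Wfef <- Wfef / rowSums(Wfef)

  ops <- list(grid = grid, n = n, nd = nd, diag_positions = diag_positions,
              Wsm = Wsm, IDX = IDX, diag_group = diag_group,
              Wg_pc = Wg_pc, Wg_cd = Wg_cd, Whs = Whs, Wfef = Wfef,
              fef_gain = config$fef$gain, norm_fef = 1)
  # normalisation of the gain-field transform: two unit bumps at the field
  # centre must map to a unit-peak output
  ref <- exp(-(grid$centers / config$pc$sigma)^2)
  cdk <- drop(Wsm %*% ref)
  raw <- drop(rowsum(as.vector(outer(cdk, cdk)), diag_group))
  ops$norm_fef <- max(raw)
  class(ops) <- "lip_operators"
  ops
}

# diagonal sums of a 2-D map (length 2n - 1)
diag_sums <- function(m, ops) {
  as.vector(rowsum(as.vector(m), ops$diag_group))
}

#' Fresh circuit state
#'
#' All seven populations at rest (zero rates).
#'
#' @param config a [lip_config()].
#' @param ops optional precomputed [lip_operators()].
#' @return A list of class `lip_state` with rate arrays `xr`, `xe_pc`,
#'   `xe_cd`, `xe_fef`, `xb_pc`, `xb_cd`, `xh`.
#' @export
lip_state <- function(config = lip_config(), ops = lip_operators(config)) {
  n <- ops$n
  structure(list(
    xr = numeric(n), xe_pc = numeric(n), xe_cd = numeric(n),
    xe_fef = numeric(ops$nd),
    xb_pc = matrix(0, n, n), xb_cd = matrix(0, n, n),
    xh = numeric(ops$nd)
  ), class = "lip_state")
}

#' Drive of the LIP(PC) gain-field map
#'
#' `drive(l, m) = (smoothed xr)(l) * (smoothed xe_pc)(m)`: the outer product
#' of the Gaussian-kernelled retinal and eye-position populations, maximal at
#' the intersection of the two input bumps.
#'
#' @param xr retinal rate vector.
#' @param xe_pc eye-position rate vector.
#' @param ops [lip_operators()].
#' @return `n x n` drive matrix (rows: retinal position, columns: eye
#'   position).
#' @export
drive_xb_pc <- function(xr, xe_pc, ops) {
  outer(drop(ops$Wsm %*% xr), drop(ops$Wsm %*% xe_pc))
}

#' Drive of the LIP(CD) gain-modulation map
#'
#' Feedforward term `cd_ff_gain * xr_k(l) * (1 + fef_k(m))` — the cells
#' respond to their
#' visual input even with a silent CD, and the anticipatory eye-position
#' signal multiplies the gain of the columns tuned to the future eye
#' position — plus, when the remapping feedback is enabled and the variant
#' has intermediate cells, the diagonal feedback
#' `fb_gain * xh_smoothed(l + m) * fef_k(m)`.
#'
#' For a purely visual cell class (`config$circuit$gain_modulated = FALSE`)
#' the feedforward gain term is dropped (the remapping path is unaffected).
#'
#' @param xr retinal rate vector.
#' @param xe_fef anticipatory eye-position rate vector (diagonal axis).
#' @param xh intermediate-cell (head-centred) rate vector.
#' @param ops [lip_operators()].
#' @param config a [lip_config()].
#' @param ablation a [lip_ablation()].
#' @return `n x n` drive matrix (rows: retinal position, columns: future eye
#'   position).
#' @export
drive_xb_cd <- function(xr, xe_fef, xh, ops, config = lip_config(),
                        ablation = lip_ablation()) {
  n <- ops$n
  xr_k <- config$circuit$cd_ff_gain * drop(ops$Wsm %*% xr)
  fef_col <- drop(ops$Wfef %*% xe_fef)
  if (isTRUE(config$circuit$gain_modulated)) {
    ff <- outer(xr_k, 1 + fef_col)
  } else {
    ff <- matrix(xr_k, n, n)
  }
  if (ablation$remapping_feedback && ablation$variant == "intermediate" &&
      max(fef_col) > 1e-12) {
    xhs <- drop(ops$Whs %*% xh)
    xhs <- xhs / (1 + xhs)        # bounded synaptic transfer keeps the
    fb <- xhs[ops$IDX]            # xh <-> LIP(CD) loop gain below one
    dim(fb) <- c(n, n)
    ff <- ff + config$circuit$fb_gain * fb * rep(fef_col, each = n)
  }
  ff
}

#' Drive of LIP(CD) in the lateral-connection variant
#'
#' Same as [drive_xb_cd()] but the diagonal input comes directly from the
#' diagonal sums of LIP(PC) (no intermediate state, hence no recurrent loop
#' back through the head-centred cells).
#'
#' @param xb_pc LIP(PC) rate matrix.
#' @inheritParams drive_xb_cd
#' @return `n x n` drive matrix.
#' @export
lateral_variant_drive <- function(xr, xe_fef, xb_pc, ops,
                                  config = lip_config(),
                                  ablation = lip_ablation(variant = "lateral")) {
  if (ablation$variant != "lateral") {
    abort("lateral_variant_drive requires variant = 'lateral'")
  }
  n <- ops$n
  xr_k <- config$circuit$cd_ff_gain * drop(ops$Wsm %*% xr)
  fef_col <- drop(ops$Wfef %*% xe_fef)
  if (isTRUE(config$circuit$gain_modulated)) {
    ff <- outer(xr_k, 1 + fef_col)
  } else {
    ff <- matrix(xr_k, n, n)
  }
  if (ablation$remapping_feedback && max(fef_col) > 1e-12) {
    lat <- drop(ops$Wg_pc %*% diag_sums(xb_pc, ops))
    lats <- drop(ops$Whs %*% lat)
    lats <- lats / (1 + lats)     # same bounded transfer as the
    fb <- lats[ops$IDX]           # intermediate-cell path
    dim(fb) <- c(n, n)
    ff <- ff + config$circuit$lat_gain * fb * rep(fef_col, each = n)
  }
  ff
}

#' Drive of the intermediate (head-centred) cells
#'
#' For head-centred bin `h`:
#' `drive(h) = sum_lm k_pc * exp(-(h + 1 - l - m)^2 / sigma^2) * xb_pc(l, m)
#'           + sum_lm k_cd * exp(-(h + 1 - l - m)^2 / sigma^2) * xb_cd(l, m)`
#' — a Gaussian-weighted collection of all activity along the diagonals of
#' both LIP maps, which makes the representation invariant to the eye
#' position the activity is paired with.
#'
#' @param xb_pc,xb_cd LIP rate matrices.
#' @param ops [lip_operators()].
#' @return Drive vector over the `2n - 1` head-centred bins.
#' @export
drive_xh <- function(xb_pc, xb_cd, ops) {
  drop(ops$Wg_pc %*% diag_sums(xb_pc, ops) +
         ops$Wg_cd %*% diag_sums(xb_cd, ops))
}

#' One synchronous circuit step
#'
#' Advances every population by one Euler step of length `dt`.  All drives
#' are computed from the *previous* state, so the update order is
#' immaterial.
#'
#' @param state a [lip_state()].
#' @param inputs list with elements `xr`, `xe_pc`, `xe_cd`: the external
#'   drive vectors at the current time.
#' @param ops [lip_operators()].
#' @param config a [lip_config()].
#' @param ablation a [lip_ablation()].
#' @param dt step in ms.
#' @return The updated state.
#' @export
step_lip <- function(state, inputs, ops, config = lip_config(),
                     ablation = lip_ablation(), dt = config$dt) {
  cv <- dt / config$tau$visual
  cl <- dt / config$tau$lip
  d_fef <- if (max(state$xe_cd) > 1e-12) {
    fef_transform(state$xe_cd, state$xe_pc, ops)
  } else numeric(ops$nd)
  d_bpc <- drive_xb_pc(state$xr, state$xe_pc, ops)
  if (ablation$variant == "lateral") {
    d_bcd <- lateral_variant_drive(state$xr, state$xe_fef, state$xb_pc, ops,
                                   config, ablation)
  } else {
    d_bcd <- drive_xb_cd(state$xr, state$xe_fef, state$xh, ops, config,
                         ablation)
  }
  d_xh <- drive_xh(state$xb_pc, state$xb_cd, ops)

  state$xr <- step_rates(state$xr, inputs$xr, cv)
  state$xe_pc <- step_rates(state$xe_pc, inputs$xe_pc, cv)
  state$xe_cd <- step_rates(state$xe_cd, inputs$xe_cd, cv)
  state$xe_fef <- step_rates(state$xe_fef, d_fef, cv)
  state$xb_pc <- step_rates(state$xb_pc, d_bpc, cl)
  state$xb_cd <- step_rates(state$xb_cd, d_bcd, cl)
  state$xh <- step_rates(state$xh, d_xh, dt / config$tau$xh)
  state
}

#' Simulate one trial of the circuit
#'
#' Integrates the full model from rest over `t_end` ms with the given
#' stimulus table and saccade, optionally running the displacement-decision
#' readout inline and recording traces.
#'
#' @param config a [lip_config()].
#' @param ablation a [lip_ablation()].
#' @param saccade a [make_trajectory()] event or `NULL` (steady fixation).
#' @param stimuli a [stimulus_set()] tibble (head-centred positions) or
#'   `NULL`.
#' @param t_end simulated duration in ms.
#' @param ops optional precomputed [lip_operators()].
#' @param decision optional list describing a displacement decision:
#'   `templates` (a [build_templates()] object), `c_pre` (decision border in
#'   degrees), `start` (accumulation start time in ms).  Uses the session
#'   RNG; seed beforehand for reproducibility.
#' @param track_cell optional `c(l, m)` index pair of a LIP(CD) cell whose
#'   rate is recorded every ms.
#' @param record character vector of extra traces to keep: `"idp"`
#'   (decision input every ms), `"xh"` (intermediate cells every ms).
#' @param snapshot_times times (ms) at which to store full map snapshots.
#' @return A list of class `lip_trial`: final `state`, `time` axis,
#'   requested traces, `decision` trace (see [accumulate()]), and
#'   `snapshots`.
#' @export
simulate_trial <- function(config = lip_config(),
                           ablation = lip_ablation(),
                           saccade = NULL, stimuli = NULL, t_end,
                           ops = NULL, decision = NULL, track_cell = NULL,
                           record = character(), snapshot_times = NULL) {
  if (is.null(ops)) ops <- lip_operators(config)
  dt <- config$dt
  nstep <- as.integer(ceiling(t_end / dt))
  state <- lip_state(config, ops)
  times <- seq_len(nstep) * dt

  cell_trace <- if (!is.null(track_cell)) numeric(nstep) else NULL
  idp_trace <- if ("idp" %in% record) {
    matrix(NA_real_, ops$nd, nstep)
  } else NULL
  xh_trace <- if ("xh" %in% record) matrix(NA_real_, ops$nd, nstep) else NULL
  snapshots <- if (!is.null(snapshot_times)) list() else NULL

  dec <- NULL
  if (!is.null(decision)) {
    dec <- decision_trace(decision$templates, decision$c_pre, config)
    dec$start <- decision$start
  }

  cd_on <- ablation$corollary_discharge
  for (k in seq_len(nstep)) {
    t <- times[k]
    eye <- eye_position(saccade, t)
    fb <- if (config$attention$enabled) rowSums(state$xb_pc) else NULL
    inputs <- list(
      xr = retinal_drive(stimuli, eye, ops$grid, fb, t, config),
      xe_pc = pc_eye_drive(t, saccade, ops$grid, config),
      xe_cd = cd_drive(t, saccade, ops$grid, config, enabled = cd_on)
    )
    state <- step_lip(state, inputs, ops, config, ablation, dt)

    if (!is.null(cell_trace)) {
      cell_trace[k] <- state$xb_cd[track_cell[1], track_cell[2]]
    }
    if (!is.null(idp_trace) || !is.null(dec)) {
      idp <- decision_input(state, ablation$variant, ops)
      if (!is.null(idp_trace)) idp_trace[, k] <- idp
      if (!is.null(dec) && !dec$done && t >= dec$start) {
        dec <- decision_step(dec, idp, dt)
      }
    }
    if (!is.null(xh_trace)) xh_trace[, k] <- state$xh
    if (!is.null(snapshot_times) && any(abs(snapshot_times - t) < dt / 2)) {
      snapshots[[sprintf("t%g", t)]] <- state
    }
  }
  if (!is.null(dec) && !dec$done) dec <- decision_finish(dec)

  structure(list(state = state, time = times, cell = cell_trace,
                 idp = idp_trace, xh = xh_trace, decision = dec,
                 snapshots = snapshots, saccade = saccade,
                 ablation = ablation),
            class = "lip_trial")
}
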