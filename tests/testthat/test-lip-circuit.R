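cfg <- default_cfg
ops <- default_ops

test_that("LIP(PC) drive is the outer product of the kernelled inputs", {
  n <- ops$n
  expect_equal(drive_xb_pc(numeric(n), rep(1, n), ops), matrix(0, n, n))

  # steady fixation: a single connected blob at (stimulus, eye) intersection
  tr <- steady_fixation(ops$grid$centers[25], eye = 0)
  blob <- tr$state$xb_pc
  idx <- unname(which(blob == max(blob), arr.ind = TRUE))
  expect_equal(idx[1, 1], 25L)
  expect_equal(idx[1, 2], nearest_idx(0, ops$grid$centers))
  above <- which(blob > 0.1 * max(blob), arr.ind = TRUE)
  # single connected region: occupied rows and columns are contiguous
  expect_equal(sort(unique(above[, 1])),
               seq(min(above[, 1]), max(above[, 1])))
  expect_equal(sort(unique(above[, 2])),
               seq(min(above[, 2]), max(above[, 2])))

  # moving the stimulus one grid step shifts the blob one row
  tr2 <- steady_fixation(ops$grid$centers[26], eye = 0)
  idx2 <- unname(which(tr2$state$xb_pc == max(tr2$state$xb_pc),
                       arr.ind = TRUE))
  expect_equal(idx2[1, 1], 26L)
  expect_equal(idx2[1, 2], idx[1, 2])
})

test_that("LIP(CD) cells respond to visual input even without CD", {
  n <- ops$n
  xr <- exp(-((ops$grid$centers - 8) / 5)^2)
  d <- drive_xb_cd(xr, numeric(ops$nd), numeric(ops$nd), ops, cfg,
                   lip_ablation())
  # silent anticipatory signal: purely visual rows, uniform across columns
  expect_gt(max(d), 0)
  expect_equal(max(apply(d, 1, function(r) diff(range(r)))), 0)
  expect_equal(which.max(d[, 1]), nearest_idx(8, ops$grid$centers))
})

test_that("remapping feedback peaks where the xh and fef bumps intersect", {
  n <- ops$n
  xh <- exp(-((ops$diag_positions - 8) / 8)^2)       # head-centred bump
  fef <- exp(-((ops$diag_positions - 14) / 6)^2)     # anticipated eye bump
  base <- drive_xb_cd(numeric(n), fef, numeric(ops$nd), ops, cfg,
                      lip_ablation())
  with_fb <- drive_xb_cd(numeric(n), fef, xh, ops, cfg, lip_ablation())
  fb <- with_fb - base
  expect_gt(max(fb), 0)

  # brute-force evaluation of the stated product over all (l, m)
  fef_col <- drop(ops$Wfef %*% fef)
  xhs <- drop(ops$Whs %*% xh)
  xhs <- xhs / (1 + xhs)
  expected <- matrix(0, n, n)
  for (l in 1:n) {
    for (m in 1:n) {
      expected[l, m] <- cfg$circuit$fb_gain * xhs[l + m - 1] * fef_col[m]
    }
  }
  expect_equal(fb, expected, tolerance = 1e-12)

  # with the feedback disabled and a stimulus only in the FRF, the
  # remapping cell receives no drive
  abl_off <- lip_ablation(remapping_feedback = FALSE)
  d_off <- drive_xb_cd(numeric(n), fef, xh, ops, cfg, abl_off)
  expect_equal(max(d_off), 0)
})

test_that("intermediate cells collect diagonal activity head-centredly", {
  n <- ops$n
  z <- matrix(0, n, n)
  expect_equal(drive_xh(z, z, ops), numeric(ops$nd))

  # single unit at (i, j) -> peak at diagonal bin i + j - 1, gain k_pc
  one <- z; one[12, 9] <- 1
  d <- drive_xh(one, z, ops)
  expect_equal(which.max(d), 12L + 9L - 1L)
  expect_equal(max(d), cfg$kernel$k_pc)
  # published kernel value one bin away (degree metric on the diagonal axis)
  sp <- diff(ops$diag_positions[1:2])
  expect_equal(d[21], cfg$kernel$k_pc * exp(-sp^2 / cfg$kernel$sigma_diag^2))

  # equal blobs on the same diagonal reinforce the same head-centred bin
  two <- one; two[13, 8] <- 1
  d2 <- drive_xh(two, z, ops)
  expect_equal(which.max(d2), 20L)
  expect_equal(d2, 2 * d)

  # the CD map feeds the same bins with gain k_cd
  dcd <- drive_xh(z, one, ops)
  expect_equal(dcd, d * cfg$kernel$k_cd / cfg$kernel$k_pc)
})

test_that("step_lip reaches a consistent steady state from constant input", {
  abl <- lip_ablation()
  state <- lip_state(cfg, ops)
  inputs <- list(
    xr = exp(-((ops$grid$centers - 4) / 4.2)^2),
    xe_pc = exp(-((ops$grid$centers - 0) / 6)^2),
    xe_cd = numeric(ops$n)
  )
  # all-zero state and inputs stay at zero
  z <- step_lip(state, list(xr = numeric(ops$n), xe_pc = numeric(ops$n),
                            xe_cd = numeric(ops$n)), ops, cfg, abl)
  expect_equal(max(abs(unlist(z[c("xr", "xb_pc", "xb_cd", "xh")]))), 0)

  for (i in 1:300) state <- step_lip(state, inputs, ops, cfg, abl)
  expect_lt(max(abs(state$xr - inputs$xr)), 0.05 * max(inputs$xr))
  bpc_fix <- drive_xb_pc(state$xr, state$xe_pc, ops)
  expect_lt(max(abs(state$xb_pc - bpc_fix)), 0.05 * max(bpc_fix))
  xh_fix <- drive_xh(state$xb_pc, state$xb_cd, ops)
  expect_lt(max(abs(state$xh - xh_fix)), 0.05 * max(xh_fix))
})

test_that("head-centred decode is invariant to eye position", {
  bins <- sapply(c(-12.3, 0, 12.3), function(eye) {
    tr <- steady_fixation(6, eye = eye)
    which.max(tr$state$xh)
  })
  expect_lte(max(bins) - min(bins), 1)
})

test_that("predictive remapping requires the corollary discharge", {
  # stimulus in the FRF of the tracked cell around a 14-degree saccade
  cell <- select_remap_cell(cfg, ops)
  onset <- 400
  sac <- make_trajectory(14, onset, config = cfg)
  # flash fully pre-saccadic so the probe never enters the RF passively
  flash <- stimulus_set(0, onset - 160, onset - 60)

  run1 <- function(abl) {
    simulate_trial(cfg, abl, sac, flash, t_end = onset + 40, ops = ops,
                   track_cell = cell)
  }
  frf_on <- run1(lip_ablation())
  frf_cd_off <- run1(lip_ablation(corollary_discharge = FALSE))
  frf_fb_off <- run1(lip_ablation(remapping_feedback = FALSE))

  # visual response of the same cell to a stimulus in its RF, no saccade
  rf <- simulate_trial(cfg, lip_ablation(), NULL,
                       stimulus_set(cfg$remap$rf_position, 50, 150),
                       t_end = 250, ops = ops, track_cell = cell)

  expect_gt(max(frf_on$cell), 0.1 * max(rf$cell))
  # without CD only the far tail of the smoothed RF reaches the cell
  expect_lt(max(frf_cd_off$cell), 0.05 * max(rf$cell))
  expect_lt(max(frf_fb_off$cell), 0.5 * max(frf_on$cell))
})

test_that("the recurrent loop slows the shift after a displacement", {
  # displace a sustained stimulus while the CD signal is active and track
  # how fast the head-centred peak moves toward the new position
  onset <- 400
  sac <- make_trajectory(8, onset, scatter = 0, config = cfg)
  stim <- stimulus_set(c(8, 12), c(100, onset + 30),
                       c(onset + 30, onset + 320))
  centroid_cross <- function(abl) {
    tr <- simulate_trial(cfg, abl, sac, stim, t_end = onset + 300,
                         ops = ops, record = "xh")
    pos <- apply(tr$xh, 2, function(v) {
      ops$diag_positions[which.max(v)]
    })
    which(pos[(onset + 30):(onset + 300)] >= 10)[1]
  }
  t_loop <- centroid_cross(lip_ablation())
  t_open <- centroid_cross(lip_ablation(remapping_feedback = FALSE))
  expect_gt(t_loop, t_open)
})

test_that("cell classes share the predictive response but not the RF gain", {
  cell <- select_remap_cell(cfg, ops)
  onset <- 400
  sac <- make_trajectory(14, onset, config = cfg)
  cfg_pure <- lip_config(circuit = list(gain_modulated = FALSE))

  run_probe <- function(cfg_i, pos) {
    flash <- stimulus_set(pos, onset - 160, onset - 60)
    tr <- simulate_trial(cfg_i, lip_ablation(), sac, flash,
                         t_end = onset + 40, ops = ops, track_cell = cell)
    tr$cell
  }
  frf_gain <- run_probe(cfg, 0)
  frf_pure <- run_probe(cfg_pure, 0)
  expect_equal(frf_gain, frf_pure, tolerance = 0.01)

  # RF probe overlapping the CD window: the gain-modulated class shows the
  # pre-saccadic enhancement, the purely visual class does not
  run_rf <- function(cfg_i) {
    flash <- stimulus_set(cfg$remap$rf_position, onset - 60, onset + 40)
    tr <- simulate_trial(cfg_i, lip_ablation(), sac, flash,
                         t_end = onset + 60, ops = ops, track_cell = cell)
    tr$cell
  }
  rf_gain <- run_rf(cfg)
  rf_pure <- run_rf(cfg_pure)
  expect_gt(max(rf_gain), 1.05 * max(rf_pure))
})

test_that("lateral variant drive has no intermediate-state memory", {
  n <- ops$n
  xr <- exp(-((ops$grid$centers - 0) / 4)^2)
  fef <- exp(-((ops$diag_positions - 13.5) / 6)^2)
  xb_pc <- outer(exp(-((ops$grid$centers - 0) / 4)^2),
                 exp(-((ops$grid$centers - 0) / 6)^2))
  d1 <- lateral_variant_drive(xr, fef, xb_pc, ops, cfg,
                              lip_ablation(variant = "lateral"))
  d0 <- lateral_variant_drive(xr, fef, 0 * xb_pc, ops, cfg,
                              lip_ablation(variant = "lateral"))
  expect_gt(max(d1 - d0), 0)          # diagonal input present
  # zeroing LIP(PC) removes it instantly (stateless path)
  expect_equal(d0, outer(cfg$circuit$cd_ff_gain * drop(ops$Wsm %*% xr),
                         1 + drop(ops$Wfef %*% fef)))
  expect_error(
    lateral_variant_drive(xr, fef, xb_pc, ops, cfg, lip_ablation()),
    "lateral")
})
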