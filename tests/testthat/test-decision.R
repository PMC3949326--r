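cfg <- default_cfg
ops <- default_ops

test_that("decision input is xh, or its kernel readout in the lateral variant", {
  st <- lip_state(cfg, ops)
  expect_equal(decision_input(st, "intermediate", ops), numeric(ops$nd))
  expect_equal(decision_input(st, "lateral", ops), numeric(ops$nd))

  st$xh <- runif(ops$nd)
  expect_identical(decision_input(st, "intermediate", ops), st$xh)

  # lateral: single unit in LIP(PC) at (i, j) projects the published
  # Gaussian kernel profile centred on diagonal bin i + j - 1
  st2 <- lip_state(cfg, ops)
  st2$xb_pc[10, 15] <- 1
  idp <- decision_input(st2, "lateral", ops)
  sp <- diff(ops$diag_positions[1:2])
  dist <- (seq_len(ops$nd) - 24) * sp
  expect_equal(idp, 0.035 * exp(-dist^2 / 15^2))
  expect_equal(max(idp), 0.035)
})

test_that("template matching is an inner product maximised by self-match", {
  tm <- build_templates(cfg, center = 8, ops = ops)
  nc <- length(tm$positions)
  expect_equal(unname(template_match(numeric(ops$nd), tm, cfg)), numeric(nc))

  cfg1 <- lip_config(decision = list(match_gain = 1))
  # an input equal to a template matches itself with its squared norm (= 1)
  j <- 17
  m <- template_match(tm$matrix[, j], tm, cfg1)
  expect_equal(unname(m[j]), sum(tm$matrix[, j]^2))
  expect_equal(unname(m[j]), 1)
  expect_equal(unname(which.max(m)), j)

  # well-separated bumps: the true position beats positions > 3 widths away
  bump <- exp(-((ops$diag_positions - 8) / 10)^2)
  mb <- template_match(bump, tm, cfg1)
  pos <- tm$positions
  far <- abs(pos - 8) > 10
  expect_true(all(mb[which.min(abs(pos - 8))] > mb[far]))
})

test_that("poissonize is an unbiased, saturating spike-average transform", {
  expect_equal(poissonize(0), 0)
  expect_equal(poissonize(1), 1)
  expect_equal(poissonize(3.7), 1)
  expect_error(poissonize(-0.1), "non-negative")

  set.seed(5)
  expect_lt(abs(poissonize(0.5, bins = 1e4) - 0.5), 0.02)

  # E[poissonize(m)] = min(m, 1) on a grid, within 3 standard errors
  set.seed(11)
  n <- 4000
  for (m in seq(0, 1.2, by = 0.1)) {
    p <- min(m, 1)
    se <- sqrt(max(p * (1 - p), 1e-12) / n)
    expect_lt(abs(poissonize(m, bins = n) - p), 3 * se + 1e-12)
  }
})

test_that("evidence splits at the decision border, border bin on both sides", {
  pos <- seq(6, 10, by = 0.5)
  m <- rep(0, length(pos)); names(m) <- pos
  m[pos == 7.5] <- 1; m[pos == 8] <- 2; m[pos == 8.5] <- 3
  ev <- split_evidence(m, pos, 8)
  expect_equal(ev$m_f, 5)
  expect_equal(ev$m_b, 3)

  m2 <- rep(0, length(pos)); m2[pos == 8] <- 4
  ev2 <- split_evidence(m2, pos, 8)
  expect_equal(ev2$m_f, ev2$m_b)

  m3 <- rep(0, length(pos)); m3[pos > 8] <- 1
  expect_equal(split_evidence(m3, pos, 8)$m_b, 0)

  expect_warning(split_evidence(m, pos, 8.1), "snapped")
})

test_that("competition is a simultaneous antisymmetric subtraction", {
  expect_equal(compete(0.3, 0.3), list(m_f = 0, m_b = 0))
  expect_equal(compete(0.6, 0.2), list(m_f = 0.4, m_b = -0.4))
  expect_equal(compete(0.7, 0), list(m_f = 0.7, m_b = -0.7))
  set.seed(3)
  for (i in 1:20) {
    x <- runif(2, 0, 5)
    cm <- compete(x[1], x[2])
    expect_equal(cm$m_f + cm$m_b, 0)
  }
})

test_that("accumulators integrate to threshold with the documented timing", {
  mk <- function(d_thresh) {
    new_decision_trace(lip_config(decision = list(d_thresh = d_thresh)))
  }

  # closed-form crossing: d = 0.1 + t * 0.2 / 50 reaches 0.3 at t = 50
  tr <- mk(0.3)
  while (!tr$done) tr <- accumulate(tr, 0.2, -0.2, dt = 1)
  expect_equal(tr$decision_time, 50)
  expect_equal(tr$outcome, "forward")
  expect_false(tr$timed_out)

  # weak evidence: timeout at 100 ms, larger accumulator wins
  tr2 <- mk(0.9)
  while (!tr2$done) tr2 <- accumulate(tr2, 0.05, -0.05, dt = 1)
  expect_true(tr2$timed_out)
  expect_equal(tr2$decision_time, 100)
  expect_equal(tr2$outcome, "forward")
  expect_equal(tr2$d_f, 0.1 + 100 * 0.05 / 50)
  expect_equal(tr2$d_b, 0)   # floored at zero

  # zero evidence: exact tie broken by the seeded coin flip
  set.seed(21)
  tr3 <- mk(0.6)
  while (!tr3$done) tr3 <- accumulate(tr3, 0, 0, dt = 1)
  expect_true(tr3$timed_out)
  expect_true(tr3$outcome %in% c("forward", "backward"))

  # raising the threshold never speeds up the decision
  times <- sapply(c(0.3, 0.6, 0.9), function(th) {
    tr <- mk(th)
    while (!tr$done) tr <- accumulate(tr, 0.4, -0.4, dt = 1)
    tr$decision_time
  })
  expect_true(all(diff(times) >= 0))
})

test_that("accumulation starts 28 ms after offset or 60 ms after reappearance", {
  cfg <- lip_config()
  s <- make_trajectory(8, onset = 500, config = cfg)   # offset 544.6
  expect_equal(accumulation_start(s, 530, cfg), 544.6 + 28)
  expect_equal(accumulation_start(s, 780, cfg), 840)
  # reappearance exactly at offset counts as post-saccadic
  expect_equal(accumulation_start(s, s$offset, cfg), s$offset + 60)
})

test_that("a symmetric input at the border yields unbiased reports", {
  pos <- seq(-4, 20, by = 0.5)
  nd <- ops$nd
  tmat <- sapply(pos, function(c) {
    v <- exp(-((ops$diag_positions - c) / 14)^2)
    v / sqrt(sum(v^2))
  })
  tm <- structure(list(matrix = tmat, positions = pos,
                       variant = "intermediate"),
                  class = "lip_templates")
  idp <- 0.6 * exp(-((ops$diag_positions - 8) / 14)^2)
  cfg1 <- lip_config(decision = list(match_gain = 0.25))

  set.seed(17)
  outcomes <- replicate(400, {
    tr <- new_decision_trace(cfg1)
    while (!tr$done) {
      m <- template_match(idp, tm, cfg1)
      sp <- poissonize(m, cfg1$decision$bins, cfg1$decision$s_max)
      ev <- split_evidence(sp, pos, 8)
      cm <- compete(ev$m_f, ev$m_b)
      tr <- accumulate(tr, cm$m_f, cm$m_b, dt = 1)
    }
    tr$outcome
  })
  p <- mean(outcomes == "forward")
  ci <- qnorm(0.995) * sqrt(0.25 / 400)
  expect_gt(p, 0.5 - ci)
  expect_lt(p, 0.5 + ci)
})
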