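# shared objects, built once per test run
default_cfg <- lip_config()
default_ops <- lip_operators(default_cfg)

# steady-state fixation trial with a single stimulus
steady_fixation <- function(stim_head, eye = 0, cfg = default_cfg,
                            ops = default_ops, t_end = 250, ...) {
  sac <- if (eye != 0) {
    make_trajectory(eye, onset = -2000, scatter = 0, config = cfg)
  } else NULL
  simulate_trial(cfg, lip_ablation(), sac,
                 stimulus_set(stim_head, 0, t_end + 1),
                 t_end = t_end, ops = ops, ...)
}

nearest_idx <- function(x, centers) which.min(abs(centers - x))
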