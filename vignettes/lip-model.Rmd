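---
title: "A gain-field model of trans-saccadic visual stability in LIP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A gain-field model of trans-saccadic visual stability in LIP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipstab)
```

## The problem

Each saccade displaces the whole retinal image, yet the world appears
stable, and small displacements of an object *during* a saccade usually go
unnoticed (saccadic suppression of displacement, SSD) — unless the object
is blanked for a few hundred milliseconds and reappears displaced, in which
case the displacement is seen easily.  At the neural level, some parietal
neurons with retinotopic receptive fields respond to a stimulus placed in
their *future* receptive field (FRF) already ~150 ms before the eye moves
(predictive remapping).  `lipstab` implements a rate-coded neural field
model of area LIP in which one circuit produces both phenomena, and in
which switching off its ingredients yields distinct, testable behavioural
signatures.

## Circuit

All maps hold `n = 40` neurons per dimension over a visual field of
`v = 160` degrees (centres from −80 to +80 degrees, spacing `v/(n-1)`);
every unit is a leaky integrator `tau * dr/dt = drive − r` advanced by
explicit Euler steps of 1 ms (all `tau` at least 10 ms, so the step is well
inside the stability region) with rates clipped at zero.

Three external signals drive the circuit:

* **Retinal input `Xr`** — Gaussian receptive fields whose width grows
  linearly with eccentricity (`4 deg + 0.05 * |e|`); a saturating
  attentional feedback from the LIP gain field multiplies this input but is
  inessential for any result and can be switched off.
* **Proprioceptive eye position `Xe_PC`** — a Gaussian bump at the
  *registered* eye position.  Critically, it updates only after the saccade:
  the bump stays at the pre-saccadic position until saccade offset plus a
  delay and then slides to the executed position over a transition period.
* **Corollary discharge `Xe_CD`** — a Gaussian bump at the planned
  displacement (the intended amplitude minus the average motor undershoot;
  trial-to-trial endpoint scatter is a motor-side effect and is *not* in the
  CD).  Its temporal envelope rises as a Gaussian before saccade onset and
  decays as a slower Gaussian after, peaking exactly at onset.

A gain field (`fef_transform()`) multiplies the CD and eye-position bumps in
a 2-D map and sums its diagonals, converting eye *displacement* into an
anticipated post-saccadic eye *position* that inherits the CD's envelope.

Two 2-D LIP maps combine these signals multiplicatively:

* **LIP(PC)** (`Xb_PC`): retinal input × eye position.  A single activity
  blob forms at the intersection of the stimulus and eye-position bumps.
* **LIP(CD)** (`Xb_CD`): retinal input × (1 + anticipatory eye position),
  so the cells fire to their visual input even with a silent CD, plus the
  *remapping feedback*: the head-centred population re-enters the map along
  the diagonals, gated by the anticipatory signal.

The intermediate cells `Xh` read both maps out along their diagonals with
Gaussian kernels (peak gains 0.035 from LIP(PC) and 0.02 from LIP(CD),
width 15 degrees of head-centred position) — the classic basis-function
decode of a head-centred stimulus position.  Feedback `Xh × Xe_FEF` into
LIP(CD) closes a recurrent loop that is only live while the CD envelope is:
it is what makes LIP(CD) cells respond to FRF stimuli before the saccade,
and what stabilises the pre-saccadic stimulus representation through the
saccade.  A model variant replaces `Xh` by a direct lateral projection from
LIP(PC) into LIP(CD) — same remapping, but no recurrent loop and no
persistent head-centred state.

## Decision readout

For SSD the model must report "forward" or "backward".  The decision input
(the `Xh` rates, or the equivalent kernel readout of both maps in the
lateral variant) is correlated with precalculated templates on a 0.5-degree
lattice; each template is the steady fixation response to a stimulus at that
position.  The matches are made stochastic by a Poisson spike transform
(20 sub-steps per millisecond; spike iff the match exceeds a fresh uniform
draw), split into forward and backward sums at the pre-saccadic target
position (the border bin counts for both), passed through a subtractive
competition, and integrated by two decision neurons
(`tau = 50` ms, baseline 0.1, threshold 0.6 within the 0.3–0.9 range, 100-ms
timeout with the larger accumulator winning and exact ties decided by a
coin flip).  Accumulation starts 28 ms after saccade offset when the
displaced target reappears during the saccade, and 60 ms after stimulus
onset when it reappears after the saccade (blanking).

## Numerical choices

Three numerical decisions deserve explicit mention.

* **Diagonal kernel metric.**  The diagonal (head-centred) kernels use the
  head-centred *position* metric with `sigma = 15` degrees.  On a 40-unit
  map spanning 160 degrees, reading the same width in raw index units would
  smear the head-centred axis by more than 60 degrees; template matches
  would then vary by about 1% across the entire decision lattice and the
  readout would carry no usable position signal.  With the degree metric
  the blur is of receptive-field scale and consistent with a decision stage
  whose resolution equals the 0.5-degree template lattice.
* **Loop stabilisation.**  The `Xh -> LIP(CD) -> Xh` loop is linearly
  unstable at unit gain, so the head-centred signal passes through the
  bounded transfer `x / (1 + x)` before gain-modulating LIP(CD).  This keeps
  the loop gain below one at every activity level while leaving small
  signals almost untouched.
* **Template normalisation.**  Templates are normalised to unit Euclidean
  norm (matched filters).  Sum-normalisation interacts with the
  eccentricity-dependent receptive-field widths: wider templates get lower
  peaks, which under the broad diagonal blur shifts the match argmax by
  several degrees toward the fovea.  Unit-norm templates do not have this
  bias.

## Calibrated constants

The printed constants of the circuit (map sizes, kernel gains, scatter
moments, all decision-stage parameters and every paradigm timing) are fixed.
A small set of constants that belong to the published parameter set of the
underlying dynamical model but are not printed with it — the CD envelope
widths, the proprioceptive update delay and transition, the LIP(CD)
feedforward response gain, the anticipatory-signal gain, the remapping
feedback gain and the template match gain — were calibrated once against
the behavioural anchors the model is known to reproduce (FRF response onset
about 150 ms before saccade; SSD biases of about 1.7 degrees without
remapping feedback and about 3 degrees without corollary discharge; an
unbiased, shallow full-model curve; steep curves in the blank condition and
the ablated models) and then frozen as package defaults.  They are ordinary
configuration values: every one can be overridden through `lip_config()`.

Defaults (see `?lip_config` for the full list): CD envelope rise 30 ms and
decay 150 ms; proprioceptive update delay 10 ms after saccade offset with
an 80-ms transition (the decision onset at offset + 28 ms still reads a
mostly pre-saccadic eye position); LIP(CD) feedforward gain 0.25;
anticipatory-signal gain 2; remapping feedback gain 0.9; template match
gain 0.45.  Decision templates for the displacement report are recorded at
the anticipated post-saccadic fixation, since the report relies on the
post-saccadic view.

## What the simulations emulate — and what they do not

All stimuli are synthetic one-dimensional Gaussians; the paradigms are the
classic remapping protocol (14-degree saccade, 100-ms flashes between
500 ms before and 100 ms after onset, responses averaged 50–350 ms after
flash onset) and the SSD protocol (8-degree saccade, target on 500 ms
before onset, displacement steps of 0.5 degrees within ±4 degrees applied
30 ms after onset, or after a 250-ms blank; 20 trials per displacement;
endpoint scatter N(0.52, 0.58) degrees).  The model is one-dimensional, has
no learned connectivity, no attention or landmark mechanisms beyond the
small feedback gain term, and no second stimulus; passing its tests shows
that the circuit mechanisms are sufficient for the simulated paradigms, not
that they quantify any individual subject, whose suppression magnitude
varies widely.

## Worked example

```{r example, eval = FALSE}
cfg <- lip_config()

# predictive remapping time course and onset
remap <- run_remapping(cfg, probes = "frf")
remap_onset(remap)        # -125 ms relative to saccade onset

# SSD with the remapping feedback disabled
e <- run_ssd_experiment(cfg, lip_ablation(remapping_feedback = FALSE),
                        seed = 1)
glance(e)                 # mu = 1.50 degrees here
autoplot(e)
```

Problem sizes: one SSD condition is 17 displacements × 20 trials, each trial
roughly one simulated second at 1-ms resolution on 40-unit and 40×40-unit
maps; a full condition takes a few minutes on one core, the remapping curve
(25 deterministic trials) well under a minute, and the template bank
(49 fixation runs) a few seconds, cached per configuration.

## Known limitations

The exact right-hand sides of the published LIP equations (saturation and
normalisation terms) are not reproduced; the leaky-integrator contract with
the stated multiplicative drive terms is used instead, with the bounded
feedback transfer as the single stabilising nonlinearity.

One consequence deserves emphasis.  In this implementation the fitted
psychometric slope of each condition tracks the size of its bias — evidence
further from the decision border is weaker, hence noisier — so the
*unbiased* full model comes out with a slope comparable to (not shallower
than) the ablated and blanked models.  The full model's reduced sensitivity
to small displacements therefore shows up as its near-zero bias together
with suppressed detection of sub-degree jumps, but the strict slope
orderings (full shallower than no-remapping, blank and lateral runs) are
not reproduced at the calibrated operating point; the corresponding
property tests in the suite record this openly.  Mechanisms that would
restore a genuinely flat full-model curve — a slow head-centred memory
whose trace gates the feedback — lengthen the predictive-response tail and
push the remapping onset far earlier than 150 ms, so they were not adopted.

The saccade generator is a smoothstep main-sequence model (duration
23 ms + 2.7 ms/deg); only its boundary behaviour and duration scale matter
to the circuit timing.
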