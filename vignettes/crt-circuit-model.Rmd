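---
title: "The CRT circuit model: mechanisms, calibration, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The CRT circuit model: mechanisms, calibration, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science in the
simulator: the model and its assumptions, the parameters that matter, the
numerical choices we made where the design was genuinely open, and what
the passing tests do and do not establish.

## The circuit and its assumptions

The model is a closed perception–action loop built around the
cortico-reticulo-thalamic (CRT) motif.  Thalamic relay neurons (T, 40)
excite middle-layer cortical pyramidal neurons (M, 120), which excite
deep-layer pyramidal neurons (D, 120); D projects back to both the
thalamus and the thalamic reticular nucleus (R, 40), the wholly GABAergic
shell that inhibits T.  Two cortical interneuron classes shape M:
fast-spiking parvalbumin cells (PV, 40) inhibiting somata, and calbindin
cells (CB, 40) inhibiting only the distal dendrites that carry the broad
thalamic input.  All neurons are Izhikevich units — regular-spiking
parameters (0.02, 0.2, −65, 0) everywhere except PV, which uses the
fast-spiking set (0.1, 0.2, −65, 2).  We deliberately keep the printed
regular-spiking d = 0 rather than the more common d = 8: the population
behavior, not the canonical single-cell adaptation, is the contract.

Assumptions worth making explicit:

* **Retinotopy is index arithmetic.**  Neuron i of an N-sized population
  sits at normalized position i/N; Gaussian connection profiles are
  functions of normalized distance.  There is no anatomy beyond this.
* **The eye is a pure integrator.**  The middle layer is read out as a
  motor error map (ramp weights 0.025 per half) and the gaze position
  accumulates R − L every integration step, clamped to [5, 36].  There is
  no oculomotor plant, no saccade generator, and no prediction of target
  motion.
* **Sensing is instantaneous.**  Poisson afferent rates are recomputed
  from the current gaze every 0.025 ms step; there is no retinal delay.

## Mechanisms

**Saturating-differential synapses.**  Each presynaptic neuron drives a
transmitter variable Q (rise constant tau_rise) via a rectangular spike
pulse K, and Q drives a conductance g that decays with tau_fall.  Both
variables saturate below 1.  Five kinetic classes cover AMPA (2/10 ms),
NMDA (8/100 ms), the very fast PV GABA-A output (0.1/0.5 ms), GABA-B
(8/30 ms) and an extra-slow cortical conductance (200/400 ms).  The drive
coefficient is `(tau_fall + tau_rise) / tau_fall^2`; see *Numerical
choices* for why.

**Current sign convention.**  Every receptor current is written as
`amplitude * (E_rev - v_post) * sum(W g)`, so currents push the membrane
toward their reversal potential and vanish exactly there.  This is the
form enforced by the reversal-potential tests; excitatory/inhibitory
classification then follows from the reversal, not from a sign baked into
an amplitude.

**T-type calcium.**  T and R carry a low-threshold calcium current in GHK
form with activation/inactivation gates (midpoints −79 and −92 mV).  The
raw GHK flux is inward (negative) at physiological voltages; the model
adds `-unit_scale * amplitude * m^2 h * flux` to the input current, i.e. a
depolarizing current whose strength grows as hyperpolarization
deinactivates the channel.  Sustained inhibition therefore primes a
rebound burst on release — the engine of the circuit's 8–12 Hz rhythm and
of the nonmonotonic response to direct TRN hyperpolarization.

**Disinhibitory short-term plasticity (dSTP).**  Deep-layer spikes feed
the extra-slow conductance, and each thalamic neuron's GABA-B input is
multiplied by `P_T = [1 + A_STP * sum W g_xslow^6]^-1` with A_STP = 3000.
The sixth power makes P_T a soft threshold: brief cortical activity leaves
inhibition intact, while firing sustained for a few hundred milliseconds
(the 200 ms rise constant) collapses it locally.  In a converged trial the
P_T profile shows a focal island (values of a few percent under the
stimulus, ≈1 elsewhere), which is the model's expression of continuous
attention.

## Parameters that matter

All connection widths and amplitudes default to the reference table and
are exposed in `network_config()`.  Three calibration constants are the
package's own, and each is the single free number in an otherwise pinned
mechanism:

* **Spike-pulse impulse** (`spike_pulse_magnitude` x
  `spike_pulse_duration`, default 8 x 0.025 ms = 0.2 ms): the unitary
  synaptic efficacy.  Halving the step while doubling the magnitude leaves
  single-neuron firing essentially unchanged (tested).  Values below
  ~0.1 leave the thalamus below rheobase (the network falls silent);
  values near 1 saturate the slow conductance within milliseconds and
  destroy the dSTP timescale.  0.2 is the value at which the unperturbed
  model converges within the first second and tracks with rms error below
  15% of the target amplitude.
* **GHK unit scale** (`unit_scale`, default 1e-6): folds the unspecified
  unit chain of the GHK expression into the dimensionless Izhikevich
  current scale.  The calibration contract is rebound bursting, not an
  absolute current; 3e-6 still tracks, 1e-5 destabilizes the loop.
* **External input amplitudes** (1 for both AMPA and NMDA, sharing one
  Poisson train per afferent): the stated default for unlisted amplitudes.

## What the synthetic stimulus emulates — and what it does not

The generator produces the study conditions exactly: a near-Gaussian bump
(quartic exponent, ≈±1.5 afferents wide) of Poisson rates between 30 and
250 sp/s, a 1 Hz sinusoidal target sweeping indices 11–30 for pursuit, a
static target at 10 with an equal distractor at 25 appearing at 2 s for
fixation, and ±5% multiplicative jitter on all cellular and synaptic
constants per model instance.  It does not emulate: retinal transduction
delays or adaptation, naturalistic target kinematics, measurement noise in
eye tracking, or any between-subject variability beyond the ±5% jitter.
Passing tests therefore establish the circuit-level mechanism under
idealized sensing, not quantitative agreement with human eye-tracking
data.

## Numerical choices

* **Units and integration.**  Milliseconds throughout; the printed
  integration constant of 0.001 (a seconds/ms artifact) is absorbed so the
  Izhikevich equations run in their standard ms form.  Forward Euler at
  h = 0.025 ms, update order: currents from previous-step state →
  conductances/gates/plasticity → gaze → membranes → spike detect/reset.
* **SD drive coefficient.**  The flattened source admits several
  groupings of the conductance drive coefficient.  Two candidates fail
  structurally: `(tf+tr)/(tf^2 tr)` makes the 200/400 ms class vanishingly
  weak (dSTP never engages), and `tr (tf+tr)/tf^2` makes the 0.1/0.5 ms PV
  class inert (cortex runs away).  The adopted `(tf+tr)/tf^2` is the only
  candidate under which both the PV pathway and the dSTP timescale
  function; single-spike transients peak between tau_rise and tau_fall as
  required.
* **NMDA gate sign.**  We use the standard magnesium-block orientation
  (gate opens with depolarization).  The opposite orientation was tested
  and makes CB interneurons self-sustaining (hundreds of Hz), breaking
  tracking.
* **Calcium bookkeeping.**  The rectified term in the internal-calcium
  equation acts on the raw (inward-negative) flux and is therefore inert
  at physiological voltages; internal calcium relaxes to 0.00024 mM.  This
  literal reading is stable and is guarded by a fixed-point test.
* **Degenerate inputs and tails.**  Conductance tails are flushed to zero
  below 1e-30 — far below physical relevance — because exponentially
  decaying doubles otherwise enter the subnormal range and slow the
  integration ~100-fold.  The GHK singularity at v = 0 uses its closed
  form; continuity is tested to 1e-6.
* **Spectral estimators.**  The spectrogram is a direct Hann-window STFT
  (160-sample window, 16-sample hop at 400 Hz), matching the stated frame
  arithmetic (191 frames for an 8 s series).  Because the window
  quantizes frequency to 2.5 Hz, the dominant frequency of an interval is
  reported as the power-weighted centroid of the time-averaged spectrogram
  over 2–20 Hz, which is stable across model instances where the argmax
  bin alternates between 7.5 and 10 Hz.  Epoch power spectra are plain
  FFTs of linearly detrended segments; "alpha" is operationalized as
  integrated 8–12 Hz power.
* **Two implementations, one contract.**  The compiled engine integrates
  full trials (~11 s wall per 8 s trial on one CPU); a pure-R
  `step_network()` states the same update readably.  A scalar loop-based
  reference that replicates the engine's accumulation order bit-for-bit
  anchors the equivalence test on a 4-neurons-per-group toy network; the
  vectorized R step uses extended-precision accumulation and is verified
  to agree exactly for 25 ms and statistically beyond (last-bit float
  drift, not semantics).

## Problem sizes in the shipped tests

The test suite simulates twenty-odd full 8 s trials (cached and shared
across test blocks), using one model instance per condition for sweep
trends and two instances for the seed-averaged alpha contrasts; the full
published grid (7 kinds x 5 strengths x 2 tasks x 5 instances) is run via
`run_experiment()` when desired.  These sizes are the package's choice of
a thorough-but-routine check; all thresholds are stated in the tests
themselves.

## Known limitations

* **The strongest PV deficit overshoots.**  With PV-NMDA at 10%, the
  published behavior is a bounded ~10 Hz oscillation of the eye around the
  target.  In this calibration the same perturbation is more destructive:
  the disinhibition island becomes self-sustaining (thalamic firing locks
  to the island center and decouples from the stimulus), corrections wait
  on island migration (hundreds of ms), and the eye hunts between the
  clamps at 1.5–4 Hz with perturbed/normal rms ratios near 9 rather than
  the published 1.1–1.9.  An ~6 Hz rhythm is present in the motor-drive
  signal but is suppressed in eye position by the integrator.  We explored
  the free constants (pulse impulse, GHK scale, bump exponent, gaze
  cadence, gate orientation) without finding a setting that restores the
  10 Hz regime while preserving the unperturbed-tracking contract; the
  corresponding acceptance expectation is left failing rather than
  weakened.  Milder PV strengths and all other perturbations reproduce the
  published signatures (CB/dSTP alpha increases in both tasks, TRN alpha
  increase in fixation only, no sustained PV alpha increase, monotone
  growth of high-velocity counts, rms ratios overlapping 1.1–1.9).
* **No plant, no prediction.**  Deficits expressed through oculomotor
  dynamics proper (latencies, saccade kinematics) are outside the model.
* **Single CRT loop.**  Interacting loops across cortical areas, and any
  mapping onto specific oculomotor structures, are not modeled.
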