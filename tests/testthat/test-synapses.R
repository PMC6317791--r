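test_that("SD conductances stay at zero without spikes and remain bounded in [0, 1]", {
  cfg <- integrator_config()
  st <- conductance_state(3, synapse_kinetics("fast"))
  for (k in 1:200) st <- step_sd_conductance(st, rep(FALSE, 3), cfg = cfg)
  expect_equal(st$Q, rep(0, 3))
  expect_equal(st$g, rep(0, 3))

  # sustained maximal drive saturates below 1 (no blow-up)
  for (kind in c("fast", "nmda", "pv_fast", "gaba_b", "xslow")) {
    st <- conductance_state(1, synapse_kinetics(kind))
    for (k in 1:40000) {   # 1 s of continuous spiking input
      st <- step_sd_conductance(st, TRUE, cfg = cfg)
      if (k %% 1000 == 0) {
        expect_true(st$Q >= 0 && st$Q <= 1)
        expect_true(st$g >= 0 && st$g <= 1)
      }
    }
  }
})

single_spike_waveform <- function(kind, t_ms = 60, cfg = integrator_config()) {
  st <- conductance_state(1, synapse_kinetics(kind))
  n <- round(t_ms / cfg$step_h)
  g <- numeric(n)
  for (k in seq_len(n)) {
    st <- step_sd_conductance(st, k == 1, cfg = cfg)
    g[k] <- st$g
  }
  g
}

test_that("a single spike produces a transient whose peak lies between the rise and fall times", {
  cfg <- integrator_config()
  for (kind in c("fast", "nmda", "gaba_b")) {
    kin <- synapse_kinetics(kind)
    g <- single_spike_waveform(kind, t_ms = 5 * kin$tau_fall)
    peak <- which.max(g)
    t_peak <- peak * cfg$step_h
    expect_gt(max(g), 0)
    expect_lte(max(g), 1)
    expect_gt(t_peak, kin$tau_rise)
    expect_lt(t_peak, kin$tau_fall)
    # decays after the peak
    expect_lt(g[length(g)], max(g) / 2)
  }
})

test_that("PV-interneuron synapse kinetics decay faster than fast-AMPA kinetics", {
  g_pv <- single_spike_waveform("pv_fast", t_ms = 120)
  g_fast <- single_spike_waveform("fast", t_ms = 120)
  # time for the waveform to fall back below 10% of its own peak
  decay_time <- function(g) {
    peak <- which.max(g)
    below <- which(g < 0.1 * max(g) & seq_along(g) > peak)
    below[1] - peak
  }
  expect_lt(decay_time(g_pv), decay_time(g_fast) / 5)
})

test_that("the NMDA gate follows the printed constants and opens with depolarization", {
  expect_equal(nmda_gate(0), 1 / (1 + 0.4202), tolerance = 1e-12)
  expect_lt(nmda_gate(-150), 0.001)   # gate closes toward hyperpolarization
  v <- seq(-90, 30, by = 0.5)
  expect_true(all(diff(nmda_gate(v)) > 0))
  expect_true(all(nmda_gate(v) > 0 & nmda_gate(v) < 1))
})

test_that("receptor currents vanish at their reversal potential and flip sign across it", {
  W <- matrix(c(0.5, 0.25), nrow = 2, ncol = 1)
  g <- c(0.3, 0.2)
  for (kind in c("ampa", "nmda", "gaba_a", "gaba_b")) {
    spec <- receptor_spec(kind, amplitude = 2)
    expect_equal(receptor_current(spec, spec$reversal, W, g), 0)
    below <- receptor_current(spec, spec$reversal - 5, W, g)
    above <- receptor_current(spec, spec$reversal + 5, W, g)
    expect_gt(below, 0)   # depolarizing below reversal
    expect_lt(above, 0)
    # zero conductance gives zero current at any voltage
    expect_equal(receptor_current(spec, -55, W, c(0, 0)), 0)
  }
  # excitatory AMPA drive at rest is depolarizing
  expect_gt(receptor_current(receptor_spec("ampa"), -65, W, g), 0)
  expect_error(receptor_current(receptor_spec("ampa"), c(-65, -65), W, g),
               "shape")
})

test_that("gap-junction currents are differential and conserve total current", {
  W <- matrix(0.3, 2, 2); diag(W) <- 0
  expect_equal(gap_current(W, c(-60, -60)), c(0, 0))
  out <- gap_current(W, c(-55, -65))
  expect_equal(out, c(-3, 3))
  set.seed(5)
  for (k in 1:10) {
    n <- 6
    A <- matrix(runif(n * n), n, n); A <- (A + t(A)) / 2; diag(A) <- 0
    v <- runif(n, -90, -40)
    expect_equal(sum(gap_current(A, v)), 0, tolerance = 1e-10)
  }
  W_bad <- matrix(c(0, 1, 0.5, 0), 2, 2)
  expect_error(gap_current(W_bad, c(-60, -60)), "symmetric")
})
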