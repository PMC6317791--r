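test_that("population initialization jitters parameters within bounds and reproducibly", {
  # zero jitter: identical to nominal
  p0 <- init_population(10, izhikevich_rs(), jitter_frac = 0, seed = 1)
  expect_equal(p0$params$a, rep(0.02, 10))
  expect_equal(p0$params$c, rep(-65, 10))
  expect_equal(p0$state$v, p0$params$c)
  expect_equal(p0$state$u, p0$params$b * p0$state$v)

  # regular-spiking nominal set before jitter
  rs <- izhikevich_rs()
  expect_equal(c(rs$a, rs$b, rs$c, rs$d), c(0.02, 0.2, -65, 0))
  fs <- izhikevich_fs()
  expect_equal(c(fs$a, fs$b, fs$c, fs$d), c(0.1, 0.2, -65, 2))

  # 5% jitter stays within [0.95, 1.05] x nominal, for every parameter
  p <- init_population(500, izhikevich_rs(), jitter_frac = 0.05, seed = 7)
  for (nm in c("a", "b", "c")) {
    ratio <- p$params[[nm]] / izhikevich_rs()[[nm]]
    expect_true(all(ratio >= 0.95 - 1e-12 & ratio <= 1.05 + 1e-12))
  }
  expect_equal(p$params$d, rep(0, 500))   # d = 0 stays 0 under jitter

  # seeded determinism
  q <- init_population(500, izhikevich_rs(), jitter_frac = 0.05, seed = 7)
  expect_identical(p, q)

  expect_error(init_population(0), "positive count")
  expect_error(init_population(5, jitter_frac = 1), "jitter_frac")
})

test_that("membrane step holds the rest fixed point and applies the after-spike reset", {
  cfg <- integrator_config()
  params <- izhikevich_params(0.02, 0.2, -65, 0)
  # (-70, -14) solves 0.04 v^2 + 5 v + 140 - u = 0 with u = b v
  st <- structure(list(v = -70, u = -14, spiked = FALSE),
                  class = "population_state")
  st2 <- step_izhikevich(st, params, 0, cfg)
  expect_equal(st2$v, -70)
  expect_equal(st2$u, -14)

  # crossing threshold resets v to c and increments u by d
  params_d <- izhikevich_params(0.02, 0.2, -65, 8)
  st <- structure(list(v = 29.999, u = 0, spiked = FALSE),
                  class = "population_state")
  st2 <- step_izhikevich(st, params_d, 1000, cfg)
  expect_true(st2$spiked)
  expect_equal(st2$v, -65)
  u_pre <- 0 + cfg$step_h * (0.02 * (0.2 * 29.999 - 0))
  expect_equal(st2$u, u_pre + 8)

  expect_error(step_izhikevich(st, params, c(0, 0), cfg), "length")
  st_bad <- structure(list(v = NaN, u = 0, spiked = FALSE),
                      class = "population_state")
  expect_error(step_izhikevich(st_bad, params, 0, cfg), "non-finite")
})

# scalar reference integration of a single driven neuron
integrate_rs_neuron <- function(I, t_ms, h, params = izhikevich_params()) {
  v <- params$c; u <- params$b * v
  spikes <- 0L
  isis <- numeric(0); last <- NA_real_
  for (n in seq_len(round(t_ms / h))) {
    vn <- v + h * (0.04 * v * v + 5 * v + 140 - u + I)
    un <- u + h * (params$a * (params$b * v - u))
    if (vn >= 30) {
      spikes <- spikes + 1L
      t <- n * h
      if (!is.na(last)) isis <- c(isis, t - last)
      last <- t
      vn <- params$c; un <- un + params$d
    }
    v <- vn; u <- un
  }
  list(count = spikes, isis = isis)
}

test_that("a driven regular-spiking neuron fires tonically, consistent with a finer-step reference", {
  ref <- integrate_rs_neuron(10, 1000, 0.0025)   # 10x finer step
  coarse <- integrate_rs_neuron(10, 1000, 0.025)
  expect_gt(coarse$count, 0)
  expect_lt(abs(coarse$count - ref$count) / ref$count, 0.05)
  # regular inter-spike intervals once settled
  isis <- utils::tail(coarse$isis, 5)
  expect_lt(max(isis) - min(isis), 0.05 * mean(isis))
})

test_that("halving the step with pulse compensation preserves spike counts of a driven neuron", {
  run_with_step <- function(h) {
    cfg <- integrator_config(step_h = h, spike_pulse_duration = h,
                             spike_pulse_magnitude = 0.2 / h)
    pre <- conductance_state(1, synapse_kinetics("fast"))
    params <- izhikevich_params()
    st <- structure(list(v = params$c, u = params$b * params$c, spiked = FALSE),
                    class = "population_state")
    count <- 0L
    spike_every <- round(4 / h)   # presynaptic spike train at 250 Hz
    for (n in seq_len(round(500 / h))) {
      pre <- step_sd_conductance(pre, n %% spike_every == 0, cfg = cfg)
      I <- (0 - st$v) * 65 * pre$g   # strong excitatory drive
      st <- step_izhikevich(st, params, I, cfg)
      count <- count + st$spiked
    }
    count
  }
  n1 <- run_with_step(0.025)
  n2 <- run_with_step(0.0125)
  expect_gt(n1, 5)
  expect_lt(abs(n1 - n2) / n1, 0.05)
})

test_that("no neuron remains above threshold after a step (reset idempotence)", {
  cfg <- integrator_config()
  params <- izhikevich_params(0.02, 0.2, -65, 2)
  set.seed(3)
  for (k in 1:20) {
    st <- structure(list(v = runif(50, -80, 29.9), u = runif(50, -20, 10),
                         spiked = rep(FALSE, 50)),
                    class = "population_state")
    st2 <- step_izhikevich(st, params, runif(50, -20, 300), cfg)
    expect_true(all(st2$v < params$spike_threshold))
    expect_true(all(st2$v[st2$spiked] == -65))
  }
})
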