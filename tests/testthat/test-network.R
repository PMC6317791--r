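test_that("the connectome follows the parameter table", {
  conn <- build_connectome(network_config())
  # deep-layer -> thalamus peaks at the aligned position with amplitude 0.04
  expect_equal(max(conn$dt), 0.04)
  expect_equal(conn$dt[120, 40], 0.04)  # i/120 == j/40 at the top corner
  expect_equal(conn$dt[3, 1], 0.04)     # 3/120 == 1/40
  # reticulo-thalamic inhibition is uniformly all-to-all
  expect_true(all(conn$rt == 0.32))
  # Gaussian rows fall off monotonically with normalized distance
  row <- conn$dt[60, ]   # presynaptic neuron at position 0.5
  peak <- which.max(row)
  expect_true(all(diff(row[peak:40]) <= 0))
  expect_true(all(diff(row[1:peak]) >= 0))
  # gap matrix symmetric with zero diagonal
  expect_equal(conn$gap, t(conn$gap))
  expect_true(all(diag(conn$gap) == 0))
  # deterministic
  expect_identical(conn, build_connectome(network_config()))
})

test_that("dendritic inhibition is rectified and cannot touch the proximal drive", {
  cfg <- network_config()
  conn <- build_connectome(cfg)
  v_M <- rep(-65, cfg$n_m)
  g_T <- rep(0.2, cfg$n_t)
  # no CB activity: distal term is the plain weighted drive
  base <- mln_dendritic_input(v_M, g_T, numeric(cfg$n_cb), conn)
  plain <- (0 - v_M) * (colSums(conn$tmp * g_T) + colSums(conn$tmd * g_T))
  expect_equal(base, plain)
  # saturating CB activity removes the distal term entirely, proximal unchanged
  blocked <- mln_dendritic_input(v_M, g_T, rep(10, cfg$n_cb), conn)
  proximal_only <- (0 - v_M) * colSums(conn$tmp * g_T)
  expect_equal(blocked, proximal_only)
})

test_that("a point thalamic source has a wider distal than proximal cortical footprint", {
  cfg <- network_config()
  conn <- build_connectome(cfg)
  g_T <- numeric(cfg$n_t); g_T[20] <- 1
  prox <- colSums(conn$tmp * g_T)
  dist <- colSums(conn$tmd * g_T)
  width <- function(x) sum(x > max(x) / 2)
  expect_gt(width(dist), 5 * width(prox))
})

test_that("a cold network without input stays silent and the toy network matches the scalar oracle", {
  # silent network: no external drive, 100 ms
  ts <- toy_setup(duration_ms = 100, seed = 5)
  ts$par$ext_spikes[] <- FALSE
  out <- crtgaze:::crt_engine(ts$par)
  expect_equal(length(out$raster_step), 0)

  # driven toy network: compiled engine against the scalar loop reference
  ts <- toy_setup(duration_ms = 100, seed = 42)
  out <- crtgaze:::crt_engine(ts$par)
  ref <- oracle_run(ts$par, ts$par$ext_spikes)
  expect_gt(length(out$raster_step), 10)   # meaningful activity in the toy
  expect_identical(as.integer(out$raster_step), as.integer(ref$raster_step))
  expect_identical(as.integer(out$raster_neuron), as.integer(ref$raster_neuron))
  expect_identical(as.integer(out$raster_pop), as.integer(ref$raster_pop))
  expect_equal(out$eye, ref$eye, tolerance = 1e-12)
})

test_that("the vectorized R network step reproduces the engine on the toy network", {
  # The R step sums with colSums (extended-precision accumulation) while the
  # engine accumulates in double, so trajectories may drift apart in the last
  # bits over tens of milliseconds; spike trains must agree early and stay
  # statistically identical.
  ts <- toy_setup(duration_ms = 50, seed = 42)
  out <- crtgaze:::crt_engine(ts$par)
  n_steps <- ts$par$n_steps
  state <- ts$state
  spikes <- list()
  for (n in seq_len(n_steps)) {
    state <- step_network(state, ts$par$ext_spikes[n, ])
    for (p in names(state$populations)) {
      sp <- which(state$populations[[p]]$spiked)
      if (length(sp))
        spikes[[length(spikes) + 1]] <- data.frame(step = n - 1L, pop = p,
                                                   neuron = sp)
    }
  }
  got <- do.call(rbind, spikes)
  pops <- c("T", "R", "M", "D", "PV", "CB")
  want <- data.frame(step = as.integer(out$raster_step),
                     pop = pops[out$raster_pop + 1],
                     neuron = as.integer(out$raster_neuron))
  key <- function(d) paste(d$step, d$pop, d$neuron)
  cut <- 1000L   # first 25 ms: bit-for-bit agreement expected
  expect_gt(sum(got$step < cut), 10)
  expect_identical(key(got[got$step < cut, ]), key(want[want$step < cut, ]))
  expect_lt(abs(nrow(got) - nrow(want)) / nrow(want), 0.05)
})

test_that("populations listed without inhibitory inputs receive none", {
  # raising PV and CB conductances changes M but leaves CB and D currents
  ts <- toy_setup(duration_ms = 1, seed = 7)
  state <- ts$state
  ext <- rep(FALSE, ts$cfg$n_t)
  base <- step_network(state, ext)
  poked <- state
  poked$synapses$pv_fast$g <- rep(0.5, ts$cfg$n_pv)
  poked$synapses$cb_fast$g <- rep(0.5, ts$cfg$n_cb)
  after <- step_network(poked, ext)
  expect_identical(after$populations$CB$v, base$populations$CB$v)
  expect_identical(after$populations$D$v, base$populations$D$v)
})

test_that("forcing the dSTP factor changes nothing until deep-layer slow conductance appears", {
  ts <- toy_setup(duration_ms = 20, seed = 13)
  # run the engine with dSTP scaled to zero strength from t = 0: identical to
  # baseline while g_xslow is still zero (the deep layer has not yet fired)
  par_off <- ts$par
  par_off$perturbation$onset_step <- 0L
  par_off$perturbation$offset_step <- ts$par$n_steps
  par_off$perturbation$dstp <- 0
  base <- crtgaze:::crt_engine(ts$par)
  off <- crtgaze:::crt_engine(par_off)
  first_d <- suppressWarnings(min(base$raster_step[base$raster_pop == 3]))
  keep <- base$raster_step <= first_d   # up to the first deep-layer spike
  expect_identical(base$raster_step[keep], off$raster_step[keep])
  expect_identical(base$raster_neuron[keep], off$raster_neuron[keep])
})

test_that("removing gap junctions reduces reticular spike synchrony", {
  skip_if(is.null(.trial_cache), "cache helper missing")
  cfg_gap <- network_config()
  cfg_nogap <- network_config(amplitude = list(gap = 0))
  sync <- function(cfg, seed = 3) {
    task <- task_spec("smooth_pursuit", duration = 3)
    rec <- run_trial(task, net_cfg = cfg, seed = seed)
    r <- rec$raster[rec$raster$pop == "R" & rec$raster$time > 1, ]
    # population synchrony: variance of the binned population rate relative
    # to the mean (2.5 ms bins)
    bins <- table(cut(r$time, breaks = seq(1, 3, by = 0.0025)))
    stats::var(as.numeric(bins)) / mean(bins)
  }
  expect_gt(sync(cfg_gap), sync(cfg_nogap))
})
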