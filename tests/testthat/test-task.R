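test_that("target trajectories match the task definitions", {
  sp <- task_spec("smooth_pursuit")
  t <- seq(0, 8, by = 0.0001)
  x <- target_position(sp, t)
  expect_equal(min(x), 11, tolerance = 1e-6)
  expect_equal(max(x), 30, tolerance = 1e-6)
  # 1 Hz periodicity
  expect_equal(target_position(sp, 0.3), target_position(sp, 1.3))
  fx <- task_spec("fixation")
  expect_true(all(target_position(fx, t) == 10))
  expect_true(all(is.na(distractor_position(fx, c(0, 1, 1.99)))))
  expect_true(all(distractor_position(fx, c(2, 5)) == 25))
  expect_error(target_position(sp, 9), "duration")
})

test_that("stimulus rates hit the printed peak and floor and are symmetric", {
  sp <- task_spec("smooth_pursuit")
  # gaze on target: bump centered on the middle of the afferent field
  r <- stimulus_rates(x_c = 20.5, x_T = 20.5, spec = sp)
  expect_equal(max(r), 250)
  expect_equal(r[20], 250)          # u = 0 exactly at afferent 20
  expect_equal(r[1], 30, tolerance = 1e-9)
  expect_equal(r[40], 30, tolerance = 1e-9)
  # symmetry about the peak
  expect_equal(r[19], r[21], tolerance = 1e-12)
  expect_equal(r[15], r[25], tolerance = 1e-12)
  # distractor adds an identical bump, ceiling preserved
  r2 <- stimulus_rates(20.5, 20.5, distractor = 10.5, spec = sp)
  expect_equal(max(r2), 250)
  expect_gt(r2[10], r[10])   # second bump at afferent 20 - (20.5 - 10.5) = 10
})

test_that("Poisson sampling respects rates, seeds, and the step-probability bound", {
  cfg <- integrator_config()
  expect_true(all(!sample_input_spikes(rep(0, 40), cfg)))
  # rate 250 sp/s over 10 s of steps: count within 3 sqrt(2500) of 2500
  set.seed(21)
  count <- sum(replicate(100, sum(sample_input_spikes(rep(250, 4000), cfg))))
  expect_lt(abs(count - 2500), 3 * sqrt(2500))
  set.seed(33); a <- replicate(50, sample_input_spikes(rep(100, 40), cfg))
  set.seed(33); b <- replicate(50, sample_input_spikes(rep(100, 40), cfg))
  expect_identical(a, b)
  expect_error(sample_input_spikes(1e9, integrator_config()), "exceeds 1")
})

test_that("the motor error map readout follows the ramp weights", {
  g <- numeric(120)
  expect_equal(motor_signals(g), list(L = 0, R = 0))
  # activity mirror-symmetric about the map center is counterbalanced
  g <- exp(-((1:120) - 60)^2 / 50)
  ms <- motor_signals(g)
  expect_equal(ms$L, ms$R, tolerance = 1e-12)
  # only the outermost right neuron active
  g <- numeric(120); g[120] <- 1
  ms <- motor_signals(g)
  expect_equal(ms$R, 0.025)
  expect_equal(ms$L, 0)
})

test_that("gaze updates integrate the motor signals and respect the bounds", {
  gs <- gaze_state(20)
  expect_equal(update_gaze(gs, 0.2, 0.2)$x_c, 20)
  expect_equal(update_gaze(gs, 0, 0.3)$x_c, 20.3)
  gs <- gaze_state(36)
  expect_equal(update_gaze(gs, 0, 1)$x_c, 36)
  gs <- gaze_state(5)
  expect_equal(update_gaze(gs, 1, 0)$x_c, 5)
})

test_that("identical seeds give bit-identical trials", {
  task <- task_spec("smooth_pursuit", duration = 1)
  a <- run_trial(task, seed = 17)
  b <- run_trial(task, seed = 17)
  expect_identical(a$eye, b$eye)
  expect_identical(a$raster, b$raster)
  expect_identical(a$mln_sum, b$mln_sum)
  c <- run_trial(task, seed = 18)
  expect_false(identical(a$eye, c$eye))
  # trace lengths equal duration x record rate; eye bounded
  expect_length(a$eye, 400)
  expect_true(all(a$eye >= 5 & a$eye <= 36))
  expect_true(all(is.finite(a$eye)))
})
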