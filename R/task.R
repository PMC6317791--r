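#' Task specification
#'
#' The two attention tasks run on the model.  In smooth pursuit the target
#' center moves sinusoidally between retinotopic indices 11 and 30 at 1 Hz
#' (center 20.5, amplitude 9.5).  In fixation the target is constant at
#' index 10 and an equal-width, equal-amplitude distractor appears at index
#' 25 from 2 s onward.
#'
#' @param kind `"smooth_pursuit"` or `"fixation"`.
#' @param duration trial duration in seconds.
#' @param target_center,target_amplitude,target_freq pursuit sinusoid
#'   parameters (index units, Hz).
#' @param fixation_position target index for the fixation task.
#' @param distractor_position,distractor_onset distractor index and onset
#'   time (s); set position to `NA` to disable.
#' @param rate_base,rate_peak baseline and maximal Poisson rates, sp/s.
#' @param bump_exponent exponent of the stimulus bump,
#'   `rate = base + (peak - base) exp(-|u|^p / 2)`; the default quartic
#'   (p = 4) gives a flat-topped bump about +/- 1.5 afferents wide.
#' @param n_afferents number of thalamic afferents (the retinotopic axis).
#' @return object of class `task_spec`.
#' @export
task_spec <- function(kind = c("smooth_pursuit", "fixation"), duration = 8,
                      target_center = 20.5, target_amplitude = 9.5,
                      target_freq = 1, fixation_position = 10,
                      distractor_position = 25, distractor_onset = 2,
                      rate_base = 30, rate_peak = 250, bump_exponent = 4,
                      n_afferents = 40) {
  kind <- match.arg(kind)
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (kind == "fixation" && !is.na(distractor_position) &&
      distractor_onset >= duration)
    stop("distractor onset must precede trial end", call. = FALSE)
  structure(list(kind = kind, duration = duration,
                 target_center = target_center,
                 target_amplitude = target_amplitude,
                 target_freq = target_freq,
                 fixation_position = fixation_position,
                 distractor_position = distractor_position,
                 distractor_onset = distractor_onset,
                 rate_base = rate_base, rate_peak = rate_peak,
                 bump_exponent = bump_exponent, n_afferents = n_afferents),
            class = "task_spec")
}

#' Target position at time t
#'
#' @param spec a [task_spec].
#' @param t time in seconds (vectorized), within `[0, duration]`.
#' @return target center in retinotopic index units.
#' @export
target_position <- function(spec, t) {
  if (any(t < 0 | t > spec$duration))
    stop("t outside trial duration", call. = FALSE)
  if (spec$kind == "smooth_pursuit") {
    spec$target_center +
      spec$target_amplitude * sin(2 * pi * spec$target_freq * t)
  } else {
    rep_len(spec$fixation_position, length(t))
  }
}

#' Distractor position at time t (NA before onset or when disabled)
#' @rdname target_position
#' @export
distractor_position <- function(spec, t) {
  out <- rep(NA_real_, length(t))
  if (spec$kind == "fixation" && !is.na(spec$distractor_position))
    out[t >= spec$distractor_onset] <- spec$distractor_position
  out
}

#' Instantaneous Poisson rates of the thalamic afferents
#'
#' The stimulus is a bump in gaze-centered retinal coordinates: afferent i
#' peaks when the retinal offset `0.5 N - i` equals the gaze-target
#' displacement `x_c - x_T`.  Rates are
#' `base + (peak - base) exp(-|u|^p / 2)`.  A distractor contributes an
#' identical bump at its own position; the two are combined by element-wise
#' maximum, preserving the printed rate ceiling, and rates are clipped at
#' the peak.
#'
#' @param x_c current gaze center (index units).
#' @param x_T target center.
#' @param distractor optional distractor center (`NULL` or `NA` for none).
#' @param spec a [task_spec].
#' @return rate vector (sp/s) over the afferents.
#' @export
stimulus_rates <- function(x_c, x_T, distractor = NULL, spec = task_spec()) {
  i <- seq_len(spec$n_afferents)
  bump <- function(x) {
    u <- 0.5 * spec$n_afferents - i - (x_c - x)
    spec$rate_base + (spec$rate_peak - spec$rate_base) *
      exp(-abs(u)^spec$bump_exponent / 2)
  }
  rates <- bump(x_T)
  if (!is.null(distractor) && !is.na(distractor))
    rates <- pmax(rates, bump(distractor))
  pmin(rates, spec$rate_peak)
}

#' Sample one step of Poisson afferent spikes
#'
#' Bernoulli approximation with per-step probability `rate * step_h / 1000`.
#'
#' @param rates rate vector in sp/s.
#' @param cfg an [integrator_config].
#' @return logical spike vector.
#' @export
sample_input_spikes <- function(rates, cfg = integrator_config()) {
  if (any(rates < 0)) stop("rates must be nonnegative", call. = FALSE)
  p <- rates * cfg$step_h / 1000
  if (any(p > 1))
    stop("rate * step exceeds 1; reduce step_h", call. = FALSE)
  runif(length(p)) < p
}

#' Motor error map readout
#'
#' The middle cortical layer is read out as a motor error map: the left
#' half (indices up to N/2) drives leftward movement with ramp weights
#' `0.025 [(N/2 - i) / (N/2)]^+`, the right half drives rightward movement
#' with `0.025 [(i - N/2) / (N/2)]^+`.
#'
#' @param g_M_fast fast conductance vector over the middle-layer neurons.
#' @return list with scalar movement signals `L` and `R`.
#' @export
motor_signals <- function(g_M_fast) {
  n <- length(g_M_fast)
  w <- motor_weights(n)
  list(L = sum(w$left * g_M_fast), R = sum(w$right * g_M_fast))
}

motor_weights <- function(n) {
  i <- seq_len(n)
  half <- 0.5 * n
  left <- 0.025 * pmax((half - i) / half, 0)
  right <- 0.025 * pmax((i - half) / half, 0)
  left[i > half] <- 0
  right[i <= half] <- 0
  list(left = left, right = right)
}

#' Gaze state
#'
#' @param x_c gaze center in retinotopic index units.
#' @param bounds lower/upper clamp for the eye position.
#' @return object of class `gaze_state`.
#' @export
gaze_state <- function(x_c = 20.5, bounds = c(5, 36)) {
  structure(list(x_c = x_c, bounds = bounds), class = "gaze_state")
}

#' Update the gaze center
#'
#' `x_c <- clamp(x_c + R - L, bounds)`; applied every integration step.
#'
#' @param state a [gaze_state].
#' @param L,R movement signals from [motor_signals()].
#' @return the updated `gaze_state`.
#' @export
update_gaze <- function(state, L, R) {
  state$x_c <- min(max(state$x_c + R - L, state$bounds[1]), state$bounds[2])
  state
}

#' Run one closed-loop trial
#'
#' Simulates the full perception-action loop at the integration step for
#' the trial duration: stimulus rates follow the gaze-relative target (and
#' distractor), Poisson afferent spikes drive the thalamus, the network
#' advances one step, the middle-layer motor map moves the eye, and the new
#' gaze position feeds back into the stimulus.  Behavioral traces are
#' recorded at the configured rate (400 Hz); spikes are recorded at full
#' resolution.  Perturbation modifiers are active only inside the
#' perturbation window (by default the final 2 s).
#'
#' @param task a [task_spec].
#' @param perturb a [perturbation_spec] (default: none).
#' @param net_cfg a [network_config].
#' @param seed integer seed; controls both the parameter jitter and the
#'   Poisson input stream.  Identical seeds and configurations reproduce
#'   the trial bit-exactly.
#' @return object of class `trial_record`: `time`, `eye`, `target`,
#'   `distractor` (400 Hz vectors), `mln_sum` (summed middle-layer
#'   voltage), `p_t` (dSTP factor matrix, afferents x samples), `raster`
#'   (data.frame with `time`, `pop`, `neuron`), plus the specs and seed.
#' @export
run_trial <- function(task = task_spec(), perturb = perturbation_spec("none"),
                      net_cfg = network_config(), seed = 1) {
  icfg <- net_cfg$integrator
  if (icfg$tau_s != 1)
    stop("the compiled engine assumes tau_s = 1 ms", call. = FALSE)
  set.seed(seed)
  state <- network_state(net_cfg)   # consumes jitter draws from the seed
  n_steps <- as.integer(round(task$duration * 1000 / icfg$step_h))
  par <- engine_params(task, perturb, net_cfg, state, n_steps)
  out <- crt_engine(par)
  build_trial_record(out, task, perturb, net_cfg, seed, n_steps)
}

# Assemble the full parameter list consumed by the compiled engine (and by
# the scalar reference implementation used in the tests).
engine_params <- function(task, perturb, net_cfg, state, n_steps) {
  icfg <- net_cfg$integrator
  t_steps <- (seq_len(n_steps) - 1) * icfg$step_h / 1000
  list(
    step_h = icfg$step_h, n_steps = n_steps,
    record_stride = icfg$record_stride,
    spike_pulse_magnitude = icfg$spike_pulse_magnitude,
    spike_pulse_steps = icfg$spike_pulse_steps,
    pops = engine_pops(state),
    synapses = engine_synapses(state),
    t_channels = list(
      T = list(amplitude = net_cfg$amplitude$t_ca,
               unit_scale = t_channel_params()$unit_scale, v_init = -65),
      R = list(amplitude = net_cfg$amplitude$r_ca,
               unit_scale = t_channel_params()$unit_scale, v_init = -65)),
    weights = state$connectome[c("dt", "tmp", "tmd", "md", "tr", "dr", "gap",
                                 "pvpv", "pvm", "cbm", "mpv", "mcb")],
    amplitudes = engine_amplitudes(net_cfg),
    motor_left = motor_weights(net_cfg$n_m)$left,
    motor_right = motor_weights(net_cfg$n_m)$right,
    task = list(target = target_position(task, t_steps),
                distractor = distractor_position(task, t_steps),
                rate_base = task$rate_base,
                rate_amp = task$rate_peak - task$rate_base,
                rate_max = task$rate_peak,
                bump_exponent = task$bump_exponent,
                gaze_init = state$gaze$x_c,
                gaze_lo = state$gaze$bounds[1],
                gaze_hi = state$gaze$bounds[2]),
    perturbation = engine_perturbation(perturb, icfg),
    use_poisson = TRUE)
}

engine_pops <- function(state) {
  lapply(state$params[c("T", "R", "M", "D", "PV", "CB")], function(p) {
    list(a = p$a, b = p$b, c = p$c, d = p$d, v0 = p$c,
         spike_threshold = p$spike_threshold)
  })
}

engine_synapses <- function(state) {
  lapply(state$synapses, function(s)
    list(tau_rise = s$tau_rise, tau_fall = s$tau_fall, coef = s$coef))
}

engine_amplitudes <- function(cfg) {
  a <- cfg$amplitude
  # Gaussian amplitudes are folded into the connectome matrices; receptor
  # level amplitudes and the uniform reticulo-thalamic weight stay explicit.
  list(dt = 1, tmp = 1, tmd = 1, md = 1, tr = 1, dr = 1, gap = 1,
       pvpv = 1, pvm = 1, cbm = 1,
       mpv_ampa = a$mpv_ampa, mpv_nmda = a$mpv_nmda,
       mcb_ampa = a$mcb_ampa, mcb_nmda = a$mcb_nmda,
       rt = a$rt, astp = a$astp, ext_ampa = a$ext_ampa, ext_nmda = a$ext_nmda)
}

engine_perturbation <- function(perturb, icfg) {
  f <- perturbation_factors(perturb)
  steps_per_s <- 1000 / icfg$step_h
  list(onset_step = as.integer(round(perturb$onset * steps_per_s)),
       offset_step = as.integer(round(perturb$offset * steps_per_s)),
       pv_nmda = f$pv_nmda, cb_nmda = f$cb_nmda, dstp = f$dstp,
       pv_gaba = f$pv_gaba, cb_gaba = f$cb_gaba, i_hyp = f$i_hyp)
}

build_trial_record <- function(out, task, perturb, net_cfg, seed, n_steps) {
  fs <- net_cfg$integrator$record_rate
  h <- net_cfg$integrator$step_h
  pops <- c("T", "R", "M", "D", "PV", "CB")
  structure(list(
    time = (seq_along(out$eye) - 1) / fs,
    eye = out$eye, target = out$target, distractor = out$distractor,
    mln_sum = out$mln_sum, p_t = out$p_t,
    raster = data.frame(time = out$raster_step * h / 1000,
                        pop = factor(pops[out$raster_pop + 1], levels = pops),
                        neuron = out$raster_neuron),
    task = task, perturbation = perturb, net_cfg = net_cfg, seed = seed,
    record_rate = fs), class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> %s, %.3g s, perturbation %s, seed %s\n",
              x$task$kind, x$task$duration, x$perturbation$kind, x$seed))
  cat(sprintf("  %d spikes, eye range [%.2f, %.2f]\n",
              nrow(x$raster), min(x$eye), max(x$eye)))
  invisible(x)
}
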