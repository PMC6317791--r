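#' Integrator configuration
#'
#' Settings for the forward-Euler integration of the network.  Time is
#' expressed in milliseconds throughout; the Izhikevich equations are used in
#' their standard millisecond form (integration time-scale constant 1 ms).
#'
#' The spike signal K driving the synaptic transmitter variable is a
#' rectangular pulse emitted when a presynaptic neuron fires.  Its product
#' `spike_pulse_magnitude * spike_pulse_duration` (the impulse) sets the
#' unitary synaptic efficacy; halving the step while doubling the magnitude
#' leaves results essentially unchanged, which is the compensation rule used
#' by the step-halving invariance checks.
#'
#' @param step_h Euler step in ms.
#' @param tau_s integration time-scale constant in ms (the membrane and
#'   synaptic rate equations are divided by it).
#' @param record_rate recording rate of behavioral traces, Hz.  The record
#'   interval must be an integer multiple of `step_h`.
#' @param spike_pulse_duration duration of the spike pulse K in ms; defaults
#'   to one integration step.
#' @param spike_pulse_magnitude dimensionless height of the spike pulse K.
#'   The default (8 at a 0.025 ms step, impulse 0.2 ms) is the unitary
#'   efficacy calibration under which single presynaptic spikes produce
#'   visible postsynaptic potentials and the full network supports accurate
#'   stimulus tracking.
#' @return an object of class `integrator_config`.
#' @export
integrator_config <- function(step_h = 0.025, tau_s = 1, record_rate = 400,
                              spike_pulse_duration = step_h,
                              spike_pulse_magnitude = 0.2 / step_h) {
  if (!is.numeric(step_h) || length(step_h) != 1L || step_h <= 0)
    stop("step_h must be a positive scalar", call. = FALSE)
  if (tau_s <= 0) stop("tau_s must be positive", call. = FALSE)
  rec_ms <- 1000 / record_rate
  if (abs(rec_ms / step_h - round(rec_ms / step_h)) > 1e-8)
    stop("record interval must be an integer multiple of step_h", call. = FALSE)
  if (spike_pulse_duration <= 0 || spike_pulse_magnitude <= 0)
    stop("spike pulse parameters must be strictly positive", call. = FALSE)
  structure(list(step_h = step_h, tau_s = tau_s, record_rate = record_rate,
                 record_stride = as.integer(round(rec_ms / step_h)),
                 spike_pulse_duration = spike_pulse_duration,
                 spike_pulse_magnitude = spike_pulse_magnitude,
                 spike_pulse_steps = max(1L, as.integer(round(spike_pulse_duration / step_h)))),
            class = "integrator_config")
}

#' Izhikevich neuron parameters
#'
#' The two canonical parameter sets used in the circuit are the regular
#' spiking set `(a, b, c, d) = (0.02, 0.2, -65, 0)` used for all excitatory
#' populations, the reticular nucleus and the calbindin interneurons, and the
#' fast-spiking set `(0.1, 0.2, -65, 2)` used for the parvalbumin
#' interneurons.
#'
#' @param a,b,c,d Izhikevich recovery/reset parameters; scalars or per-neuron
#'   vectors.  `c` is the post-spike reset voltage in mV.
#' @param spike_threshold spike detection threshold in mV.
#' @return an object of class `izhikevich_params`.
#' @export
izhikevich_params <- function(a = 0.02, b = 0.2, c = -65, d = 0,
                              spike_threshold = 30) {
  if (any(a <= 0) || any(b <= 0)) stop("a and b must be positive", call. = FALSE)
  if (any(c >= spike_threshold)) stop("reset c must lie below threshold", call. = FALSE)
  structure(list(a = a, b = b, c = c, d = d, spike_threshold = spike_threshold),
            class = "izhikevich_params")
}

#' Regular-spiking and fast-spiking parameter sets
#' @rdname izhikevich_params
#' @export
izhikevich_rs <- function() izhikevich_params(0.02, 0.2, -65, 0)

#' @rdname izhikevich_params
#' @export
izhikevich_fs <- function() izhikevich_params(0.1, 0.2, -65, 2)

#' Initialize a neuron population with parameter jitter
#'
#' Draws per-neuron parameters as `nominal * uniform(1 - jitter_frac,
#' 1 + jitter_frac)`, independently per neuron and per parameter, and sets the
#' initial state to the (jittered) reset potential with `u = b * v`.
#'
#' @param n number of neurons.
#' @param nominal an [izhikevich_params] object with scalar entries.
#' @param jitter_frac relative jitter half-width (default 0.05, i.e. +/- 5%).
#' @param seed optional integer seed; when given, `set.seed()` is called.
#' @return list with elements `params` (per-neuron [izhikevich_params]) and
#'   `state` (a `population_state`: vectors `v`, `u`, logical `spiked`).
#' @export
init_population <- function(n, nominal = izhikevich_rs(), jitter_frac = 0.05,
                            seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a positive count", call. = FALSE)
  if (jitter_frac < 0 || jitter_frac >= 1)
    stop("jitter_frac must lie in [0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  jit <- function(x) x * runif(n, 1 - jitter_frac, 1 + jitter_frac)
  params <- izhikevich_params(a = jit(nominal$a), b = jit(nominal$b),
                              c = jit(nominal$c), d = jit(nominal$d),
                              spike_threshold = nominal$spike_threshold)
  v <- params$c
  state <- structure(list(v = v, u = params$b * v, spiked = rep(FALSE, n)),
                     class = "population_state")
  list(params = params, state = state)
}

#' One forward-Euler step of an Izhikevich population
#'
#' Advances `v` and `u` by one Euler step of the membrane equations
#' `dv/dt = 0.04 v^2 + 5 v + 140 - u + I` and `du/dt = a (b v - u)`, then
#' applies the after-spike reset: neurons whose updated voltage reaches the
#' threshold are flagged, reset to `c`, and have `d` added to `u`.
#'
#' @param state a `population_state` (vectors `v`, `u`).
#' @param params an [izhikevich_params] object (scalar or per-neuron).
#' @param total_input summed input current, one value per neuron.
#' @param cfg an [integrator_config].
#' @return the updated `population_state`.
#' @export
step_izhikevich <- function(state, params, total_input, cfg = integrator_config()) {
  v <- state$v; u <- state$u
  if (length(total_input) != length(v))
    stop("total_input length must equal population size", call. = FALSE)
  if (!all(is.finite(v)) || !all(is.finite(u)) || !all(is.finite(total_input)))
    stop("non-finite state or input in step_izhikevich", call. = FALSE)
  h <- cfg$step_h / cfg$tau_s
  vn <- v + h * (0.04 * v * v + 5 * v + 140 - u + total_input)
  un <- u + h * (params$a * (params$b * v - u))
  sp <- vn >= params$spike_threshold
  cc <- rep_len(params$c, length(v)); dd <- rep_len(params$d, length(v))
  vn[sp] <- cc[sp]
  un[sp] <- un[sp] + dd[sp]
  structure(list(v = vn, u = un, spiked = sp), class = "population_state")
}
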