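#' T-type calcium channel parameters
#'
#' Low-threshold calcium channel with Goldman-Hodgkin-Katz (GHK) current
#' form, the substrate of hyperpolarization-driven rebound bursting in
#' thalamus and reticular nucleus.
#'
#' `unit_scale` folds the unit chain of the GHK expression into the model's
#' dimensionless current scale; the calibration contract is rebound bursting
#' rather than an absolute current magnitude.
#'
#' @param amplitude channel amplitude: 20 for thalamic relay neurons, 12 for
#'   reticular neurons.
#' @param p_ca maximum open-channel permeability (30 cm^3/s).
#' @param z calcium ion charge (+2).
#' @param faraday Faraday constant, C/mol.
#' @param gas_constant gas constant, J/(mol K).
#' @param temperature kelvin.
#' @param ca_ext external calcium concentration, mM.
#' @param ca_rest resting internal calcium concentration, mM.
#' @param unit_scale conversion from raw GHK flux to model current units.
#' @return object of class `t_channel_params`.
#' @export
t_channel_params <- function(amplitude = 20, p_ca = 30, z = 2,
                             faraday = 96485.3, gas_constant = 8.314,
                             temperature = 298, ca_ext = 2,
                             ca_rest = 0.00024, unit_scale = 1e-6) {
  stopifnot(amplitude > 0, p_ca > 0, z > 0, faraday > 0, gas_constant > 0,
            temperature > 0, ca_ext > 0, ca_rest > 0, unit_scale > 0)
  structure(list(amplitude = amplitude, p_ca = p_ca, z = z, faraday = faraday,
                 gas_constant = gas_constant, temperature = temperature,
                 ca_ext = ca_ext, ca_rest = ca_rest, unit_scale = unit_scale),
            class = "t_channel_params")
}

#' Steady states and time constants of the T-channel gates
#'
#' Activation: `m_inf(v) = 1 / (1 + exp(-(v + 79) / 6.2))`; inactivation:
#' `h_inf(v) = 1 / (1 + exp((v + 92) / 4))`; Huguenard-McCormick style
#' voltage-dependent time constants (ms).
#'
#' @param v membrane voltage in mV (vectorized).
#' @return list with `m_inf`, `h_inf`, `tau_m`, `tau_h`.
#' @export
t_gate_functions <- function(v) {
  list(m_inf = 1 / (1 + exp(-(v + 79) / 6.2)),
       h_inf = 1 / (1 + exp((v + 92) / 4)),
       tau_m = 0.999 + 0.333 / (exp((v + 31) / 10) + exp(-(v + 106) / 15)),
       tau_h = (30.8 + (211.4 + exp((v + 119.2) / 5)) /
                  (1 + exp((v + 90) / 3.2))) / 3.7373)
}

#' Raw GHK calcium flux
#'
#' Evaluates the GHK current expression
#' `P z^2 F^2 V / (R T) * (Ca_int - Ca_ext exp(-zFV/RT)) / (1 - exp(-zFV/RT))`
#' with `V` the membrane potential converted to volts.  The removable
#' singularity at `v = 0` is handled by its limit
#' `P z F (Ca_int - Ca_ext)`.  The flux is negative (inward) at
#' physiological voltages because internal calcium is far below external.
#'
#' @param v membrane voltage in mV (vectorized).
#' @param ca_int internal calcium concentration, mM.
#' @param params a [t_channel_params].
#' @return raw flux (model units before `amplitude * unit_scale` folding).
#' @export
ghk_flux <- function(v, ca_int, params = t_channel_params()) {
  V <- v / 1000
  with(params, {
    x <- z * faraday * V / (gas_constant * temperature)
    out <- numeric(length(x))
    small <- abs(x) < 1e-6
    out[small] <- p_ca * z * faraday * (rep_len(ca_int, length(x))[small] - ca_ext)
    xb <- x[!small]
    out[!small] <- p_ca * z * z * faraday * faraday * V[!small] /
      (gas_constant * temperature) *
      (rep_len(ca_int, length(x))[!small] - ca_ext * exp(-xb)) / (1 - exp(-xb))
    out
  })
}

#' Create a T-channel state
#'
#' Gates start at their steady states for the initial voltage; internal
#' calcium at rest.
#'
#' @param n number of neurons.
#' @param v_init initial membrane voltage, mV.
#' @param params a [t_channel_params].
#' @return object of class `t_channel_state` with gates `m`, `h` and
#'   calcium pool `ca_int`.
#' @export
t_channel_state <- function(n, v_init = -65, params = t_channel_params()) {
  gf <- t_gate_functions(v_init)
  structure(list(m = rep_len(gf$m_inf, n), h = rep_len(gf$h_inf, n),
                 ca_int = rep(params$ca_rest, n)),
            class = "t_channel_state")
}

#' One step of the T-type calcium channel
#'
#' Returns the depolarizing model current computed from the previous-step
#' state, `I = -unit_scale * amplitude * m^2 h * ghk_flux(v, ca_int)`
#' (positive at subthreshold voltages since the raw GHK flux is inward),
#' then advances the gates by first-order relaxation to their steady states
#' and the calcium pool by
#' `dCa/dt = -(10 / (z F)) [I_raw]^+ - 0.2 (Ca - ca_rest)`,
#' where the rectifier acts on the raw (inward-negative) flux so calcium
#' relaxes to its resting point absent outward current.
#'
#' @param state a [t_channel_state].
#' @param v membrane voltages, mV.
#' @param params a [t_channel_params].
#' @param cfg an [integrator_config].
#' @return list with the updated `state` and the `current` vector.
#' @export
step_t_channel <- function(state, v, params = t_channel_params(),
                           cfg = integrator_config()) {
  raw <- params$amplitude * state$m^2 * state$h * ghk_flux(v, state$ca_int, params)
  current <- -params$unit_scale * raw
  h <- cfg$step_h / cfg$tau_s
  gf <- t_gate_functions(v)
  state$ca_int <- state$ca_int +
    h * (-10 / (params$z * params$faraday) * pmax(raw, 0) -
           0.2 * (state$ca_int - params$ca_rest))
  state$m <- state$m + h * (gf$m_inf - state$m) / gf$tau_m
  state$h <- state$h + h * (gf$h_inf - state$h) / gf$tau_h
  list(state = state, current = current)
}
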