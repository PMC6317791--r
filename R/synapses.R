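#' Synapse kinetics
#'
#' Rise/fall time constants of the saturating-differential (SD) postsynaptic
#' conductance classes.  The five classes are: `fast` (2/10 ms; AMPA and the
#' GABA-A output of calbindin interneurons), `nmda` (8/100 ms), `pv_fast`
#' (0.1/0.5 ms; the parvalbumin interneuron GABA-A output), `gaba_b`
#' (8/30 ms; the reticulo-thalamic synapse) and `xslow` (200/400 ms; the
#' extra-slow deep-layer conductance that drives disinhibitory short-term
#' plasticity).
#'
#' @param kind one of `"fast"`, `"nmda"`, `"pv_fast"`, `"gaba_b"`, `"xslow"`.
#' @param tau_rise,tau_fall optional overrides in ms (`0 < tau_rise <
#'   tau_fall`); vectors allowed for per-neuron jittered kinetics.
#' @return an object of class `synapse_kinetics`.
#' @export
synapse_kinetics <- function(kind = c("fast", "nmda", "pv_fast", "gaba_b", "xslow"),
                             tau_rise = NULL, tau_fall = NULL) {
  kind <- match.arg(kind)
  defaults <- list(fast = c(2, 10), nmda = c(8, 100), pv_fast = c(0.1, 0.5),
                   gaba_b = c(8, 30), xslow = c(200, 400))[[kind]]
  if (is.null(tau_rise)) tau_rise <- defaults[1]
  if (is.null(tau_fall)) tau_fall <- defaults[2]
  if (any(tau_rise <= 0) || any(tau_fall <= tau_rise))
    stop("need 0 < tau_rise < tau_fall", call. = FALSE)
  structure(list(kind = kind, tau_rise = tau_rise, tau_fall = tau_fall),
            class = "synapse_kinetics")
}

#' SD conductance drive coefficient
#'
#' Coefficient of the transmitter-driven rise term in the conductance
#' equation, `(tau_fall + tau_rise) / tau_fall^2`.  Together with the decay
#' `g / tau_fall` this yields unitary conductance transients that peak
#' between `tau_rise` and `tau_fall` and saturate below 1 under sustained
#' drive.
#'
#' @param kin a [synapse_kinetics] object.
#' @return numeric coefficient (vector if the kinetics are per-neuron).
#' @export
sd_coefficient <- function(kin) {
  (kin$tau_fall + kin$tau_rise) / (kin$tau_fall^2)
}

#' Create an SD conductance state
#'
#' @param n number of presynaptic neurons.
#' @param kin a [synapse_kinetics] object.
#' @return object of class `conductance_state` with transmitter `Q`,
#'   conductance `g` (both zero) and the per-neuron spike-pulse countdown.
#' @export
conductance_state <- function(n, kin) {
  structure(list(Q = numeric(n), g = numeric(n), pulse_remaining = integer(n),
                 kinetics = kin, coef = rep_len(sd_coefficient(kin), n),
                 tau_rise = rep_len(kin$tau_rise, n),
                 tau_fall = rep_len(kin$tau_fall, n)),
            class = "conductance_state")
}

#' One Euler step of the SD conductance pair
#'
#' A presynaptic spike loads a rectangular pulse K (height
#' `spike_pulse_magnitude` for `spike_pulse_duration`).  The transmitter
#' variable Q relaxes as `dQ/dt = (1 - Q) K - Q / tau_rise` and the
#' conductance as `dg/dt = coef (1 - g) Q - g / tau_fall`; both saturate
#' below 1.
#'
#' @param state a [conductance_state].
#' @param spikes logical vector of presynaptic spikes for this step.
#' @param kin unused placeholder kept for call symmetry; kinetics live in the
#'   state.
#' @param cfg an [integrator_config].
#' @return the updated `conductance_state`.
#' @export
step_sd_conductance <- function(state, spikes, kin = NULL, cfg = integrator_config()) {
  if (length(spikes) != length(state$Q))
    stop("spikes length must match conductance state", call. = FALSE)
  pulse <- state$pulse_remaining
  pulse[spikes] <- cfg$spike_pulse_steps
  K <- ifelse(pulse > 0L, cfg$spike_pulse_magnitude, 0)
  pulse <- pmax(pulse - 1L, 0L)
  h <- cfg$step_h / cfg$tau_s
  Q <- state$Q; g <- state$g
  Q <- Q + h * ((1 - Q) * K - Q / state$tau_rise)
  g <- g + h * (state$coef * (1 - g) * Q - g / state$tau_fall)
  # flush decaying tails to zero before they reach subnormal range
  Q[Q < 1e-30] <- 0
  g[g < 1e-30] <- 0
  state$Q <- Q; state$g <- g; state$pulse_remaining <- pulse
  state
}

#' NMDA voltage gate
#'
#' Fraction of NMDA conductance unblocked at postsynaptic voltage `v`:
#' `B(v) = 1 / (1 + 0.4202 exp(-0.062 v))`, the standard magnesium-block
#' form that opens with depolarization.
#'
#' @param v membrane voltage in mV (vectorized).
#' @return gate fraction in (0, 1).
#' @export
nmda_gate <- function(v) {
  1 / (1 + 0.4202 * exp(-0.062 * v))
}

#' Receptor specification
#'
#' @param kind `"ampa"`, `"nmda"`, `"gaba_a"` or `"gaba_b"`.
#' @param reversal reversal potential in mV (defaults 0, 0, -70, -90).
#' @param amplitude nonnegative current amplitude.
#' @return object of class `receptor_spec`.
#' @export
receptor_spec <- function(kind = c("ampa", "nmda", "gaba_a", "gaba_b"),
                          reversal = NULL, amplitude = 1) {
  kind <- match.arg(kind)
  if (is.null(reversal))
    reversal <- c(ampa = 0, nmda = 0, gaba_a = -70, gaba_b = -90)[[kind]]
  if (amplitude < 0) stop("amplitude must be nonnegative", call. = FALSE)
  structure(list(kind = kind, reversal = reversal, amplitude = amplitude),
            class = "receptor_spec")
}

#' Postsynaptic receptor current
#'
#' Computes `amplitude * (E_rev - v_post) * sum_pre W g_pre`, so the current
#' depolarizes the postsynaptic neuron when its voltage lies below the
#' receptor reversal potential and hyperpolarizes it above; it vanishes
#' exactly at the reversal.  NMDA currents are additionally scaled by the
#' voltage gate [nmda_gate()].
#'
#' @param spec a [receptor_spec].
#' @param v_post postsynaptic voltages (length = number of postsynaptic
#'   neurons).
#' @param W weight matrix, presynaptic rows by postsynaptic columns.
#' @param g_pre presynaptic conductance vector.
#' @return signed current vector over postsynaptic neurons.
#' @export
receptor_current <- function(spec, v_post, W, g_pre) {
  if (nrow(W) != length(g_pre) || ncol(W) != length(v_post))
    stop("weight matrix shape does not map pre to post", call. = FALSE)
  drive <- spec$reversal - v_post
  if (spec$kind == "nmda") drive <- drive * nmda_gate(v_post)
  spec$amplitude * drive * colSums(W * g_pre)
}

#' Gap-junction coupling current
#'
#' For each neuron, `sum_pre W (v_pre - v_post)`.  The matrix must be
#' symmetric with zero diagonal; the total summed gap current over the
#' population is therefore zero.
#'
#' @param W_gap symmetric weight matrix with zero diagonal.
#' @param v membrane voltages.
#' @return current vector.
#' @export
gap_current <- function(W_gap, v) {
  if (!isTRUE(all.equal(W_gap, t(W_gap))))
    stop("gap-junction matrix must be symmetric", call. = FALSE)
  dv <- outer(v, v, "-")   # dv[pre, post] = v_pre - v_post
  colSums(W_gap * dv)
}
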