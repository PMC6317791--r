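#' Network configuration
#'
#' Population sizes, Gaussian connection widths (sigma) and amplitudes (A)
#' of the six-population CRT circuit.  Defaults reproduce the reference
#' parameter table exactly.
#'
#' Population key: T = thalamic relay, R = thalamic reticular nucleus,
#' M = middle-layer pyramidal neurons, D = deep-layer pyramidal neurons,
#' PV = parvalbumin interneurons, CB = calbindin interneurons.
#'
#' @param n_t,n_r,n_pv,n_cb,n_m,n_d population sizes (40, 40, 40, 40, 120, 120).
#' @param sigma named list of Gaussian widths in normalized position units.
#' @param amplitude named list of connection/current amplitudes.
#' @param jitter_frac per-neuron parameter jitter half-width.
#' @param integrator an [integrator_config].
#' @return object of class `network_config`.
#' @export
network_config <- function(n_t = 40, n_r = 40, n_pv = 40, n_cb = 40,
                           n_m = 120, n_d = 120,
                           sigma = list(), amplitude = list(),
                           jitter_frac = 0.05,
                           integrator = integrator_config()) {
  sig <- list(dt = 0.05, tmp = 0.0625, tmd = 0.9375, md = 0.0125,
              tr = 0.0938, dr = 0.0125, gap = 0.0313, pvpv = 0.0313,
              pvm = 0.4375, cbm = 1.25, mpv = 0.025, mcb = 0.125)
  amp <- list(dt = 0.04, tmp = 4.8, tmd = 1.2, md = 1.4, tr = 0.15, dr = 1,
              gap = 0.3, pvpv = 10, pvm = 50, cbm = 1,
              mpv_ampa = 0.5, mpv_nmda = 4, mcb_ampa = 0.03, mcb_nmda = 1,
              rt = 0.32, t_ca = 20, r_ca = 12, astp = 3000,
              ext_ampa = 1, ext_nmda = 1)
  sig[names(sigma)] <- sigma
  amp[names(amplitude)] <- amplitude
  if (any(unlist(sig) <= 0)) stop("all sigma must be positive", call. = FALSE)
  if (any(unlist(amp) < 0)) stop("amplitudes must be nonnegative", call. = FALSE)
  structure(list(n_t = n_t, n_r = n_r, n_pv = n_pv, n_cb = n_cb,
                 n_m = n_m, n_d = n_d, sigma = sig, amplitude = amp,
                 jitter_frac = jitter_frac, integrator = integrator),
            class = "network_config")
}

gaussian_weights <- function(n_pre, n_post, sigma, amplitude = 1) {
  i <- (seq_len(n_pre) / n_pre)
  j <- (seq_len(n_post) / n_post)
  amplitude * exp(-(outer(i, j, "-") / sigma)^2)
}

#' Build the CRT connectome
#'
#' Weight matrices are Gaussian in normalized retinotopic position,
#' `W[i, j] = A exp(-((i/N_pre - j/N_post) / sigma)^2)` (presynaptic rows),
#' with connection amplitudes folded in.  Exceptions: the reticulo-thalamic
#' matrix `rt` is uniformly all-to-all at 0.32; the gap-junction matrix is
#' symmetric with zero diagonal; `mpv` and `mcb` are unit-amplitude shapes
#' because their AMPA and NMDA receptor amplitudes are applied separately in
#' the current equations.
#'
#' @param cfg a [network_config].
#' @return object of class `connectome`: a named list of matrices
#'   (`dt`, `tmp`, `tmd`, `md`, `tr`, `dr`, `gap`, `pvpv`, `pvm`, `cbm`,
#'   `mpv`, `mcb`, `rt`).
#' @export
build_connectome <- function(cfg = network_config()) {
  s <- cfg$sigma; a <- cfg$amplitude
  gap <- gaussian_weights(cfg$n_r, cfg$n_r, s$gap, a$gap)
  diag(gap) <- 0
  structure(list(
    dt   = gaussian_weights(cfg$n_d, cfg$n_t, s$dt, a$dt),
    tmp  = gaussian_weights(cfg$n_t, cfg$n_m, s$tmp, a$tmp),
    tmd  = gaussian_weights(cfg$n_t, cfg$n_m, s$tmd, a$tmd),
    md   = gaussian_weights(cfg$n_m, cfg$n_d, s$md, a$md),
    tr   = gaussian_weights(cfg$n_t, cfg$n_r, s$tr, a$tr),
    dr   = gaussian_weights(cfg$n_d, cfg$n_r, s$dr, a$dr),
    gap  = gap,
    pvpv = gaussian_weights(cfg$n_pv, cfg$n_pv, s$pvpv, a$pvpv),
    pvm  = gaussian_weights(cfg$n_pv, cfg$n_m, s$pvm, a$pvm),
    cbm  = gaussian_weights(cfg$n_cb, cfg$n_m, s$cbm, a$cbm),
    mpv  = gaussian_weights(cfg$n_m, cfg$n_pv, s$mpv, 1),
    mcb  = gaussian_weights(cfg$n_m, cfg$n_cb, s$mcb, 1),
    rt   = matrix(a$rt, cfg$n_r, cfg$n_t)), class = "connectome")
}

#' Middle-layer dendritic input
#'
#' Thalamo-cortical drive onto middle-layer pyramidal neurons has a
#' proximal and a distal dendritic component.  Calbindin interneurons
#' inhibit only the distal component, whose bracket is rectified at zero so
#' dendritic inhibition can never invert the proximal excitation:
#' `I = drive(v) * (W_p g_T + [W_d g_T - W_cb g_CB]^+)` with
#' `drive(v) = (0 - v)`.
#'
#' @param v_M middle-layer membrane voltages.
#' @param g_T thalamic fast conductances.
#' @param g_CB calbindin fast conductances.
#' @param conn a [connectome] (amplitudes folded into `tmp`, `tmd`, `cbm`).
#' @param scale optional named multipliers `proximal`, `distal`, `cb`
#'   (defaults 1), used by the direct CB-GABA perturbation.
#' @return current vector over middle-layer neurons.
#' @export
mln_dendritic_input <- function(v_M, g_T, g_CB, conn,
                                scale = list(proximal = 1, distal = 1, cb = 1)) {
  if (length(g_T) != nrow(conn$tmp) || length(v_M) != ncol(conn$tmp) ||
      length(g_CB) != nrow(conn$cbm))
    stop("shape mismatch in mln_dendritic_input", call. = FALSE)
  proximal <- scale$proximal * colSums(conn$tmp * g_T)
  distal <- scale$distal * colSums(conn$tmd * g_T) -
    scale$cb * colSums(conn$cbm * g_CB)
  (0 - v_M) * (proximal + pmax(distal, 0))
}

#' Initialize the full network state
#'
#' Creates jittered populations (regular-spiking everywhere except the
#' fast-spiking PV interneurons), per-presynaptic-neuron jittered synaptic
#' kinetics for the ten conductance channels, T-type calcium channels for
#' thalamus and reticular nucleus, and the gaze state.
#'
#' Jitter draws consume the R random number stream; call `set.seed()` first
#' (or use [run_trial()] which does) for reproducibility.
#'
#' @param cfg a [network_config].
#' @return object of class `network_state`.
#' @export
network_state <- function(cfg = network_config()) {
  jf <- cfg$jitter_frac
  pops <- list(
    T  = init_population(cfg$n_t, izhikevich_rs(), jf),
    R  = init_population(cfg$n_r, izhikevich_rs(), jf),
    M  = init_population(cfg$n_m, izhikevich_rs(), jf),
    D  = init_population(cfg$n_d, izhikevich_rs(), jf),
    PV = init_population(cfg$n_pv, izhikevich_fs(), jf),
    CB = init_population(cfg$n_cb, izhikevich_rs(), jf))
  jit_kin <- function(kind, n) {
    base <- synapse_kinetics(kind)
    synapse_kinetics(kind,
                     tau_rise = base$tau_rise * runif(n, 1 - jf, 1 + jf),
                     tau_fall = base$tau_fall * runif(n, 1 - jf, 1 + jf))
  }
  chan <- function(kind, n) conductance_state(n, jit_kin(kind, n))
  synapses <- list(
    ext_fast = chan("fast", cfg$n_t),  ext_nmda = chan("nmda", cfg$n_t),
    t_fast   = chan("fast", cfg$n_t),  r_gabab  = chan("gaba_b", cfg$n_r),
    m_fast   = chan("fast", cfg$n_m),  m_nmda   = chan("nmda", cfg$n_m),
    d_fast   = chan("fast", cfg$n_d),  d_xslow  = chan("xslow", cfg$n_d),
    pv_fast  = chan("pv_fast", cfg$n_pv), cb_fast = chan("fast", cfg$n_cb))
  structure(list(
    populations = lapply(pops, `[[`, "state"),
    params = lapply(pops, `[[`, "params"),
    synapses = synapses,
    t_channels = list(
      T = t_channel_state(cfg$n_t, -65,
                          t_channel_params(amplitude = cfg$amplitude$t_ca)),
      R = t_channel_state(cfg$n_r, -65,
                          t_channel_params(amplitude = cfg$amplitude$r_ca))),
    connectome = build_connectome(cfg),
    gaze = gaze_state(),
    p_t = rep(1, cfg$n_t),
    cfg = cfg), class = "network_state")
}

#' Advance the whole network one integration step
#'
#' Pure-R reference implementation of the network update.  Per step:
#' (1) all input currents are assembled from previous-step states exactly as
#' specified for each population (thalamus: external AMPA + NMDA, deep-layer
#' AMPA, calcium current, minus the dSTP-scaled reticular GABA-B; reticular
#' nucleus: thalamic and deep-layer AMPA, calcium, gap junctions, plus any
#' hyperpolarizing input; middle layer: proximal/distal dendritic drive
#' minus PV GABA-A; PV: middle-layer AMPA + NMDA minus PV GABA-A; CB:
#' middle-layer AMPA + NMDA; deep layer: middle-layer AMPA);
#' (2) conductances, calcium gates and the gaze state advance;
#' (3) membranes advance with spike detection and reset.
#'
#' The compiled engine used by [run_trial()] performs the identical
#' computation; the two agree spike-for-spike.
#'
#' @param state a [network_state].
#' @param ext_spikes logical vector of external afferent spikes for this
#'   step (length `n_t`).
#' @param modifiers perturbation modifiers as returned by
#'   [resolve_perturbation()].
#' @return the updated `network_state`, with `spiked` flags per population
#'   and the current dSTP factor in `p_t`.
#' @export
step_network <- function(state, ext_spikes,
                         modifiers = list(pv_nmda = 1, cb_nmda = 1, dstp = 1,
                                          pv_gaba = 1, cb_gaba = 1, i_hyp = 0)) {
  cfg <- state$cfg; a <- cfg$amplitude; W <- state$connectome
  pop <- state$populations; syn <- state$synapses; icfg <- cfg$integrator
  vT <- pop$T$v; vR <- pop$R$v; vM <- pop$M$v; vD <- pop$D$v
  vPV <- pop$PV$v; vCB <- pop$CB$v
  if (!all(vapply(pop, function(p) all(is.finite(p$v)), logical(1))))
    stop("non-finite membrane state in step_network", call. = FALSE)

  # dSTP factor and currents from previous-step conductances
  p_t <- 1 / (1 + a$astp * modifiers$dstp * colSums(W$dt * syn$d_xslow$g^6))
  tchT <- step_t_channel(state$t_channels$T, vT,
                         t_channel_params(amplitude = a$t_ca), icfg)
  tchR <- step_t_channel(state$t_channels$R, vR,
                         t_channel_params(amplitude = a$r_ca), icfg)
  sum_rb <- sum(syn$r_gabab$g)
  I_T <- (0 - vT) * (a$ext_ampa * syn$ext_fast$g + colSums(W$dt * syn$d_fast$g)) +
    (0 - vT) * nmda_gate(vT) * a$ext_nmda * syn$ext_nmda$g +
    tchT$current + p_t * (-90 - vT) * a$rt * sum_rb
  dvR <- outer(vR, vR, "-")
  I_R <- (0 - vR) * (colSums(W$tr * syn$t_fast$g) + colSums(W$dr * syn$d_fast$g)) +
    tchR$current + colSums(W$gap * dvR) + modifiers$i_hyp
  dist <- colSums(W$tmd * syn$t_fast$g) -
    modifiers$cb_gaba * colSums(W$cbm * syn$cb_fast$g)
  I_M <- (0 - vM) * (colSums(W$tmp * syn$t_fast$g) + pmax(dist, 0)) +
    (-70 - vM) * modifiers$pv_gaba * colSums(W$pvm * syn$pv_fast$g)
  I_PV <- (0 - vPV) * a$mpv_ampa * colSums(W$mpv * syn$m_fast$g) +
    (0 - vPV) * nmda_gate(vPV) * modifiers$pv_nmda * a$mpv_nmda *
      colSums(W$mpv * syn$m_nmda$g) +
    (-70 - vPV) * modifiers$pv_gaba * a$pvpv * colSums(W$pvpv * syn$pv_fast$g)
  I_CB <- (0 - vCB) * a$mcb_ampa * colSums(W$mcb * syn$m_fast$g) +
    (0 - vCB) * nmda_gate(vCB) * modifiers$cb_nmda * a$mcb_nmda *
      colSums(W$mcb * syn$m_nmda$g)
  I_D <- (0 - vD) * colSums(W$md * syn$m_fast$g)

  # conductances advance on previous-step spikes (external spikes this step)
  syn$ext_fast <- step_sd_conductance(syn$ext_fast, ext_spikes, cfg = icfg)
  syn$ext_nmda <- step_sd_conductance(syn$ext_nmda, ext_spikes, cfg = icfg)
  syn$t_fast   <- step_sd_conductance(syn$t_fast, pop$T$spiked, cfg = icfg)
  syn$r_gabab  <- step_sd_conductance(syn$r_gabab, pop$R$spiked, cfg = icfg)
  syn$m_fast   <- step_sd_conductance(syn$m_fast, pop$M$spiked, cfg = icfg)
  syn$m_nmda   <- step_sd_conductance(syn$m_nmda, pop$M$spiked, cfg = icfg)
  syn$d_fast   <- step_sd_conductance(syn$d_fast, pop$D$spiked, cfg = icfg)
  syn$d_xslow  <- step_sd_conductance(syn$d_xslow, pop$D$spiked, cfg = icfg)
  syn$pv_fast  <- step_sd_conductance(syn$pv_fast, pop$PV$spiked, cfg = icfg)
  syn$cb_fast  <- step_sd_conductance(syn$cb_fast, pop$CB$spiked, cfg = icfg)
  state$t_channels$T <- tchT$state
  state$t_channels$R <- tchR$state

  # motor error map readout and gaze update
  ms <- motor_signals(syn$m_fast$g)
  state$gaze <- update_gaze(state$gaze, ms$L, ms$R)

  # membranes advance; spikes detected and reset
  pop$T  <- step_izhikevich(pop$T, state$params$T, I_T, icfg)
  pop$R  <- step_izhikevich(pop$R, state$params$R, I_R, icfg)
  pop$M  <- step_izhikevich(pop$M, state$params$M, I_M, icfg)
  pop$D  <- step_izhikevich(pop$D, state$params$D, I_D, icfg)
  pop$PV <- step_izhikevich(pop$PV, state$params$PV, I_PV, icfg)
  pop$CB <- step_izhikevich(pop$CB, state$params$CB, I_CB, icfg)

  state$populations <- pop
  state$synapses <- syn
  state$p_t <- p_t
  state
}
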