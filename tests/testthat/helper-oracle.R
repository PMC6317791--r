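# Scalar loop-based reference implementation of the network update, written
# independently of the compiled engine as plain per-neuron loops.  Used to
# verify the engine spike-for-spike on small networks.

oracle_colsum <- function(W, g, post) {
  col <- W[, post]
  npre <- length(g)
  a <- c(0, 0, 0, 0)
  i <- 1L
  while (i + 3L <= npre) {
    a[1] <- a[1] + col[i] * g[i]
    a[2] <- a[2] + col[i + 1L] * g[i + 1L]
    a[3] <- a[3] + col[i + 2L] * g[i + 2L]
    a[4] <- a[4] + col[i + 3L] * g[i + 3L]
    i <- i + 4L
  }
  acc <- (a[1] + a[2]) + (a[3] + a[4])
  while (i <= npre) {
    acc <- acc + col[i] * g[i]
    i <- i + 1L
  }
  acc
}

oracle_seq_sum <- function(x) {
  acc <- 0
  for (v in x) acc <- acc + v
  acc
}

oracle_ghk <- function(v, ca) {
  faraday <- 96485.3; gas <- 8.314; tempk <- 298; z <- 2; pca <- 30; caext <- 2
  V <- v / 1000
  x <- z * faraday * V / (gas * tempk)
  if (abs(x) < 1e-6) return(pca * z * faraday * (ca - caext))
  pca * z * z * faraday * faraday * V / (gas * tempk) *
    (ca - caext * exp(-x)) / (1 - exp(-x))
}

oracle_nmda_gate <- function(v) 1 / (1 + 0.4202 * exp(-0.062 * v))

oracle_run <- function(par, ext_spikes) {
  h <- par$step_h; n_steps <- par$n_steps
  kmag <- par$spike_pulse_magnitude; kdur <- par$spike_pulse_steps
  pops <- lapply(par$pops, function(p) {
    n <- length(p$a)
    list(a = p$a, b = p$b, c = p$c, d = p$d, v = p$v0, u = p$b * p$v0,
         sp = rep(FALSE, n), thresh = p$spike_threshold, n = n)
  })
  syn <- lapply(par$synapses, function(s) {
    n <- length(s$tau_rise)
    list(Q = numeric(n), g = numeric(n), pulse = integer(n),
         tr = s$tau_rise, tf = s$tau_fall, coef = s$coef, n = n)
  })
  tch <- lapply(list(T = par$t_channels$T, R = par$t_channels$R), function(tc) {
    list(amp = tc$amplitude, kappa = tc$unit_scale,
         m = NULL, h = NULL, ca = NULL, raw = NULL, v0 = tc$v_init)
  })
  for (k in names(tch)) {
    n <- pops[[k]]$n
    v0 <- tch[[k]]$v0
    tch[[k]]$m <- rep(1 / (1 + exp(-(v0 + 79) / 6.2)), n)
    tch[[k]]$h <- rep(1 / (1 + exp((v0 + 92) / 4)), n)
    tch[[k]]$ca <- rep(0.00024, n)
    tch[[k]]$raw <- numeric(n)
  }
  W <- par$weights; a <- par$amplitudes
  xc <- par$task$gaze_init
  lo <- par$task$gaze_lo; hi <- par$task$gaze_hi
  pert <- par$perturbation
  rast <- list(step = integer(0), neuron = integer(0), pop = integer(0))
  eye <- numeric(0)
  step_syn <- function(s, spikes) {
    for (i in seq_len(s$n)) {
      if (spikes[i]) s$pulse[i] <- kdur
      K <- if (s$pulse[i] > 0L) kmag else 0
      if (s$pulse[i] > 0L) s$pulse[i] <- s$pulse[i] - 1L
      s$Q[i] <- s$Q[i] + h * ((1 - s$Q[i]) * K - s$Q[i] / s$tr[i])
      s$g[i] <- s$g[i] + h * (s$coef[i] * (1 - s$g[i]) * s$Q[i] - s$g[i] / s$tf[i])
      if (s$Q[i] < 1e-30) s$Q[i] <- 0
      if (s$g[i] < 1e-30) s$g[i] <- 0
    }
    s
  }
  step_pop <- function(p, I) {
    for (i in seq_len(p$n)) {
      vi <- p$v[i]; ui <- p$u[i]
      vn <- vi + h * (0.04 * vi * vi + 5 * vi + 140 - ui + I[i])
      un <- ui + h * (p$a[i] * (p$b[i] * vi - ui))
      if (vn >= p$thresh) {
        p$sp[i] <- TRUE; vn <- p$c[i]; un <- un + p$d[i]
      } else p$sp[i] <- FALSE
      p$v[i] <- vn; p$u[i] <- un
    }
    p
  }
  for (n in seq_len(n_steps) - 1L) {
    pert_on <- n >= pert$onset_step && n < pert$offset_step
    fpvn <- if (pert_on) pert$pv_nmda else 1
    fcbn <- if (pert_on) pert$cb_nmda else 1
    fstp <- if (pert_on) pert$dstp else 1
    fpvg <- if (pert_on) pert$pv_gaba else 1
    fcbg <- if (pert_on) pert$cb_gaba else 1
    ih <- if (pert_on) pert$i_hyp else 0
    ext <- ext_spikes[n + 1L, ]
    g2 <- syn$d_xslow$g * syn$d_xslow$g
    gx6 <- g2 * g2 * g2
    sum_rb <- oracle_seq_sum(syn$r_gabab$g)
    NT <- pops$T$n
    PT <- numeric(NT); IT <- numeric(NT)
    for (i in seq_len(NT)) {
      vi <- pops$T$v[i]
      tch$T$raw[i] <- tch$T$amp * tch$T$m[i] * tch$T$m[i] * tch$T$h[i] *
        oracle_ghk(vi, tch$T$ca[i])
      tTI <- -tch$T$kappa * tch$T$raw[i]
      PT[i] <- 1 / (1 + a$astp * fstp * a$dt * oracle_colsum(W$dt, gx6, i))
      IT[i] <- (0 - vi) * (a$ext_ampa * syn$ext_fast$g[i] +
                             a$dt * oracle_colsum(W$dt, syn$d_fast$g, i)) +
        (0 - vi) * oracle_nmda_gate(vi) * a$ext_nmda * syn$ext_nmda$g[i] +
        tTI + PT[i] * (-90 - vi) * a$rt * sum_rb
    }
    NR <- pops$R$n
    IR <- numeric(NR)
    for (i in seq_len(NR)) {
      vi <- pops$R$v[i]
      tch$R$raw[i] <- tch$R$amp * tch$R$m[i] * tch$R$m[i] * tch$R$h[i] *
        oracle_ghk(vi, tch$R$ca[i])
      tRI <- -tch$R$kappa * tch$R$raw[i]
      accg <- 0
      for (j in seq_len(NR)) accg <- accg + W$gap[j, i] * (pops$R$v[j] - vi)
      IR[i] <- (0 - vi) * (a$tr * oracle_colsum(W$tr, syn$t_fast$g, i) +
                             a$dr * oracle_colsum(W$dr, syn$d_fast$g, i)) +
        tRI + a$gap * accg + ih
    }
    NM <- pops$M$n
    IM <- numeric(NM)
    for (i in seq_len(NM)) {
      vi <- pops$M$v[i]
      dist <- a$tmd * oracle_colsum(W$tmd, syn$t_fast$g, i) -
        fcbg * a$cbm * oracle_colsum(W$cbm, syn$cb_fast$g, i)
      if (dist < 0) dist <- 0
      IM[i] <- (0 - vi) * (a$tmp * oracle_colsum(W$tmp, syn$t_fast$g, i) + dist) +
        (-70 - vi) * fpvg * a$pvm * oracle_colsum(W$pvm, syn$pv_fast$g, i)
    }
    NPV <- pops$PV$n
    IPV <- numeric(NPV)
    for (i in seq_len(NPV)) {
      vi <- pops$PV$v[i]
      IPV[i] <- (0 - vi) * a$mpv_ampa * oracle_colsum(W$mpv, syn$m_fast$g, i) +
        (0 - vi) * oracle_nmda_gate(vi) * fpvn * a$mpv_nmda *
          oracle_colsum(W$mpv, syn$m_nmda$g, i) +
        (-70 - vi) * fpvg * a$pvpv * oracle_colsum(W$pvpv, syn$pv_fast$g, i)
    }
    NCB <- pops$CB$n
    ICB <- numeric(NCB)
    for (i in seq_len(NCB)) {
      vi <- pops$CB$v[i]
      ICB[i] <- (0 - vi) * a$mcb_ampa * oracle_colsum(W$mcb, syn$m_fast$g, i) +
        (0 - vi) * oracle_nmda_gate(vi) * fcbn * a$mcb_nmda *
          oracle_colsum(W$mcb, syn$m_nmda$g, i)
    }
    ND <- pops$D$n
    ID <- numeric(ND)
    for (i in seq_len(ND))
      ID[i] <- (0 - pops$D$v[i]) * a$md * oracle_colsum(W$md, syn$m_fast$g, i)

    if (n %% par$record_stride == 0L) eye <- c(eye, xc)

    syn$ext_fast <- step_syn(syn$ext_fast, ext)
    syn$ext_nmda <- step_syn(syn$ext_nmda, ext)
    syn$t_fast <- step_syn(syn$t_fast, pops$T$sp)
    syn$r_gabab <- step_syn(syn$r_gabab, pops$R$sp)
    syn$m_fast <- step_syn(syn$m_fast, pops$M$sp)
    syn$m_nmda <- step_syn(syn$m_nmda, pops$M$sp)
    syn$d_fast <- step_syn(syn$d_fast, pops$D$sp)
    syn$d_xslow <- step_syn(syn$d_xslow, pops$D$sp)
    syn$pv_fast <- step_syn(syn$pv_fast, pops$PV$sp)
    syn$cb_fast <- step_syn(syn$cb_fast, pops$CB$sp)
    for (k in c("T", "R")) {
      for (i in seq_len(pops[[k]]$n)) {
        rect <- if (tch[[k]]$raw[i] > 0) tch[[k]]$raw[i] else 0
        vi <- pops[[k]]$v[i]
        tch[[k]]$ca[i] <- tch[[k]]$ca[i] +
          h * (-10 / (2 * 96485.3) * rect - 0.2 * (tch[[k]]$ca[i] - 0.00024))
        tch[[k]]$m[i] <- tch[[k]]$m[i] +
          h * (1 / (1 + exp(-(vi + 79) / 6.2)) - tch[[k]]$m[i]) /
            (0.999 + 0.333 / (exp((vi + 31) / 10) + exp(-(vi + 106) / 15)))
        tch[[k]]$h[i] <- tch[[k]]$h[i] +
          h * (1 / (1 + exp((vi + 92) / 4)) - tch[[k]]$h[i]) /
            ((30.8 + (211.4 + exp((vi + 119.2) / 5)) /
                (1 + exp((vi + 90) / 3.2))) / 3.7373)
      }
    }
    accL <- 0; accR <- 0
    for (i in seq_len(NM)) accL <- accL + par$motor_left[i] * syn$m_fast$g[i]
    for (i in seq_len(NM)) accR <- accR + par$motor_right[i] * syn$m_fast$g[i]
    xc <- xc + (accR - accL)
    if (xc < lo) xc <- lo
    if (xc > hi) xc <- hi

    pops$T <- step_pop(pops$T, IT)
    pops$R <- step_pop(pops$R, IR)
    pops$M <- step_pop(pops$M, IM)
    pops$D <- step_pop(pops$D, ID)
    pops$PV <- step_pop(pops$PV, IPV)
    pops$CB <- step_pop(pops$CB, ICB)
    pn <- 0L
    for (k in c("T", "R", "M", "D", "PV", "CB")) {
      for (i in seq_len(pops[[k]]$n)) if (pops[[k]]$sp[i]) {
        rast$step <- c(rast$step, n)
        rast$neuron <- c(rast$neuron, i)
        rast$pop <- c(rast$pop, pn)
      }
      pn <- pn + 1L
    }
  }
  list(eye = eye, raster_step = rast$step, raster_neuron = rast$neuron,
       raster_pop = rast$pop)
}

# A 4-neuron-per-group toy configuration with deterministic external drive.
toy_setup <- function(duration_ms = 100, seed = 42, jitter = 0.05,
                      perturb = perturbation_spec("none")) {
  cfg <- network_config(n_t = 4, n_r = 4, n_pv = 4, n_cb = 4, n_m = 4, n_d = 4,
                        jitter_frac = jitter)
  task <- task_spec("smooth_pursuit", duration = 1, n_afferents = 4)
  set.seed(seed)
  state <- network_state(cfg)
  n_steps <- as.integer(round(duration_ms / cfg$integrator$step_h))
  par <- crtgaze:::engine_params(task, perturb, cfg, state, n_steps)
  # strong regular drive: every afferent spikes every 2 ms
  ext <- matrix(FALSE, n_steps, cfg$n_t)
  ext[seq(1, n_steps, by = 80), ] <- TRUE
  par$use_poisson <- FALSE
  par$ext_spikes <- ext
  list(par = par, ext = ext, cfg = cfg, state = state)
}
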