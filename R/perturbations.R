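#' Perturbation specification
#'
#' Encodes the inhibitory perturbation protocols as pure modifier schedules.
#' Kinds and their targets:
#' \describe{
#'   \item{pv_nmda}{scales the NMDA amplitude onto PV interneurons.}
#'   \item{cb_nmda}{scales the NMDA amplitude onto CB interneurons.}
#'   \item{combined_nmda}{scales both interneuron NMDA amplitudes jointly.}
#'   \item{trn_hyperpolarize}{adds a constant hyperpolarizing current
#'     (`strength`, negative) to every reticular neuron.}
#'   \item{dstp_reduce}{scales the disinhibitory plasticity constant A_STP.}
#'   \item{pv_gaba_direct}{scales the PV output GABA amplitudes (onto both
#'     middle-layer neurons and other PV interneurons) jointly.}
#'   \item{cb_gaba_direct}{scales the CB output GABA amplitude.}
#'   \item{none}{identity.}
#' }
#'
#' @param kind perturbation kind (see Details).
#' @param strength scale factor in (0, 1] for the scaling kinds, or the
#'   hyperpolarizing current (negative) for `trn_hyperpolarize`.
#' @param onset,offset perturbation window in seconds (defaults 6 to 8:
#'   the final quarter of the standard trial).
#' @return object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(kind = c("none", "pv_nmda", "cb_nmda",
                                       "trn_hyperpolarize", "dstp_reduce",
                                       "pv_gaba_direct", "cb_gaba_direct",
                                       "combined_nmda"),
                              strength = 1, onset = 6, offset = 8) {
  kind <- match.arg(kind)
  if (onset >= offset) stop("onset must precede offset", call. = FALSE)
  if (kind == "trn_hyperpolarize") {
    if (strength > 0) stop("trn_hyperpolarize strength is a current; use a nonpositive value",
                           call. = FALSE)
  } else if (kind != "none" && (strength < 0 || strength > 1)) {
    stop("scaling strengths must lie in [0, 1]", call. = FALSE)
  }
  structure(list(kind = kind, strength = strength, onset = onset,
                 offset = offset), class = "perturbation_spec")
}

perturbation_factors <- function(spec) {
  f <- list(pv_nmda = 1, cb_nmda = 1, dstp = 1, pv_gaba = 1, cb_gaba = 1,
            i_hyp = 0)
  s <- spec$strength
  switch(spec$kind,
         none = f,
         pv_nmda = { f$pv_nmda <- s; f },
         cb_nmda = { f$cb_nmda <- s; f },
         combined_nmda = { f$pv_nmda <- s; f$cb_nmda <- s; f },
         trn_hyperpolarize = { f$i_hyp <- s; f },
         dstp_reduce = { f$dstp <- s; f },
         pv_gaba_direct = { f$pv_gaba <- s; f },
         cb_gaba_direct = { f$cb_gaba <- s; f },
         stop("unknown perturbation kind", call. = FALSE))
}

#' Resolve a perturbation at time t
#'
#' Pure function mapping a perturbation schedule and a time to the
#' parameter modifiers in force: the identity before onset and after
#' offset, the perturbed values inside the window (a step function, no
#' ramp).  The baseline configuration is never mutated.
#'
#' @param spec a [perturbation_spec].
#' @param t time in seconds.
#' @param baseline a [network_config]; returned modifiers are multipliers
#'   relative to it (and `i_hyp` an additive current on the reticular
#'   population).
#' @return named list with multipliers `pv_nmda`, `cb_nmda`, `dstp`,
#'   `pv_gaba`, `cb_gaba` and the additive current `i_hyp`.
#' @export
resolve_perturbation <- function(spec, t, baseline = network_config()) {
  if (t >= spec$onset && t < spec$offset) perturbation_factors(spec)
  else perturbation_factors(perturbation_spec("none"))
}

#' Parametric sweep grids
#'
#' The published strength grids per perturbation kind: NMDA and dSTP scales
#' 50..10% in steps of 10%, PV direct-GABA 90..50%, CB direct-GABA 50..10%,
#' reticular hyperpolarization -15 to -75 in steps of -15.
#'
#' @param kind perturbation kind.
#' @return numeric vector of strengths (mildest first).
#' @export
perturbation_grid <- function(kind) {
  switch(kind,
         pv_nmda = ,
         cb_nmda = ,
         combined_nmda = ,
         dstp_reduce = c(0.5, 0.4, 0.3, 0.2, 0.1),
         pv_gaba_direct = c(0.9, 0.8, 0.7, 0.6, 0.5),
         cb_gaba_direct = c(0.5, 0.4, 0.3, 0.2, 0.1),
         trn_hyperpolarize = c(-15, -30, -45, -60, -75),
         none = 1,
         stop("unknown perturbation kind", call. = FALSE))
}

#' All perturbation kinds with defined sweep grids
#' @return character vector.
#' @export
perturbation_kinds <- function() {
  c("pv_nmda", "cb_nmda", "trn_hyperpolarize", "dstp_reduce",
    "pv_gaba_direct", "cb_gaba_direct", "combined_nmda")
}
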