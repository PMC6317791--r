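#' Disinhibitory short-term plasticity factor
#'
#' Deep-layer cortical firing drives an extra-slow conductance (200/400 ms
#' kinetics) that multiplicatively weakens reticulo-thalamic GABA-B
#' inhibition: for thalamic neuron i,
#' `P_T[i] = 1 / (1 + A_STP * sum_j W[j, i] * g_xslow[j]^6)`.
#'
#' `P_T` equals 1 when cortex is silent, decreases monotonically as any
#' deep-layer slow conductance grows, and is bounded in (0, 1].  With a
#' topographic (Gaussian) weight matrix the disinhibition is spatially focal
#' ("islands" of reduced inhibition under the attended stimulus), and the
#' sixth power makes it engage only for persistent firing on the order of
#' the 200 ms rise time.
#'
#' @param g_xslow slow conductance vector over deep-layer neurons.
#' @param W_D_to_T weight matrix, deep-layer rows by thalamic columns
#'   (amplitude folded in).
#' @param A_STP scaling constant (default 3000).
#' @return disinhibition factor vector over thalamic neurons, in (0, 1].
#' @export
dstp_factor <- function(g_xslow, W_D_to_T, A_STP = 3000) {
  if (any(g_xslow < 0)) stop("g_xslow must be nonnegative", call. = FALSE)
  if (A_STP < 0) stop("A_STP must be nonnegative", call. = FALSE)
  if (nrow(W_D_to_T) != length(g_xslow))
    stop("W_D_to_T rows must match g_xslow length", call. = FALSE)
  1 / (1 + A_STP * colSums(W_D_to_T * g_xslow^6))
}
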