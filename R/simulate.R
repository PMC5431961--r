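#' Simulate the dentate gyrus neural mass model
#'
#' Integrates the full three-subpopulation model: the granule-cell (GC)
#' population receives Gaussian input noise `p(t)` plus an optional
#' modulation signal (see [modulation_signal()]), a slow dendritic
#' inhibitory feedback loop (amplitude `B`), a fast somatic inhibitory loop
#' (amplitude `G`) and a slow-to-fast interneuron inhibitory connection.
#' Stimulation offsets `dV1`, `dV2`, `dV3` (mV) are added to the summed
#' presynaptic potential of the GC, IFSI and ISDI populations respectively,
#' immediately before each population's sigmoid.  The LFP output is the net
#' summed postsynaptic potential at the GC population.
#'
#' Each synaptic kernel is advanced with its exact zero-order-hold state
#' transition (see [kernel_step()]); noise is drawn once per step, with the
#' per-step standard deviation scaled by `sqrt(fs / 512)` so that the noise
#' spectral density — and hence the statistics of the output — do not depend
#' on the simulation rate.
#'
#' @param params A [model_params()] object.
#' @param duration Simulated time (s).
#' @param modulation Optional numeric vector sampled at `params$fs`
#'   (length `duration * fs`), added to the input noise p(t); `NULL` means 0.
#' @param offsets Optional list with numeric vectors `dv1`, `dv2`, `dv3`
#'   sampled at `params$fs` (mV); missing entries are treated as 0.
#' @param seed Optional integer seed for exact reproducibility.
#' @param return_states Logical; also return the five kernel output states.
#' @return An [lfp_signal()]; if `return_states` is `TRUE`, the signal
#'   carries a `states` attribute (matrix, one column per kernel instance).
#' @examples
#' sig <- simulate_lfp(model_params(), duration = 2, seed = 1)
#' sig
#' @export
simulate_lfp <- function(params, duration, modulation = NULL, offsets = NULL,
                         seed = NULL, return_states = FALSE) {
  stopifnot(inherits(params, "model_params"), duration > 0)
  n <- round(duration * params$fs)
  dt <- 1 / params$fs
  none <- numeric(0)
  as_input <- function(x, what) {
    if (is.null(x)) return(none)
    stopifnot(is.numeric(x))
    if (length(x) != n)
      stop(what, " must have length duration * fs = ", n,
           ", got ", length(x))
    x
  }
  mod <- as_input(modulation, "modulation")
  offsets <- offsets %||% list()
  dv1 <- as_input(offsets$dv1, "offsets$dv1")
  dv2 <- as_input(offsets$dv2, "offsets$dv2")
  dv3 <- as_input(offsets$dv3, "offsets$dv3")
  if (!is.null(seed)) set.seed(seed)
  sd_step <- params$noise_sd * sqrt(params$fs / 512)
  out <- simulate_nmm_cpp(
    n = n, dt = dt,
    A = params$A, B = params$B, G = params$G,
    tau_a = params$tau_exc, tau_b = params$tau_slow, tau_g = params$tau_fast,
    C = unname(params$connectivity),
    e0 = params$sigmoid$e0, v0 = params$sigmoid$v0, r = params$sigmoid$r,
    noise_mean = params$noise_mean, noise_sd = sd_step,
    modulation = mod, dv1 = dv1, dv2 = dv2, dv3 = dv3,
    return_states = return_states)
  lfp <- if (params$lfp_invert) -out$lfp else out$lfp
  sig <- lfp_signal(lfp, params$fs)
  if (return_states) attr(sig, "states") <- out$states
  sig
}

`%||%` <- function(a, b) if (is.null(a)) b else a
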