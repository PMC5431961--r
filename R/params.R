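#' Sigmoid (wave-to-pulse) parameters
#'
#' Parameters of the static nonlinearity converting a population's mean
#' postsynaptic potential into a mean firing rate,
#' \eqn{S(v) = 2 e_0 / (1 + e^{r (v_0 - v)})}.
#'
#' @param e0 Half of the maximum firing rate (1/s).
#' @param v0 Potential at which the rate equals `e0` (mV).
#' @param r Sigmoid steepness (1/mV).
#' @return An object of class `sigmoid_params`.
#' @examples
#' sigmoid_params()
#' @export
sigmoid_params <- function(e0 = 2.5, v0 = 6, r = 0.56) {
  stopifnot(is.numeric(e0), is.numeric(v0), is.numeric(r),
            length(e0) == 1, length(v0) == 1, length(r) == 1,
            e0 > 0, r > 0)
  structure(list(e0 = e0, v0 = v0, r = r), class = "sigmoid_params")
}

#' Second-order synaptic kernel
#'
#' A linear second-order low-pass filter with transfer function
#' \eqn{H(s) = W / (s + 1/\tau_w)^2} and impulse response
#' \eqn{h(t) = W\, t\, e^{-t/\tau_w}}. `W/\tau_w^2` is the static gain and
#' `1/\tau_w` the central (angular) frequency.  The amplitude/rate
#' parameterization common in the neural mass literature, kernel
#' `A a t e^{-a t}`, maps to `W = A a`, `tau_w = 1/a`; pass `A` and `a`
#' instead of `W` and `tau_w` to use it.
#'
#' @param W Kernel gain (mV/s).
#' @param tau_w Synaptic time constant (s).
#' @param A,a Alternative parameterization: PSP amplitude `A` (mV) and rate
#'   constant `a` (1/s); converted as `W = A * a`, `tau_w = 1/a`.
#' @return An object of class `synaptic_kernel` with fields `W` and `tau_w`.
#' @examples
#' synaptic_kernel(W = 325, tau_w = 0.01)
#' synaptic_kernel(A = 3.25, a = 100)   # identical kernel
#' @export
synaptic_kernel <- function(W = NULL, tau_w = NULL, A = NULL, a = NULL) {
  if (is.null(W) != is.null(tau_w) || is.null(A) != is.null(a))
    stop("supply both of (W, tau_w) or both of (A, a)")
  if (!is.null(A)) {
    if (!is.null(W)) stop("supply either (W, tau_w) or (A, a), not both")
    stopifnot(a > 0)
    W <- A * a
    tau_w <- 1 / a
  }
  stopifnot(is.numeric(W), is.numeric(tau_w), tau_w > 0)
  structure(list(W = W, tau_w = tau_w), class = "synaptic_kernel")
}

#' Neural mass model parameters
#'
#' Full parameter set of the three-subpopulation dentate gyrus model: a
#' granule-cell (GC) population with recurrent excitation, a slow
#' dendritic-projecting inhibitory population (ISDI) and a fast
#' somatic-projecting inhibitory population (IFSI), each synapse type
#' represented by a second-order kernel (see [synaptic_kernel()]).
#'
#' The seven dimensionless connectivity constants follow the usual
#' convention: `C1` GC -> excitatory collaterals, `C2` collaterals -> GC,
#' `C3` GC -> ISDI, `C4` ISDI -> GC, `C5` GC -> IFSI, `C6` ISDI -> IFSI,
#' `C7` IFSI -> GC.  By default they are fixed fractions of a single
#' constant `C`.
#'
#' @param A,B,G EPSP, slow-IPSP and fast-IPSP kernel amplitudes (mV).
#' @param tau_exc,tau_slow,tau_fast Time constants of the three kernel types
#'   (s); equivalently `1/a`, `1/b`, `1/g` of the rate-constant convention.
#' @param C Base connectivity constant; `connectivity` overrides individual
#'   entries.
#' @param connectivity Optional named numeric vector `C1`..`C7`.
#' @param sigmoid A [sigmoid_params()] object shared by all populations.
#' @param noise_mean,noise_sd Moments of the Gaussian input firing-rate noise
#'   p(t) (1/s).  `noise_sd` is referenced to the default 512 Hz simulation
#'   rate; simulation at another rate rescales the per-step deviate so that
#'   the noise spectral density is unchanged.
#' @param fs Simulation sampling rate (Hz).
#' @param lfp_invert Logical; flip the sign of the simulated LFP for
#'   comparison with recordings using the opposite polarity convention.
#' @return An object of class `model_params`.
#' @seealso [model_preset()] for calibrated background / discharge regimes.
#' @examples
#' p <- model_params()
#' p$connectivity
#' @export
model_params <- function(A = 3.25, B = 22, G = 10,
                         tau_exc = 1 / 100, tau_slow = 1 / 50,
                         tau_fast = 1 / 500,
                         C = 135, connectivity = NULL,
                         sigmoid = sigmoid_params(),
                         noise_mean = 90, noise_sd = 30,
                         fs = 512, lfp_invert = FALSE) {
  stopifnot(A >= 0, B >= 0, G >= 0,
            tau_exc > 0, tau_slow > 0, tau_fast > 0,
            fs > 0, noise_sd >= 0,
            inherits(sigmoid, "sigmoid_params"))
  conn <- c(C1 = C, C2 = 0.8 * C, C3 = 0.25 * C, C4 = 0.25 * C,
            C5 = 0.3 * C, C6 = 0.1 * C, C7 = 0.8 * C)
  if (!is.null(connectivity)) {
    stopifnot(all(names(connectivity) %in% names(conn)))
    conn[names(connectivity)] <- connectivity
  }
  structure(list(A = A, B = B, G = G,
                 tau_exc = tau_exc, tau_slow = tau_slow, tau_fast = tau_fast,
                 connectivity = conn, sigmoid = sigmoid,
                 noise_mean = noise_mean, noise_sd = noise_sd,
                 fs = fs, lfp_invert = lfp_invert),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Neural mass model parameters\n")
  cat(sprintf("  amplitudes  A = %.3g, B = %.3g, G = %.3g mV\n", x$A, x$B, x$G))
  cat(sprintf("  time consts %.4g / %.4g / %.4g s (exc/slow/fast)\n",
              x$tau_exc, x$tau_slow, x$tau_fast))
  cat(sprintf("  noise p(t)  %.3g +/- %.3g 1/s,  fs = %g Hz\n",
              x$noise_mean, x$noise_sd, x$fs))
  invisible(x)
}

# Calibrated preset table.  "background" sits at a stable fixed point under
# the default input noise; "hpd_regime" uses the same operating point, and
# the input-noise modulation step K (see inmf_config()) pushes it across the
# bifurcation to the discharge limit cycle while K is on.
.presets <- function() {
  list(
    background = list(params = model_params(A = 4, B = 30, G = 10),
                      K = 0),
    hpd_regime = list(params = model_params(A = 4, B = 30, G = 10),
                      K = 200)
  )
}

#' Calibrated model presets
#'
#' Named operating points of the model.  `"background"` produces
#' discharge-free background activity under the default input noise;
#' `"hpd_regime"` is the same operating point together with the calibrated
#' modulation amplitude `K` that switches the model into sustained
#' discharges while the modulation step is on.
#'
#' @param name `"background"` or `"hpd_regime"`.
#' @return A list with elements `params` ([model_params()]) and `K`
#'   (modulation amplitude, 1/s).
#' @examples
#' model_preset("background")$K      # 0: no modulation
#' @export
model_preset <- function(name = c("background", "hpd_regime")) {
  name <- match.arg(name)
  .presets()[[name]]
}
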