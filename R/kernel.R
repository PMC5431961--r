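#' Advance a synaptic kernel one time step
#'
#' Integrates the second-order ODE realization of the kernel,
#' \eqn{\ddot y = W x - (2/\tau_w)\dot y - y/\tau_w^2}, over one step of
#' length `dt` with the input held constant (zero-order hold), using the
#' exact state-transition matrix of the double pole at \eqn{-1/\tau_w}.
#' The impulse response therefore reproduces \eqn{W t e^{-t/\tau_w}} and
#' the step response \eqn{W \tau_w^2 (1 - (1 + t/\tau_w) e^{-t/\tau_w})}
#' up to the hold error on time-varying inputs.
#'
#' @param state Numeric length-2 vector `c(y, ydot)` (mV, mV/s).
#' @param x Input firing rate over the step (1/s).
#' @param k A [synaptic_kernel()].
#' @param dt Step length (s); must satisfy `dt < tau_w` (the input hold is
#'   meaningless at coarser steps).
#' @return Updated `c(y, ydot)`.
#' @examples
#' k <- synaptic_kernel(A = 3.25, a = 100)
#' kernel_step(c(0, 0), x = 90, k, dt = 1e-3)
#' @export
kernel_step <- function(state, x, k, dt) {
  stopifnot(inherits(k, "synaptic_kernel"), length(state) == 2,
            is.finite(state), is.finite(x), dt > 0)
  if (dt >= k$tau_w)
    stop("dt = ", dt, " must be smaller than tau_w = ", k$tau_w)
  tau <- k$tau_w
  e <- exp(-dt / tau)
  ys <- k$W * tau^2 * x
  y <- state[1] - ys
  yd <- state[2]
  c(e * (1 + dt / tau) * y + e * dt * yd + ys,
    -e * dt / tau^2 * y + e * (1 - dt / tau) * yd)
}

#' Kernel impulse and step responses
#'
#' Closed-form responses of the second-order synaptic kernel, used as
#' references for the numerical integrator.
#'
#' @param t Time(s) since stimulus onset (s); vectorized.
#' @param k A [synaptic_kernel()].
#' @return Response in mV.
#' @export
kernel_impulse_response <- function(t, k) {
  stopifnot(inherits(k, "synaptic_kernel"))
  ifelse(t < 0, 0, k$W * t * exp(-t / k$tau_w))
}

#' @rdname kernel_impulse_response
#' @export
kernel_step_response <- function(t, k) {
  stopifnot(inherits(k, "synaptic_kernel"))
  tau <- k$tau_w
  ifelse(t < 0, 0, k$W * tau^2 * (1 - (1 + t / tau) * exp(-t / tau)))
}
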