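#' Wave-to-pulse sigmoid
#'
#' Converts a mean postsynaptic potential into a population firing rate,
#' \eqn{S(v) = 2 e_0 / (1 + e^{r (v_0 - v)})}: strictly increasing in `v`,
#' bounded in `(0, 2 e0)`, equal to `e0` at `v = v0`.
#'
#' @param v Membrane potential (mV); vectorized.
#' @param p A [sigmoid_params()] object.
#' @return Firing rate(s) in 1/s.
#' @examples
#' wave_to_pulse(6, sigmoid_params())   # e0 = 2.5 at the midpoint
#' @export
wave_to_pulse <- function(v, p = sigmoid_params()) {
  stopifnot(inherits(p, "sigmoid_params"), is.numeric(v))
  2 * p$e0 / (1 + exp(p$r * (p$v0 - v)))
}
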