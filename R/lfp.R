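#' LFP-like signal container
#'
#' A uniformly sampled potential trace with its sampling rate and start
#' time.  Used for both simulated and recorded local field potentials.
#'
#' @param samples Numeric vector of potentials (mV).
#' @param fs Sampling rate (Hz).
#' @param t0 Start time of the first sample (s).
#' @return An object of class `lfp_signal`.
#' @examples
#' lfp_signal(sin(2 * pi * 5 * seq(0, 1, by = 1/512)), fs = 512)
#' @export
lfp_signal <- function(samples, fs, t0 = 0) {
  stopifnot(is.numeric(samples), is.numeric(fs), length(fs) == 1, fs > 0,
            is.numeric(t0), length(t0) == 1)
  structure(list(samples = as.numeric(samples), fs = fs, t0 = t0),
            class = "lfp_signal")
}

#' @export
print.lfp_signal <- function(x, ...) {
  cat(sprintf("LFP signal: %d samples @ %g Hz (%.2f s), t0 = %g s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$t0))
  cat(sprintf("  range [%.3g, %.3g] mV\n",
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' Sample times of an LFP signal
#'
#' @param sig An [lfp_signal()].
#' @return Numeric vector of times (s), one per sample.
#' @export
signal_times <- function(sig) {
  stopifnot(inherits(sig, "lfp_signal"))
  sig$t0 + (seq_along(sig$samples) - 1) / sig$fs
}

#' Duration of an LFP signal in seconds
#'
#' @param sig An [lfp_signal()].
#' @return Length of the trace (s).
#' @export
signal_duration <- function(sig) {
  stopifnot(inherits(sig, "lfp_signal"))
  length(sig$samples) / sig$fs
}

#' Resample an LFP signal
#'
#' Linear-interpolation resampling, e.g. to compare 512 Hz simulations with
#' 2048 Hz recordings.  Adequate for the smooth model output; use a
#' band-limited resampler for wide-band recorded data.
#'
#' @param sig An [lfp_signal()].
#' @param fs_out Target sampling rate (Hz).
#' @return An [lfp_signal()] at `fs_out`.
#' @export
resample_signal <- function(sig, fs_out) {
  stopifnot(inherits(sig, "lfp_signal"), fs_out > 0)
  t_in <- signal_times(sig)
  t_out <- seq(sig$t0, max(t_in), by = 1 / fs_out)
  lfp_signal(approx(t_in, sig$samples, xout = t_out)$y, fs_out, sig$t0)
}

#' Extract a time window from an LFP signal
#'
#' @param sig An [lfp_signal()].
#' @param from,to Window bounds (s, half-open `[from, to)`), in the signal's
#'   time base.
#' @return An [lfp_signal()] covering the requested window.
#' @export
window_signal <- function(sig, from, to) {
  stopifnot(inherits(sig, "lfp_signal"), to > from)
  i0 <- max(1L, floor((from - sig$t0) * sig$fs) + 1L)
  i1 <- min(length(sig$samples), ceiling((to - sig$t0) * sig$fs))
  if (i1 < i0) stop("window [", from, ", ", to, ") outside the signal span")
  lfp_signal(sig$samples[i0:i1], sig$fs, sig$t0 + (i0 - 1L) / sig$fs)
}
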