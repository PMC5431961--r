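# Synthetic spiky-LFP fixture, independent of the neural mass simulator:
# Gaussian background plus bursts of 20-80 Hz sharp transients, with
# gamma-distributed burst and inter-burst durations.  Returns the signal
# and the generating burst manifest, so detection tests have ground truth
# that does not come from the code under test.
make_spiky_fixture <- function(duration = 60, fs = 512, seed = 1,
                               burst_shape = 3, burst_rate = 0.5,
                               gap_shape = 2, gap_rate = 0.2,
                               spike_rate_hz = 8, spike_amp = 10,
                               noise_sd = 0.3) {
  set.seed(seed)
  n <- round(duration * fs)
  x <- rnorm(n, 0, noise_sd)
  t <- 0
  onset <- offset <- numeric(0)
  repeat {
    gap <- rgamma(1, gap_shape, gap_rate)
    len <- rgamma(1, burst_shape, burst_rate)
    on <- t + gap
    if (on >= duration) break
    off <- min(on + len, duration)
    onset <- c(onset, on); offset <- c(offset, off)
    # sharp transients: one damped 40 Hz wavelet per spike
    sp <- seq(on, off, by = 1 / spike_rate_hz)
    for (s in sp) {
      i0 <- round(s * fs) + 1
      tt <- seq(0, 0.05, by = 1 / fs)
      w <- spike_amp * sin(2 * pi * 40 * tt) * exp(-tt / 0.015)
      idx <- i0:(i0 + length(w) - 1)
      ok <- idx <= n
      x[idx[ok]] <- x[idx[ok]] + w[ok]
    }
    t <- on + len
    if (t >= duration) break
  }
  list(signal = hpdsim::lfp_signal(x, fs),
       bursts = data.frame(onset = onset, offset = offset))
}

# reference gamma density written out explicitly, as an oracle independent
# of stats::dgamma
gamma_density_oracle <- function(x, a, b) b^a * x^(a - 1) * exp(-b * x) / gamma(a)

# exact two-sided Mann-Whitney p-value by exhaustive enumeration of all
# group assignments (oracle for small n)
mw_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  u_stat <- function(idx) {
    g1 <- pooled[idx]
    g2 <- pooled[-idx]
    sum(outer(g1, g2, ">")) + 0.5 * sum(outer(g1, g2, "=="))
  }
  u_obs <- u_stat(seq_len(n))
  all_u <- combn(length(pooled), n, u_stat)
  mu <- length(a) * length(b) / 2
  mean(abs(all_u - mu) >= abs(u_obs - mu) - 1e-12)
}
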