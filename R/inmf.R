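#' Gamma law for discharge / background durations
#'
#' Shape/rate parameterization of the gamma distribution with density
#' \eqn{f(x; a, b) = b^a x^{a-1} e^{-b x} / \Gamma(a)}, used for the HPD
#' duration (`dHPD`) and inter-HPD duration (`dBKG`) renewal variables.
#' The gamma function generalizes the factorial normalization of the
#' integer-shape case, so shapes fitted from data need not be integers.
#'
#' @param a Shape (dimensionless), > 0.
#' @param b Rate (1/s), > 0.
#' @return An object of class `gamma_law`; mean is `a/b`.
#' @examples
#' law <- gamma_law(3, 0.3)   # mean 10 s
#' @export
gamma_law <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1, length(b) == 1,
            a > 0, b > 0)
  structure(list(a = a, b = b), class = "gamma_law")
}

#' @export
print.gamma_law <- function(x, ...) {
  cat(sprintf("Gamma(shape a = %.4g, rate b = %.4g 1/s), mean %.4g s\n",
              x$a, x$b, x$a / x$b))
  invisible(x)
}

#' Gamma probability density
#'
#' @param x Duration(s) (s); negative values have density 0 by convention.
#' @param law A [gamma_law()].
#' @return Density value(s).
#' @examples
#' gamma_pdf(1, gamma_law(2, 1))   # e^-1
#' @export
gamma_pdf <- function(x, law) {
  stopifnot(inherits(law, "gamma_law"), is.numeric(x))
  out <- numeric(length(x))
  ok <- x >= 0
  out[ok] <- dgamma(x[ok], shape = law$a, rate = law$b)
  out
}

#' Input Noise Modulation Function configuration
#'
#' The INMF is an alternating gamma-renewal process: background periods of
#' length `dBKG ~ law_bkg` alternate with discharge periods of length
#' `dHPD ~ law_hpd`, during which a constant step `K` is added to the
#' model's input noise p(t).
#'
#' Defaults emulate the discharge statistics of chronically epileptic mice:
#' mean discharge duration 10 s (shape 3 — discharges are never
#' near-instantaneous), mean inter-discharge interval about 31 s, giving a
#' baseline relative discharge duration near 0.24.
#'
#' @param law_hpd [gamma_law()] for discharge durations dHPD.
#' @param law_bkg [gamma_law()] for inter-discharge durations dBKG.
#' @param K Square-step amplitude added to p(t) during discharges (1/s).
#' @return An object of class `inmf_config`.
#' @export
inmf_config <- function(law_hpd = gamma_law(3, 0.3),
                        law_bkg = gamma_law(2.5, 0.08),
                        K = model_preset("hpd_regime")$K) {
  stopifnot(inherits(law_hpd, "gamma_law"), inherits(law_bkg, "gamma_law"),
            is.finite(K))
  structure(list(law_hpd = law_hpd, law_bkg = law_bkg, K = K),
            class = "inmf_config")
}

#' Discharge schedule container
#'
#' An ordered set of disjoint discharge slots (onset, offset) in seconds.
#'
#' @param onset,offset Numeric vectors of slot bounds (s); slots must be
#'   disjoint and strictly increasing with `offset > onset`.
#' @return An object of class `hpd_schedule` (a data frame with columns
#'   `onset` and `offset`).
#' @export
hpd_schedule <- function(onset = numeric(0), offset = numeric(0)) {
  stopifnot(length(onset) == length(offset), all(offset > onset))
  if (length(onset) > 1) {
    stopifnot(all(diff(onset) > 0), all(onset[-1] >= offset[-length(offset)]))
  }
  structure(data.frame(onset = onset, offset = offset),
            class = c("hpd_schedule", "data.frame"))
}

#' Draw a discharge schedule from the alternating renewal process
#'
#' From t = 0, draws `dBKG` then `dHPD`, places a discharge slot at
#' `[t + dBKG, t + dBKG + dHPD]`, then redraws both variables at each slot
#' end, repeating until `duration` is reached.  A final slot extending past
#' the end of the run is truncated at `duration` (a finite recording clips
#' the last discharge the same way).
#'
#' @param cfg An [inmf_config()].
#' @param duration Run length (s).
#' @param seed Optional integer seed.
#' @return An [hpd_schedule()].
#' @examples
#' sample_schedule(inmf_config(), duration = 200, seed = 1)
#' @export
sample_schedule <- function(cfg, duration, seed = NULL) {
  stopifnot(inherits(cfg, "inmf_config"), duration > 0)
  if (!is.null(seed)) set.seed(seed)
  onset <- offset <- numeric(0)
  t <- 0
  repeat {
    d_bkg <- rgamma(1, shape = cfg$law_bkg$a, rate = cfg$law_bkg$b)
    d_hpd <- rgamma(1, shape = cfg$law_hpd$a, rate = cfg$law_hpd$b)
    on <- t + d_bkg
    if (on >= duration) break
    off <- min(on + d_hpd, duration)
    onset <- c(onset, on)
    offset <- c(offset, off)
    t <- on + d_hpd
    if (t >= duration) break
  }
  hpd_schedule(onset, offset)
}

#' Sampled square-wave modulation signal
#'
#' Converts a discharge schedule into the piecewise-constant signal added
#' to the input noise: `K` inside discharge slots, 0 outside.
#'
#' @param sched An [hpd_schedule()].
#' @param K Step amplitude (1/s).
#' @param fs Sampling rate (Hz).
#' @param duration Signal length (s).
#' @return Numeric vector of length `round(duration * fs)`.
#' @export
modulation_signal <- function(sched, K, fs, duration) {
  stopifnot(inherits(sched, "hpd_schedule"), fs > 0, duration > 0)
  n <- round(duration * fs)
  out <- numeric(n)
  if (K == 0 || nrow(sched) == 0) return(out)
  for (i in seq_len(nrow(sched))) {
    i0 <- max(1L, floor(sched$onset[i] * fs) + 1L)
    i1 <- min(n, ceiling(sched$offset[i] * fs))
    if (i1 >= i0) out[i0:i1] <- K
  }
  out
}

#' Maximum-likelihood gamma fit of duration samples
#'
#' Fits shape and rate by maximum likelihood (method-of-moments start),
#' as used to identify the discharge and inter-discharge duration laws
#' from detected event intervals.
#'
#' @param samples Numeric vector of positive durations (s), length >= 2,
#'   not all equal.
#' @return A [gamma_law()] with the fitted parameters.
#' @examples
#' set.seed(1)
#' fit_gamma(rgamma(2000, shape = 3, rate = 0.5))
#' @export
fit_gamma <- function(samples) {
  stopifnot(is.numeric(samples))
  if (length(samples) < 2) stop("need at least 2 duration samples")
  if (any(samples <= 0)) stop("durations must be positive")
  if (var(samples) == 0) stop("degenerate sample: all durations equal")
  start <- list(shape = mean(samples)^2 / var(samples),
                rate = mean(samples) / var(samples))
  fit <- fitdistrplus::fitdist(samples, "gamma", method = "mle",
                               start = start)
  est <- fit$estimate
  gamma_law(unname(est["shape"]), unname(est["rate"]))
}
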