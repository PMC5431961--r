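test_that("bandpass keeps the pass band and rejects out-of-band tones", {
  fs <- 512
  t <- seq(0, 4, by = 1 / fs)
  in_band <- lfp_signal(sin(2 * pi * 50 * t), fs)
  out <- bandpass(in_band)
  core <- out$samples[(fs):(3 * fs)]   # avoid edge transients
  expect_lt(abs(max(core) - 1), 0.05)
  slow <- bandpass(lfp_signal(sin(2 * pi * 2 * t), fs))
  expect_lt(max(abs(slow$samples[(fs):(3 * fs)])), 10^(-20 / 20))
  zero <- bandpass(lfp_signal(rep(0, 1000), fs))
  expect_equal(zero$samples, rep(0, 1000))
  expect_error(bandpass(lfp_signal(rnorm(100), 100)), "Nyquist")
})

test_that("page_hinkley alarms once at a large step and stays quiet otherwise", {
  fs <- 512
  expect_length(page_hinkley(lfp_signal(rep(1, 1000), fs),
                             ph_params(lambda = 5)), 0)
  # flat signal with one injected step far above lambda: the first step
  # sample alone drives the statistic past lambda, and after the reset the
  # running mean re-adapts, so exactly one alarm fires, at the step
  x <- c(rep(0, fs), rep(10, fs))
  al <- page_hinkley(lfp_signal(x, fs), ph_params(lambda = 5))
  expect_length(al, 1)
  expect_equal(al, 1.0)
  # white noise with a 10x-noise-scale threshold and unit drift: quiet
  total <- 0
  for (s in 1:20) {
    set.seed(s)
    al <- page_hinkley(lfp_signal(rnorm(60 * fs), fs),
                       ph_params(lambda = 10, delta = 1, two_sided = TRUE))
    total <- total + length(al)
  }
  expect_equal(total, 0)
})

test_that("page_hinkley with a fixed baseline re-alarms through a sustained change", {
  fs <- 512
  x <- c(rep(0, fs), rep(10, 4 * fs), rep(0, fs))
  al_run <- page_hinkley(lfp_signal(x, fs), ph_params(lambda = 5))
  al_fix <- page_hinkley(lfp_signal(x, fs), ph_params(lambda = 5, mean0 = 0))
  expect_length(al_run, 1)
  expect_gt(length(al_fix), 100)
  expect_true(all(al_fix >= 1 & al_fix <= 5))
})

test_that("slot construction and merging follow the published rules", {
  # two peaks 0.4 s apart: slots [0.9,1.4] and [1.3,1.8] overlap -> merged
  tb <- peaks_to_events(c(1.0, 1.4))
  expect_equal(nrow(tb), 1)
  expect_equal(tb$onset, 0.9)
  expect_equal(tb$offset, 1.8)
  # boundary case: 1.0 s apart leaves exactly a 0.5 s gap, not < 0.5
  tb2 <- peaks_to_events(c(1.0, 2.0))
  expect_equal(nrow(tb2), 2)
  # 0.99 s apart: gap 0.49 s < 0.5 -> same discharge
  expect_equal(nrow(peaks_to_events(c(1.0, 1.99))), 1)
  expect_equal(nrow(peaks_to_events(numeric(0))), 0)
})

test_that("merging is idempotent", {
  set.seed(8)
  for (rep in 1:20) {
    peaks <- sort(runif(30, 0, 20))
    tb <- peaks_to_events(peaks)
    tb2 <- peaks_to_events(unlist(tb$peaks))
    expect_equal(tb2$onset, tb$onset)
    expect_equal(tb2$offset, tb$offset)
  }
})

test_that("event features implement the energy and duration definitions", {
  fs <- 100
  sig <- lfp_signal(rep(0, 10 * fs), fs)
  empty <- event_features(sig, event_table(), t_win = 10)
  expect_equal(empty$total_duration, 0)
  expect_equal(empty$energy, 0)
  expect_equal(empty$rms, 0)
  # one event of N samples all equal to c: energy = c / sqrt(N)
  c0 <- 3
  x <- rep(0, 10 * fs); x[101:200] <- c0
  sig <- lfp_signal(x, fs)
  tb <- event_table(1, 2)
  f <- event_features(sig, tb, t_win = 10)
  expect_equal(f$energy, c0 / sqrt(100))
  expect_equal(f$total_duration, 1)
  expect_equal(f$relative_duration, 0.1)
  expect_equal(f$rms, c0)
  # two identical events double the energy (additivity)
  x2 <- x; x2[401:500] <- c0
  f2 <- event_features(lfp_signal(x2, fs), event_table(c(1, 4), c(2, 5)), 10)
  expect_equal(f2$energy, 2 * f$energy)
  # sign flip leaves energy, duration and peak count unchanged
  f3 <- event_features(lfp_signal(-x, fs), tb, 10)
  expect_equal(f3$energy, f$energy)
  expect_equal(f3$total_duration, f$total_duration)
  expect_equal(f3$peak_count, f$peak_count)
  # events outside the signal span are rejected
  expect_error(event_features(sig, event_table(9, 11), 10), "span")
})

test_that("interval statistics split event and gap durations", {
  tb <- event_table(c(1, 5), c(3, 6))
  iv <- interval_statistics(tb, 10)
  expect_equal(iv$d_hpd, c(2, 1))
  expect_equal(iv$d_bkg, 2)
  one <- interval_statistics(event_table(1, 3), 10)
  expect_equal(one$d_bkg, numeric(0))
})

test_that("the detector finds the bursts of a synthetic spiky fixture", {
  fx <- make_spiky_fixture(duration = 120, seed = 21)
  ref <- window_signal(fx$signal, 0, 3)   # burst-free head by construction
  expect_lt(nrow(fx$bursts[fx$bursts$onset < 3, ]), 1)
  tb <- detect_hpd(fx$signal, reference = bandpass(ref))
  expect_equal(nrow(tb), nrow(fx$bursts), tolerance = 0.15)
  # detected total duration close to generated burst time
  expect_equal(sum(tb$offset - tb$onset),
               sum(fx$bursts$offset - fx$bursts$onset), tolerance = 0.25)
})

test_that("detector false-alarm rate on the background preset is zero", {
  pre <- model_preset("background")
  n_alarm <- 0
  for (s in 1:20) {
    sig <- simulate_lfp(pre$params, 60, seed = 300 + s)
    n_alarm <- n_alarm + nrow(detect_hpd(sig))
  }
  expect_equal(n_alarm, 0)
})

test_that("detected relative duration tracks the generating duty cycle", {
  pre <- model_preset("hpd_regime")
  # detector fixed across conditions, calibrated on discharge-free data
  # (self-calibration assumes discharges are a minority of the trace, which
  # high duty cycles violate)
  ph <- calibrate_ph(
    bandpass(simulate_lfp(model_preset("background")$params, 60,
                          seed = 555))$samples^2)
  duty_rates <- c(0.3, 0.15, 0.08, 0.04, 0.02)  # bkg rate: higher = denser
  rel <- vapply(seq_along(duty_rates), function(i) {
    cfg <- inmf_config(law_bkg = gamma_law(2.5, duty_rates[i]), K = pre$K)
    set.seed(40 + i)
    sched <- sample_schedule(cfg, 400)
    mod <- modulation_signal(sched, cfg$K, pre$params$fs, 400)
    sig <- simulate_lfp(pre$params, 400, modulation = mod)
    tb <- detect_hpd(sig, ph = ph)
    sum(tb$offset - tb$onset) / 400
  }, numeric(1))
  duty <- (3 / 0.3) / (3 / 0.3 + 2.5 / duty_rates)
  expect_equal(cor(rel, duty, method = "spearman"), 1)
})
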