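test_that("wave_to_pulse follows the sigmoid definition", {
  p <- sigmoid_params()
  expect_equal(wave_to_pulse(p$v0, p), p$e0)
  # saturation: well above v0 the rate approaches 2 e0
  expect_gt(wave_to_pulse(p$v0 + 100 / p$r, p), 1.99 * p$e0)
  # direct evaluation at v = 0 with the published constants
  expect_equal(wave_to_pulse(0, sigmoid_params(e0 = 2.5, v0 = 6, r = 0.56)),
               2 * 2.5 / (1 + exp(0.56 * 6)))
})

test_that("wave_to_pulse is strictly increasing and bounded in (0, 2 e0)", {
  p <- sigmoid_params()
  v <- seq(-30, 30, by = 0.5)
  s <- wave_to_pulse(v, p)
  expect_true(all(diff(s) > 0))
  expect_true(all(s > 0 & s < 2 * p$e0))
})

test_that("kernel_step reproduces the analytic impulse response", {
  for (k in list(synaptic_kernel(A = 3.25, a = 100),
                 synaptic_kernel(A = 22, a = 50),
                 synaptic_kernel(A = 10, a = 500))) {
    fs <- max(512, 200 / k$tau_w)  # fine relative to tau for the 1% check
    dt <- 1 / fs
    n <- round(8 * k$tau_w / dt)
    # discrete impulse: input W-normalized spike of area 1 in the first step
    st <- c(0, 0)
    y <- numeric(n)
    for (i in seq_len(n)) {
      st <- kernel_step(st, if (i == 1) 1 / dt else 0, k, dt)
      y[i] <- st[1]
    }
    t <- seq_len(n) * dt
    ref <- kernel_impulse_response(t, k)
    expect_lt(max(abs(y - ref)) / max(ref), 0.01)
    # peak at tau with value ~ W tau / e
    expect_equal(t[which.max(y)], k$tau_w, tolerance = 2 * dt / k$tau_w)
    expect_equal(max(y), k$W * k$tau_w / exp(1), tolerance = 0.01)
  }
})

test_that("kernel_step reproduces the static gain and zero dynamics", {
  k <- synaptic_kernel(A = 3.25, a = 100)
  dt <- 1 / 2048
  # zero input, zero state: stays at rest
  expect_equal(kernel_step(c(0, 0), 0, k, dt), c(0, 0))
  # constant input c: settles to W tau^2 c
  st <- c(0, 0)
  for (i in seq_len(round(10 * k$tau_w / dt))) st <- kernel_step(st, 90, k, dt)
  expect_equal(st[1], k$W * k$tau_w^2 * 90, tolerance = 1e-3)
  # step response matches the closed form along the way
  st <- c(0, 0)
  ts <- seq_len(200)
  y <- numeric(200)
  for (i in ts) { st <- kernel_step(st, 1, k, dt); y[i] <- st[1] }
  expect_equal(y, kernel_step_response(ts * dt, k), tolerance = 0.01)
})

test_that("kernel_step rejects unstable steps", {
  k <- synaptic_kernel(A = 10, a = 500)
  expect_error(kernel_step(c(0, 0), 0, k, dt = k$tau_w), "tau_w")
})

test_that("simulation with no synaptic gain and no noise is constant", {
  p <- model_params(A = 0, B = 0, G = 0, noise_sd = 0)
  sig <- simulate_lfp(p, duration = 2, seed = 1)
  expect_equal(diff(range(sig$samples)), 0)
})

test_that("identical seed and inputs give bitwise-identical traces", {
  pre <- model_preset("hpd_regime")
  cfg <- inmf_config(K = pre$K)
  set.seed(3); sched <- sample_schedule(cfg, 20)
  mod <- modulation_signal(sched, cfg$K, pre$params$fs, 20)
  a <- simulate_lfp(pre$params, 20, modulation = mod, seed = 11)
  b <- simulate_lfp(pre$params, 20, modulation = mod, seed = 11)
  expect_identical(a$samples, b$samples)
})

test_that("halving the integration step changes the trace RMS by < 2%", {
  pre <- model_preset("hpd_regime")
  cfg <- inmf_config(K = pre$K)
  set.seed(5); sched <- sample_schedule(cfg, 60)
  rms <- vapply(c(512, 1024), function(fs) {
    p <- pre$params; p$fs <- fs
    mod <- modulation_signal(sched, cfg$K, fs, 60)
    sig <- simulate_lfp(p, 60, modulation = mod, seed = 5)
    sqrt(mean(sig$samples^2))
  }, numeric(1))
  expect_lt(abs(rms[2] - rms[1]) / rms[1], 0.02)
})

test_that("the background preset yields a discharge-free trace", {
  pre <- model_preset("background")
  expect_identical(pre$K, 0)
  sig <- simulate_lfp(pre$params, 400, seed = 2)
  tb <- detect_hpd(sig)
  expect_equal(nrow(tb), 0)
})

test_that("the discharge preset alternates background and discharge epochs", {
  pre <- model_preset("hpd_regime")
  cfg <- inmf_config(K = pre$K)
  set.seed(9)
  sched <- sample_schedule(cfg, 300)
  mod <- modulation_signal(sched, cfg$K, pre$params$fs, 300)
  sig <- simulate_lfp(pre$params, 300, modulation = mod)
  tb <- detect_hpd(sig)
  expect_gt(nrow(tb), 1)
  # discharge epochs are large-amplitude relative to background
  f <- attr(tb, "filtered")
  in_ev <- rep(FALSE, length(f$samples))
  for (i in seq_len(nrow(tb)))
    in_ev[ceiling(tb$onset[i] * f$fs + 1):floor(tb$offset[i] * f$fs)] <- TRUE
  expect_gt(sd(f$samples[in_ev]), 4 * sd(f$samples[!in_ev]))
})

test_that("stimulation offsets shift the membrane potential where applied", {
  # a strong negative GC offset silences the discharge regime
  pre <- model_preset("hpd_regime")
  n <- 20 * pre$params$fs
  mod <- rep(pre$K, n)
  quiet <- simulate_lfp(pre$params, 20, modulation = mod,
                        offsets = list(dv1 = rep(-30, n)), seed = 4)
  loud <- simulate_lfp(pre$params, 20, modulation = mod, seed = 4)
  expect_lt(diff(range(quiet$samples[-(1:512)])),
            0.25 * diff(range(loud$samples[-(1:512)])))
})
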