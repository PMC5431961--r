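test_that("interface time constant is Zf * Cdl", {
  expect_equal(time_constant(interface_circuit(Zf = 0.1e6, Cdl = 1e-3)), 100)
  expect_equal(time_constant(interface_circuit(Zf = 1e6, Cdl = 1e-6)), 1)
  expect_equal(time_constant(interface_circuit(Cdl = 0)), 0)
})

test_that("tissue resistance matches the cylindrical-conductor value", {
  # stainless bipolar electrode: 125 um tips, 400 um apart, grey matter
  r <- tissue_resistance(0.35, 125e-6, 400e-6)
  expect_equal(round(r / 1e3), 93)
  expect_equal(tissue_resistance(0.7, 125e-6, 400e-6), r / 2)
  expect_equal(tissue_resistance(0.35, 125e-6, 800e-6), 2 * r)
})

test_that("current-mode interface matches the RC charging closed form", {
  c <- interface_circuit(Zf = 0.1e6, Cdl = 1e-3, Rs = 93e3)
  tau <- time_constant(c)
  dt <- tau / 2000
  n <- round(50 / dt)
  r <- interface_response(c, rep(1, n), mode = "current", dt = dt)
  expect_equal(r$current, rep(1, n))           # ideal current source
  t <- seq_len(n) * dt
  ref <- 1 * c$Zf * (1 - exp(-t / tau))        # V_dl in uA * Ohm = uV
  expect_lt(max(abs(r$v_dl - ref)) / max(ref), 0.005)
  # zero drive: nothing happens
  z <- interface_response(c, rep(0, 100), mode = "current", dt = dt)
  expect_equal(z$current, rep(0, 100))
  expect_equal(z$v_dl, rep(0, 100))
})

test_that("voltage-mode interface matches first-order circuit analysis", {
  c <- interface_circuit(Zf = 0.1e6, Cdl = 1e-3, Rs = 93e3)
  tau_eff <- c$Cdl * c$Rs * c$Zf / (c$Rs + c$Zf)
  dt <- tau_eff / 5000
  n <- round(3 * tau_eff / dt)
  v0 <- 1
  r <- interface_response(c, rep(v0, n), mode = "voltage", dt = dt)
  expect_equal(r$current[1], v0 / c$Rs, tolerance = 1e-3)
  i_inf <- v0 / (c$Rs + c$Zf)
  t <- seq_len(n) * dt
  ref <- i_inf + (v0 / c$Rs - i_inf) * exp(-t / tau_eff)
  expect_lt(max(abs(r$current - ref)) / max(ref), 0.005)
  # coarse steps are rejected as unstable
  expect_error(interface_response(c, rep(1, 10), mode = "voltage",
                                  dt = tau_eff), "coarse")
})

test_that("monophasic epochs accumulate charge exactly", {
  prot <- stim_protocol(onset = 10, duration = 50, amplitude = 1)
  fs <- 512
  drive <- protocol_drive(prot, fs, duration = 120)
  r <- interface_response(interface_circuit(), drive, "current", dt = 1 / fs)
  expect_equal(sum(r$current) / fs, 1 * 50)    # uA * s, imbalanced by design
})

test_that("membrane offsets are the coupling-weighted current", {
  i <- c(0, 1, 1, 0)
  off <- membrane_offsets(coupling_triplet(30, 5, -5), i)
  expect_equal(off$dv1, 30 * i)
  expect_equal(off$dv2, 5 * i)
  expect_equal(off$dv3, -5 * i)
  # zero triplet and zero current give identically zero offsets
  z <- membrane_offsets(coupling_triplet(0, 0, 0), i)
  expect_true(all(z$dv1 == 0 & z$dv2 == 0 & z$dv3 == 0))
  # sign flip of the current flips every offset
  off2 <- membrane_offsets(coupling_triplet(30, 5, -5), -i)
  expect_equal(off2$dv1, -off$dv1)
  expect_equal(off2$dv3, -off$dv3)
  # offsets vanish wherever no epoch is active
  expect_true(all(off$dv1[i == 0] == 0))
})

test_that("protocol builders reproduce the published epoch schedules", {
  p1 <- build_protocol("protocol1")
  expect_equal(nrow(p1), 8)
  expect_equal(unique(p1$duration), 50)
  expect_equal(unique(p1$amplitude), 1)
  expect_equal(p1$sub_session, rep(1:2, each = 4))
  expect_equal(p1$sign, rep(c(1, -1), each = 4))
  # 300 s between the end of one epoch and the start of the next
  within1 <- diff(p1$onset[1:4])
  expect_equal(within1, rep(350, 3))
  # one hour between sub-sessions
  expect_equal(p1$onset[5] - (p1$onset[4] + 50), 3600)

  p2 <- build_protocol("protocol2")
  expect_equal(nrow(p2), 11)
  expect_equal(diff(p2$onset), rep(300, 10))   # one epoch every 5 minutes
  blocks <- attr(p2, "blocks")
  expect_equal(blocks$to[1] - blocks$from[1], 3600)
  expect_equal(blocks$to[3] - blocks$from[3], 3600)
  expect_equal(blocks$from[2], p2$onset[1])

  # epochs are pairwise disjoint for both protocols
  for (p in list(p1, p2)) {
    ends <- p$onset + p$duration
    expect_true(all(p$onset[-1] >= ends[-nrow(p)]))
  }
  expect_error(stim_protocol(c(0, 10), c(20, 20), c(1, 1)), "overlap")
})
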