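# RCR outlet models: closed-form dynamics, calibration, exchange contract.

test_that("homogeneous decay follows exp(-t / Rd C) toward P_ref", {
  wk <- wk_params(Rp = 1e7, C = 1e-8, Rd = 1.9e8, P_ref = 500)
  sim <- rcr_simulate(wk, function(t) rep(0, length(t)), dt = 1e-3, t_end = 2,
                      P_d0 = 1500)
  expected <- 500 + 1000 * exp(-2 / (1.9e8 * 1e-8))
  expect_equal(utils::tail(sim$P_d, 1), expected, tolerance = 1e-3)
})

test_that("constant flow approaches P_ref + Q (Rp + Rd)", {
  wk <- wk_params(1e7, 1e-8, 1.9e8)
  sim <- rcr_simulate(wk, function(t) rep(1e-4, length(t)), 0.01, 30)
  expect_equal(utils::tail(sim$P, 1), 1e-4 * (1e7 + 1.9e8), tolerance = 1e-4)
})

test_that("sinusoidal flow: steady-cycle amplitude equals |Z(omega)| |Q|", {
  wk <- wk_params(1e7, 1e-8, 1.9e8)
  omega <- 2 * pi / 0.8
  Q0 <- 5e-5
  sim <- rcr_simulate(wk, function(t) Q0 * sin(omega * t), dt = 1e-4,
                      t_end = 20, P_d0 = 0)
  last <- sim$t > 20 - 0.8
  amp <- (max(sim$P[last]) - min(sim$P[last])) / 2
  expect_equal(amp, Mod(rcr_impedance(wk, omega)) * Q0, tolerance = 2e-3)
})

test_that("backward Euler is first order: halving dt halves the error", {
  wk <- wk_params(1e7, 1e-8, 1.9e8)
  exact <- 1000 * exp(-1 / (1.9e8 * 1e-8))
  err <- vapply(c(1e-2, 5e-3, 2.5e-3), function(dt) {
    sim <- rcr_simulate(wk, function(t) rep(0, length(t)), dt, 1, P_d0 = 1000)
    abs(utils::tail(sim$P_d, 1) - exact)
  }, numeric(1))
  expect_equal(err[1] / err[2], 2, tolerance = 0.1)
  expect_equal(err[2] / err[3], 2, tolerance = 0.1)
})

test_that("calibration: Ohmic total resistance and physiological window", {
  wf <- fix_waveform()
  bank <- fix_bank()
  expect_equal(bank$R_total, mmHg_to_Pa(100) / (53e-6 * 75 / 60),
               tolerance = 1e-10)
  expect_gte(bank$P_min_mmHg, 80)
  expect_lte(bank$P_max_mmHg, 120 + 0.01)
  # per-outlet resistances split inversely to flow fractions
  expect_equal(bank$outlets$desc$Rd / bank$outlets$branch1$Rd, 0.05 / 0.85,
               tolerance = 1e-10)
  # single-outlet degenerate case: outlet resistance equals the total
  b1 <- calibrate_windkessel(wf, splits = c(desc = 1))
  expect_equal(b1$outlets$desc$Rp + b1$outlets$desc$Rd, b1$R_total,
               tolerance = 1e-10)
})

test_that("calibration idempotence and error paths", {
  wf <- fix_waveform()
  b1 <- fix_bank()
  b2 <- calibrate_windkessel(wf)
  expect_equal(b1$C_total, b2$C_total, tolerance = 1e-10)
  expect_equal(b1$outlets$desc$Rd, b2$outlets$desc$Rd, tolerance = 1e-10)
  expect_error(calibrate_windkessel(wf, splits = c(a = 0.5, b = 0.6)),
               "sum to 1")
  expect_error(calibrate_windkessel(wf, mean_pressure_mmHg = 200),
               "calibration error")
})

test_that("exchange contract: outlet count enforced, values passed exactly", {
  bank <- fix_bank()
  expect_error(couple_windkessel(bank, rep(0, 4), Q = c(1e-5, 1e-5), dt = 1e-3),
               "configuration error")
  st <- couple_windkessel(bank, rep(0, 4), Q = rep(0, 4), dt = 1e-3)
  expect_true(all(st$P <= 1e-9))  # zero flow relaxes toward P_ref = 0
  # against a direct rcr_step call, outlet by outlet (order independence)
  Q <- c(1e-5, 2e-5, 3e-5, 4e-4)
  st2 <- couple_windkessel(bank, rep(1000, 4), Q, dt = 1e-3)
  for (i in seq_len(4)) {
    ref <- rcr_step(bank$outlets[[i]], 1000, Q[i], 1e-3)
    expect_equal(st2$P[i], ref$P, tolerance = 1e-14)
  }
})

test_that("waveform: period, stroke-volume integral, mean flow", {
  wf <- fix_waveform()
  expect_equal(wf$T, 0.8, tolerance = 1e-12)
  integ <- integrate(function(t) wf$Q_fun(t), 0, wf$T,
                     subdivisions = 2000L)$value
  expect_equal(integ, 53e-6, tolerance = 1e-3)
  expect_equal(wf$SV * wf$HR / 60, 66.25e-6, tolerance = 1e-12)
  # periodicity
  tt <- seq(0, 0.79, by = 0.01)
  expect_equal(wf$Q_fun(tt), wf$Q_fun(tt + 3 * wf$T), tolerance = 1e-12)
  expect_error(make_waveform(HR = -1), "positive")
})

test_that("cyclic convergence checker: exact repeat, monotone tolerance", {
  m <- matrix(rnorm(300), 3, 100)
  m[2, ] <- m[1, ]; m[3, ] <- m[1, ]
  r <- check_cyclic_convergence(m, tol = 0.01)
  expect_true(r$converged)
  expect_equal(r$cycle, 2L)
  # pure-0D relaxation: convergence cycle tracks the exp(-T/(Rd C)) envelope
  wk <- wk_params(1e7, 5e-9, 1.9e8)
  wf <- fix_waveform()
  sim <- rcr_simulate(wk, wf$Q_fun, dt = 1e-3, t_end = 12 * wf$T, P_d0 = 0)
  n_per <- 80
  tr <- matrix(NA_real_, 12, n_per)
  for (c_ in 1:12) {
    tq <- (c_ - 1) * wf$T + seq_len(n_per) / n_per * wf$T
    tr[c_, ] <- approx(sim$t, sim$P, xout = tq, rule = 2)$y
  }
  tol <- 0.01
  got <- check_cyclic_convergence(tr, tol = tol)$cycle
  # envelope prediction: residual decays by exp(-T/tau) per cycle from O(1)
  tau <- 1.9e8 * 5e-9
  pred <- ceiling(log(1 / tol) / (wf$T / tau)) + 1
  expect_lte(abs(got - pred), 2)
  # decreasing tol never decreases the converged cycle index
  cyc_loose <- check_cyclic_convergence(tr, tol = 0.05)$cycle
  expect_gte(got, cyc_loose)
  expect_error(check_cyclic_convergence(tr[1, , drop = FALSE]), "two")
})
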