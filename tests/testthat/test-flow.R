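# Incompressible solvers: Poiseuille / Womersley oracles, planar channel,
# mass conservation, 0D-3D coupling equivalence.

test_that("steady tube flow reproduces the Poiseuille wall shear within 10%", {
  fl <- fluid_params()
  R <- 0.015; Q0 <- 1e-4
  ff <- run_tube_flow(R, 0.1, function(t) rep(Q0, length(t)), fl,
                      t_end = 1.0, nz = 40, nr = 24, dt = 5e-4)
  wt <- wall_traction(ff)
  tau_mid <- wt$tau[nrow(wt$tau), 21]
  expect_equal(tau_mid, poiseuille_wss(fl$mu, Q0, R), tolerance = 0.1)
  # parabolic profile and axis velocity
  expect_equal(ff$u_z[21, 1], 2 * Q0 / (pi * R^2), tolerance = 0.02)
  # mass conservation: reconstructed flow within 1% of the prescribed one
  for (i in c(11, 21, 31)) {
    Qrec <- 2 * pi * sum(diff(ff$r) *
      (ff$u_z[i, -1] * ff$r[-1] + ff$u_z[i, -25] * ff$r[-25]) / 2)
    expect_equal(Qrec, Q0, tolerance = 0.01)
  }
})

test_that("a too-large step triggers the documented dt reduction", {
  fl <- fluid_params()
  w <- capture_warnings(
    run_tube_flow(0.01, 0.05, function(t) rep(2e-4, length(t)), fl,
                  t_end = 0.02, nz = 20, nr = 12, dt = 5e-3))
  expect_true(any(grepl("CFL", w)))
})

test_that("zero inflow from zero state stays identically zero", {
  fl <- fluid_params()
  ff <- run_tube_flow(0.01, 0.05, function(t) rep(0, length(t)), fl,
                      t_end = 0.05, nz = 10, nr = 8, dt = 5e-3)
  expect_equal(max(abs(ff$u_z)), 0)
  expect_equal(max(abs(ff$omega)), 0)
})

test_that("oscillatory tube flow matches the analytic pulsatile profile", {
  fl <- fluid_params()
  R <- 0.003; alpha <- 3
  omega <- alpha^2 * fl$nu / R^2
  T <- 2 * pi / omega
  Q0 <- 1e-6
  t_end <- 4.25 * T
  # dt near the advective limit: the solver may halve it (documented, warns)
  ff <- suppressWarnings(
    run_tube_flow(R, 0.05, function(t) Q0 * sin(omega * t), fl,
                  t_end = t_end, nz = 40, nr = 24, dt = T / 1500))
  ua <- womersley_profile(ff$r, R, fl$nu, omega, Q0, t_end)
  err <- max(abs(ff$u_z[30, ] - ua)) / max(abs(ua))
  expect_lt(err, 0.05)
  # refinement shrinks the error (convergence, no fixed threshold)
  ff2 <- suppressWarnings(
    run_tube_flow(R, 0.05, function(t) Q0 * sin(omega * t), fl,
                  t_end = t_end, nz = 40, nr = 36, dt = T / 3000))
  ua2 <- womersley_profile(ff2$r, R, fl$nu, omega, Q0, t_end)
  err2 <- max(abs(ff2$u_z[30, ] - ua2)) / max(abs(ua2))
  expect_lt(err2, err)
})

test_that("planar channel reproduces plane Poiseuille on both walls", {
  fl <- fluid_params()
  n1 <- 40; n2 <- 20; h <- 0.03
  X <- matrix(rep(seq(0, 0.1, length.out = n1), n2), n1, n2)
  Y <- matrix(rep(seq(0, h, length.out = n2), each = n1), n1, n2)
  Q2 <- 3e-3
  ff <- run_channel_flow(X, Y, function(t) rep(Q2, length(t)), fl,
                         t_end = 1.0, dt = 1e-3)
  tau_exp <- 6 * fl$mu * Q2 / h^2
  wt <- wall_traction(ff)
  expect_equal(wt$tau_lower[nrow(wt$tau_lower), 20], tau_exp, tolerance = 0.05)
  expect_equal(wt$tau_upper[nrow(wt$tau_upper), 20], tau_exp, tolerance = 0.05)
  expect_equal(max(ff$u[20, ]), 1.5 * Q2 / h, tolerance = 0.02)
})

test_that("coupled single-outlet tube equals the pure-0D solution", {
  fl <- fluid_params()
  wf <- fix_waveform()
  wk <- wk_params(1e7, 8e-9, 1.9e8)
  dt <- 1e-3
  ff <- run_tube_flow(0.015, 0.1, wf$Q_fun, fl, t_end = wf$T, nz = 20,
                      nr = 12, dt = dt, wk = wk, P_d0 = 12000)
  ref <- rcr_simulate(wk, wf$Q_fun, dt, wf$T, P_d0 = 12000)
  expect_equal(ff$P_trace, ref$P, tolerance = 1e-10)
})

test_that("junction split conserves mass exactly across the four outlets", {
  sol <- fix_baseline()
  wf <- sol$waveform
  tt <- sol$outlet_traces$desc$t
  Qsum <- Reduce(`+`, lapply(sol$outlet_traces, function(tr) tr$Q))
  expect_equal(Qsum, wf$Q_fun(tt), tolerance = 1e-12)
})

test_that("pre-FET baseline: cyclic convergence and physiological pressures", {
  sol <- fix_baseline()
  expect_true(sol$cyclic$converged)
  expect_lte(sol$cyclic$cycle, 2L)
  P <- sol$outlet_traces$desc$P / 133.3224
  expect_gte(min(P), 80 - 0.5)
  expect_lte(max(P), 120 + 0.5)
})
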