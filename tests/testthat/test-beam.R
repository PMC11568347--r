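# Co-rotational beam elements and penalty contact.

test_that("cantilever tip deflection matches Euler-Bernoulli closed form", {
  L <- 100; nel <- 20
  bm <- beam_model(cbind(seq(0, L, length.out = nel + 1), 0),
                   E = 1, A = 10, I = 1000)
  f <- numeric(3 * (nel + 1)); f[3 * (nel + 1) - 1] <- 1e-3
  sol <- beam_solve(bm, fixed = c(1, 2, 3), force = f)
  expect_true(sol$converged)
  expect_equal(sol$x[nel + 1, 2], 1e-3 * L^3 / (3 * 1000), tolerance = 1e-4)
})

test_that("large rotation: tip moment 2 pi EI / L rolls the beam closed", {
  L <- 100; nel <- 20; EI <- 1000
  bm <- beam_model(cbind(seq(0, L, length.out = nel + 1), 0),
                   E = 1, A = 10, I = EI)
  f <- numeric(3 * (nel + 1)); f[3 * (nel + 1)] <- 2 * pi * EI / L
  sol <- beam_solve(bm, fixed = c(1, 2, 3), force = f, n_steps = 40,
                    max_iter = 100)
  expect_true(sol$converged)
  expect_lt(sqrt(sum(sol$x[nel + 1, 1:2]^2)), 1e-6 * L)  # tip returns to root
})

test_that("rigid-body motion produces zero internal force", {
  bm <- beam_model(cbind(seq(0, 50, length.out = 6), 0), 1, 10, 100)
  th <- 0.7
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  x <- cbind(bm$xy %*% t(Rm) + rep(1, 6) %o% c(3, -2), th)
  asm <- fetsim:::beam_assemble(bm, x)
  expect_lt(max(abs(asm$f)), 1e-9)
})

test_that("contact: separation, action-reaction, frictionless direction", {
  master <- cbind(seq(0, 10, by = 1), 0)
  # separated points: empty active set
  ct0 <- contact_eval(cbind(c(2, 5), c(1, 2)), master, 3, 3, 10)
  expect_false(any(ct0$active))
  expect_true(all(ct0$f_slave == 0))
  # penetrating points: compressive springs, exact action-reaction
  ct <- contact_eval(cbind(c(2.5, 7), c(4, -5)), master, 3, 3, c(10, 20))
  expect_true(all(ct$active))
  expect_equal(colSums(ct$f_slave), -colSums(ct$f_master), tolerance = 1e-12)
  expect_equal(ct$f_slave[1, 2], -10 * 1, tolerance = 1e-12)   # 1 mm over
  expect_equal(ct$f_slave[2, 2], 20 * 2, tolerance = 1e-12)    # 2 mm under
  # frictionless: no tangential (x) component against a horizontal master
  expect_true(all(abs(ct$f_slave[, 1]) < 1e-12))
})

test_that("two bodies pressed with force F carry total contact force F", {
  # stiff straight master clamped at both ends, slave beam pushed onto it
  master <- beam_model(cbind(seq(0, 100, length.out = 21), 0), 1000, 100, 1e5)
  # zero clearance: the channel springs stay engaged and ground the slave
  slave <- beam_model(cbind(seq(30, 70, length.out = 9), 0.4), 10, 10, 1e3)
  n1 <- 21; n2 <- 9
  Ftot <- 2
  extra <- numeric(3 * (n1 + n2))
  sl_y <- 3 * n1 + 3 * seq_len(n2) - 1
  extra[sl_y] <- -Ftot / n2                  # uniform push toward the master
  sol <- fetsim:::beam_system_solve(
    master, slave,
    x = list(master = cbind(master$xy, 0), slave = cbind(slave$xy, 0)),
    fixed_master = c(1, 2, 3, 3 * n1 - 2, 3 * n1 - 1, 3 * n1),
    fixed_slave = 1L,                        # frictionless: pin one x dof
    clear_plus = 0, clear_minus = 0, k_pen = 5,
    extra_force = extra, tol = 1e-8, max_iter = 100)
  expect_true(sol$converged)
  expect_equal(sum(sol$contact$f_slave[, 2]), Ftot, tolerance = 1e-6)
  # compressive-only: all slave reactions push back (+y)
  expect_true(all(sol$contact$f_slave[sol$contact$active, 2] >= 0))
})
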