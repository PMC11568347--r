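# Continuum FEM core: patch test, Hooke's law, pressure loads, Lame tube.

test_that("patch test: uniform stress reproduced to 1e-8 relative", {
  m <- fem_rect_mesh(0, 2, 0, 1, 1, 1)
  op <- assemble_elasticity(m$nodes, m$quads, E = 3, nu = 0.3, "plane_strain")
  # prescribed linear displacement field -> exact uniform strain state
  exx <- 0.01; eyy <- -0.004; gxy <- 0.006
  u <- as.vector(rbind(exx * m$nodes[, 1] + gxy * m$nodes[, 2],
                       eyy * m$nodes[, 2]))
  st <- op$stress(u)
  D <- fetsim:::elasticity_D(3, 0.3, "plane_strain")
  expected <- as.numeric(D %*% c(exx, eyy, gxy))
  for (k in 1:3)
    expect_equal(unname(st[, k]), rep(expected[k], 4), tolerance = 1e-8)
})

test_that("rigid translation gives zero internal force; uniaxial Hooke", {
  m <- fem_rect_mesh(0, 1, 0, 1, 2, 2)
  op <- assemble_elasticity(m$nodes, m$quads, E = 1, nu = 0.3, "plane_strain")
  u_rigid <- rep(c(0.37, -0.12), nrow(m$nodes))
  expect_lt(max(abs(op$internal_force(u_rigid))), 1e-12)
  # uniaxial bar, E = 1 MPa, 1% strain -> 0.01 MPa axial stress (nu ~ 0)
  op0 <- assemble_elasticity(m$nodes, m$quads, E = 1, nu = 1e-9, "plane_strain")
  u <- as.vector(rbind(0.01 * m$nodes[, 1], 0 * m$nodes[, 2]))
  st <- op0$stress(u)
  expect_equal(unname(st[, 1]), rep(0.01, nrow(m$nodes)), tolerance = 1e-9)
})

test_that("pressure loads: zero pressure, closed-loop equilibrium, cap force", {
  m <- fem_rect_mesh(0, 1, 0, 1, 3, 3)
  edges <- cbind(1:3, 2:4)
  expect_true(all(apply_pressure(m$nodes, edges, 0, "plane_strain") == 0))
  # closed polygon (square boundary walked CCW): net pressure force ~ 0
  n <- 4
  bnd <- c(m$nid(1:3, 1), m$nid(4, 1:3), m$nid(4:2, 4), m$nid(1, 4:2))
  loop <- cbind(bnd, c(bnd[-1], bnd[1]))
  f <- apply_pressure(m$nodes, loop, 0.5, "plane_strain")
  expect_lt(abs(sum(f[seq(1, length(f), 2)])), 1e-12)
  expect_lt(abs(sum(f[seq(2, length(f), 2)])), 1e-12)
  # axisymmetric cap: axial resultant p * pi * r^2
  mz <- fem_rect_mesh(0.001, 15, 0, 1, 30, 1)
  cap <- which(abs(mz$nodes[, 2]) < 1e-9)
  cap <- cap[order(mz$nodes[cap, 1])]
  ed <- cbind(cap[-length(cap)], cap[-1])
  fz <- apply_pressure(mz$nodes, ed, 0.0133, "axisymmetric")
  expect_equal(sum(fz[seq(2, length(fz), 2)]), -0.0133 * pi * 15^2,
               tolerance = 1e-6)
})

test_that("Lame tube: FEM matches thick-wall closed form and converges", {
  lt <- lame_tube(nr = 8)
  expect_equal(lt$lame_inner, lame_sigma_inner(mmHg_to_MPa(100), 15, 17),
               tolerance = 1e-12)
  err8 <- abs(lt$sigma_theta[1] - lt$lame_inner) / lt$lame_inner
  expect_lt(err8, 0.05)
  lt16 <- lame_tube(nr = 16)
  err16 <- abs(lt16$sigma_theta[1] - lt16$lame_inner) / lt16$lame_inner
  expect_lt(err16, err8)          # converging under refinement
  expect_lt(err16, 0.02)
  # through-thickness average equals the Laplace membrane value p ri / t
  expect_equal(lt$sigma_avg, lt$laplace, tolerance = 1e-4)
  expect_equal(lt$laplace, mmHg_to_MPa(100) * 15 / 2, tolerance = 1e-12)
})

test_that("constraint handling: unconstrained solve is refused", {
  m <- fem_rect_mesh(0, 1, 0, 1, 1, 1)
  op <- assemble_elasticity(m$nodes, m$quads, 1, 0.3, "plane_strain")
  expect_error(solve_static(op, numeric(op$ndof), integer(0)), "rank error")
})

test_that("material parameter validation", {
  expect_error(material_params(nu = 0.6), "Poisson")
  expect_error(material_params(E_aorta = -1), "positive")
  mp <- material_params(polyester_model = "elastic")
  expect_equal(mp$E_polyester, 1780)
})
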