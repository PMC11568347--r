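# Deploy / release protocol, stress recovery, bending angle, path profiles.

# elastic energy of a beam chain at configuration x (independent of the
# solver's internal force path: local strains -> quadratic form)
beam_energy <- function(bm, x) {
  EA <- bm$E * bm$A; EI <- bm$E * bm$I
  en <- 0
  for (e in seq_len(bm$n - 1)) {
    pe <- c(x[e, 1], x[e, 2], x[e, 3], x[e + 1, 1], x[e + 1, 2], x[e + 1, 3])
    dx <- pe[4] - pe[1]; dy <- pe[5] - pe[2]
    L <- sqrt(dx^2 + dy^2)
    a <- atan2(dy, dx)
    wrap <- function(v) atan2(sin(v), cos(v))
    t1 <- wrap(pe[3] - (a - bm$alpha0[e])); t2 <- wrap(pe[6] - (a - bm$alpha0[e]))
    L0 <- bm$L0[e]
    en <- en + 0.5 * EA / L0 * (L - L0)^2 +
      0.5 * EI / L0 * (4 * t1^2 + 4 * t1 * t2 + 4 * t2^2) / 2
  }
  en
}

test_that("deploy: conforming fit at 0% has ~zero tractions; axis on centerline", {
  dep <- solve_deploy(assemble_treated(fp = fet_params(0)))
  expect_true(dep$converged)
  expect_lt(dep$residual, 1e-6)
  expect_lt(max(abs(dep$contact$viol)), 1e-9)
  # deployed skeleton axis lies on the aortic centerline
  fr <- centerline_frame(dep$treated$centerline, dep$s_skeleton)
  gap <- sqrt(rowSums((dep$state$slave[, 1:2] - fr$xyz[, c(1, 3)])^2))
  expect_lt(max(gap), 1e-9)
})

test_that("release: recoil pushes the distal edge toward the greater curvature", {
  rec <- fix_recoil(0.15)
  expect_true(rec$converged)
  expect_lt(rec$residual, 1e-6)
  cl <- rec$treated$centerline
  n <- nrow(rec$state$slave)
  fr_tip <- centerline_frame(cl, rec$treated$s_edge)
  g_tip <- c(-fr_tip$normal[1, 1], -fr_tip$normal[1, 3])
  tip_disp <- rec$state$slave[n, 1:2] - rec$deployed_state$slave[n, 1:2]
  expect_gt(sum(tip_disp * g_tip), 1)   # millimetres toward the outer bend
  # passive release cannot add energy to the skeleton
  e_before <- beam_energy(rec$bm_skeleton, rec$deployed_state$slave)
  e_after <- beam_energy(rec$bm_skeleton, rec$state$slave)
  expect_lt(e_after, e_before)
})

test_that("vanishing skeleton stiffness removes the recoil (limit case)", {
  tr <- assemble_treated(fp = fet_params(0.10))
  rec <- solve_recoil(tr, material_params(E_skeleton = 1e-6))
  n <- nrow(rec$state$slave)
  # lateral (recoil-direction) displacement vanishes; tangential sliding of
  # a force-free body along the frictionless channel is unconstrained
  fr_tip <- centerline_frame(tr$centerline, tr$s_edge)
  g_tip <- c(-fr_tip$normal[1, 1], -fr_tip$normal[1, 3])
  tip_disp <- rec$state$slave[n, 1:2] - rec$deployed_state$slave[n, 1:2]
  expect_lt(abs(sum(tip_disp * g_tip)), 0.05)
})

test_that("bending angle: collinear zero, constructed rotation, trend", {
  rec <- fix_recoil(0.15)
  fake <- rec
  cl <- rec$treated$centerline
  ax <- centerline_frame(cl, cl$total_len)$tangent[1, c(1, 3)]
  mk <- function(theta) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    tip_dir <- as.numeric(R %*% ax)
    fake$state$slave <- rbind(c(0, 0, 0), c(tip_dir * 10, 0))
    bending_angle(fake)
  }
  expect_equal(mk(0), 0, tolerance = 1e-9)
  expect_equal(mk(12 * pi / 180), 12, tolerance = 1e-9)
  # phi non-decreasing over the sweep (computed states)
  phis <- vapply(c(0, 0.15, 0.30), function(r) fix_recoil(r)$bending_angle,
                 numeric(1))
  expect_true(all(diff(phis) >= 0))
})

test_that("stress profiles: Laplace state pre-recoil, edge peak post-recoil", {
  rec <- fix_recoil(0.15)
  pre2 <- stress_path_profile(rec, "zeta2", include_recoil = FALSE)
  pre1 <- stress_path_profile(rec, "zeta1", include_recoil = FALSE)
  # away from the stented edge the pre-recoil state is the ~0.1 MPa Laplace
  # membrane state on both curvature paths
  far <- pre2$s_mm >= 20
  expect_equal(mean(pre2$sigma_theta_Pa[far]) / 1e6, 0.1, tolerance = 0.05)
  expect_equal(mean(pre1$sigma_theta_Pa[far]) / 1e6, 0.1, tolerance = 0.05)
  post2 <- stress_path_profile(rec, "zeta2")
  post1 <- stress_path_profile(rec, "zeta1")
  # maximum at the distal edge (s = 0)
  expect_lte(post2$s_mm[which.max(post2$sigma_theta_Pa)], 2)
  expect_equal(attr(post2, "sigma_max"), max(post2$sigma_theta_Pa))
  # lesser-curvature insensitivity: change on zeta1 << change on zeta2
  d1 <- max(abs(post1$sigma_theta_Pa - pre1$sigma_theta_Pa))
  d2 <- max(abs(post2$sigma_theta_Pa - pre2$sigma_theta_Pa))
  expect_lt(d1, 0.2 * d2)
  # sigma_max non-decreasing in oversizing rate
  smax <- vapply(c(0, 0.15, 0.30), function(r)
    attr(stress_path_profile(fix_recoil(r), "zeta2"), "sigma_max"),
    numeric(1))
  expect_true(all(diff(smax) >= 0))
})

test_that("constant synthetic field: profile constant with matching maximum", {
  path <- data.frame(s = seq(0, 50, by = 2))
  prof <- profile_path(path, rep(3.2, nrow(path)), ds = 1)
  expect_true(all(prof$value == 3.2))
  expect_equal(attr(prof, "value_max"), 3.2)
})

test_that("rigid vs elastic polyester graft give closely matching profiles", {
  tr <- assemble_treated(fp = fet_params(0.15))
  rec_r <- fix_recoil(0.15)
  rec_e <- solve_recoil(tr, material_params(polyester_model = "elastic"))
  p_r <- stress_path_profile(rec_r, "zeta2")$sigma_theta_Pa
  p_e <- stress_path_profile(rec_e, "zeta2")$sigma_theta_Pa
  expect_lt(max(abs(p_r - p_e)) / max(p_r), 0.05)
  expect_equal(rec_e$bending_angle, rec_r$bending_angle, tolerance = 0.05)
})
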