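# Post-processing operators: OSI, WSSD, paths, exceedance length, notch.

test_that("OSI closed forms: bounds and the 3-forward/1-back quarter case", {
  nt <- 2000
  t <- seq(0, 1, length.out = nt)
  # unidirectional constant shear
  expect_equal(osi(matrix(2, nt, 5), t), rep(0, 5), tolerance = 1e-12)
  # perfectly reversing sinusoid
  tau_sin <- matrix(sin(2 * pi * t), nt, 3)
  expect_equal(osi(tau_sin, t), rep(0.5, 3), tolerance = 1e-3)
  # +3 for half the cycle, -1 for the other half: 0.5 (1 - 2/4) = 0.25
  tau_sq <- matrix(ifelse(t < 0.5, 3, -1), nt, 2)
  expect_equal(osi(tau_sq, t), rep(0.25, 2), tolerance = 2e-3)
  # all-zero series: defined as 0, logged
  expect_message(o0 <- osi(matrix(0, nt, 2), t), "all-zero")
  expect_equal(o0, c(0, 0))
  # vector-valued reversing field
  tau3 <- array(0, c(nt, 2, 3))
  tau3[, , 1] <- sin(2 * pi * t)
  expect_equal(osi(tau3, t), rep(0.5, 2), tolerance = 1e-3)
  expect_error(osi(matrix(1, 1, 3)), "two time samples")
})

test_that("OSI bounds hold on pipeline-like random series", {
  set.seed(42)
  for (k in 1:5) {
    tau <- matrix(rnorm(40 * 10), 40, 10)
    o <- osi(tau, seq(0, 1, length.out = 40))
    expect_true(all(o >= 0 & o <= 0.5))
  }
})

test_that("surface WSSD: uniform, linear radial and rotational fields", {
  fp <- flat_patch(n = 7, L = 2)
  nodes <- fp$mesh$nodes
  # spatially uniform field
  tau_u <- matrix(rep(c(1.3, -0.4, 0), each = nrow(nodes)), ncol = 3)
  expect_equal(wssd(fp$mesh, tau_u)[fp$interior],
               rep(0, length(fp$interior)), tolerance = 1e-12)
  # tau = a (x, y): divergence 2a (exact for P1 on a flat patch)
  a <- 0.7
  tau_r <- cbind(a * nodes[, 1], a * nodes[, 2], 0)
  expect_equal(wssd(fp$mesh, tau_r)[fp$interior],
               rep(2 * a, length(fp$interior)), tolerance = 1e-10)
  # rigid rotation a (-y, x): divergence-free
  tau_w <- cbind(-a * nodes[, 2], a * nodes[, 1], 0)
  expect_equal(wssd(fp$mesh, tau_w)[fp$interior],
               rep(0, length(fp$interior)), tolerance = 1e-10)
})

test_that("path WSSD equals the streamwise derivative", {
  s <- seq(0, 10, by = 0.5)
  expect_equal(wssd_path(s, 3 * s + 1), rep(3, length(s)), tolerance = 1e-12)
})

test_that("extract_path: straight tube arc length and edge anchoring", {
  tr <- assemble_treated()
  pth <- extract_path(tr$aorta_lumen, "greater")
  # s = 0 lies on the FET distal edge ring
  p0 <- pth[which.min(abs(pth$s)), ]
  expect_lt(abs(p0$s), 1e-9)
  expect_true(p0$node %in% tr$aorta_lumen$node_sets$fet_distal_edge)
  # on the straight descending portion arc length equals Euclidean distance
  seg <- pth[pth$s > 50 & pth$s < 300, ]
  d_euc <- sqrt((seg$x[nrow(seg)] - seg$x[1])^2 + (seg$z[nrow(seg)] - seg$z[1])^2)
  expect_equal(seg$s[nrow(seg)] - seg$s[1], d_euc, tolerance = 1e-9)
  # total path length bounded by the remaining aorta
  expect_lte(max(pth$s), tr$total_len - tr$s_edge + 1e-9)
  expect_error(extract_path(fs_mesh(matrix(0, 1, 3)), "greater"), "sampling error")
})

test_that("profile sampling: constant field, Gaussian argmax, clipping", {
  path <- data.frame(s = seq(-20, 60, by = 2))
  vals <- exp(-((path$s - 10) / 5)^2)
  prof <- profile_path(path, vals, ds = 1)
  expect_equal(attr(prof, "s_max_location"), 10)
  cst <- profile_path(path, rep(4, nrow(path)), ds = 1)
  expect_true(all(cst$value == 4))
  expect_equal(high_wss_length(cst, 3), diff(range(path$s)))
  expect_equal(high_wss_length(cst, 5), 0)
  expect_warning(profile_path(path, vals, ds = 1, s_range = c(-30, 70)),
                 "clipped")
})

test_that("high-WSS length: triangular crossings, ties, monotonicity", {
  s <- seq(0, 16, by = 1)
  v <- 0.85 * ifelse(s <= 8, s, 16 - s)   # crosses 1.7 at s = 2 and 14
  prof <- data.frame(s = s, value = v)
  expect_equal(high_wss_length(prof, 1.7), 12, tolerance = 1e-12)
  expect_equal(high_wss_length(data.frame(s = s, value = rep(1, 17)), 1.7), 0)
  # samples exactly at the threshold do not count as exceeding
  expect_equal(high_wss_length(data.frame(s = 0:2, value = c(1.7, 1.7, 1.7)),
                               1.7), 0)
  thr <- seq(0.5, 6, by = 0.5)
  Ls <- vapply(thr, function(th) high_wss_length(prof, th), numeric(1))
  expect_true(all(diff(Ls) <= 1e-12))
})

test_that("notch area: constructed rectangular pocket of 3 mm x 5 mm", {
  s <- seq(0, 20, by = 0.1)
  y_dev <- ifelse(s >= 5 & s <= 10, -12, -15)   # device wall 3 mm above
  y_nat <- rep(-15, length(s))
  nm <- notch_measure(s, y_device = y_dev, y_native = y_nat)
  expect_equal(nm$area, 15, tolerance = 0.05)
  # conforming geometry: zero area
  expect_equal(notch_measure(s, y_device = y_nat, y_native = y_nat)$area, 0)
})

test_that("sweep summary: rows, trends, determinism, missing rates", {
  res <- list(`0` = list(sigma_max_Pa = 1, phi_deg = 1, wss_max_Pa = 5,
                         high_wss_mm = 9, notch_mm2 = 8),
              `0.15` = list(sigma_max_Pa = 2, phi_deg = 2, wss_max_Pa = 4,
                            high_wss_mm = 7, notch_mm2 = 6),
              `0.3` = list(sigma_max_Pa = 3, phi_deg = 3, wss_max_Pa = 3,
                           high_wss_mm = 5, notch_mm2 = 4))
  tab <- summarize_sweep(res)
  expect_equal(nrow(tab), 3)
  tr <- attr(tab, "trends")
  expect_equal(unname(tr[c("sigma_max_Pa", "phi_deg")]), c(1, 1))
  expect_equal(unname(tr[c("wss_max_Pa", "notch_mm2")]), c(-1, -1))
  expect_identical(tab, summarize_sweep(res))   # deterministic
  res$`0.15`$notch_mm2 <- NULL
  expect_warning(summarize_sweep(res), "missing")
})
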