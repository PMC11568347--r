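# Parametric geometry: centerline, sweeps, device, assembly, CFD domain,
# volume meshing.

test_that("centerline arc length, curvature and degenerate cases", {
  cl <- build_centerline(aorta_params())
  expect_equal(cl$total_len, pi * 50 + 400, tolerance = 1e-12)
  # finite-difference curvature oracle on the arch portion
  fd <- centerline_fd_curvature(cl)
  on_arch <- cl$s[2:(length(cl$s) - 1)] < cl$arch_len - 5
  expect_true(all(abs(fd[on_arch] - 1 / 50) < 1e-4))
  expect_true(all(abs(fd[cl$s[2:(length(cl$s) - 1)] > cl$arch_len + 5]) < 1e-8))
  # frames orthonormal
  fr <- centerline_frame(cl, c(0, 100, 300, 557))
  expect_true(all(abs(rowSums(fr$tangent^2) - 1) < 1e-10))
  expect_true(all(abs(rowSums(fr$tangent * fr$normal)) < 1e-10))
  # degenerate descending length: centerline ends at the arch end pointing
  # straight down the arch-end tangent
  cl0 <- build_centerline(aorta_params(desc_length = 0))
  expect_equal(cl0$total_len, pi * 50, tolerance = 1e-12)
  tip_t <- centerline_frame(cl0, cl0$total_len)$tangent[1, ]
  expect_equal(unname(tip_t), c(0, 0, -1), tolerance = 1e-9)
  expect_error(aorta_params(arch_radius = -1), "positive")
  expect_error(aorta_params(arch_span = 300), "arch_span")
})

test_that("tube sweep reproduces cylinder volume and annulus area", {
  clS <- build_centerline(aorta_params(arch_span = 1e-4, desc_length = 100))
  tube <- sweep_tube(clS, 30, 2, n_theta = 32, half = FALSE)
  cap <- cap_openings(tube$lumen)
  expect_true(is_watertight(cap))
  expect_equal(euler_characteristic(cap), 2)
  expect_equal(enclosed_volume(cap), pi * 15^2 * 100, tolerance = 0.01)
  # annulus cross-section area via hex volumes of one full ring sweep
  vol_wall <- sum(abs(tet_hex_volume(tube$wall)))
  expect_equal(vol_wall / 100, pi * (17^2 - 15^2), tolerance = 0.01)
  # zero wall thickness: lumen valid, wall empty
  t0 <- sweep_tube(clS, 30, 0, n_theta = 16)
  expect_equal(n_elems(t0$wall), 0)
  expect_gt(n_elems(t0$lumen, "quad"), 0)
  expect_error(sweep_tube(build_centerline(aorta_params()), 120),
               "self-intersecting")
})

test_that("half-model symmetry: tagged nodes on plane, mirror closes", {
  tube <- sweep_tube(build_centerline(aorta_params()), 30, 0, n_theta = 12)
  sym <- tube$lumen$node_sets$symmetry
  expect_gt(length(sym), 0)
  expect_true(all(abs(tube$lumen$nodes[sym, 2]) < 1e-9))
  full <- cap_openings(mirror_sagittal(tube$lumen))
  expect_true(is_watertight(full))
  expect_equal(euler_characteristic(full), 2)
})

test_that("FET device: oversizing diameter law and natural shapes", {
  for (rate in seq(0, 0.30, by = 0.05)) {
    fp <- fet_params(rate)
    expect_equal(fp$outer_diameter, 30 * (1 + rate), tolerance = 1e-12)
    m <- make_fet(fp)
    d_meas <- 2 * max(sqrt(m$skeleton$nodes[, 1]^2 + m$skeleton$nodes[, 2]^2))
    expect_equal(d_meas, 30 * (1 + rate), tolerance = 1e-9)
  }
  expect_equal(fet_params(0.30)$outer_diameter, 39)
  expect_equal(fet_params(0)$outer_diameter, 30)
  expect_equal(fet_params(0.15)$outer_diameter, 34.5)
  expect_identical(fet_params(0.1)$skeleton_natural_shape, "straight")
})

test_that("treated assembly: stations, gap, contact pair, error paths", {
  tr <- assemble_treated(fp = fet_params(0))
  expect_equal(tr$nominal_gap, 0)
  expect_equal(assemble_treated(fp = fet_params(0.30))$nominal_gap, -4.5)
  expect_gt(length(tr$aorta_lumen$node_sets$fet_distal_edge), 0)
  expect_gt(n_elems(tr$skeleton, "quad"), 0)
  expect_gt(n_elems(tr$aorta_wall, "hex"), 0)
  expect_equal(tr$s_edge - tr$s_sk0, 50)
  # FET longer than the available aorta
  expect_error(assemble_treated(aorta_params(desc_length = 10),
                                fet_params(0.15, skeleton_length = 200,
                                           skeleton_arc_fraction = 0)),
               "assembly error")
})

test_that("CFD domain: four outlets, 50 mm extensions, watertight", {
  tr <- assemble_treated()
  dom <- build_cfd_domain(tr)
  outs <- attr(dom, "outlets")
  expect_length(outs, 4)
  for (o in outs) expect_gt(length(dom$node_sets[[o]]), 0)
  # descending outlet extended 50 mm beyond the native end
  desc_out <- dom$nodes[dom$node_sets$outlet_desc, , drop = FALSE]
  end_native <- centerline_frame(tr$centerline, tr$total_len)$xyz[1, ]
  d_ext <- mean(sqrt(colSums((t(desc_out) - end_native)^2)))
  expect_equal(d_ext, sqrt(50^2 + 15^2), tolerance = 0.05)
  # branch extensions measured along the branch axis
  b1 <- dom$nodes[dom$node_sets$outlet_branch1, , drop = FALSE]
  ctr_b1 <- colMeans(b1)
  expect_equal(sqrt(sum(ctr_b1^2)) - 50, 50, tolerance = 0.1) # 50 mm arch radius + 50 mm
  full <- cap_openings(mirror_sagittal(dom))
  expect_true(is_watertight(full))
  expect_equal(euler_characteristic(full), 2)
  expect_error(build_cfd_domain(tr, branch_angles = c(100, 101, 130)),
               "geometry error")
})

test_that("volume mesh: cell-count scaling, coarse preset size, Jacobians", {
  clS <- build_centerline(aorta_params(arch_span = 1e-4, desc_length = 100))
  vm1 <- volume_mesh(clS, 15, 4, half = FALSE, s_range = c(0, 100))
  vm2 <- volume_mesh(clS, 15, 2, half = FALSE, s_range = c(0, 100))
  ratio <- n_elems(vm2) / n_elems(vm1)
  expect_gt(ratio, 8 * 0.7)
  expect_lt(ratio, 8 * 1.3)
  expect_gt(min_scaled_jacobian(vm1), 0)
  expect_gt(min_scaled_jacobian(vm2), 0)
  vma <- volume_mesh(build_centerline(aorta_params()), 15, 4)
  expect_gte(n_elems(vma), 1e4)
  expect_gt(min_scaled_jacobian(vma), 0)
  for (nm in c("inlet", "outlet", "wall", "symmetry"))
    expect_gt(length(vma$node_sets[[nm]]), 0)
  expect_error(volume_mesh(clS, 15, 0), "target_h")
})

test_that("mesh IO writers emit valid ASCII artifacts", {
  tube <- sweep_tube(build_centerline(aorta_params(arch_span = 1e-4,
                                                   desc_length = 20)),
                     30, 0, n_theta = 8)
  stl <- tempfile(fileext = ".stl")
  write_stl(tube$lumen, stl)
  ln <- readLines(stl)
  expect_identical(ln[1], "solid fetsim")
  expect_identical(ln[length(ln)], "endsolid fetsim")
  vtu <- tempfile(fileext = ".vtu")
  write_vtu(tube$lumen, vtu, point_data = list(s = tube$lumen$nodes[, 3]))
  doc <- readLines(vtu)
  expect_true(any(grepl("UnstructuredGrid", doc)))
  expect_true(any(grepl("DataArray", doc)))
})
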