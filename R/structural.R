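## Two-stage deploy-then-release elastic-recoil solution on the treated
## model, and recovery of the circumferential-stress field on the aortic
## wall. Sagittal-plane reduction: the aorta and the skeleton are
## co-rotational beams (tube section properties); cross-section distension
## is carried by ring/shell theory. Contact is frictionless and
## compressive-only; its penalty stiffness is the physical lateral ring
## stiffness of the wall, so band penetration is wall distension, which is
## exactly what the hoop-stress recovery consumes. Units mm / N / MPa.

#' Load case for the structural stage
#' @param internal_pressure_mmHg luminal pressure held through deploy and
#'   release (default 100 mmHg).
#' @return object of class `load_case`.
#' @export
load_case <- function(internal_pressure_mmHg = 100) {
  if (internal_pressure_mmHg < 0) stop("pressure must be >= 0")
  structure(list(pressure_mmHg = internal_pressure_mmHg,
                 pressure_MPa = mmHg_to_MPa(internal_pressure_mmHg)),
            class = "load_case")
}

# thin-walled tube section properties about the bending axis
tube_section <- function(r_mid, t) {
  list(A = 2 * pi * r_mid * t, I = pi * r_mid^3 * t)
}

# lateral ring (Winkler) stiffness of the wall per unit axial length:
# cosine-weighted ring compression over the loaded half circumference
wall_lateral_stiffness <- function(E, nu, t, r_mid) {
  (pi / 2) * (E / (1 - nu^2)) * t / r_mid
}

# shell boundary-layer parameter of the cylindrical wall (1/mm)
shell_beta <- function(nu, r_mid, t) {
  (3 * (1 - nu^2) / (r_mid^2 * t^2))^0.25
}

# pressurized-wall reference state via the axisymmetric FEM
ring_reference <- function(ap, mat, p, nr = 8) {
  ri <- ap$inner_diameter / 2
  ro <- ri + ap$wall_thickness
  lt <- lame_tube(p = p, ri = ri, ro = ro, E = mat$E_aorta, nu = mat$nu,
                  nr = nr)
  # radial displacement of the inner-surface node at z = 0
  w_p <- lt$u[1]  # node 1 is (ri, 0); dof 1 is radial
  list(sigma_avg = lt$sigma_avg, w_p = w_p, lame = lt, ri = ri, ro = ro)
}

# press-fit of the (pressurized) skeleton ring inside the (pressurized)
# aortic ring: linear compatibility for the contact pressure
ring_interference <- function(ap, fp, mat, p, w_p) {
  ri <- ap$inner_diameter / 2
  r_s_out <- fp$outer_diameter / 2
  r_s_mid <- r_s_out - fp$device_thickness / 2
  Es_eff <- mat$E_skeleton / (1 - mat$nu^2)
  c_s <- r_s_mid^2 / (fp$device_thickness * Es_eff)  # skeleton ring compliance
  c_a <- w_p / p                                      # aortic ring compliance
  # free (uncontacted) radii under pressure
  r_a_free <- ri + w_p
  r_s_free <- r_s_out + p * c_s
  if (r_s_free <= r_a_free)
    return(list(contact = FALSE, p_c = p, w_sten = w_p))
  # contact: r_a(p_c) = ri + p_c c_a ; r_s(p_c) = r_s_out + (p - p_c) c_s
  p_c <- (r_s_out - ri + p * c_s) / (c_a + c_s)
  list(contact = TRUE, p_c = p_c, w_sten = p_c * c_a)
}

#' Deploy the FET skeleton into the aortic lumen
#'
#' Stage one of the recoil protocol: the skeleton (straight natural shape,
#' root clamped at the graft junction) is forcibly displaced so its axis
#' interpolates from straight to the aortic centerline over `n_increments`;
#' at each increment the aorta is equilibrated against the contact forces.
#' Internal pressure is held throughout (its distension enters through the
#' ring reference state; on the beam the lateral pressure resultant of a
#' capped curved tube cancels against wall axial tension).
#'
#' @param treated `fet_treated`.
#' @param materials `material_params`.
#' @param load `load_case`.
#' @param control list: `beam_ds` (mm), `n_increments`, `tol`, `max_iter`.
#' @return object of class `fet_deployed` carrying the beam models, the
#'   converged configuration, contact state and all reference quantities.
#' @export
solve_deploy <- function(treated, materials = material_params(),
                         load = load_case(), control = list()) {
  ctl <- modifyList(list(beam_ds = 2.5, n_increments = 10, tol = 1e-6,
                         max_iter = 60), control)
  ap <- treated$aorta; fp <- treated$fet
  p <- load$pressure_MPa
  ref <- ring_reference(ap, materials, max(p, 1e-9))
  if (load$pressure_mmHg == 0) { ref$w_p <- 0; ref$sigma_avg <- 0 }
  intf <- ring_interference(ap, fp, materials, max(p, 1e-9), max(ref$w_p, 1e-12))

  cl <- treated$centerline
  s_a <- seq(treated$s_sk0, treated$total_len, by = ctl$beam_ds)
  fr_a <- centerline_frame(cl, s_a)
  xy_a <- fr_a$xyz[, c(1, 3)]
  r_mid_a <- ap$inner_diameter / 2 + ap$wall_thickness / 2
  sec_a <- tube_section(r_mid_a, ap$wall_thickness)
  bm_a <- beam_model(xy_a, materials$E_aorta, sec_a$A, sec_a$I)

  s_k <- seq(treated$s_sk0, treated$s_edge, by = ctl$beam_ds)
  if (utils::tail(s_k, 1) < treated$s_edge) s_k <- c(s_k, treated$s_edge)
  fr_k <- centerline_frame(cl, s_k)
  r_s_out <- fp$outer_diameter / 2
  r_s_mid <- r_s_out - fp$device_thickness / 2
  sec_k <- tube_section(r_s_mid, fp$device_thickness)
  # natural (stress-free) shape: straight along the root tangent
  root <- fr_k$xyz[1, c(1, 3)]
  tan0 <- fr_k$tangent[1, c(1, 3)]
  xy_k_nat <- sweep(outer(s_k - s_k[1], tan0), 2, root, `+`)
  bm_k <- beam_model(xy_k_nat, materials$E_skeleton, sec_k$A, sec_k$I)

  # deployed target: skeleton axis on the aortic centerline
  xy_k_dep <- fr_k$xyz[, c(1, 3)]
  # rotation dofs are measured from the straight natural reference
  th_nat <- rep(0, length(s_k))
  th_dep <- atan2(fr_k$tangent[, 3], fr_k$tangent[, 1]) -
    atan2(tan0[2], tan0[1])
  th_dep <- atan2(sin(th_dep), cos(th_dep))

  clearance <- max(0, (ref$ri + ref$w_p) - r_s_out)
  k_lat <- wall_lateral_stiffness(materials$E_aorta, materials$nu,
                                  ap$wall_thickness, r_mid_a)
  trib <- c(diff(s_k) / 2, 0) + c(0, diff(s_k) / 2)
  k_pen <- k_lat * trib

  n_a <- nrow(xy_a); n_k <- length(s_k)
  fixed_master <- c(1, 2, 3, 3 * n_a - 2, 3 * n_a - 1, 3 * n_a)
  fixed_slave_all <- seq_len(3 * n_k)
  x <- list(master = cbind(xy_a, 0), slave = cbind(xy_k_nat, th_nat))
  # The device is sheathed while being forced in: wall contact is inactive
  # during the (fictitious) intermediate deploy path and engages at release.
  sol <- NULL
  for (inc in seq_len(ctl$n_increments)) {
    lam <- inc / ctl$n_increments
    x$slave <- cbind((1 - lam) * xy_k_nat + lam * xy_k_dep,
                     (1 - lam) * th_nat + lam * th_dep)
    sol <- beam_system_solve(bm_a, bm_k, x, fixed_master, fixed_slave_all,
                             clear_plus = clearance, clear_minus = clearance,
                             k_pen = 0 * k_pen, tol = ctl$tol,
                             max_iter = ctl$max_iter)
    if (!sol$converged)
      stop("deploy non-convergence at increment ", inc,
           " (residual ", signif(sol$residual, 3), ")")
    x <- sol$state
  }
  # contact status of the deployed state (conforming fit: ~zero tractions)
  sol$contact <- contact_eval(x$slave[, 1:2], x$master[, 1:2],
                              clearance, clearance, k_pen)
  structure(list(treated = treated, materials = materials, load = load,
                 control = ctl, bm_aorta = bm_a, bm_skeleton = bm_k,
                 s_aorta = s_a, s_skeleton = s_k, state = sol$state,
                 contact = sol$contact, clearance = clearance,
                 k_pen = k_pen, ref = ref, interference = intf,
                 fixed_master = fixed_master,
                 xy_aorta_ref = xy_a, converged = sol$converged,
                 residual = sol$residual),
            class = "fet_deployed")
}

#' Release the deployment constraint and solve the elastic recoil
#'
#' Stage two: the forced displacement of the skeleton is removed (only the
#' root stays tied to the rigid graft; with the elastic polyester option the
#' root rotation is held by the graft's bending-spring stiffness instead).
#' The retaining reactions are unloaded over `n_increments` continuation
#' steps; each step is equilibrated by damped Newton with channel contact
#' between the skeleton and the aortic wall.
#'
#' @param deployed `fet_deployed`.
#' @param n_increments continuation steps.
#' @return object of class `fet_recoil`: converged configuration, contact
#'   tractions/distensions, bending angle, residual, plus everything needed
#'   by the stress recovery and the flow stage.
#' @export
release_recoil <- function(deployed, n_increments = 10) {
  d <- deployed
  n_a <- d$bm_aorta$n; n_k <- d$bm_skeleton$n
  nd1 <- 3 * n_a
  # retaining force: residual at the skeleton dofs in the deployed state
  asm_k <- beam_assemble(d$bm_skeleton, d$state$slave)
  ct <- contact_eval(d$state$slave[, 1:2], d$state$master[, 1:2],
                     d$clearance, d$clearance, d$k_pen)
  hold <- asm_k$f
  hold[3 * seq_len(n_k) - 2] <- hold[3 * seq_len(n_k) - 2] - ct$f_slave[, 1]
  hold[3 * seq_len(n_k) - 1] <- hold[3 * seq_len(n_k) - 1] - ct$f_slave[, 2]
  mat <- d$materials
  root_spring <- NULL
  fixed_slave <- c(1, 2, 3)
  if (mat$polyester_model == "elastic") {
    fp <- d$treated$fet; ap <- d$treated$aorta
    rg <- ap$inner_diameter / 2 + fp$device_thickness / 2
    Ig <- pi * rg^3 * fp$device_thickness
    Lg <- max(d$treated$s_sk0 - d$treated$s_graft0, 1)
    root_spring <- list(k = 3 * mat$E_polyester * Ig / Lg,
                        theta0 = d$state$slave[1, 3])
    fixed_slave <- c(1, 2)
  }
  x <- d$state
  sol <- NULL
  for (inc in seq_len(n_increments)) {
    lam <- inc / n_increments
    extra <- numeric(nd1 + 3 * n_k)
    extra[nd1 + seq_len(3 * n_k)] <- (1 - lam) * hold
    sol <- beam_system_solve(d$bm_aorta, d$bm_skeleton, x, d$fixed_master,
                             fixed_slave, d$clearance, d$clearance, d$k_pen,
                             extra_force = extra, root_spring = root_spring,
                             tol = d$control$tol,
                             max_iter = d$control$max_iter)
    if (!sol$converged)
      stop("recoil non-convergence at release step ", inc,
           " (residual ", signif(sol$residual, 3), ")")
    x <- sol$state
  }
  out <- structure(c(d[c("treated", "materials", "load", "control",
                         "bm_aorta", "bm_skeleton", "s_aorta", "s_skeleton",
                         "clearance", "k_pen", "ref", "interference",
                         "xy_aorta_ref")],
                     list(state = sol$state, contact = sol$contact,
                          deployed_state = d$state,
                          converged = sol$converged,
                          residual = sol$residual)),
                   class = "fet_recoil")
  out$bending_angle <- bending_angle(out)
  out
}

#' Convenience wrapper: deploy then release
#' @inheritParams solve_deploy
#' @param release_increments continuation steps for the release stage.
#' @return `fet_recoil`.
#' @export
solve_recoil <- function(treated, materials = material_params(),
                         load = load_case(), control = list(),
                         release_increments = 10) {
  release_recoil(solve_deploy(treated, materials, load, control),
                 n_increments = release_increments)
}

#' Bending angle between the recoiled FET and the descending aorta
#'
#' Angle between the deformed skeleton's distal-end axis tangent and the
#' undisturbed descending-aorta axis, degrees.
#' @param state `fet_recoil` (or `fet_deployed`).
#' @return angle in degrees.
#' @export
bending_angle <- function(state) {
  sk <- state$state$slave
  n <- nrow(sk)
  tip <- sk[n, 1:2] - sk[n - 1, 1:2]
  tip <- tip / sqrt(sum(tip^2))
  cl <- state$treated$centerline
  fr <- centerline_frame(cl, cl$total_len)
  axis <- fr$tangent[1, c(1, 3)]
  ang <- acos(pmin(1, pmax(-1, sum(tip * axis)))) * 180 / pi
  ang
}

## ---- stress recovery -------------------------------------------------------

# Hetenyi influence kernel of the shell boundary layer, normalized to unit
# integral on the given grid
shell_kernel <- function(s, beta) {
  g <- exp(-beta * abs(s)) * (cos(beta * s) + sin(beta * abs(s)))
  g / sum(g)
}

smooth_shell <- function(w, s, beta) {
  ds <- s[2] - s[1]
  half <- ceiling(6 / beta / ds)
  ker <- shell_kernel(seq(-half, half) * ds, beta)
  n <- length(w)
  wp <- c(rep(w[1], half), w, rep(w[n], half))
  as.numeric(stats::filter(wp, ker, sides = 2))[half + seq_len(n)]
}

# wall distension fields on a regular s grid (arc length along the aorta,
# origin at the proximal aortic end s_sk0): smooth base field (pressure +
# press-fit step) plus the recoil contact deposits (station, local distension)
wall_distension <- function(state, ds = 1) {
  tr <- state$treated
  s0 <- tr$s_sk0
  s_grid <- seq(0, tr$total_len - s0, by = ds)
  w_g <- rep(state$ref$w_p, length(s_grid))
  w_l <- rep(state$ref$w_p, length(s_grid))
  sten <- s_grid + s0 <= tr$s_edge + 1e-9
  if (state$interference$contact) {
    w_g[sten] <- state$interference$w_sten
    w_l[sten] <- state$interference$w_sten
  }
  ct <- state$contact
  s_master <- state$s_aorta - s0
  dg <- NULL; dl <- NULL
  for (i in which(ct$active)) {
    sp <- s_master[ct$seg[i]] * (1 - ct$tpar[i]) +
      s_master[ct$seg[i] + 1] * ct$tpar[i]
    if (ct$viol[i] > 0) dg <- rbind(dg, c(sp, ct$viol[i]))
    else dl <- rbind(dl, c(sp, -ct$viol[i]))
  }
  list(s = s_grid, w_g = w_g, w_l = w_l, s0 = s0,
       dep_g = dg, dep_l = dl)
}

# Hetenyi line-load shape function, unit peak: the local wall distension at a
# contact site equals the contact penetration and decays away from it with
# the shell boundary layer. Overlapping sites combine by envelope (each
# penetration already includes its neighbours' contribution).
deposit_envelope <- function(s_grid, dep, beta) {
  w <- numeric(length(s_grid))
  if (is.null(dep)) return(w)
  for (i in seq_len(nrow(dep))) {
    x <- beta * abs(s_grid - dep[i, 1])
    w <- pmax(w, dep[i, 2] * exp(-x) * (cos(x) + sin(x)))
  }
  w
}

#' Circumferential stress along the wall curvature traces
#'
#' Hoop stress on the greater- and lesser-curvature lines reconstructed from
#' the wall distension field: the pressurized reference state (anchored to
#' the axisymmetric FEM / Lame solution), the press-fit distension in the
#' stented region, and the recoil contact distension, convolved with the
#' shell boundary-layer influence kernel.
#'
#' @param state `fet_recoil` or `fet_deployed`.
#' @param ds sampling step, mm.
#' @param include_recoil if `FALSE`, the pre-recoil (deployed) field.
#' @return list with `s` (arc length from the proximal aortic end), `sigma_g`,
#'   `sigma_l` (MPa) and the smoothed distensions.
#' @export
circumferential_stress <- function(state, ds = 1, include_recoil = TRUE) {
  wd <- wall_distension(state, ds = ds)
  ap <- state$treated$aorta
  beta <- shell_beta(state$materials$nu,
                     ap$inner_diameter / 2 + ap$wall_thickness / 2,
                     ap$wall_thickness)
  wg_s <- smooth_shell(wd$w_g, wd$s, beta)
  wl_s <- smooth_shell(wd$w_l, wd$s, beta)
  if (include_recoil) {
    wg_s <- wg_s + deposit_envelope(wd$s, wd$dep_g, beta)
    wl_s <- wl_s + deposit_envelope(wd$s, wd$dep_l, beta)
  }
  scale <- state$ref$sigma_avg / state$ref$w_p
  list(s = wd$s, s0 = wd$s0, sigma_g = scale * wg_s, sigma_l = scale * wl_s,
       w_g = wg_s, w_l = wl_s)
}

#' Export the recoil solution onto the 3-D wall mesh (VTU)
#'
#' Maps the sagittal-plane solution onto the swept aortic wall mesh:
#' nodal displacement (beam translation plus side-dependent radial
#' distension, blended around the circumference) and the circumferential
#' stress field, written as VTU point data.
#'
#' @param state `fet_recoil`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_recoil_vtu <- function(state, path) {
  tr <- state$treated
  wall <- tr$aorta_wall
  cs <- circumferential_stress(state, ds = 1)
  cl <- tr$centerline
  # wall station + angle of every node: project onto the centerline
  clpts <- centerline_frame(cl, seq(tr$s_sk0, tr$total_len, by = 2))
  s_cl <- seq(tr$s_sk0, tr$total_len, by = 2)
  xy <- wall$nodes[, c(1, 3)]
  n <- nrow(xy)
  sig <- numeric(n); disp <- matrix(0, n, 3)
  d_a <- approx(state$s_aorta, {
    frb <- centerline_frame(cl, state$s_aorta)
    rowSums((state$state$master[, 1:2] - state$xy_aorta_ref) *
              cbind(-frb$normal[, 1], -frb$normal[, 3]))
  }, xout = s_cl, rule = 2)$y
  ref2 <- clpts$xyz[, c(1, 3)]
  for (i in seq_len(n)) {
    d2 <- (xy[i, 1] - ref2[, 1])^2 + (xy[i, 2] - ref2[, 2])^2
    k <- which.min(d2)
    s_rel <- s_cl[k] - cs$s0
    j <- which.min(abs(cs$s - s_rel))
    g <- c(-clpts$normal[k, 1], -clpts$normal[k, 3])
    v <- c(xy[i, 1] - ref2[k, 1], xy[i, 2] - ref2[k, 2])
    r_loc <- sqrt(sum(v^2) + wall$nodes[i, 2]^2)
    cosg <- sum(v * g) / max(r_loc, 1e-12)     # +1 greater, -1 lesser side
    wgt <- (1 + cosg) / 2
    sig[i] <- cs$sigma_l[j] + wgt * (cs$sigma_g[j] - cs$sigma_l[j])
    w_side <- cs$w_l[j] + wgt * (cs$w_g[j] - cs$w_l[j]) - state$ref$w_p
    rad3 <- c(v[1], wall$nodes[i, 2], v[2]) / max(r_loc, 1e-12)
    lat <- d_a[k] * c(g[1], 0, g[2])
    disp[i, ] <- lat + w_side * rad3
  }
  write_vtu(wall, path, point_data = list(displacement_mm = disp,
                                          sigma_theta_MPa = sig))
  invisible(path)
}

#' Hoop-stress profile along a curvature path
#'
#' Paths follow the study's conventions: `zeta1` runs along the lesser
#' curvature, `zeta2` along the greater curvature, both with origin s = 0 at
#' the FET distal edge and oriented distally.
#'
#' @param state `fet_recoil`/`fet_deployed`.
#' @param path `"zeta1"` or `"zeta2"`.
#' @param s_max profile length distal of the edge, mm.
#' @param ds station spacing, mm.
#' @param include_recoil `FALSE` for the pre-recoil profile.
#' @return data.frame `path_id`, `s_mm`, `sigma_theta_Pa` with attribute
#'   `sigma_max` (Pa, maximum over the profile).
#' @export
stress_path_profile <- function(state, path = c("zeta2", "zeta1"),
                                s_max = 100, ds = 1, include_recoil = TRUE) {
  path <- match.arg(path)
  cs <- circumferential_stress(state, ds = min(ds, 1),
                               include_recoil = include_recoil)
  edge_rel <- state$treated$s_edge - cs$s0
  s_out <- seq(0, s_max, by = ds)
  src <- if (path == "zeta2") cs$sigma_g else cs$sigma_l
  sig <- approx(cs$s - edge_rel, src, xout = s_out, rule = 2)$y
  out <- data.frame(path_id = path, s_mm = s_out,
                    sigma_theta_Pa = sig * 1e6)
  attr(out, "sigma_max") <- max(out$sigma_theta_Pa)
  out
}
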