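## Transient incompressible Newtonian flow in streamfunction-vorticity form.
## Two modes share one architecture (explicit upwind advection, implicit
## diffusion, prefactored sparse solves):
##  - axisymmetric (z, r) on a straight tube: Poiseuille/Womersley oracles and
##    the pre-FET descending aorta;
##  - planar, body-fitted FEM-operator channel in the sagittal plane: the
##    recoiled lumen with its jet, impingement and notch recirculation.
## SI units throughout (m, s, Pa).

#' Fluid parameters
#' @param mu dynamic viscosity, Pa s.
#' @param rho density, kg/m^3.
#' @return object of class `fluid_params`.
#' @export
fluid_params <- function(mu = 0.004, rho = 1050) {
  if (mu <= 0 || rho <= 0) stop("mu and rho must be positive")
  structure(list(mu = mu, rho = rho, nu = mu / rho), class = "fluid_params")
}

# nonuniform central first/second derivative weights for a 1-D grid
nonuni_weights <- function(x) {
  n <- length(x)
  h1 <- x[2:(n - 1)] - x[1:(n - 2)]
  h2 <- x[3:n] - x[2:(n - 1)]
  list(
    d1 = cbind(-h2 / (h1 * (h1 + h2)),
               (h2 - h1) / (h1 * h2),
               h1 / (h2 * (h1 + h2))),
    d2 = cbind(2 / (h1 * (h1 + h2)),
               -2 / (h1 * h2),
               2 / (h2 * (h1 + h2))))
}

## ---- axisymmetric tube solver ---------------------------------------------

# radial grid clustered at the wall
radial_grid <- function(R, nr, g = 1.3) {
  eta <- seq(0, 1, length.out = nr + 1)
  R * tanh(g * eta) / tanh(g)
}

#' Transient axisymmetric flow in a straight circular tube
#'
#' Streamfunction-vorticity solve driven by a prescribed flow-rate waveform
#' with a parabolic (or plug) inlet profile; the outlet carries a
#' zero-gradient condition and, when a Windkessel model is attached, its
#' pressure trace. Diffusion is implicit (prefactored Helmholtz solve),
#' advection first-order upwind explicit.
#'
#' @param R tube radius, m.
#' @param L tube length, m.
#' @param Q_fun function(t) -> flow rate m^3/s.
#' @param fluid `fluid_params`.
#' @param t_end simulated time, s.
#' @param nz,nr axial / radial intervals.
#' @param dt time step, s (reduced automatically on CFL violation).
#' @param inlet `"parabolic"` or `"plug"` (plug is blended near the wall).
#' @param n_store stored wall-shear frames (evenly spaced over `t_end`).
#' @param wk optional `wk_params` for the outlet; its pressure trace is
#'   recorded (the velocity field of a rigid tube with prescribed inflow is
#'   independent of the pressure level).
#' @return object of class `flow_field`: grid, stored times, wall shear
#'   series `tau_wall` (n_store x nz+1, signed, Pa), the final velocity
#'   field, and the outlet pressure/flow traces.
#' @export
run_tube_flow <- function(R, L, Q_fun, fluid, t_end, nz = 80, nr = 24,
                          dt = 5e-4, inlet = "parabolic", n_store = 40,
                          wk = NULL, P_d0 = 0) {
  z <- seq(0, L, length.out = nz + 1)
  r <- radial_grid(R, nr)
  dz <- z[2] - z[1]
  wr <- nonuni_weights(r)
  ni <- nz + 1; nj <- nr + 1
  idx <- function(i, j) (j - 1L) * ni + i
  # unit-flow inlet streamfunction / vorticity profiles
  rho_ <- r / R
  if (inlet == "parabolic") {
    psi_in1 <- (2 * rho_^2 - rho_^4) / (2 * pi)      # psi for Q = 1
    om_in1 <- 4 * r / (pi * R^4)                     # -du/dr for Q = 1
  } else {
    u1 <- 1 / (pi * R^2) * (1 - rho_^40)             # blended plug
    psi_in1 <- c(0, cumsum(diff(r) * (u1[-nj] * r[-nj] + u1[-1] * r[-1]) / 2))
    sc <- psi_in1[nj] * 2 * pi
    psi_in1 <- psi_in1 / sc; u1 <- u1 / sc
    om_in1 <- -c(0, diff(u1) / diff(r))
  }
  ## Poisson operator: psi_rr - psi_r/r + psi_zz = -r * omega
  trip <- list(i = integer(0), j = integer(0), x = numeric(0))
  add <- function(ii, jj, vv) {
    trip$i <<- c(trip$i, ii); trip$j <<- c(trip$j, jj); trip$x <<- c(trip$x, vv)
  }
  for (j in 2:(nr)) {
    w1 <- wr$d1[j - 1, ]; w2 <- wr$d2[j - 1, ]
    for (i in 2:nz) {
      k <- idx(i, j)
      add(rep(k, 3), c(idx(i, j - 1), k, idx(i, j + 1)),
          w2 - w1 / r[j])
      add(rep(k, 3), c(idx(i - 1, j), k, idx(i + 1, j)),
          c(1, -2, 1) / dz^2)
    }
  }
  # boundary rows
  for (j in 1:nj) {
    add(idx(1, j), idx(1, j), 1)                      # inlet Dirichlet
    k <- idx(ni, j); add(c(k, k), c(k, idx(nz, j)), c(1, -1))  # outlet dpsi/dz=0
  }
  for (i in 2:nz) {
    add(idx(i, 1), idx(i, 1), 1)                      # axis psi = 0
    add(idx(i, nj), idx(i, nj), 1)                    # wall psi = Q/2pi
  }
  A <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                            dims = c(ni * nj, ni * nj))
  lu <- Matrix::lu(A)
  ## implicit diffusion operator for omega:
  ## (I - dt nu (d_zz + d_rr + d_r/r - 1/r^2)) interior; Dirichlet elsewhere
  nu <- fluid$nu
  build_helm <- function(dt) {
    trip <- list(i = integer(0), j = integer(0), x = numeric(0))
    add <- function(ii, jj, vv) {
      trip$i <<- c(trip$i, ii); trip$j <<- c(trip$j, jj)
      trip$x <<- c(trip$x, vv)
    }
    for (j in 2:nr) {
      w1 <- wr$d1[j - 1, ]; w2 <- wr$d2[j - 1, ]
      for (i in 2:nz) {
        k <- idx(i, j)
        cr <- w2 + w1 / r[j]
        add(rep(k, 3), c(idx(i, j - 1), k, idx(i, j + 1)), -dt * nu * cr)
        add(rep(k, 3), c(idx(i - 1, j), k, idx(i + 1, j)),
            -dt * nu * c(1, -2, 1) / dz^2)
        add(k, k, 1 + dt * nu / r[j]^2)
      }
    }
    for (j in 1:nj) { add(idx(1, j), idx(1, j), 1)
      k <- idx(ni, j); add(c(k, k), c(k, idx(nz, j)), c(1, -1)) }
    for (i in 2:nz) { add(idx(i, 1), idx(i, 1), 1)
      add(idx(i, nj), idx(i, nj), 1) }
    Matrix::lu(Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                                    dims = c(ni * nj, ni * nj)))
  }
  helm <- build_helm(dt)

  PSI <- matrix(0, ni, nj); OM <- matrix(0, ni, nj)
  # derivative helpers (matrices i x j)
  dz_c <- function(F) { G <- F
    G[2:nz, ] <- (F[3:ni, ] - F[1:(nz - 1), ]) / (2 * dz)
    G[1, ] <- (F[2, ] - F[1, ]) / dz; G[ni, ] <- (F[ni, ] - F[nz, ]) / dz; G }
  dr_c <- function(F) { G <- F
    for (j in 2:nr) G[, j] <- F[, j - 1] * wr$d1[j - 1, 1] +
      F[, j] * wr$d1[j - 1, 2] + F[, j + 1] * wr$d1[j - 1, 3]
    G[, 1] <- (F[, 2] - F[, 1]) / (r[2] - r[1])
    G[, nj] <- (F[, nj] - F[, nr]) / (r[nj] - r[nr]); G }

  store_times <- seq(t_end / n_store, t_end, length.out = n_store)
  tau_wall <- matrix(NA_real_, n_store, ni)
  t_store <- numeric(n_store); si <- 1L
  P_trace <- numeric(0); Q_trace <- numeric(0); t_trace <- numeric(0)
  Pd <- P_d0
  rmat <- matrix(r, ni, nj, byrow = TRUE)
  rmat[, 1] <- 1  # placeholder to avoid 0/0; axis handled separately
  h_wall <- r[nj] - r[nr]
  t_now <- 0
  while (t_now < t_end - 1e-12) {
    t_new <- t_now + dt
    Qn <- Q_fun(t_new)
    # velocities from current psi
    UZ <- dr_c(PSI) / rmat
    UZ[, 1] <- 2 * PSI[, 2] / r[2]^2
    UR <- -dz_c(PSI) / rmat
    UR[, 1] <- 0
    drloc <- matrix(c(r[2] - r[1], diff(r)), ni, nj, byrow = TRUE)
    cfl <- dt * max(abs(UZ) / dz + abs(UR) / drloc)
    if (cfl > 0.95) {
      warning("CFL violation; reducing dt", call. = FALSE)
      dt <- dt / 2; helm <- build_helm(dt)
      next
    }
    # upwind advection of omega
    Fz_p <- (OM - rbind(OM[1, ], OM[1:nz, ])) / dz      # backward
    Fz_m <- (rbind(OM[2:ni, ], OM[ni, ]) - OM) / dz     # forward
    adv_z <- ifelse(UZ > 0, UZ * Fz_p, UZ * Fz_m)
    OMl <- cbind(OM[, 1], OM[, 1:nr]); OMr <- cbind(OM[, 2:nj], OM[, nj])
    hback <- matrix(c(1, diff(r)), ni, nj, byrow = TRUE)
    hfwd <- matrix(c(diff(r), 1), ni, nj, byrow = TRUE)
    adv_r <- ifelse(UR > 0, UR * (OM - OMl) / hback, UR * (OMr - OM) / hfwd)
    src <- UR * OM / rmat
    src[, 1] <- 0
    OMs <- OM + dt * (-adv_z - adv_r + src)
    # boundary values at new time
    OMs[1, ] <- om_in1 * Qn
    OMs[, 1] <- 0
    OMs[, nj] <- OM[, nj]   # provisional; replaced after psi solve
    rhs <- as.numeric(OMs)
    rhs[idx(ni, 1:nj)] <- 0            # outlet zero-gradient rows
    OMnew <- matrix(as.numeric(Matrix::solve(helm, rhs)), ni, nj)
    OMnew[ni, ] <- OMnew[nz, ]
    # psi solve
    b <- -as.numeric(rmat * OMnew)
    b[idx(1, 1:nj)] <- psi_in1 * Qn
    b[idx(ni, 1:nj)] <- 0
    b[idx(2:nz, 1)] <- 0
    b[idx(2:nz, nj)] <- Qn / (2 * pi)
    PSI <- matrix(as.numeric(Matrix::solve(lu, b)), ni, nj)
    # wall vorticity (Thom, axisymmetric)
    OMnew[, nj] <- -2 * (PSI[, nr] - PSI[, nj]) / (R * h_wall^2)
    OM <- OMnew
    # outlet Windkessel (rigid wall: Q_out = Q_in)
    if (!is.null(wk)) {
      stw <- rcr_step(wk, Pd, Qn, dt)
      Pd <- stw$P_d; P_trace <- c(P_trace, stw$P)
    } else P_trace <- c(P_trace, 0)
    Q_trace <- c(Q_trace, Qn); t_trace <- c(t_trace, t_new)
    t_now <- t_new
    if (si <= n_store && t_now >= store_times[si] - 1e-12) {
      tau_wall[si, ] <- fluid$mu * OM[, nj]
      t_store[si] <- t_now
      si <- si + 1L
    }
  }
  structure(list(mode = "axisymmetric", z = z, r = r, psi = PSI, omega = OM,
                 u_z = UZ, u_r = UR, t_store = t_store, tau_wall = tau_wall,
                 P_trace = P_trace, Q_trace = Q_trace, t_trace = t_trace,
                 dt = dt,
                 fluid = fluid, R = R), class = "flow_field")
}

## ---- planar body-fitted channel solver ------------------------------------

# scalar bilinear FEM operators on a mapped quad grid
assemble_scalar_fem <- function(nodes, quads) {
  nn <- nrow(nodes); ne <- nrow(quads)
  gp <- expand.grid(xi = gauss2, eta = gauss2)
  ti <- vector("list", ne); tj <- vector("list", ne); tx <- vector("list", ne)
  ml <- numeric(nn)
  for (e in seq_len(ne)) {
    en <- quads[e, ]
    xy <- nodes[en, , drop = FALSE]
    Ke <- matrix(0, 4, 4)
    for (g in 1:4) {
      sh <- quad_shape(gp$xi[g], gp$eta[g])
      J <- sh$dN %*% xy
      detJ <- det(J)
      if (detJ <= 0) stop("meshing failure: inverted cell in flow grid")
      dNx <- solve(J, sh$dN)
      Ke <- Ke + (t(dNx) %*% dNx) * detJ
      ml[en] <- ml[en] + sh$N * detJ
    }
    ti[[e]] <- rep(en, 4); tj[[e]] <- rep(en, each = 4); tx[[e]] <- as.vector(Ke)
  }
  list(K = Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj),
                                x = unlist(tx), dims = c(nn, nn)),
       M = ml)
}

#' Transient planar flow in a body-fitted channel
#'
#' Streamfunction-vorticity solve on a structured curvilinear grid between
#' two wall polylines (sagittal section of the lumen). FEM Laplacian
#' operators (exact on the mapped grid), implicit diffusion, upwind
#' advection in contravariant form, Thom wall vorticity. Driven by a 2-D
#' discharge waveform `Q2_fun` (m^2/s); walls are rigid and no-slip.
#'
#' @param X,Y n1 x n2 matrices of grid coordinates (column j = 1 on the
#'   lower/lesser wall, j = n2 on the upper/greater wall), metres.
#' @param Q2_fun function(t) -> discharge per unit depth, m^2/s.
#' @param fluid `fluid_params`.
#' @param t_end simulated time, s.
#' @param dt step, s (halved automatically on CFL violation).
#' @param n_store stored wall-shear frames.
#' @param wk optional `wk_params` for the single downstream outlet.
#' @return `flow_field` (mode `"planar"`): stored signed wall shear on both
#'   walls (`tau_lower`, `tau_upper`, Pa, positive streamwise), arc lengths
#'   along each wall, final velocity field, traces.
#' @export
run_channel_flow <- function(X, Y, Q2_fun, fluid, t_end, dt = 5e-4,
                             n_store = 40, wk = NULL, P_d0 = 0,
                             Qwk_fun = NULL, avg_from = 0) {
  if (is.null(Qwk_fun)) Qwk_fun <- Q2_fun  # 3-D flow for the 0D coupling
  n1 <- nrow(X); n2 <- ncol(X)
  nodes <- cbind(as.vector(X), as.vector(Y))   # column-major: i fastest
  idx <- function(i, j) (j - 1L) * n1 + i
  quads <- NULL
  for (j in seq_len(n2 - 1)) {
    i <- seq_len(n1 - 1)
    quads <- rbind(quads, cbind(idx(i, j), idx(i + 1, j),
                                idx(i + 1, j + 1), idx(i, j + 1)))
  }
  fem <- assemble_scalar_fem(nodes, quads)
  nn <- n1 * n2
  lower <- idx(seq_len(n1), 1); upper <- idx(seq_len(n1), n2)
  inlet <- idx(1, seq_len(n2)); outlet <- idx(n1, seq_len(n2))
  # inlet profile (parabolic in physical cross-channel distance), unit Q2
  din <- sqrt((X[1, ] - X[1, 1])^2 + (Y[1, ] - Y[1, 1])^2)
  H <- din[n2]
  eta_in <- din / H
  psi_in1 <- 3 * eta_in^2 - 2 * eta_in^3            # psi for Q2 = 1
  om_in1 <- -6 * (1 - 2 * eta_in) / H^2             # -du/dn for Q2 = 1
  # Dirichlet sets (unique; corner nodes get consistent values)
  dir_psi <- sort(unique(c(inlet, lower, upper)))
  free_psi <- setdiff(seq_len(nn), dir_psi)
  Kff <- fem$K[free_psi, free_psi]
  Kfd <- fem$K[free_psi, dir_psi]
  ch_psi <- Matrix::Cholesky(Kff)
  psi_vals <- function(Qn) {
    v <- numeric(nn)
    v[lower] <- 0; v[upper] <- Qn
    v[inlet] <- psi_in1 * Qn
    v[dir_psi]
  }
  # wall-normal spacing for Thom formula
  nrm_dist <- function(jw, jin) {
    dx <- X[, jin] - X[, jw]; dy <- Y[, jin] - Y[, jw]
    # tangent along wall
    tx <- c(diff(X[, jw]), 0); ty <- c(diff(Y[, jw]), 0)
    tx[n1] <- tx[n1 - 1]; ty[n1] <- ty[n1 - 1]
    tl <- sqrt(tx^2 + ty^2)
    abs(dx * (-ty / tl) + dy * (tx / tl))
  }
  d_lo <- nrm_dist(1, 2); d_up <- nrm_dist(n2, n2 - 1)
  # metric derivatives for advection (central, one-sided at edges)
  dxi <- function(F) { G <- F
    G[2:(n1 - 1), ] <- (F[3:n1, ] - F[1:(n1 - 2), ]) / 2
    G[1, ] <- F[2, ] - F[1, ]; G[n1, ] <- F[n1, ] - F[n1 - 1, ]; G }
  deta <- function(F) { G <- F
    G[, 2:(n2 - 1)] <- (F[, 3:n2] - F[, 1:(n2 - 2)]) / 2
    G[, 1] <- F[, 2] - F[, 1]; G[, n2] <- F[, n2] - F[, n2 - 1]; G }
  Xxi <- dxi(X); Xeta <- deta(X); Yxi <- dxi(Y); Yeta <- deta(Y)
  Jm <- Xxi * Yeta - Xeta * Yxi
  nu <- fluid$nu
  build_helm <- function(dt) {
    H <- Matrix::Diagonal(x = fem$M) + dt * nu * fem$K
    dir_om <- dir_psi
    free_om <- free_psi
    list(Hff = Matrix::Cholesky(H[free_om, free_om]),
         Hfd = H[free_om, dir_om], free = free_om, dir = dir_om,
         Mf = fem$M[free_om])
  }
  hl <- build_helm(dt)
  PSI <- matrix(0, n1, n2); OM <- matrix(0, n1, n2)
  store_times <- seq(t_end / n_store, t_end, length.out = n_store)
  tau_lower <- matrix(NA_real_, n_store, n1)
  tau_upper <- matrix(NA_real_, n_store, n1)
  t_store <- numeric(n_store); si <- 1L
  P_trace <- numeric(0); Q_trace <- numeric(0); t_trace <- numeric(0)
  Pd <- P_d0
  UU <- VV <- NULL
  spd_sum <- matrix(0, n1, n2); n_avg <- 0L
  t_now <- 0
  while (t_now < t_end - 1e-12) {
    t_new <- t_now + dt
    Qn <- Q2_fun(t_new)
    Pxi <- dxi(PSI); Peta <- deta(PSI)
    # f_x = (Yeta f_xi - Yxi f_eta)/J ; f_y = (-Xeta f_xi + Xxi f_eta)/J
    UU <- (-Xeta * Pxi + Xxi * Peta) / Jm          # psi_y
    VV <- -(Yeta * Pxi - Yxi * Peta) / Jm          # -psi_x
    # contravariant advecting speeds
    Uc <- Peta / Jm; Vc <- -Pxi / Jm
    hxi <- sqrt(Xxi^2 + Yxi^2); heta <- sqrt(Xeta^2 + Yeta^2)
    cfl <- dt * max(abs(Uc) * 1, abs(Vc) * 1) # computational-space speeds
    if (cfl > 0.9) {
      warning("CFL violation; reducing dt", call. = FALSE)
      dt <- dt / 2; hl <- build_helm(dt)
      next
    }
    Ob <- rbind(OM[1, ], OM[1:(n1 - 1), ]); Of <- rbind(OM[2:n1, ], OM[n1, ])
    Ol <- cbind(OM[, 1], OM[, 1:(n2 - 1)]); Or <- cbind(OM[, 2:n2], OM[, n2])
    adv <- ifelse(Uc > 0, Uc * (OM - Ob), Uc * (Of - OM)) +
           ifelse(Vc > 0, Vc * (OM - Ol), Vc * (Or - OM))
    OMs <- OM - dt * adv
    # implicit diffusion with Dirichlet walls (Thom at old psi), inlet profile
    om_lo <- -2 * (PSI[, 2] - PSI[, 1]) / d_lo^2
    om_up <- -2 * (PSI[, n2 - 1] - PSI[, n2]) / d_up^2
    om_full <- numeric(nn)
    om_full[lower] <- om_lo; om_full[upper] <- om_up
    om_full[inlet] <- om_in1 * Qn
    om_dir <- om_full[dir_psi]
    rhs <- hl$Mf * as.numeric(OMs)[hl$free] -
      as.numeric(hl$Hfd %*% om_dir)
    om_new <- numeric(nn)
    om_new[hl$free] <- as.numeric(Matrix::solve(hl$Hff, rhs))
    om_new[hl$dir] <- om_dir
    OM <- matrix(om_new, n1, n2)
    # psi solve: K psi = M om  (natural outflow at the outlet column)
    psi_dir <- psi_vals(Qn)
    rhs_p <- (fem$M * as.numeric(OM))[free_psi] -
      as.numeric(Kfd %*% psi_dir)
    psi <- numeric(nn)
    psi[free_psi] <- as.numeric(Matrix::solve(ch_psi, rhs_p))
    psi[dir_psi] <- psi_dir
    PSI <- matrix(psi, n1, n2)
    if (!is.null(wk)) {
      stw <- rcr_step(wk, Pd, Qwk_fun(t_new), dt)  # rigid: Q_out = Q_in
      Pd <- stw$P_d; P_trace <- c(P_trace, stw$P)
    } else P_trace <- c(P_trace, 0)
    Q_trace <- c(Q_trace, Qn); t_trace <- c(t_trace, t_new)
    if (t_new >= avg_from) {
      spd_sum <- spd_sum + sqrt(UU^2 + VV^2); n_avg <- n_avg + 1L
    }
    t_now <- t_new
    if (si <= n_store && t_now >= store_times[si] - 1e-12) {
      tau_lower[si, ] <- -fluid$mu * (-2 * (PSI[, 2] - PSI[, 1]) / d_lo^2)
      tau_upper[si, ] <- fluid$mu * (-2 * (PSI[, n2 - 1] - PSI[, n2]) / d_up^2)
      t_store[si] <- t_now
      si <- si + 1L
    }
  }
  s_lower <- c(0, cumsum(sqrt(diff(X[, 1])^2 + diff(Y[, 1])^2)))
  s_upper <- c(0, cumsum(sqrt(diff(X[, n2])^2 + diff(Y[, n2])^2)))
  structure(list(mode = "planar", X = X, Y = Y, psi = PSI, omega = OM,
                 u = UU, v = VV, t_store = t_store,
                 tau_lower = tau_lower, tau_upper = tau_upper,
                 s_lower = s_lower, s_upper = s_upper,
                 speed_mean = spd_sum / max(n_avg, 1L),
                 P_trace = P_trace, Q_trace = Q_trace, t_trace = t_trace,
                 dt = dt,
                 fluid = fluid), class = "flow_field")
}

#' Wall shear stress vectors from a flow field
#'
#' Returns the stored signed wall shear series: for the axisymmetric mode one
#' wall (the tube wall), for the planar mode the lesser (lower) and greater
#' (upper) walls. Sign is positive streamwise.
#'
#' @param field `flow_field`.
#' @return list of matrices (frames x stations) plus station coordinates, m.
#' @export
wall_traction <- function(field) {
  if (field$mode == "axisymmetric")
    list(tau = field$tau_wall, s = field$z, t = field$t_store)
  else
    list(tau_lower = field$tau_lower, tau_upper = field$tau_upper,
         s_lower = field$s_lower, s_upper = field$s_upper, t = field$t_store)
}
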