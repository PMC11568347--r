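## Planar co-rotational Euler-Bernoulli beam finite elements with frictionless
## penalty node-to-curve contact and an incremental-load Newton driver.
## Linear-elastic section response inside a geometrically nonlinear
## (large-rotation) equilibrium formulation: linear kinematics cannot
## represent the straightening of the skeleton, the co-rotational frame can.
## Working plane is the sagittal plane; 3 dof/node (ux, uy, rot).

#' Create a planar beam model
#'
#' @param xy n x 2 reference node coordinates (the stress-free shape).
#' @param E Young's modulus, MPa.
#' @param A section area, mm^2.
#' @param I second moment of area, mm^4.
#' @return object of class `beam_model` (chain of n-1 elements).
#' @export
beam_model <- function(xy, E, A, I) {
  n <- nrow(xy)
  d <- diff(xy)
  L0 <- sqrt(rowSums(d^2))
  if (any(L0 <= 0)) stop("coincident beam nodes")
  alpha0 <- atan2(d[, 2], d[, 1])
  structure(list(xy = xy, n = n, E = E, A = A, I = I, L0 = L0,
                 alpha0 = alpha0), class = "beam_model")
}

# internal force and tangent of one co-rotational element
# p = c(x1, y1, th1, x2, y2, th2) current configuration (absolute)
corot_element <- function(p, L0, alpha0, EA, EI) {
  dx <- p[4] - p[1]; dy <- p[5] - p[2]
  L <- sqrt(dx^2 + dy^2)
  cs <- dx / L; sn <- dy / L
  alpha <- atan2(dy, dx)
  # local rotations, unwrapped to (-pi, pi)
  wrap <- function(a) atan2(sin(a), cos(a))
  t1 <- wrap(p[3] - (alpha - alpha0))
  t2 <- wrap(p[6] - (alpha - alpha0))
  ul <- L - L0
  N <- EA * ul / L0
  M1 <- EI / L0 * (4 * t1 + 2 * t2)
  M2 <- EI / L0 * (2 * t1 + 4 * t2)
  r <- c(-cs, -sn, 0, cs, sn, 0)
  z <- c(sn, -cs, 0, -sn, cs, 0)
  B <- rbind(r,
             c(0, 0, 1, 0, 0, 0) - z / L,
             c(0, 0, 0, 0, 0, 1) - z / L)
  fl <- c(N, M1, M2)
  fint <- drop(t(B) %*% fl)
  Cl <- matrix(c(EA / L0, 0, 0,
                 0, 4 * EI / L0, 2 * EI / L0,
                 0, 2 * EI / L0, 4 * EI / L0), 3, 3)
  Kt <- t(B) %*% Cl %*% B +
    N / L * outer(z, z) +
    (M1 + M2) / L^2 * (outer(r, z) + outer(z, r))
  list(fint = fint, K = Kt)
}

# assemble internal force + tangent for a beam chain at configuration x
# x: n x 3 (x, y, theta) absolute
beam_assemble <- function(bm, x) {
  n <- bm$n
  f <- numeric(3 * n)
  trips <- vector("list", n - 1)
  EA <- bm$E * bm$A; EI <- bm$E * bm$I
  for (e in seq_len(n - 1)) {
    idx <- c(3 * e - 2, 3 * e - 1, 3 * e, 3 * e + 1, 3 * e + 2, 3 * e + 3)
    pe <- c(x[e, 1], x[e, 2], x[e, 3], x[e + 1, 1], x[e + 1, 2], x[e + 1, 3])
    el <- corot_element(pe, bm$L0[e], bm$alpha0[e], EA, EI)
    f[idx] <- f[idx] + el$fint
    trips[[e]] <- list(i = rep(idx, 6), j = rep(idx, each = 6),
                       x = as.vector(el$K))
  }
  list(f = f,
       K = Matrix::sparseMatrix(
         i = unlist(lapply(trips, `[[`, "i")),
         j = unlist(lapply(trips, `[[`, "j")),
         x = unlist(lapply(trips, `[[`, "x")), dims = c(3 * n, 3 * n)))
}

## ---- contact ---------------------------------------------------------------

# project point q onto polyline (m x 2); returns segment, parameter, point,
# and left normal of the segment (CCW rotation of its tangent)
polyline_project <- function(q, poly) {
  a <- poly[-nrow(poly), , drop = FALSE]
  b <- poly[-1, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  t <- pmin(1, pmax(0, ((q[1] - a[, 1]) * ab[, 1] +
                        (q[2] - a[, 2]) * ab[, 2]) / len2))
  px <- a[, 1] + t * ab[, 1]; py <- a[, 2] + t * ab[, 2]
  d2 <- (q[1] - px)^2 + (q[2] - py)^2
  k <- which.min(d2)
  tang <- ab[k, ] / sqrt(len2[k])
  list(seg = k, t = t[k], point = c(px[k], py[k]),
       normal = c(-tang[2], tang[1]))
}

#' Evaluate frictionless penalty contact between a point set and a curve
#'
#' Two-sided channel contact: each slave point must stay within a signed
#' lateral clearance band around the master polyline. Compressive-only spring
#' forces along the master normal; equal and opposite reactions distributed to
#' the master segment nodes. Penetration of the band is interpreted physically
#' as radial wall distension (the penalty stiffness is the wall's ring
#' stiffness), and is reported for stress recovery.
#'
#' @param slave_xy m x 2 slave point positions.
#' @param master_xy k x 2 master polyline positions.
#' @param clear_plus,clear_minus clearance on the +normal / -normal side of
#'   the master curve (per slave point, recycled; may be negative for a
#'   press fit).
#' @param k_pen penalty stiffness per slave point, N/mm.
#' @return list: `f_slave` (m x 2), `f_master` (k x 2), `active` logical,
#'   `viol` signed band violation (+ = pushed toward +normal side),
#'   `seg`, `tpar` projection info, `normal` (m x 2).
#' @export
contact_eval <- function(slave_xy, master_xy, clear_plus, clear_minus, k_pen) {
  m <- nrow(slave_xy)
  clear_plus <- rep_len(clear_plus, m)
  clear_minus <- rep_len(clear_minus, m)
  k_pen <- rep_len(k_pen, m)
  f_slave <- matrix(0, m, 2)
  f_master <- matrix(0, nrow(master_xy), 2)
  viol <- numeric(m); active <- logical(m)
  seg <- integer(m); tpar <- numeric(m); nrm <- matrix(0, m, 2)
  for (i in seq_len(m)) {
    pr <- polyline_project(slave_xy[i, ], master_xy)
    seg[i] <- pr$seg; tpar[i] <- pr$t; nrm[i, ] <- pr$normal
    delta <- sum((slave_xy[i, ] - pr$point) * pr$normal)
    over_p <- delta - clear_plus[i]       # violation on +normal side
    over_m <- -clear_minus[i] - delta     # violation on -normal side
    fi <- 0
    if (over_p > 0) { fi <- fi - k_pen[i] * over_p; active[i] <- TRUE
                      viol[i] <- viol[i] + over_p }
    if (over_m > 0) { fi <- fi + k_pen[i] * over_m; active[i] <- TRUE
                      viol[i] <- viol[i] - over_m }
    if (active[i]) {
      fv <- fi * pr$normal
      f_slave[i, ] <- fv
      f_master[pr$seg, ] <- f_master[pr$seg, ] - (1 - pr$t) * fv
      f_master[pr$seg + 1, ] <- f_master[pr$seg + 1, ] - pr$t * fv
    }
  }
  list(f_slave = f_slave, f_master = f_master, active = active, viol = viol,
       seg = seg, tpar = tpar, normal = nrm)
}

#' Static Newton solve of a single beam chain
#'
#' @param bm `beam_model`.
#' @param x0 starting configuration (n x 3 absolute; default reference).
#' @param fixed dof indices (3 per node: x, y, rot) held at their `x0` value.
#' @param force external nodal force vector (length 3n).
#' @param n_steps load increments.
#' @param tol relative residual tolerance.
#' @param max_iter Newton iterations per increment.
#' @return list `x` (n x 3), `converged`, `residual`.
#' @export
beam_solve <- function(bm, x0 = NULL, fixed, force = NULL, n_steps = 5,
                       tol = 1e-8, max_iter = 50) {
  n <- bm$n
  if (is.null(x0)) x0 <- cbind(bm$xy, 0)  # rotations measured from reference
  if (is.null(force)) force <- numeric(3 * n)
  v <- as.vector(t(x0))
  free <- setdiff(seq_len(3 * n), fixed)
  fscale <- max(sqrt(sum(force^2)), 1)
  conv <- FALSE; res <- NA_real_
  for (stp in seq_len(n_steps)) {
    lam <- stp / n_steps
    for (it in seq_len(max_iter)) {
      x <- matrix(v, n, 3, byrow = TRUE)
      asm <- beam_assemble(bm, x)
      R <- asm$f - lam * force
      res <- sqrt(sum(R[free]^2)) / fscale
      if (res < tol) { conv <- TRUE; break }
      conv <- FALSE
      dv <- numeric(3 * n)
      dv[free] <- -as.numeric(Matrix::solve(asm$K[free, free], R[free]))
      v <- v + dv
    }
  }
  list(x = matrix(v, n, 3, byrow = TRUE), converged = conv, residual = res)
}

## ---- coupled Newton driver -------------------------------------------------

# Two-beam system: master (aorta) + slave (skeleton) with channel contact.
# State x: list(master = n1 x 3, slave = n2 x 3) absolute configurations.
# fixed: list(master = dof indices, slave = dof indices) into each beam's
# 3n local numbering; prescribed values are taken from the current x.
beam_system_solve <- function(bm_master, bm_slave, x, fixed_master,
                              fixed_slave, clear_plus, clear_minus, k_pen,
                              extra_force = NULL, root_spring = NULL,
                              tol = 1e-6, max_iter = 60) {
  n1 <- bm_master$n; n2 <- bm_slave$n
  nd1 <- 3 * n1; nd <- nd1 + 3 * n2
  fixed <- c(fixed_master, nd1 + fixed_slave)
  free <- setdiff(seq_len(nd), fixed)
  pack <- function(x) c(as.vector(t(x$master)), as.vector(t(x$slave)))
  unpack <- function(v) list(master = matrix(v[1:nd1], n1, 3, byrow = TRUE),
                             slave = matrix(v[-(1:nd1)], n2, 3, byrow = TRUE))
  v <- pack(x)
  ref_scale <- NULL
  conv <- FALSE; res <- NA_real_
  for (it in seq_len(max_iter)) {
    st <- unpack(v)
    am <- beam_assemble(bm_master, st$master)
    as_ <- beam_assemble(bm_slave, st$slave)
    ct <- contact_eval(st$slave[, 1:2], st$master[, 1:2],
                       clear_plus, clear_minus, k_pen)
    R <- numeric(nd)
    R[1:nd1] <- am$f
    R[-(1:nd1)] <- as_$f
    # contact: external forces enter with minus sign in the residual
    sl_dofs_x <- nd1 + 3 * seq_len(n2) - 2
    R[sl_dofs_x] <- R[sl_dofs_x] - ct$f_slave[, 1]
    R[sl_dofs_x + 1] <- R[sl_dofs_x + 1] - ct$f_slave[, 2]
    ms_dofs_x <- 3 * seq_len(n1) - 2
    R[ms_dofs_x] <- R[ms_dofs_x] - ct$f_master[, 1]
    R[ms_dofs_x + 1] <- R[ms_dofs_x + 1] - ct$f_master[, 2]
    if (!is.null(extra_force)) R <- R - extra_force
    if (!is.null(root_spring)) {
      # rotational spring tying slave root rotation to its reference value
      i <- nd1 + 3
      R[i] <- R[i] + root_spring$k * (v[i] - root_spring$theta0)
    }
    # tangent
    K <- Matrix::bdiag(am$K, as_$K)
    trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
    for (i in which(ct$active)) {
      g <- ct$normal[i, ]
      kk <- k_pen[min(i, length(k_pen))]
      sdof <- nd1 + c(3 * i - 2, 3 * i - 1)
      mdof_a <- c(3 * ct$seg[i] - 2, 3 * ct$seg[i] - 1)
      mdof_b <- c(3 * ct$seg[i] + 1, 3 * ct$seg[i] + 2)
      w <- c(1 - ct$tpar[i], ct$tpar[i])
      dofs <- c(sdof, mdof_a, mdof_b)
      coef <- c(1, 1, -w[1], -w[1], -w[2], -w[2]) *
        rep(c(g[1], g[2]), 3)
      Kc <- kk * outer(coef, coef)
      trip_i <- c(trip_i, rep(dofs, 6))
      trip_j <- c(trip_j, rep(dofs, each = 6))
      trip_x <- c(trip_x, as.vector(Kc))
    }
    if (length(trip_i))
      K <- K + Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                                    dims = c(nd, nd))
    if (!is.null(root_spring)) {
      i <- nd1 + 3
      K[i, i] <- K[i, i] + root_spring$k
    }
    if (is.null(ref_scale))
      ref_scale <- max(sum(abs(ct$f_slave)), sqrt(sum(R[free]^2)), 1e-8)
    rnorm <- sqrt(sum(R[free]^2))
    res <- rnorm / ref_scale
    if (res < tol || rnorm < 1e-8) { conv <- TRUE; break }
    dv <- numeric(nd)
    dv[free] <- -as.numeric(Matrix::solve(K[free, free], R[free]))
    # damped line search on the residual norm
    step <- 1; r0 <- sqrt(sum(R[free]^2))
    repeat {
      vt <- v + step * dv
      stt <- unpack(vt)
      Rt <- tryCatch({
        amt <- beam_assemble(bm_master, stt$master)
        ast <- beam_assemble(bm_slave, stt$slave)
        ctt <- contact_eval(stt$slave[, 1:2], stt$master[, 1:2],
                            clear_plus, clear_minus, k_pen)
        Rt <- numeric(nd)
        Rt[1:nd1] <- amt$f; Rt[-(1:nd1)] <- ast$f
        Rt[sl_dofs_x] <- Rt[sl_dofs_x] - ctt$f_slave[, 1]
        Rt[sl_dofs_x + 1] <- Rt[sl_dofs_x + 1] - ctt$f_slave[, 2]
        Rt[ms_dofs_x] <- Rt[ms_dofs_x] - ctt$f_master[, 1]
        Rt[ms_dofs_x + 1] <- Rt[ms_dofs_x + 1] - ctt$f_master[, 2]
        if (!is.null(extra_force)) Rt <- Rt - extra_force
        if (!is.null(root_spring)) {
          i <- nd1 + 3
          Rt[i] <- Rt[i] + root_spring$k * (vt[i] - root_spring$theta0)
        }
        Rt
      }, error = function(e) NULL)
      if (!is.null(Rt) && sqrt(sum(Rt[free]^2)) < r0 * (1 - 1e-4 * step)) {
        v <- vt; break
      }
      step <- step / 2
      if (step < 1 / 64) { v <- v + step * 2 * dv; break }
    }
  }
  st <- unpack(v)
  ct <- contact_eval(st$slave[, 1:2], st$master[, 1:2],
                     clear_plus, clear_minus, k_pen)
  list(state = st, contact = ct, converged = conv, residual = res,
       iterations = if (conv) it else max_iter)
}
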