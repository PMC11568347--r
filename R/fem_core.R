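## Small-strain continuum finite elements: bilinear quadrilaterals in
## plane-strain and axisymmetric (r, z) formulations. Units are consistent
## mm / N / MPa throughout the structural stage (1 mmHg = 1.333224e-4 MPa).
## This core underpins the pressurized-wall (Laplace/Lame) state and the
## patch-test / closed-form oracles; the recoil kinematics live in the
## co-rotational beam solver.

#' Material parameters for the structural stage
#'
#' Linear-elastic constants: aorta 1 MPa, homogenized metallic skeleton 5 MPa,
#' Poisson's ratio 0.48 for both. The polyester graft is rigid by default;
#' `polyester_model = "elastic"` uses E = 1.78 GPa (= 1780 MPa) instead.
#'
#' @param E_aorta Young's modulus of the aortic wall, MPa.
#' @param E_skeleton Young's modulus of the homogenized skeleton tube, MPa.
#' @param nu Poisson's ratio (both materials), in (0, 0.5).
#' @param polyester_model `"rigid"` or `"elastic"`.
#' @param E_polyester Young's modulus used when `polyester_model = "elastic"`,
#'   MPa.
#' @return object of class `material_params`.
#' @export
material_params <- function(E_aorta = 1, E_skeleton = 5, nu = 0.48,
                            polyester_model = c("rigid", "elastic"),
                            E_polyester = 1780) {
  polyester_model <- match.arg(polyester_model)
  if (nu <= 0 || nu >= 0.5) stop("Poisson's ratio must lie in (0, 0.5)")
  if (E_aorta <= 0 || E_skeleton <= 0 || E_polyester <= 0)
    stop("Young's moduli must be positive")
  structure(list(E_aorta = E_aorta, E_skeleton = E_skeleton, nu = nu,
                 polyester_model = polyester_model,
                 E_polyester = E_polyester),
            class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  cat("<material_params> E_aorta=", x$E_aorta, " MPa, E_skeleton=",
      x$E_skeleton, " MPa, nu=", x$nu, ", polyester=", x$polyester_model,
      "\n", sep = "")
  invisible(x)
}

#' mmHg to MPa conversion
#' @param mmHg pressure in millimetres of mercury.
#' @return pressure in MPa.
#' @export
mmHg_to_MPa <- function(mmHg) mmHg * 133.3224e-6

#' mmHg to Pa conversion
#' @param mmHg pressure in millimetres of mercury.
#' @return pressure in Pa.
#' @export
mmHg_to_Pa <- function(mmHg) mmHg * 133.3224

#' Structured rectangular quad mesh
#' @param x0,x1,y0,y1 rectangle bounds (interpreted as (r, z) in axisymmetric
#'   problems).
#' @param nx,ny element counts.
#' @return list `nodes` (n x 2), `quads` (m x 4, CCW), index helpers.
#' @export
fem_rect_mesh <- function(x0, x1, y0, y1, nx, ny) {
  xs <- seq(x0, x1, length.out = nx + 1)
  ys <- seq(y0, y1, length.out = ny + 1)
  nodes <- cbind(rep(xs, times = ny + 1), rep(ys, each = nx + 1))
  nid <- function(i, j) (j - 1L) * (nx + 1L) + i
  quads <- NULL
  for (j in seq_len(ny)) {
    i <- seq_len(nx)
    quads <- rbind(quads, cbind(nid(i, j), nid(i + 1, j),
                                nid(i + 1, j + 1), nid(i, j + 1)))
  }
  list(nodes = nodes, quads = quads, nx = nx, ny = ny, nid = nid)
}

elasticity_D <- function(E, nu, type) {
  if (type == "plane_strain") {
    c1 <- E / ((1 + nu) * (1 - 2 * nu))
    matrix(c(c1 * (1 - nu), c1 * nu, 0,
             c1 * nu, c1 * (1 - nu), 0,
             0, 0, E / (2 * (1 + nu))), 3, 3)
  } else { # axisymmetric: (e_rr, e_zz, g_rz, e_theta)
    c1 <- E / ((1 + nu) * (1 - 2 * nu))
    D <- matrix(0, 4, 4)
    D[c(1, 2, 4), c(1, 2, 4)] <- c1 * nu
    diag(D)[c(1, 2, 4)] <- c1 * (1 - nu)
    D[3, 3] <- E / (2 * (1 + nu))
    D
  }
}

gauss2 <- 1 / sqrt(3) * c(-1, 1)

quad_shape <- function(xi, eta) {
  N <- c((1 - xi) * (1 - eta), (1 + xi) * (1 - eta),
         (1 + xi) * (1 + eta), (1 - xi) * (1 + eta)) / 4
  dN <- rbind(c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)) / 4,
              c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)) / 4)
  list(N = N, dN = dN)
}

#' Assemble the linear-elastic stiffness operator
#'
#' Bilinear quads, 2 x 2 Gauss quadrature. `type = "plane_strain"` works in
#' (x, y); `type = "axisymmetric"` works in (r, z) with the hoop strain u_r/r
#' carried as a fourth strain component and weights 2*pi*r. Returns the sparse
#' stiffness `K`, an internal-force evaluator (`K %*% u` for this linear
#' constitutive law) and the data needed for stress recovery.
#'
#' @param nodes n x 2 coordinates.
#' @param quads m x 4 connectivity (CCW).
#' @param E,nu material constants (MPa, -). `E` may be a per-element vector.
#' @param type `"plane_strain"` or `"axisymmetric"`.
#' @return object of class `fem_operator`: `K` (dgCMatrix, 2n x 2n, dof
#'   order (u1x, u1y, u2x, ...)), `internal_force(u)`, `stress(u)` (nodal
#'   averaged), `ndof`.
#' @export
assemble_elasticity <- function(nodes, quads, E, nu,
                                type = c("plane_strain", "axisymmetric")) {
  type <- match.arg(type)
  nn <- nrow(nodes); ne <- nrow(quads)
  if (length(E) == 1) E <- rep(E, ne)
  nstr <- if (type == "plane_strain") 3L else 4L
  trip_i <- vector("list", ne); trip_j <- vector("list", ne)
  trip_x <- vector("list", ne)
  gp <- expand.grid(xi = gauss2, eta = gauss2)
  Bstore <- vector("list", ne)
  for (e in seq_len(ne)) {
    en <- quads[e, ]
    xy <- nodes[en, , drop = FALSE]
    dofs <- as.vector(rbind(2 * en - 1, 2 * en))
    Ke <- matrix(0, 8, 8)
    D <- elasticity_D(E[e], nu, type)
    Bg <- vector("list", 4)
    for (g in 1:4) {
      sh <- quad_shape(gp$xi[g], gp$eta[g])
      J <- sh$dN %*% xy
      detJ <- det(J)
      if (detJ <= 0) stop("rank error: inverted element ", e)
      dNx <- solve(J, sh$dN)          # 2 x 4, derivatives w.r.t. x/r, y/z
      B <- matrix(0, nstr, 8)
      B[1, seq(1, 8, 2)] <- dNx[1, ]
      B[2, seq(2, 8, 2)] <- dNx[2, ]
      B[3, seq(1, 8, 2)] <- dNx[2, ]
      B[3, seq(2, 8, 2)] <- dNx[1, ]
      w <- detJ
      if (type == "axisymmetric") {
        r <- sum(sh$N * xy[, 1])
        B[4, seq(1, 8, 2)] <- sh$N / r
        w <- w * 2 * pi * r
      }
      Ke <- Ke + t(B) %*% D %*% B * w
      Bg[[g]] <- list(B = B, D = D, w = w)
    }
    Bstore[[e]] <- Bg
    trip_i[[e]] <- rep(dofs, times = 8)
    trip_j[[e]] <- rep(dofs, each = 8)
    trip_x[[e]] <- as.vector(Ke)
  }
  K <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = unlist(trip_x), dims = c(2 * nn, 2 * nn))
  op <- list(K = K, nodes = nodes, quads = quads, type = type,
             Bstore = Bstore, ndof = 2L * nn)
  op$internal_force <- function(u) as.numeric(K %*% u)
  op$stress <- function(u) fem_nodal_stress(op, u)
  class(op) <- "fem_operator"
  op
}

# Gauss-point stresses extrapolated by nodal averaging
fem_nodal_stress <- function(op, u) {
  nn <- nrow(op$nodes)
  nstr <- if (op$type == "plane_strain") 3L else 4L
  acc <- matrix(0, nn, nstr); cnt <- numeric(nn)
  for (e in seq_len(nrow(op$quads))) {
    en <- op$quads[e, ]
    dofs <- as.vector(rbind(2 * en - 1, 2 * en))
    ue <- u[dofs]
    sg <- vapply(op$Bstore[[e]],
                 function(g) as.numeric(g$D %*% (g$B %*% ue)), numeric(nstr))
    se <- rowMeans(sg)
    acc[en, ] <- acc[en, ] + matrix(se, 4, nstr, byrow = TRUE)
    cnt[en] <- cnt[en] + 1
  }
  acc / cnt
}

#' Solve the constrained static problem K u = f
#' @param op `fem_operator` (or any list with sparse `K`).
#' @param f load vector.
#' @param fixed integer dof indices with prescribed values.
#' @param fixed_vals prescribed values (recycled; default 0).
#' @return displacement vector u.
#' @export
solve_static <- function(op, f, fixed, fixed_vals = 0) {
  K <- op$K
  n <- nrow(K)
  if (!length(fixed)) stop("rank error: no constraints supplied")
  fixed_vals <- rep_len(fixed_vals, length(fixed))
  free <- setdiff(seq_len(n), fixed)
  u <- numeric(n)
  u[fixed] <- fixed_vals
  rhs <- f[free] - as.numeric(K[free, fixed, drop = FALSE] %*% fixed_vals)
  u[free] <- as.numeric(Matrix::solve(K[free, free], rhs))
  u
}

#' Pressure load on boundary edges
#'
#' Consistent nodal loads for a uniform pressure acting along the inward
#' normal of each 2-node boundary edge (pressure pushes from the fluid side
#' toward the solid: edges must be ordered so the fluid lies to their left).
#' In the axisymmetric case loads are weighted by 2*pi*r and an `axial_cap`
#' pressure resultant can be requested for capped tubes.
#'
#' @param nodes n x 2 coordinates.
#' @param edges m x 2 node pairs, fluid on the left of 1 -> 2.
#' @param p pressure (MPa; positive pushes left-to-right across the edge).
#' @param type `"plane_strain"` or `"axisymmetric"`.
#' @return load vector of length 2 * n.
#' @export
apply_pressure <- function(nodes, edges, p,
                           type = c("plane_strain", "axisymmetric")) {
  type <- match.arg(type)
  f <- numeric(2 * nrow(nodes))
  if (p == 0 || !nrow(edges)) return(f)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    d <- nodes[b, ] - nodes[a, ]
    len <- sqrt(sum(d^2))
    nrm <- c(d[2], -d[1]) / len       # right-hand normal: fluid left -> push right
    if (type == "plane_strain") {
      fa <- p * len / 2 * nrm
      f[2 * a - 1] <- f[2 * a - 1] + fa[1]; f[2 * a] <- f[2 * a] + fa[2]
      f[2 * b - 1] <- f[2 * b - 1] + fa[1]; f[2 * b] <- f[2 * b] + fa[2]
    } else {
      # linear shape functions with 2*pi*r weight: exact 2-point integration
      ra <- nodes[a, 1]; rb <- nodes[b, 1]
      wa <- 2 * pi * len * (2 * ra + rb) / 6
      wb <- 2 * pi * len * (ra + 2 * rb) / 6
      f[2 * a - 1] <- f[2 * a - 1] + p * wa * nrm[1]
      f[2 * a]     <- f[2 * a]     + p * wa * nrm[2]
      f[2 * b - 1] <- f[2 * b - 1] + p * wb * nrm[1]
      f[2 * b]     <- f[2 * b]     + p * wb * nrm[2]
    }
  }
  f
}

#' Pressurized thick-walled tube (Lame problem), axisymmetric FEM
#'
#' Solves the internally pressurized annulus in (r, z) with plane-strain axial
#' constraint and returns the hoop-stress profile through the wall together
#' with the thin-wall (Laplace, p r_i / t) and thick-wall (Lame inner-surface)
#' closed forms. This is the pre-recoil stress state of the idealized aorta:
#' the reference wall stress of about 0.1 MPa.
#'
#' @param p internal pressure, MPa (default 100 mmHg).
#' @param ri,ro inner/outer wall radii, mm.
#' @param E,nu wall material (MPa, -).
#' @param nr radial element count.
#' @return list: `r` radii, `sigma_theta` nodal hoop stress (MPa),
#'   `sigma_avg` through-thickness average, `laplace`, `lame_inner`, `u`.
#' @export
lame_tube <- function(p = mmHg_to_MPa(100), ri = 15, ro = 17,
                      E = 1, nu = 0.48, nr = 8) {
  mesh <- fem_rect_mesh(ri, ro, 0, (ro - ri) / 2, nr, 1)
  op <- assemble_elasticity(mesh$nodes, mesh$quads, E, nu, "axisymmetric")
  # inner edge r = ri: fluid at smaller r. Walking in +z, the fluid lies on
  # the left of the edge and pressure pushes toward +r.
  inner <- which(abs(mesh$nodes[, 1] - ri) < 1e-9)
  inner <- inner[order(mesh$nodes[inner, 2])]
  edges <- cbind(inner[-length(inner)], inner[-1])
  f <- apply_pressure(mesh$nodes, edges, p, "axisymmetric")
  zdofs <- 2 * seq_len(nrow(mesh$nodes))   # plane strain: w = 0 everywhere
  u <- solve_static(op, f, fixed = zdofs)
  st <- op$stress(u)
  bottom <- which(abs(mesh$nodes[, 2]) < 1e-9)
  ord <- order(mesh$nodes[bottom, 1])
  r <- mesh$nodes[bottom[ord], 1]
  s_theta <- st[bottom[ord], 4]
  # through-thickness average by trapezoid (equilibrium value = p ri / t)
  avg <- sum(diff(r) * (utils::head(s_theta, -1) + utils::tail(s_theta, -1)) / 2) /
    (ro - ri)
  list(r = r, sigma_theta = s_theta, sigma_avg = avg,
       laplace = p * ri / (ro - ri),
       lame_inner = p * (ro^2 + ri^2) / (ro^2 - ri^2), u = u)
}
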