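# Independent closed-form oracles used across the suite.

# complex Bessel J0 / J1 by power series (|z| modest; used for the
# pulsatile-tube analytic solution)
besselJ0c <- function(z) {
  s <- 0 + 0i; term <- 1 + 0i; k <- 0
  repeat {
    s <- s + term; k <- k + 1
    term <- term * (-(z / 2)^2) / (k^2)
    if (abs(term) < 1e-16) break
  }
  s
}
besselJ1c <- function(z) {
  s <- 0 + 0i; term <- z / 2; k <- 0
  repeat {
    s <- s + term; k <- k + 1
    term <- term * (-(z / 2)^2) / (k * (k + 1))
    if (abs(term) < 1e-16) break
  }
  s
}

# analytic oscillatory-tube axial velocity profile for prescribed flow
# Q(t) = Q0 sin(omega t); returns u(r) at time t
womersley_profile <- function(r, R, nu, omega, Q0, t) {
  alpha <- R * sqrt(omega / nu)
  L <- complex(real = 0, imaginary = 1)^1.5 * alpha
  denomQ <- 1 - 2 * besselJ1c(L) / (L * besselJ0c(L))
  vapply(r, function(rr)
    Im(Q0 / (pi * R^2 * denomQ) *
         (1 - besselJ0c(L * rr / R) / besselJ0c(L)) * exp(1i * omega * t)),
    numeric(1))
}

# Poiseuille tube wall shear for flow rate Q
poiseuille_wss <- function(mu, Q, R) 4 * mu * Q / (pi * R^3)

# Lame inner-surface hoop stress of a pressurized annulus
lame_sigma_inner <- function(p, ri, ro) p * (ro^2 + ri^2) / (ro^2 - ri^2)

# volumes of all volume elements of a mesh (hexes via 5-tet decomposition);
# independent of the package's Jacobian code paths
tet_hex_volume <- function(mesh) {
  out <- numeric(0)
  tv <- function(tet) fetsim:::tet_volume(mesh$nodes, tet)
  if (!is.null(mesh$elems$tet) && nrow(mesh$elems$tet))
    out <- c(out, tv(mesh$elems$tet))
  if (!is.null(mesh$elems$hex) && nrow(mesh$elems$hex)) {
    h <- mesh$elems$hex
    dec <- list(c(1, 2, 4, 5), c(2, 3, 4, 7), c(2, 5, 6, 7),
                c(4, 5, 7, 8), c(2, 4, 5, 7))
    vol <- rowSums(vapply(dec, function(d) abs(tv(h[, d, drop = FALSE])),
                          numeric(nrow(h))))
    out <- c(out, vol)
  }
  out
}

# small flat triangulated patch in the z = 0 plane for surface-operator tests
flat_patch <- function(n = 6, L = 2) {
  xs <- seq(-L / 2, L / 2, length.out = n)
  nodes <- as.matrix(expand.grid(x = xs, y = xs))
  nodes <- cbind(nodes, 0)
  nid <- function(i, j) (j - 1L) * n + i
  tris <- NULL
  for (j in seq_len(n - 1)) for (i in seq_len(n - 1)) {
    tris <- rbind(tris, c(nid(i, j), nid(i + 1, j), nid(i + 1, j + 1)),
                  c(nid(i, j), nid(i + 1, j + 1), nid(i, j + 1)))
  }
  interior <- which(abs(nodes[, 1]) < L / 2 - 1e-9 &
                    abs(nodes[, 2]) < L / 2 - 1e-9)
  list(mesh = fs_mesh(nodes, list(tri = tris)), interior = interior)
}
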