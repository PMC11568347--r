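## Parametric geometry of the idealized aorta, the FET device, the treated
## assembly and the CFD lumen. This module is the pipeline's synthetic-data
## generator: every downstream stage consumes its output. All lengths mm.

#' Aorta geometry parameters
#'
#' Defaults are the idealized thoracic aorta used throughout: arch (ascending +
#' transverse) of 50 mm centerline radius spanning 180 degrees, a straight
#' 400 mm descending segment, 30 mm inner diameter, 2 mm wall.
#'
#' @param arch_radius centerline radius of curvature of the arch, mm.
#' @param desc_length length of the straight descending segment, mm.
#' @param inner_diameter luminal diameter, mm.
#' @param wall_thickness aortic wall thickness, mm.
#' @param arch_span angular span of the arch, degrees, in (0, 270].
#' @return object of class `aorta_params`.
#' @export
aorta_params <- function(arch_radius = 50, desc_length = 400,
                         inner_diameter = 30, wall_thickness = 2,
                         arch_span = 180) {
  if (arch_radius <= 0 || inner_diameter <= 0)
    stop("aorta parameters: lengths must be positive")
  if (desc_length < 0 || wall_thickness < 0)
    stop("aorta parameters: desc_length and wall_thickness must be >= 0")
  if (arch_span <= 0 || arch_span > 270)
    stop("arch_span must lie in (0, 270] degrees")
  structure(list(arch_radius = arch_radius, desc_length = desc_length,
                 inner_diameter = inner_diameter,
                 wall_thickness = wall_thickness, arch_span = arch_span),
            class = "aorta_params")
}

#' FET device parameters
#'
#' The device is a curved polyester graft (arch part) continued by a straight
#' stented segment: a 50 mm homogenized metallic-skeleton tube whose natural
#' (stress-free) shape is straight. Oversizing is defined against a 30 mm
#' reference aortic inner diameter: outer diameter = reference * (1 + rate).
#'
#' @param oversizing_rate fraction in `[0, 0.30]` (the study sweeps 0 to 30%
#'   in 5% steps).
#' @param device_thickness wall thickness of graft and skeleton, mm.
#' @param skeleton_length length of the stented segment, mm.
#' @param reference_id aortic inner diameter the rate refers to, mm.
#' @param skeleton_arc_fraction fraction of the skeleton landed on the distal
#'   arch (the remainder lies on the straight descending segment). Must be
#'   > 0 for elastic recoil to exist: a skeleton deployed entirely straight
#'   has no stored bending energy.
#' @param graft_start_angle arch angle (degrees from the ascending end) of the
#'   proximal anastomosis; the aorta proximal of it is replaced by the graft.
#' @return object of class `fet_params` with derived `outer_diameter`.
#' @export
fet_params <- function(oversizing_rate = 0.15, device_thickness = 1.75,
                       skeleton_length = 50, reference_id = 30,
                       skeleton_arc_fraction = 0.5, graft_start_angle = 90) {
  if (oversizing_rate < 0 || oversizing_rate > 0.5)
    stop("oversizing_rate out of range")
  if (skeleton_length <= 0 || device_thickness <= 0)
    stop("FET parameters: lengths must be positive")
  if (skeleton_arc_fraction < 0 || skeleton_arc_fraction > 1)
    stop("skeleton_arc_fraction must lie in [0, 1]")
  structure(list(oversizing_rate = oversizing_rate,
                 outer_diameter = reference_id * (1 + oversizing_rate),
                 device_thickness = device_thickness,
                 skeleton_length = skeleton_length,
                 reference_id = reference_id,
                 skeleton_arc_fraction = skeleton_arc_fraction,
                 graft_start_angle = graft_start_angle,
                 skeleton_natural_shape = "straight",
                 graft_shape = "curved"),
            class = "fet_params")
}

#' Build the sagittal-plane centerline of the idealized aorta
#'
#' A planar arc of radius `arch_radius` spanning `arch_span`, continued
#' tangent-continuously by a straight descending segment. The curve lies in
#' the sagittal plane y = 0; the local frame is (tangent, normal, binormal)
#' with the normal pointing toward the arch center (lesser curvature side) and
#' binormal +y.
#'
#' @param p `aorta_params`.
#' @param ds sample spacing along arc length, mm.
#' @return object of class `fs_centerline`: sample arrays `s`, `xyz`,
#'   `tangent`, `normal`, `binormal`, `curvature`, plus the generating
#'   parameters (frames at arbitrary s via [centerline_frame()]).
#' @export
build_centerline <- function(p, ds = 2) {
  stopifnot(inherits(p, "aorta_params"))
  span <- p$arch_span * pi / 180
  arch_len <- p$arch_radius * span
  total <- arch_len + p$desc_length
  n <- max(2L, ceiling(total / ds) + 1L)
  s <- seq(0, total, length.out = n)
  cl <- structure(list(arch_radius = p$arch_radius, arch_span_rad = span,
                       arch_len = arch_len, desc_length = p$desc_length,
                       total_len = total, s = s),
                  class = "fs_centerline")
  fr <- centerline_frame(cl, s)
  cl$xyz <- fr$xyz; cl$tangent <- fr$tangent; cl$normal <- fr$normal
  cl$binormal <- fr$binormal; cl$curvature <- fr$curvature
  cl
}

#' Evaluate centerline position and frame at arbitrary arc length
#' @param cl `fs_centerline`.
#' @param s arc-length stations, mm (0 at the ascending end).
#' @return list of matrices `xyz`, `tangent`, `normal`, `binormal` and vector
#'   `curvature` (1/mm).
#' @export
centerline_frame <- function(cl, s) {
  R <- cl$arch_radius
  a <- pmin(s, cl$arch_len) / R          # arch angle
  on_arch <- s <= cl$arch_len + 1e-12
  ds <- pmax(s - cl$arch_len, 0)         # distance along straight part
  a_end <- cl$arch_span_rad
  # arch: P = (-R cos a, 0, R sin a); tangent (sin a, 0, cos a)
  x <- ifelse(on_arch, -R * cos(a), -R * cos(a_end) + ds * sin(a_end))
  z <- ifelse(on_arch,  R * sin(a),  R * sin(a_end) + ds * cos(a_end))
  ta <- ifelse(on_arch, a, a_end)
  tangent <- cbind(sin(ta), 0, cos(ta))
  normal <- cbind(cos(ta), 0, -sin(ta))  # toward arch center (lesser curvature)
  binormal <- cbind(0, 1, 0)[rep(1, length(s)), , drop = FALSE]
  list(xyz = cbind(x, 0, z), tangent = tangent, normal = normal,
       binormal = binormal, curvature = ifelse(on_arch, 1 / R, 0))
}

#' Discrete curvature of a sampled centerline (finite differences)
#'
#' Independent check of the analytic frame; central second differences with
#' respect to arc length.
#' @param cl `fs_centerline`.
#' @return curvature estimate at interior samples, 1/mm.
#' @export
centerline_fd_curvature <- function(cl) {
  x <- cl$xyz; s <- cl$s; n <- nrow(x)
  i <- 2:(n - 1)
  h1 <- s[i] - s[i - 1]; h2 <- s[i + 1] - s[i]
  d2 <- 2 * (h1 * x[i + 1, ] - (h1 + h2) * x[i, ] + h2 * x[i - 1, ]) /
    (h1 * h2 * (h1 + h2))
  sqrt(rowSums(d2^2))
}

## ---- tube sweeping --------------------------------------------------------

#' Sweep a circular tube along a centerline
#'
#' Circular cross-sections normal to the centerline; optional wall volume mesh
#' (hexahedra) between the lumen radius and lumen radius + thickness. Half
#' model (y >= 0) by default, clipped at the sagittal plane with symmetry
#' nodes tagged. Node sets: `inlet`, `outlet`, `symmetry`, `lesser_trace`
#' (theta = 0, arch-center side), `greater_trace` (theta = pi).
#'
#' @param cl `fs_centerline` (or any object with `s` stations and frames via
#'   [centerline_frame()]).
#' @param inner_diameter lumen diameter, mm.
#' @param wall_thickness wall thickness, mm (0 for lumen-only).
#' @param n_theta circumferential divisions of the half (or full) section.
#' @param n_layers radial element layers through the wall.
#' @param half logical, half-model about the sagittal plane.
#' @param s_range optional `c(s0, s1)` sub-interval of arc length to sweep.
#' @param radius_fun optional function(s) -> lumen radius (overrides
#'   `inner_diameter`, enables tapered/deformed sweeps).
#' @param offset_fun optional function(s) -> lateral in-plane offset of the
#'   section center, mm, positive toward the greater curvature.
#' @return list with `lumen` (`fs_mesh`, quads) and `wall` (`fs_mesh`, hexes;
#'   empty elems if `wall_thickness == 0`).
#' @export
sweep_tube <- function(cl, inner_diameter, wall_thickness = 0, n_theta = 16,
                       n_layers = 2, half = TRUE, s_range = NULL,
                       radius_fun = NULL, offset_fun = NULL) {
  r0 <- inner_diameter / 2
  if (is.null(radius_fun)) radius_fun <- function(s) rep(r0, length(s))
  if (is.null(s_range)) s_range <- c(0, cl$total_len)
  if (r0 >= cl$arch_radius)
    stop("geometry error: tube radius >= arch radius (self-intersecting sweep)")
  idx <- cl$s >= s_range[1] - 1e-9 & cl$s <= s_range[2] + 1e-9
  s <- cl$s[idx]
  if (length(s) < 2) stop("s_range selects fewer than two stations")
  fr <- centerline_frame(cl, s)
  ns <- length(s)
  theta <- if (half) seq(0, pi, length.out = n_theta + 1)
           else seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  nth <- length(theta)
  rad <- radius_fun(s)
  off <- if (is.null(offset_fun)) rep(0, ns) else offset_fun(s)
  ring <- function(i, r) {
    ctr <- fr$xyz[i, ] - off[i] * fr$normal[i, ]   # +off toward greater curvature
    t(ctr + outer(fr$normal[i, ], r * cos(theta)) +
        outer(fr$binormal[i, ], r * sin(theta)))
  }
  nodes <- do.call(rbind, lapply(seq_len(ns), function(i) ring(i, rad[i])))
  nid <- function(i, j) (i - 1L) * nth + j
  jnext <- if (half) NULL else c(2:nth, 1L)
  quads <- NULL
  jj <- if (half) seq_len(nth - 1) else seq_len(nth)
  j2 <- if (half) jj + 1L else jnext[jj]
  for (i in seq_len(ns - 1)) {
    quads <- rbind(quads, cbind(nid(i, jj), nid(i + 1, jj),
                                nid(i + 1, j2), nid(i, j2)))
  }
  sym <- if (half) c(nid(seq_len(ns), 1L), nid(seq_len(ns), nth)) else integer(0)
  sets <- list(inlet = nid(1L, seq_len(nth)),
               outlet = nid(ns, seq_len(nth)),
               symmetry = sym,
               lesser_trace = nid(seq_len(ns), 1L),
               greater_trace = if (half) nid(seq_len(ns), nth)
                               else nid(seq_len(ns), nth %/% 2 + 1L))
  lumen <- fs_mesh(nodes, list(quad = quads), sets)
  lumen$s_stations <- s; lumen$n_theta <- nth; lumen$half <- half

  wall <- fs_mesh(matrix(numeric(0), 0, 3))
  if (wall_thickness > 0) {
    radii <- seq(0, wall_thickness, length.out = n_layers + 1)
    wn <- do.call(rbind, lapply(seq_len(ns), function(i)
      do.call(rbind, lapply(radii, function(dr) ring(i, rad[i] + dr)))))
    # node index: station i, layer k (1..n_layers+1), angular j
    wid <- function(i, k, j) ((i - 1L) * (n_layers + 1L) + (k - 1L)) * nth + j
    hexes <- NULL
    for (i in seq_len(ns - 1)) for (k in seq_len(n_layers)) {
      hexes <- rbind(hexes,
        cbind(wid(i, k, jj),     wid(i, k, j2),
              wid(i + 1, k, j2), wid(i + 1, k, jj),
              wid(i, k + 1, jj),     wid(i, k + 1, j2),
              wid(i + 1, k + 1, j2), wid(i + 1, k + 1, jj)))
    }
    ii <- seq_len(ns); kk <- seq_len(n_layers + 1)
    wsets <- list(
      inner_surface = as.vector(vapply(seq_len(nth), function(j) wid(ii, 1L, j),
                                       numeric(ns))),
      fixed_face = as.vector(vapply(kk, function(k) wid(ns, k, seq_len(nth)),
                                    numeric(nth))),
      symmetry = if (half)
        c(as.vector(vapply(kk, function(k) wid(ii, k, 1L), numeric(ns))),
          as.vector(vapply(kk, function(k) wid(ii, k, nth), numeric(ns))))
        else integer(0))
    wall <- fs_mesh(wn, list(hex = hexes), wsets)
    wall$s_stations <- s; wall$n_theta <- nth; wall$half <- half
  }
  list(lumen = lumen, wall = wall)
}

#' Enclosed volume of a closed triangulated surface
#'
#' Divergence-theorem sum over (possibly mixed tri/quad) faces; quads are
#' split. Returns the absolute volume in mm^3.
#' @param mesh closed `fs_mesh`.
#' @return volume, mm^3.
#' @export
enclosed_volume <- function(mesh) {
  tri <- mesh$elems$tri
  if (!is.null(mesh$elems$quad)) {
    q <- mesh$elems$quad
    tri <- rbind(tri, q[, c(1, 2, 3)], q[, c(1, 3, 4)])
  }
  tri <- orient_tris(tri)
  p1 <- mesh$nodes[tri[, 1], , drop = FALSE]
  p2 <- mesh$nodes[tri[, 2], , drop = FALSE]
  p3 <- mesh$nodes[tri[, 3], , drop = FALSE]
  abs(sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
          p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
          p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1]))) / 6
}

# Propagate a consistent orientation over a closed triangle soup (BFS across
# shared edges); required before the divergence-theorem volume sum.
orient_tris <- function(tri) {
  nf <- nrow(tri)
  ek <- function(a, b) paste(pmin(a, b), pmax(a, b))
  keys <- cbind(ek(tri[, 1], tri[, 2]), ek(tri[, 2], tri[, 3]),
                ek(tri[, 3], tri[, 1]))
  edge_faces <- split(rep(seq_len(nf), 3), as.vector(keys))
  visited <- rep(FALSE, nf)
  flip <- rep(FALSE, nf)
  dir_has <- function(f, a, b) {
    tt <- if (flip[f]) tri[f, c(1, 3, 2)] else tri[f, ]
    any((tt == a) & (c(tt[2], tt[3], tt[1]) == b))
  }
  queue <- 1L; visited[1] <- TRUE
  while (length(queue)) {
    f <- queue[1]; queue <- queue[-1]
    tt <- if (flip[f]) tri[f, c(1, 3, 2)] else tri[f, ]
    for (e in 1:3) {
      a <- tt[e]; b <- tt[c(2, 3, 1)[e]]
      for (g in edge_faces[[ek(a, b)]]) {
        if (g == f || visited[g]) next
        visited[g] <- TRUE
        # neighbour must traverse the shared edge in the opposite direction
        if (dir_has(g, a, b)) flip[g] <- TRUE
        queue <- c(queue, g)
      }
    }
  }
  out <- tri
  out[flip, ] <- tri[flip, c(1, 3, 2)]
  out
}

#' Cap the open rings of a surface mesh with triangle fans
#'
#' Boundary loops are detected as edges used by exactly one face; each loop is
#' walked and fanned from its centroid. Used before watertightness / volume
#' checks on swept or branched surfaces.
#' @param mesh `fs_mesh` surface.
#' @return capped `fs_mesh` (adds one centroid node and a `tri` fan per loop).
#' @export
cap_openings <- function(mesh) {
  ed <- surface_edges(mesh)
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  cnt <- table(key)
  open_keys <- names(cnt)[cnt == 1L]
  if (!length(open_keys)) return(mesh)
  be <- ed[match(open_keys, key), , drop = FALSE]
  # adjacency among boundary nodes
  nodes <- mesh$nodes; tris <- NULL
  remaining <- be
  while (nrow(remaining)) {
    loop <- remaining[1, ]
    remaining <- remaining[-1, , drop = FALSE]
    repeat {
      last <- loop[length(loop)]
      hit <- which(remaining[, 1] == last | remaining[, 2] == last)[1]
      if (is.na(hit)) break
      nxt <- if (remaining[hit, 1] == last) remaining[hit, 2] else remaining[hit, 1]
      remaining <- remaining[-hit, , drop = FALSE]
      if (nxt == loop[1]) break
      loop <- c(loop, nxt)
    }
    ctr <- colMeans(mesh$nodes[loop, , drop = FALSE])
    nodes <- rbind(nodes, ctr)
    cid <- nrow(nodes)
    nl <- length(loop)
    tris <- rbind(tris, cbind(loop, c(loop[-1], loop[1]), rep(cid, nl)))
  }
  elems <- mesh$elems
  elems$tri <- rbind(elems$tri, tris)
  out <- fs_mesh(nodes, elems, mesh$node_sets, mesh$elem_sets)
  out$s_stations <- mesh$s_stations; out$n_theta <- mesh$n_theta
  out$half <- mesh$half
  out
}
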