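## FET device meshes, treated-model assembly, CFD domain with arch branches,
## and swept-tube volume meshing.

#' Build the FET component meshes
#'
#' The graft (polyester arch part) follows the arch curvature and is meshed as
#' a surface shell (it is kinematically rigid in the default material model);
#' the skeleton is a straight tube of `skeleton_length` and the oversized
#' outer diameter in its natural, stress-free configuration.
#'
#' @param fp `fet_params`.
#' @param ap `aorta_params`.
#' @param n_theta circumferential divisions.
#' @param ds axial sample spacing, mm.
#' @param half half-model about the sagittal plane.
#' @return list `graft` (`fs_mesh` shell), `skeleton` (`fs_mesh` shell of the
#'   straight natural shape), `params`.
#' @export
make_fet <- function(fp, ap = aorta_params(), n_theta = 12, ds = 2.5,
                     half = TRUE) {
  stopifnot(inherits(fp, "fet_params"), inherits(ap, "aorta_params"))
  st <- treated_stations(ap, fp)
  cl <- build_centerline(ap, ds = ds)
  graft <- sweep_tube(cl, ap$inner_diameter, 0, n_theta = n_theta,
                      half = half, s_range = c(st$s_graft0, st$s_sk0))$lumen
  # natural skeleton: straight cylinder along +z, outer surface
  L <- fp$skeleton_length
  r_out <- fp$outer_diameter / 2
  ns <- max(2L, ceiling(L / ds) + 1L)
  z <- seq(0, L, length.out = ns)
  theta <- if (half) seq(0, pi, length.out = n_theta + 1)
           else seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  nth <- length(theta)
  nodes <- cbind(rep(r_out * cos(theta), times = ns),
                 rep(r_out * sin(theta), times = ns),
                 rep(z, each = nth))
  nid <- function(i, j) (i - 1L) * nth + j
  jj <- if (half) seq_len(nth - 1) else seq_len(nth)
  j2 <- if (half) jj + 1L else c(2:nth, 1L)[jj]
  quads <- NULL
  for (i in seq_len(ns - 1))
    quads <- rbind(quads, cbind(nid(i, jj), nid(i + 1, jj),
                                nid(i + 1, j2), nid(i, j2)))
  skel <- fs_mesh(nodes, list(quad = quads),
                  list(proximal_ring = nid(1L, seq_len(nth)),
                       distal_ring = nid(ns, seq_len(nth))))
  list(graft = graft, skeleton = skel, params = fp)
}

# arc-length stations of the treated assembly along the aortic centerline
treated_stations <- function(ap, fp) {
  span <- ap$arch_span * pi / 180
  arch_len <- ap$arch_radius * span
  s_graft0 <- ap$arch_radius * fp$graft_start_angle * pi / 180
  s_sk0 <- arch_len - fp$skeleton_arc_fraction * fp$skeleton_length
  s_edge <- s_sk0 + fp$skeleton_length
  total <- arch_len + ap$desc_length
  if (s_graft0 >= s_sk0)
    stop("assembly error: graft start lies distal to the skeleton landing zone")
  if (s_edge > total)
    stop("assembly error: FET longer than the available aorta")
  if (s_sk0 < 0)
    stop("assembly error: skeleton arc fraction exceeds the arch")
  list(s_graft0 = s_graft0, s_sk0 = s_sk0, s_edge = s_edge,
       arch_len = arch_len, total = total)
}

#' Assemble the treated model (native aorta + FET)
#'
#' The aorta proximal of the graft anastomosis is removed; the graft occupies
#' the arch between the anastomosis and the skeleton landing zone; the
#' skeleton (straight natural shape) is registered for the deploy stage inside
#' the native aorta, spanning the distal arch and the proximal descending
#' segment. The contact pair (skeleton outer surface vs aortic inner surface)
#' shares no nodes.
#'
#' @param ap `aorta_params`.
#' @param fp `fet_params`.
#' @param n_theta,ds,n_layers meshing controls.
#' @return object of class `fet_treated`: params, centerline, key stations
#'   (`s_graft0`, `s_sk0`, `s_edge`), component meshes, contact-pair
#'   registration, and the nominal radial gap (negative = interference).
#' @export
assemble_treated <- function(ap = aorta_params(), fp = fet_params(),
                             n_theta = 12, ds = 2.5, n_layers = 2) {
  st <- treated_stations(ap, fp)
  cl <- build_centerline(ap, ds = ds)
  # snap key stations into the sample set
  cl$s <- sort(unique(c(cl$s, st$s_graft0, st$s_sk0, st$s_edge)))
  fr <- centerline_frame(cl, cl$s)
  cl$xyz <- fr$xyz; cl$tangent <- fr$tangent; cl$normal <- fr$normal
  cl$binormal <- fr$binormal; cl$curvature <- fr$curvature
  native <- sweep_tube(cl, ap$inner_diameter, ap$wall_thickness,
                       n_theta = n_theta, n_layers = n_layers,
                       s_range = c(st$s_sk0, st$total))
  fet <- make_fet(fp, ap, n_theta = n_theta, ds = ds)
  edge_i <- which.min(abs(native$lumen$s_stations - st$s_edge))
  nth <- native$lumen$n_theta
  native$lumen$node_sets$fet_distal_edge <-
    (edge_i - 1L) * nth + seq_len(nth)
  gap <- (ap$inner_diameter - fp$outer_diameter) / 2
  structure(list(aorta = ap, fet = fp, centerline = cl,
                 s_graft0 = st$s_graft0, s_sk0 = st$s_sk0,
                 s_edge = st$s_edge, total_len = st$total,
                 aorta_wall = native$wall, aorta_lumen = native$lumen,
                 graft = fet$graft, skeleton = fet$skeleton,
                 contact_pair = list(master = "aorta_lumen",
                                     slave = "skeleton_outer"),
                 nominal_gap = gap),
            class = "fet_treated")
}

## ---- CFD domain -----------------------------------------------------------

#' Build the CFD lumen domain with arch branches and outlet extensions
#'
#' The lumen runs from the FET entrance (graft anastomosis, inlet face) to the
#' descending outlet, which is extended by `extension` mm; three supra-aortic
#' branches (equal diameter, evenly spaced on the superior/greater-curvature
#' arch, symmetric about the sagittal plane) are stitched onto the surface and
#' serve as the remaining outlets, each `extension` mm long. Optional radius /
#' offset functions deform the tube to the recoiled configuration.
#'
#' @param treated `fet_treated` (supplies parameters and key stations).
#' @param n_theta circumferential divisions (even, >= 12).
#' @param ds axial spacing, mm.
#' @param branch_diameter mm.
#' @param branch_angles arch angles of the branch ostia, degrees.
#' @param extension outlet extension length, mm.
#' @param radius_fun,offset_fun optional deformation of the main tube (see
#'   [sweep_tube()]).
#' @return `fs_mesh` half-model surface with node sets `inlet`, `wall`,
#'   `symmetry`, `outlet_desc`, `outlet_branch1..3`; attribute `outlets`
#'   lists the 4 outlet set names.
#' @export
build_cfd_domain <- function(treated, n_theta = 16, ds = 2.5,
                             branch_diameter = 10,
                             branch_angles = c(100, 115, 130),
                             extension = 50,
                             radius_fun = NULL, offset_fun = NULL) {
  ap <- treated$aorta
  cl <- build_centerline(aorta_params(ap$arch_radius,
                                      ap$desc_length + extension,
                                      ap$inner_diameter, ap$wall_thickness,
                                      ap$arch_span), ds = ds)
  tube <- sweep_tube(cl, ap$inner_diameter, 0, n_theta = n_theta,
                     s_range = c(treated$s_graft0, cl$total_len),
                     radius_fun = radius_fun, offset_fun = offset_fun)$lumen
  s <- tube$s_stations; nth <- tube$n_theta; ns <- length(s)
  nid <- function(i, j) (i - 1L) * nth + j
  k <- 4L                                  # footprint size (k x k quads)
  s_branch <- ap$arch_radius * branch_angles * pi / 180
  if (any(s_branch + branch_diameter / 2 > treated$s_sk0))
    stop("geometry error: branch placement intersects the FET body")
  i0 <- vapply(s_branch, function(sb) which.min(abs(s - sb)), integer(1))
  lo <- i0 - k %/% 2; hi <- lo + k
  if (any(lo < 2) || any(hi > ns - 1))
    stop("geometry error: branch footprint outside the meshed arch")
  if (any(utils::head(hi, -1) >= utils::tail(lo, -1)))
    stop("geometry error: branch footprints overlap; refine ds or respace")

  quads <- tube$elems$quad
  # tag quad by (i, j-row): quad row built as i-major blocks of (nth-1)
  qi <- rep(seq_len(ns - 1), each = nth - 1)
  qj <- rep(seq_len(nth - 1), times = ns - 1)
  drop <- rep(FALSE, nrow(quads))
  for (b in seq_along(i0))
    drop <- drop | (qi >= lo[b] & qi <= hi[b] - 1 & qj >= nth - k)
  quads <- quads[!drop, , drop = FALSE]

  nodes <- tube$nodes
  sets <- tube$node_sets
  names(sets)[names(sets) == "outlet"] <- "outlet_desc"
  fr <- centerline_frame(cl, s)
  rb <- branch_diameter / 2
  for (b in seq_along(i0)) {
    # ordered hole-boundary path: on-plane upstream -> around -> on-plane downstream
    path <- c(nid(lo[b], nth:(nth - k)),
              nid((lo[b] + 1):hi[b], nth - k),
              nid(hi[b], (nth - k + 1):nth))
    npth <- length(path)                    # 3k + 1
    ib <- i0[b]
    ctr0 <- fr$xyz[ib, ]
    axis <- -fr$normal[ib, ]                # outward radial (superior)
    e1 <- fr$tangent[ib, ]; e2 <- c(0, 1, 0)
    gam <- pi - pi * (seq_len(npth) - 1) / (npth - 1)
    m_rings <- max(4L, ceiling(extension / (2 * ds)))
    prev <- path
    for (m in seq_len(m_rings)) {
      d <- extension * m / m_rings
      w <- min(1, d / (0.4 * extension))    # blend footprint -> circle
      base <- nodes[path, , drop = FALSE]
      proj <- base + outer(rep(d, npth), axis)
      circ <- t(ctr0 + d * axis + rb * (outer(e1, cos(gam)) + outer(e2, sin(gam))))
      ring <- (1 - w) * proj + w * circ
      ring[c(1, npth), 2] <- 0              # keep rim nodes on the sagittal plane
      idx <- nrow(nodes) + seq_len(npth)
      nodes <- rbind(nodes, ring)
      quads <- rbind(quads, cbind(prev[-npth], idx[-npth], idx[-1], prev[-1]))
      sets$symmetry <- c(sets$symmetry, idx[c(1, npth)])
      prev <- idx
    }
    sets[[paste0("outlet_branch", b)]] <- prev
  }
  dom <- fs_mesh(nodes, list(quad = quads), sets)
  dom$s_stations <- s; dom$n_theta <- nth; dom$half <- TRUE
  attr(dom, "outlets") <- c("outlet_desc", paste0("outlet_branch",
                                                  seq_along(i0)))
  dom
}

## ---- volume meshing -------------------------------------------------------

#' Tetra/hex volume mesh of a swept tube domain
#'
#' Structured polar discretization of the lumen interior of a tube swept along
#' an aortic centerline: hexahedral rings with a tetrahedral core (no boundary
#' layers; the coarse preset is boundary-layer-free by construction). Named
#' sets (`inlet`, `outlet`, `wall`, `symmetry`) are inherited.
#'
#' @param cl `fs_centerline`.
#' @param radius lumen radius, mm (constant).
#' @param target_h target cell size, mm.
#' @param half half-model.
#' @param s_range optional arc-length interval.
#' @return `fs_mesh` with `hex` and `tet` blocks.
#' @export
volume_mesh <- function(cl, radius, target_h, half = TRUE, s_range = NULL) {
  if (target_h <= 0) stop("target_h must be positive")
  if (is.null(s_range)) s_range <- c(0, cl$total_len)
  L <- diff(s_range)
  ns <- max(3L, ceiling(L / target_h) + 1L)
  s <- seq(s_range[1], s_range[2], length.out = ns)
  n_r <- max(2L, round(radius / target_h))
  n_th_full <- max(8L, 2L * round(pi * radius / target_h))
  n_th <- if (half) n_th_full %/% 2L else n_th_full
  theta <- if (half) seq(0, pi, length.out = n_th + 1)
           else seq(0, 2 * pi, length.out = n_th + 1)[-(n_th + 1)]
  nth <- length(theta)
  fr <- centerline_frame(cl, s)
  radii <- radius * seq_len(n_r) / n_r
  # per station: 1 center node + n_r rings of nth nodes
  per <- 1L + n_r * nth
  nodes <- matrix(0, ns * per, 3)
  for (i in seq_len(ns)) {
    base <- (i - 1L) * per
    nodes[base + 1L, ] <- fr$xyz[i, ]
    for (kk in seq_len(n_r)) {
      idx <- base + 1L + (kk - 1L) * nth + seq_len(nth)
      nodes[idx, ] <- t(fr$xyz[i, ] + outer(fr$normal[i, ],
                                            radii[kk] * cos(theta)) +
                          outer(fr$binormal[i, ], radii[kk] * sin(theta)))
    }
  }
  cid <- function(i) (i - 1L) * per + 1L
  rid <- function(i, kk, j) (i - 1L) * per + 1L + (kk - 1L) * nth + j
  jj <- if (half) seq_len(nth - 1) else seq_len(nth)
  j2 <- if (half) jj + 1L else c(2:nth, 1L)[jj]
  hexes <- NULL; tets <- NULL
  for (i in seq_len(ns - 1)) {
    # core wedges -> 3 tets each
    a <- rep(cid(i), length(jj)); b <- rid(i, 1L, jj); c_ <- rid(i, 1L, j2)
    d <- rep(cid(i + 1), length(jj)); e <- rid(i + 1, 1L, jj)
    f <- rid(i + 1, 1L, j2)
    tets <- rbind(tets, cbind(a, b, c_, d), cbind(b, c_, d, e),
                  cbind(c_, d, e, f))
    if (n_r > 1) for (kk in seq_len(n_r - 1)) {
      hexes <- rbind(hexes,
        cbind(rid(i, kk, j2), rid(i, kk, jj),
              rid(i, kk + 1L, jj), rid(i, kk + 1L, j2),
              rid(i + 1, kk, j2), rid(i + 1, kk, jj),
              rid(i + 1, kk + 1L, jj), rid(i + 1, kk + 1L, j2)))
    }
  }
  # orient tets positively
  v <- tet_volume(nodes, tets)
  neg <- v < 0
  if (any(neg)) tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
  sets <- list(
    inlet = c(cid(1L), rid(1L, seq_len(n_r), rep(seq_len(nth), each = n_r))),
    outlet = c(cid(ns), rid(ns, seq_len(n_r), rep(seq_len(nth), each = n_r))),
    wall = as.vector(vapply(seq_len(ns), function(i) rid(i, n_r, seq_len(nth)),
                            numeric(nth))),
    symmetry = if (half)
      unique(c(vapply(seq_len(ns), cid, numeric(1)),
               as.vector(vapply(seq_len(ns), function(i)
                 c(rid(i, seq_len(n_r), 1L), rid(i, seq_len(n_r), nth)),
                 numeric(2 * n_r))))) else integer(0))
  m <- fs_mesh(nodes, list(hex = if (is.null(hexes))
                             matrix(integer(0), 0, 8) else hexes,
                           tet = tets), sets)
  m$s_stations <- s
  m
}
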