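## Post-processing of structural and flow results into the study's
## figures-of-merit: OSI, WSSD, path profiles, threshold-exceedance length,
## notch geometry, and the oversizing-sweep summary table.

#' Oscillatory shear index
#'
#' `OSI = 0.5 (1 - |integral tau dt| / integral |tau| dt)` over one cycle,
#' per station; 0 for unidirectional shear, 0.5 for perfectly reversing
#' shear. Accepts a matrix of signed scalars (frames x stations, shear along
#' the wall tangent) or a 3-D array (frames x stations x components).
#'
#' @param tau shear series (frames x stations [x components]), Pa.
#' @param t frame times, s (default: uniform over the cycle).
#' @return OSI per station, in `[0, 0.5]`; all-zero series give 0 (logged
#'   via `message`).
#' @export
osi <- function(tau, t = NULL) {
  if (is.matrix(tau)) tau <- array(tau, c(nrow(tau), ncol(tau), 1))
  nf <- dim(tau)[1]
  if (nf < 2) stop("need at least two time samples over the cycle")
  if (is.null(t)) t <- seq_len(nf)
  w <- numeric(nf)                 # trapezoid weights
  dtv <- diff(t)
  w[1] <- dtv[1] / 2; w[nf] <- dtv[nf - 1] / 2
  if (nf > 2) w[2:(nf - 1)] <- (dtv[-1] + dtv[-(nf - 1)]) / 2
  mag <- sqrt(apply(tau^2, c(1, 2), sum))
  int_mag <- colSums(w * mag)
  int_vec2 <- 0
  for (k in seq_len(dim(tau)[3]))
    int_vec2 <- int_vec2 + colSums(w * tau[, , k])^2
  int_vec <- sqrt(int_vec2)
  out <- ifelse(int_mag > 0, 0.5 * (1 - int_vec / int_mag), 0)
  if (any(int_mag == 0))
    message("osi: ", sum(int_mag == 0), " station(s) with all-zero shear; OSI set to 0")
  pmin(pmax(out, 0), 0.5)
}

#' Surface divergence of a wall vector field (triangulated surface)
#'
#' P1 finite-element tangent-plane divergence: per-triangle divergence of
#' the (in-plane) field, area-averaged onto nodes. Quads are split into
#' triangles. Vanishes for spatially uniform and for rigid-rotation fields;
#' equals `2a` for the planar field `a (x, y)`.
#'
#' @param mesh `fs_mesh` surface (tri/quad), coordinates mm or m.
#' @param tau n x 3 vector field on the nodes.
#' @return per-node divergence (field units per coordinate unit); isolated
#'   nodes (no incident face) are `NA` with a warning.
#' @export
wssd <- function(mesh, tau) {
  tri <- mesh$elems$tri
  if (!is.null(mesh$elems$quad)) {
    q <- mesh$elems$quad
    tri <- rbind(tri, q[, c(1, 2, 3)], q[, c(1, 3, 4)])
  }
  if (is.null(tri) || !nrow(tri)) stop("mesh has no surface elements")
  nn <- nrow(mesh$nodes)
  acc <- numeric(nn); wt <- numeric(nn)
  for (e in seq_len(nrow(tri))) {
    en <- tri[e, ]
    p <- mesh$nodes[en, , drop = FALSE]
    e1 <- p[2, ] - p[1, ]; e2 <- p[3, ] - p[1, ]
    nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
             e1[3] * e2[1] - e1[1] * e2[3],
             e1[1] * e2[2] - e1[2] * e2[1])
    a2 <- sqrt(sum(nrm^2))            # 2 * area
    if (a2 < 1e-300) next
    nrm <- nrm / a2
    # in-plane gradients of P1 shape functions: grad phi_k = (n x opposite edge)/2A
    g1 <- c(nrm[2] * (p[3, 3] - p[2, 3]) - nrm[3] * (p[3, 2] - p[2, 2]),
            nrm[3] * (p[3, 1] - p[2, 1]) - nrm[1] * (p[3, 3] - p[2, 3]),
            nrm[1] * (p[3, 2] - p[2, 2]) - nrm[2] * (p[3, 1] - p[2, 1])) / a2
    g2 <- c(nrm[2] * (p[1, 3] - p[3, 3]) - nrm[3] * (p[1, 2] - p[3, 2]),
            nrm[3] * (p[1, 1] - p[3, 1]) - nrm[1] * (p[1, 3] - p[3, 3]),
            nrm[1] * (p[1, 2] - p[3, 2]) - nrm[2] * (p[1, 1] - p[3, 1])) / a2
    g3 <- -(g1 + g2)
    div_e <- sum(g1 * tau[en[1], ]) + sum(g2 * tau[en[2], ]) +
      sum(g3 * tau[en[3], ])
    acc[en] <- acc[en] + div_e * a2 / 2
    wt[en] <- wt[en] + a2 / 2
  }
  out <- ifelse(wt > 0, acc / wt, NA_real_)
  if (anyNA(out))
    warning(sum(is.na(out)), " isolated node(s) excluded from WSSD")
  out
}

#' Streamwise divergence of the wall shear along a path
#' @param s arc-length stations (mm or m).
#' @param tau signed shear at the stations.
#' @return d tau / d s (central differences, one-sided at the ends).
#' @export
wssd_path <- function(s, tau) {
  n <- length(s)
  d <- numeric(n)
  d[2:(n - 1)] <- (tau[3:n] - tau[1:(n - 2)]) / (s[3:n] - s[1:(n - 2)])
  d[1] <- (tau[2] - tau[1]) / (s[2] - s[1])
  d[n] <- (tau[n] - tau[n - 1]) / (s[n] - s[n - 1])
  d
}

#' Extract a curvature path from a swept wall surface or a channel
#'
#' For a swept `fs_mesh` with tagged sagittal traces, returns the requested
#' trace (intersection of the wall with the sagittal plane) parameterized by
#' arc length from the FET distal edge, oriented distally. For a
#' `fet_channel`, returns the corresponding wall polyline.
#'
#' @param x `fs_mesh` (with node sets `lesser_trace`/`greater_trace` and
#'   `fet_distal_edge`) or `fet_channel`.
#' @param side `"greater"` or `"lesser"`.
#' @return data.frame `s` (mm, 0 at the FET distal edge, increasing
#'   distally; negative = proximal of the edge), `x`, `y`, `z` (mm), plus
#'   node ids for meshes.
#' @export
extract_path <- function(x, side = c("greater", "lesser")) {
  side <- match.arg(side)
  if (inherits(x, "fet_channel")) {
    pts <- if (side == "greater") x$upper else x$lower
    s_rel <- x$s - x$s0 - x$s_edge_rel
    return(data.frame(s = s_rel, x = pts[, 1], y = 0, z = pts[, 2]))
  }
  stopifnot(inherits(x, "fs_mesh"))
  set_name <- paste0(side, "_trace")
  ids <- x$node_sets[[set_name]]
  if (is.null(ids) || !length(ids))
    stop("sampling error: mesh has no ", set_name, " node set")
  edge <- x$node_sets$fet_distal_edge
  if (is.null(edge)) stop("sampling error: mesh has no FET distal edge ring")
  pts <- x$nodes[ids, , drop = FALSE]
  seg <- sqrt(rowSums(diff(pts)^2))
  s_raw <- c(0, cumsum(seg))
  # origin: the trace node that lies on the edge ring
  hit <- which(ids %in% edge)
  if (!length(hit)) stop("sampling error: trace does not meet the edge ring")
  data.frame(s = s_raw - s_raw[hit[1]], x = pts[, 1], y = pts[, 2],
             z = pts[, 3], node = ids)
}

#' Sample a field along a path at regular stations
#'
#' @param path data.frame with `s` (as from [extract_path()]).
#' @param values field values at the path points.
#' @param ds station spacing (default 1 mm).
#' @param s_range optional `c(min, max)` station window.
#' @return object of class `path_profile`: data.frame `s`, `value` with
#'   attributes `s_max_location` (argmax), `value_max`.
#' @export
profile_path <- function(path, values, ds = 1, s_range = NULL) {
  if (length(values) != nrow(path))
    stop("field length does not match path")
  if (is.null(s_range)) s_range <- range(path$s)
  s_out <- seq(s_range[1], s_range[2], by = ds)
  clip <- s_out < min(path$s) | s_out > max(path$s)
  if (any(clip))
    warning("profile: ", sum(clip), " station(s) clipped to field support")
  v <- approx(path$s, values, xout = s_out, rule = 2)$y
  out <- data.frame(s = s_out, value = v)
  class(out) <- c("path_profile", "data.frame")
  attr(out, "s_max_location") <- s_out[which.max(v)]
  attr(out, "value_max") <- max(v)
  out
}

#' Path length where a profile exceeds a threshold
#'
#' Total arc length of the sub-paths with `value > threshold`; crossings are
#' located by linear interpolation, and samples exactly at the threshold
#' count as not exceeding.
#'
#' @param prof `path_profile` (or data.frame `s`, `value`).
#' @param threshold threshold value (default 1.7, the reference wall shear
#'   of the untreated descending aorta, Pa).
#' @return exceedance length in the units of `s`.
#' @export
high_wss_length <- function(prof, threshold = 1.7) {
  s <- prof$s; v <- prof$value
  n <- length(s)
  L <- 0
  for (i in seq_len(n - 1)) {
    a <- v[i] - threshold; b <- v[i + 1] - threshold
    h <- s[i + 1] - s[i]
    if (a > 0 && b > 0) L <- L + h
    else if (a > 0 && b <= 0) L <- L + h * a / (a - b)
    else if (a <= 0 && b > 0) L <- L + h * b / (b - a)
  }
  L
}

#' Notch pocket area on the lesser curvature
#'
#' Planar (sagittal) area of the pocket between the device's outer wall and
#' the native wall, `integral max(0, y_device - y_native) ds`. Generic form
#' for constructed geometries plus a method for the recoiled channel;
#' optionally corroborated by a flow-stagnation check (cycle-mean velocity
#' magnitude inside the pocket vs the core).
#'
#' @param x `fet_channel`, or a numeric vector of stations `s` (with
#'   `y_device`, `y_native` supplied).
#' @param y_device,y_native lateral wall positions for the generic form.
#' @param flow optional `flow_field` (planar) for the stagnation check.
#' @return list `area` (mm^2), `stagnant` (logical or NA), `velocity_ratio`
#'   (pocket / core mean speed, NA without `flow`).
#' @export
notch_measure <- function(x, y_device = NULL, y_native = NULL, flow = NULL) {
  if (inherits(x, "fet_channel")) {
    area <- x$notch$area_mm2
  } else {
    s <- x
    dep <- pmax(0, y_device - y_native)
    area <- sum((utils::head(dep, -1) + utils::tail(dep, -1)) / 2 * diff(s))
  }
  vr <- NA_real_; stag <- NA
  if (!is.null(flow) && inherits(x, "fet_channel") &&
      !is.null(x$notch$polygon)) {
    # recirculation region: columns just distal of the edge step, near the
    # lesser (lower) wall where the widened channel detaches; cycle-mean
    # speed against the core
    spd <- if (!is.null(flow$speed_mean)) flow$speed_mean
           else sqrt(flow$u^2 + flow$v^2)
    n1 <- nrow(spd); n2 <- ncol(spd)
    i_edge <- which.min(abs(flow$s_mm - flow$s_edge_rel))
    ip <- min(n1, i_edge + 1):min(n1, i_edge + 6)
    pocket_spd <- mean(spd[ip, 2:max(3, floor(n2 / 5))])
    core_spd <- mean(spd[ip, floor(n2 / 3):ceiling(2 * n2 / 3)])
    vr <- pocket_spd / core_spd
    stag <- vr < 0.5
  }
  list(area = area, stagnant = stag, velocity_ratio = vr)
}

#' Per-station wall metrics over the converged cycle
#'
#' TAWSS, peak-systolic WSS magnitude, OSI and streamwise WSSD on a wall of
#' a planar flow solution (frames restricted to the last cycle).
#'
#' @param sol result of [solve_transient()] (channel mode).
#' @param side `"greater"` (upper) or `"lesser"` (lower).
#' @return data.frame `s_mm` (from the stented entrance), `s_edge_mm`
#'   (from the device edge), `tawss`, `wss_peak`, `osi`, `wssd` columns.
#' @export
wall_metrics <- function(sol, side = c("greater", "lesser")) {
  side <- match.arg(side)
  f <- sol$field
  tau <- if (side == "greater") f$tau_upper else f$tau_lower
  Tc <- sol$waveform$T
  t_last <- f$t_store > max(f$t_store) - Tc + 1e-9
  tau_c <- tau[t_last, , drop = FALSE]
  tt <- f$t_store[t_last]
  o <- osi(tau_c, tt)
  tawss <- colMeans(abs(tau_c))
  pk <- tau[sol$peak_frame, ]
  data.frame(s_mm = f$s_mm, s_edge_mm = f$s_mm - f$s_edge_rel,
             tawss = tawss, wss_peak = abs(pk), osi = o,
             wssd = wssd_path(f$s_mm * 1e-3, pk))
}

#' Summary table of the oversizing sweep
#'
#' One row per rate with the figures-of-merit; monotone-trend flags are
#' computed by Spearman rank correlation against the rate.
#'
#' @param results named list (by rate) of lists with elements `sigma_max_Pa`,
#'   `phi_deg`, `wss_max_Pa`, `high_wss_mm`, `notch_mm2` (missing rates are
#'   tolerated with a warning).
#' @return data.frame with attribute `trends` (named vector of Spearman
#'   rho) and class `sweep_summary`.
#' @export
summarize_sweep <- function(results) {
  rates <- as.numeric(names(results))
  cols <- c("sigma_max_Pa", "phi_deg", "wss_max_Pa", "high_wss_mm",
            "notch_mm2")
  tab <- data.frame(rate_pct = rates * 100)
  for (cc in cols)
    tab[[cc]] <- vapply(results, function(r) r[[cc]] %||% NA_real_,
                        numeric(1))
  if (anyNA(tab[cols]))
    warning("sweep summary: missing figures for some rates")
  trends <- vapply(cols, function(cc) {
    v <- tab[[cc]]
    if (all(is.na(v)) || length(unique(v[!is.na(v)])) < 2) return(NA_real_)
    stats::cor(tab$rate_pct, v, method = "spearman", use = "complete.obs")
  }, numeric(1))
  attr(tab, "trends") <- trends
  class(tab) <- c("sweep_summary", "data.frame")
  tab
}
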