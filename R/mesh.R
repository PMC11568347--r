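#' @importFrom stats approx integrate optimize setNames spline uniroot
#' @importFrom utils modifyList write.csv read.csv
NULL

#' Surface / volume mesh container
#'
#' Lightweight container used by every stage of the pipeline. Coordinates are
#' millimetres. Element blocks are stored by type (`tri`, `quad`, `tet`,
#' `hex`), 1-based node indices, VTK corner ordering. Named node sets and
#' element sets carry the boundary tags (inlet, outlets, wall, symmetry plane,
#' FET distal edge ring, curvature traces) downstream.
#'
#' @param nodes numeric matrix, n x 3, node coordinates in mm.
#' @param elems named list of integer matrices (one row per element).
#' @param node_sets named list of integer vectors (node indices).
#' @param elem_sets named list of lists `list(type=, ids=)`.
#' @return object of class `fs_mesh`.
#' @export
fs_mesh <- function(nodes, elems = list(), node_sets = list(), elem_sets = list()) {
  stopifnot(is.matrix(nodes), ncol(nodes) == 3)
  ok <- c("tri", "quad", "tet", "hex")
  if (length(elems) && !all(names(elems) %in% ok))
    stop("unknown element type(s): ", paste(setdiff(names(elems), ok), collapse = ", "))
  for (nm in names(elems)) {
    el <- elems[[nm]]
    if (length(el) && (min(el) < 1 || max(el) > nrow(nodes)))
      stop("element connectivity out of range for block '", nm, "'")
  }
  structure(list(nodes = nodes, elems = elems, node_sets = node_sets,
                 elem_sets = elem_sets), class = "fs_mesh")
}

#' @export
print.fs_mesh <- function(x, ...) {
  cnt <- vapply(x$elems, nrow, integer(1))
  cat("<fs_mesh> ", nrow(x$nodes), " nodes; ",
      paste(sprintf("%s:%d", names(cnt), cnt), collapse = ", "), "\n", sep = "")
  if (length(x$node_sets))
    cat("  node sets: ", paste(names(x$node_sets), collapse = ", "), "\n", sep = "")
  invisible(x)
}

n_elems <- function(mesh, type = NULL) {
  if (is.null(type)) sum(vapply(mesh$elems, nrow, integer(1)))
  else if (is.null(mesh$elems[[type]])) 0L else nrow(mesh$elems[[type]])
}

## ---- topology -------------------------------------------------------------

surface_edges <- function(mesh) {
  ed <- NULL
  if (!is.null(mesh$elems$tri)) {
    t <- mesh$elems$tri
    ed <- rbind(ed, cbind(t[, 1], t[, 2]), cbind(t[, 2], t[, 3]), cbind(t[, 3], t[, 1]))
  }
  if (!is.null(mesh$elems$quad)) {
    q <- mesh$elems$quad
    ed <- rbind(ed, cbind(q[, 1], q[, 2]), cbind(q[, 2], q[, 3]),
                cbind(q[, 3], q[, 4]), cbind(q[, 4], q[, 1]))
  }
  ed
}

#' Euler characteristic of a surface mesh
#'
#' V - E + F over the tri/quad blocks; a closed orientable surface of genus 0
#' (a watertight capped vessel) has characteristic 2.
#' @param mesh `fs_mesh` with surface elements.
#' @return integer Euler characteristic.
#' @export
euler_characteristic <- function(mesh) {
  ed <- surface_edges(mesh)
  if (is.null(ed)) stop("mesh has no surface elements")
  used <- sort(unique(as.vector(ed)))
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  length(used) - length(unique(key)) + n_elems(mesh, "tri") + n_elems(mesh, "quad")
}

#' Check that a surface mesh is watertight
#'
#' Every edge must be shared by exactly two faces.
#' @param mesh `fs_mesh`.
#' @return logical.
#' @export
is_watertight <- function(mesh) {
  ed <- surface_edges(mesh)
  if (is.null(ed)) return(FALSE)
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  all(table(key) == 2L)
}

## ---- quality --------------------------------------------------------------

tet_volume <- function(nodes, tet) {
  a <- nodes[tet[, 2], , drop = FALSE] - nodes[tet[, 1], , drop = FALSE]
  b <- nodes[tet[, 3], , drop = FALSE] - nodes[tet[, 1], , drop = FALSE]
  c_ <- nodes[tet[, 4], , drop = FALSE] - nodes[tet[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
   a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
   a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

# corner Jacobians of a trilinear hex (VTK ordering), normalized by edge lengths
hex_scaled_jacobian <- function(nodes, hex) {
  # corner k: edges to its three neighbours in the VTK hex graph
  nb <- list(c(2, 4, 5), c(3, 1, 6), c(4, 2, 7), c(1, 3, 8),
             c(8, 6, 1), c(5, 7, 2), c(6, 8, 3), c(7, 5, 4))
  sj <- rep(Inf, nrow(hex))
  for (k in 1:8) {
    p0 <- nodes[hex[, k], , drop = FALSE]
    e1 <- nodes[hex[, nb[[k]][1]], , drop = FALSE] - p0
    e2 <- nodes[hex[, nb[[k]][2]], , drop = FALSE] - p0
    e3 <- nodes[hex[, nb[[k]][3]], , drop = FALSE] - p0
    det3 <- e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
            e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
            e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])
    nrm <- sqrt(rowSums(e1^2)) * sqrt(rowSums(e2^2)) * sqrt(rowSums(e3^2))
    s <- ifelse(k %in% c(1, 3, 6, 8), 1, 1) # orientation uniform in VTK ordering
    sj <- pmin(sj, s * det3 / nrm)
  }
  sj
}

#' Minimum scaled Jacobian over the volume elements
#' @param mesh `fs_mesh` with `tet` and/or `hex` blocks.
#' @return numeric scalar (positive for a valid mesh).
#' @export
min_scaled_jacobian <- function(mesh) {
  vals <- numeric(0)
  if (!is.null(mesh$elems$tet) && nrow(mesh$elems$tet)) {
    v <- tet_volume(mesh$nodes, mesh$elems$tet)
    ed <- mesh$nodes[mesh$elems$tet[, 2], ] - mesh$nodes[mesh$elems$tet[, 1], ]
    h <- sqrt(rowSums(ed^2))
    vals <- c(vals, v / h^3)  # sign carries validity; scale is nominal
  }
  if (!is.null(mesh$elems$hex) && nrow(mesh$elems$hex))
    vals <- c(vals, hex_scaled_jacobian(mesh$nodes, mesh$elems$hex))
  if (!length(vals)) stop("mesh has no volume elements")
  min(vals)
}

## ---- transforms -----------------------------------------------------------

#' Mirror a half-model about the sagittal plane (y = 0)
#'
#' Nodes on the plane (|y| < tol) are shared; faces of the mirrored copy are
#' flipped to keep a consistent outward orientation.
#' @param mesh half-model `fs_mesh`.
#' @param tol on-plane tolerance in mm.
#' @return full-model `fs_mesh`.
#' @export
mirror_sagittal <- function(mesh, tol = 1e-8) {
  on_pl <- abs(mesh$nodes[, 2]) < tol
  n <- nrow(mesh$nodes)
  map <- integer(n)                       # index of mirrored image of node i
  map[on_pl] <- which(on_pl)
  new_idx <- n + seq_len(sum(!on_pl))
  map[!on_pl] <- new_idx
  mnodes <- mesh$nodes[!on_pl, , drop = FALSE]
  mnodes[, 2] <- -mnodes[, 2]
  nodes <- rbind(mesh$nodes, mnodes)
  elems <- mesh$elems
  flip <- function(el) el[, rev(seq_len(ncol(el))), drop = FALSE]
  for (nm in intersect(names(elems), c("tri", "quad"))) {
    el <- elems[[nm]]
    el2 <- matrix(map[el], nrow = nrow(el))
    elems[[nm]] <- rbind(el, flip(el2))
  }
  sets <- lapply(mesh$node_sets, function(s) unique(c(s, map[s])))
  fs_mesh(nodes, elems, sets)
}

## ---- IO -------------------------------------------------------------------

#' Write a surface mesh as ASCII STL
#' @param mesh `fs_mesh` with tri (quads are split).
#' @param path output file.
#' @export
write_stl <- function(mesh, path) {
  tri <- mesh$elems$tri
  if (!is.null(mesh$elems$quad)) {
    q <- mesh$elems$quad
    tri <- rbind(tri, q[, c(1, 2, 3)], q[, c(1, 3, 4)])
  }
  if (is.null(tri) || !nrow(tri)) stop("no surface elements to write")
  p1 <- mesh$nodes[tri[, 1], , drop = FALSE]
  p2 <- mesh$nodes[tri[, 2], , drop = FALSE]
  p3 <- mesh$nodes[tri[, 3], , drop = FALSE]
  nrm <- cross3(p2 - p1, p3 - p1)
  len <- pmax(sqrt(rowSums(nrm^2)), 1e-300)
  nrm <- nrm / len
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid fetsim", con)
  body <- sprintf(
    "facet normal %g %g %g\n outer loop\n  vertex %g %g %g\n  vertex %g %g %g\n  vertex %g %g %g\n endloop\nendfacet",
    nrm[, 1], nrm[, 2], nrm[, 3], p1[, 1], p1[, 2], p1[, 3],
    p2[, 1], p2[, 2], p2[, 3], p3[, 1], p3[, 2], p3[, 3])
  writeLines(body, con)
  writeLines("endsolid fetsim", con)
  invisible(path)
}

vtk_type_code <- c(tri = 5L, quad = 9L, tet = 10L, hex = 12L)

#' Write a mesh (with optional point data) as ASCII VTU
#' @param mesh `fs_mesh`.
#' @param path output file.
#' @param point_data named list of numeric vectors/matrices (per node).
#' @export
write_vtu <- function(mesh, path, point_data = list()) {
  nn <- nrow(mesh$nodes)
  conn <- integer(0); offs <- integer(0); types <- integer(0)
  for (nm in names(mesh$elems)) {
    el <- mesh$elems[[nm]]
    if (!nrow(el)) next
    conn <- c(conn, as.vector(t(el)) - 1L)
    prev <- if (length(offs)) offs[length(offs)] else 0L
    offs <- c(offs, prev + cumsum(rep(ncol(el), nrow(el))))
    types <- c(types, rep(vtk_type_code[[nm]], nrow(el)))
  }
  ne <- length(types)
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid><Piece NumberOfPoints="', nn, '" NumberOfCells="', ne, '">')
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(apply(mesh$nodes, 1, paste, collapse = " "), con)
  w('</DataArray></Points>')
  if (length(point_data)) {
    w('<PointData>')
    for (nm in names(point_data)) {
      d <- point_data[[nm]]
      nc <- if (is.matrix(d)) ncol(d) else 1L
      w('<DataArray type="Float64" Name="', nm, '" NumberOfComponents="', nc,
        '" format="ascii">')
      if (is.matrix(d)) writeLines(apply(d, 1, paste, collapse = " "), con)
      else writeLines(as.character(d), con)
      w('</DataArray>')
    }
    w('</PointData>')
  }
  w('<Cells>')
  w('<DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(paste(conn, collapse = " "), con)
  w('</DataArray><DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(paste(offs, collapse = " "), con)
  w('</DataArray><DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(paste(types, collapse = " "), con)
  w('</DataArray></Cells></Piece></UnstructuredGrid></VTKFile>')
  invisible(path)
}

cross3 <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, 1)
  if (is.null(dim(b))) b <- matrix(b, 1)
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}
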