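# Tetrahedral mesh container and geometry helpers.

#' Construct a tetrahedral mesh object
#'
#' @param nodes M x 3 matrix of node coordinates (mm).
#' @param tets ne x 4 integer matrix of 1-based node indices. Tets are
#'   reoriented to positive signed volume on construction.
#' @return An object of class `gm_mesh` with `nodes`, `tets`,
#'   `boundary_nodes` (indices of nodes on the outer surface).
#' @export
gm_mesh <- function(nodes, tets) {
  stopifnot(is.matrix(nodes), ncol(nodes) == 3L,
            is.matrix(tets), ncol(tets) == 4L,
            min(tets) >= 1L, max(tets) <= nrow(nodes))
  tets <- matrix(as.integer(tets), ncol = 4L)
  v <- .signed_volumes(nodes, tets)
  flip <- v < 0
  if (any(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  v <- abs(v)
  if (any(v == 0)) stop("degenerate tetrahedron (zero volume) at cell ",
                        which(v == 0)[1])
  m <- structure(list(nodes = nodes, tets = tets), class = "gm_mesh")
  m$boundary_nodes <- .boundary_nodes(tets)
  m
}

.signed_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  c_ <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
     b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
     b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

# Boundary nodes: nodes of faces that appear in exactly one tet.
.boundary_nodes <- function(tets) {
  faces <- rbind(tets[, c(1, 2, 3)], tets[, c(1, 2, 4)],
                 tets[, c(1, 3, 4)], tets[, c(2, 3, 4)])
  key <- apply(faces, 1, function(f) paste(sort(f), collapse = "-"))
  tab <- table(key)
  bkey <- names(tab)[tab == 1L]
  sort(unique(as.integer(unlist(strsplit(bkey, "-", fixed = TRUE)))))
}

#' Cell volumes, barycentres and quality of a mesh
#'
#' `cell_volumes` returns tet volumes (mm^3); `cell_barycentres` the ne x 3
#' barycentre coordinates; `mesh_quality` per-cell aspect ratios (longest
#' edge / (2 sqrt(6) * inradius), the common normalized tet aspect ratio that
#' equals 1 for the regular tetrahedron) and edge statistics.
#'
#' @param mesh A `gm_mesh` object.
#' @return See details.
#' @export
cell_volumes <- function(mesh) abs(.signed_volumes(mesh$nodes, mesh$tets))

#' @rdname cell_volumes
#' @export
cell_barycentres <- function(mesh) {
  (mesh$nodes[mesh$tets[, 1], ] + mesh$nodes[mesh$tets[, 2], ] +
     mesh$nodes[mesh$tets[, 3], ] + mesh$nodes[mesh$tets[, 4], ]) / 4
}

.edge_pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))

.cell_edge_lengths <- function(mesh) {
  out <- matrix(0, nrow(mesh$tets), 6)
  for (k in 1:6) {
    d <- mesh$nodes[mesh$tets[, .edge_pairs[k, 1]], , drop = FALSE] -
      mesh$nodes[mesh$tets[, .edge_pairs[k, 2]], , drop = FALSE]
    out[, k] <- sqrt(rowSums(d^2))
  }
  out
}

#' @rdname cell_volumes
#' @export
mesh_quality <- function(mesh) {
  el <- .cell_edge_lengths(mesh)
  vol <- cell_volumes(mesh)
  # total face area per tet
  tri_area <- function(i, j, k) {
    a <- mesh$nodes[mesh$tets[, i], , drop = FALSE]
    b <- mesh$nodes[mesh$tets[, j], , drop = FALSE] - a
    c_ <- mesh$nodes[mesh$tets[, k], , drop = FALSE] - a
    cr <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
                b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
                b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
    0.5 * sqrt(rowSums(cr^2))
  }
  area <- tri_area(1, 2, 3) + tri_area(1, 2, 4) + tri_area(1, 3, 4) +
    tri_area(2, 3, 4)
  inradius <- 3 * vol / area
  aspect <- apply(el, 1, max) / (2 * sqrt(6) * inradius)
  list(aspect_ratio = aspect,
       max_edge = apply(el, 1, max),
       min_edge = apply(el, 1, min),
       volume = vol)
}

#' P1 interpolation of a nodal field at arbitrary points
#'
#' Locates each point in the mesh by brute-force barycentric test and
#' interpolates the piecewise-linear field there. Points outside every cell
#' get `NA`.
#'
#' @param mesh A `gm_mesh` object.
#' @param field Nodal values (length = number of nodes).
#' @param points n x 3 matrix of query points.
#' @param tol Barycentric tolerance for point-in-tet tests.
#' @return Numeric vector of interpolated values (NA outside the mesh).
#' @export
interpolate_p1 <- function(mesh, field, points, tol = 1e-9) {
  stopifnot(length(field) == nrow(mesh$nodes))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  out <- rep(NA_real_, nrow(points))
  a <- mesh$nodes[mesh$tets[, 1], , drop = FALSE]
  # columns of the inverse affine map, precomputed per tet
  B1 <- mesh$nodes[mesh$tets[, 2], , drop = FALSE] - a
  B2 <- mesh$nodes[mesh$tets[, 3], , drop = FALSE] - a
  B3 <- mesh$nodes[mesh$tets[, 4], , drop = FALSE] - a
  det3 <- function(x, y, z)
    x[, 1] * (y[, 2] * z[, 3] - y[, 3] * z[, 2]) -
    x[, 2] * (y[, 1] * z[, 3] - y[, 3] * z[, 1]) +
    x[, 3] * (y[, 1] * z[, 2] - y[, 2] * z[, 1])
  D <- det3(B1, B2, B3)
  for (q in seq_len(nrow(points))) {
    r <- sweep(a, 2, points[q, ], "-") * -1  # point - a, rowwise
    l1 <- det3(r, B2, B3) / D
    l2 <- det3(B1, r, B3) / D
    l3 <- det3(B1, B2, r) / D
    l0 <- 1 - l1 - l2 - l3
    hit <- which(l0 >= -tol & l1 >= -tol & l2 >= -tol & l3 >= -tol)
    if (length(hit)) {
      e <- hit[1]
      out[q] <- l0[e] * field[mesh$tets[e, 1]] + l1[e] * field[mesh$tets[e, 2]] +
        l2[e] * field[mesh$tets[e, 3]] + l3[e] * field[mesh$tets[e, 4]]
    }
  }
  out
}
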