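#' Mesh measures
#'
#' `meshVolume` integrates the signed volume enclosed by an oriented closed
#' mesh (divergence theorem over triangle fans from the origin); the
#' absolute value is returned. `eulerCharacteristic` returns V - E + F
#' (2 for a closed genus-0 surface).
#'
#' @param mesh a [TriMesh-class].
#' @return scalar.
#' @export
meshVolume <- function(mesh) {
  tr <- mesh@triangles + 1L
  v <- mesh@vertices
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  c_ <- v[tr[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
              b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
              b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  abs(sum(rowSums(a * cr)) / 6)
}

#' @rdname meshVolume
#' @export
eulerCharacteristic <- function(mesh) {
  tr <- mesh@triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  nrow(mesh@vertices) - nrow(e) + nrow(tr)
}

# unit icosahedron, 12 vertices / 20 faces (0-based triangles)
icosahedron <- function() {
  p <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, p, 0), c(1, p, 0), c(-1, -p, 0), c(1, -p, 0),
             c(0, -1, p), c(0, 1, p), c(0, -1, -p), c(0, 1, -p),
             c(p, 0, -1), c(p, 0, 1), c(-p, 0, -1), c(-p, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  t <- rbind(c(0, 11, 5), c(0, 5, 1), c(0, 1, 7), c(0, 7, 10), c(0, 10, 11),
             c(1, 5, 9), c(5, 11, 4), c(11, 10, 2), c(10, 7, 6), c(7, 1, 8),
             c(3, 9, 4), c(3, 4, 2), c(3, 2, 6), c(3, 6, 8), c(3, 8, 9),
             c(4, 9, 5), c(2, 4, 11), c(6, 2, 10), c(8, 6, 7), c(9, 8, 1))
  TriMesh(v, t)
}

# one 4-to-1 midpoint subdivision step with shared-edge vertex reuse
subdivideOnce <- function(mesh, project_sphere = FALSE) {
  v <- mesh@vertices
  tr <- mesh@triangles + 1L
  nv <- nrow(v)
  edges <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  uk <- unique(key)
  mid_id <- match(key, uk) + nv
  ue <- edges[!duplicated(key), , drop = FALSE]
  mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
  if (project_sphere) mids <- mids / sqrt(rowSums(mids^2))
  nt <- nrow(tr)
  mab <- mid_id[seq_len(nt)]
  mbc <- mid_id[nt + seq_len(nt)]
  mca <- mid_id[2 * nt + seq_len(nt)]
  newtr <- rbind(cbind(tr[, 1], mab, mca),
                 cbind(tr[, 2], mbc, mab),
                 cbind(tr[, 3], mca, mbc),
                 cbind(mab, mbc, mca))
  TriMesh(rbind(v, mids), newtr - 1L)
}

# subdivide until the longest edge is <= maxEdge mm
subdivideToEdge <- function(mesh, maxEdge, maxSteps = 8L) {
  for (i in seq_len(maxSteps)) {
    v <- mesh@vertices
    tr <- mesh@triangles + 1L
    e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
    len <- sqrt(rowSums((v[e[, 1], , drop = FALSE] -
                         v[e[, 2], , drop = FALSE])^2))
    if (max(len) <= maxEdge) break
    mesh <- subdivideOnce(mesh)
  }
  mesh
}

# sparse uniform vertex adjacency (averaging) operator
adjacencyOperator <- function(mesh) {
  tr <- mesh@triangles + 1L
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  e <- unique(rbind(e, e[, 2:1]))
  A <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1,
                            dims = rep(nrow(mesh@vertices), 2))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  A / deg
}

#' Taubin (shrinkage-corrected Laplacian) mesh smoothing
#'
#' Alternates a positive Laplacian smoothing step (factor `lambda`) with a
#' negative inflation step (factor `mu`), which smooths without the volume
#' shrinkage of plain Laplacian iteration.
#'
#' @param mesh a [TriMesh-class].
#' @param iterations number of lambda/mu passes.
#' @param lambda,mu Taubin factors (defaults 0.5 / -0.53).
#' @return smoothed [TriMesh-class] (same connectivity).
#' @export
taubinSmooth <- function(mesh, iterations, lambda = 0.5, mu = -0.53) {
  if (iterations <= 0) return(mesh)
  W <- adjacencyOperator(mesh)
  v <- mesh@vertices
  for (i in seq_len(iterations)) {
    v <- v + lambda * (as.matrix(W %*% v) - v)
    v <- v + mu * (as.matrix(W %*% v) - v)
  }
  TriMesh(v, mesh@triangles)
}

# icosphere with n subdivision levels; vertices on the unit sphere
icosphere <- function(n_subdiv) {
  m <- icosahedron()
  for (i in seq_len(n_subdiv)) m <- subdivideOnce(m, project_sphere = TRUE)
  m
}

#' Convex hull of a 3D point set
#'
#' Quickhull over the input points; the result is a watertight outward-
#' oriented triangle mesh whose vertices are the hull-extreme input points.
#'
#' @param pts N x 3 coordinate matrix.
#' @return a [TriMesh-class].
#' @export
convexHullMesh <- function(pts) {
  pts <- as.matrix(pts)
  res <- .convexHullCpp(pts)
  tri <- res$triangles              # 1-based into pts
  used <- sort(unique(as.vector(tri)))
  remap <- match(tri, used)
  TriMesh(pts[used, , drop = FALSE],
          matrix(remap, ncol = 3) - 1L)
}
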