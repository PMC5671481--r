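# small geometric fixtures shared across tests

unitTetrahedron <- function() {
  TriMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
          rbind(c(0, 2, 1), c(0, 1, 3), c(0, 3, 2), c(1, 2, 3)))
}

# brute-force nearest-vertex scan, the labeling oracle
bruteNearest <- function(pts, verts) {
  apply(pts, 1, function(p) {
    d2 <- colSums((t(verts) - p)^2)
    which.min(d2)  # which.min takes the first (lowest-index) minimum
  })
}

# signed distance of points to every face plane of a convex hull mesh;
# a point is inside/on the hull iff max over faces <= tol
hullPlaneExcess <- function(pts, hull) {
  v <- vertices(hull)
  tr <- triangles(hull, one_based = TRUE)
  ex <- rep(-Inf, nrow(pts))
  for (k in seq_len(nrow(tr))) {
    a <- v[tr[k, 1], ]
    e1 <- v[tr[k, 2], ] - a
    e2 <- v[tr[k, 3], ] - a
    n <- c(e1[2] * e2[3] - e1[3] * e2[2],
           e1[3] * e2[1] - e1[1] * e2[3],
           e1[1] * e2[2] - e1[2] * e2[1])
    n <- n / sqrt(sum(n^2))
    ex <- pmax(ex, as.vector(pts %*% n) - sum(n * a))
  }
  ex
}

smallPhantomSpec <- function(seed, displacement = RigidTransform(),
                             gridDim = c(48L, 48L, 48L)) {
  phantomSpec(gridDim = gridDim, voxelSize = 2,
              brainSemiAxes = c(32, 42, 36),
              displacement = displacement, seed = seed)
}
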