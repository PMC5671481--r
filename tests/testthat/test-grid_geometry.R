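sq <- rbind(c(0, 0, 0), c(0, 60, 0), c(60, 0, 0), c(60, 60, 0))

test_that("grid interpolation reproduces corners and spacing", {
  # 2x2 grid: output is exactly the 4 corners, in channel order
  set.seed(2)
  c4 <- matrix(rnorm(12, sd = 20), 4, 3)
  expect_equal(interpGrid(c4, 2, 2), c4, ignore_attr = TRUE)

  # unit square, 3x3: center channel is the bilinear midpoint
  uc <- rbind(c(0, 0, 0), c(0, 1, 0), c(1, 0, 0), c(1, 1, 0))
  g3 <- interpGrid(uc, 3, 3)
  expect_equal(g3[5, ], c(0.5, 0.5, 0))

  # 16x16 high-density grid, 60 mm sides: 256 channels at 4 mm pitch
  g <- interpGrid(sq, 16, 16)
  expect_equal(nrow(g), 256)
  expect_equal(g[1, ], sq[1, ])     # corner 1 = channel 1
  expect_equal(g[16, ], sq[2, ])    # corner 2 = channel 16
  expect_equal(g[241, ], sq[3, ])   # corner 3 = channel 241
  expect_equal(g[256, ], sq[4, ])   # corner 4 = channel 256
  nnd <- vapply(seq_len(256), function(i) {
    d <- sqrt(rowSums((g[-i, , drop = FALSE] -
                         matrix(g[i, ], 255, 3, byrow = TRUE))^2))
    min(d)
  }, 0)
  expect_equal(nnd, rep(4, 256), tolerance = 1e-12)

  expect_error(interpGrid(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                                c(3, 0, 0)), 4, 4), "degenerate")
})

test_that("grid interpolation is affine-equivariant", {
  set.seed(3)
  c4 <- matrix(rnorm(12, sd = 20), 4, 3)
  A <- matrix(rnorm(9), 3) + 2 * diag(3)
  b <- rnorm(3)
  lhs <- interpGrid(t(A %*% t(c4) + b), 5, 7)
  rhs <- t(A %*% t(interpGrid(c4, 5, 7)) + b)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("grid frame normals are sign-consistent with a sensible mean", {
  fr <- gridFrame(sq, 16, 16)
  expect_equal(abs(meanNormal(fr)), c(0, 0, 1))
  expect_equal(unname(rowSums(fr@cornerNormals^2)), rep(1, 4))

  # lift one corner 2 mm out of plane: mean normal within 10 degrees
  bent <- sq
  bent[4, 3] <- 2
  frb <- gridFrame(bent, 16, 16)
  ang <- acos(abs(sum(meanNormal(frb) * c(0, 0, 1)))) * 180 / pi
  expect_lt(ang, 10)

  # strongly non-planar (saddle) corners: raw cross products disagree in
  # sign, returned normals must all lie in one half-space
  saddle <- rbind(c(0, 0, 0), c(0, 40, 8), c(40, 0, 8), c(40, 40, 0))
  frs <- gridFrame(saddle, 8, 8)
  dots <- frs@cornerNormals %*% meanNormal(frs)
  expect_true(all(dots > 0))
  expect_equal(sqrt(sum(meanNormal(frs)^2)), 1)
})

test_that("dural surfaces enclose the pial mesh", {
  pf <- makePialFixture(nSubdiv = 3, bumpiness = 5, seed = 13)
  hull <- duralSurface(pf$pial, "convex_hull")
  expect_gt(meshVolume(duralMesh(hull)), meshVolume(pf$pial))
  # every pial vertex inside or on the hull (face-plane oracle)
  ex <- hullPlaneExcess(vertices(pf$pial), duralMesh(hull))
  expect_lt(max(ex), 1e-6)

  # icosphere: hull is the sphere itself
  ico <- ElecLoc:::icosphere(3)
  h2 <- duralSurface(ico, "convex_hull")
  expect_equal(meshVolume(duralMesh(h2)), meshVolume(ico), tolerance = 1e-9)
  expect_gte(meshVolume(duralMesh(h2)), meshVolume(ico) - 1e-12)

  # zero smoothing iterations: smoothed hull == subdivided hull
  s0 <- duralSurface(pf$pial, "smoothed_hull", smoothingIters = 0)
  sub <- ElecLoc:::subdivideToEdge(convexHullMesh(vertices(pf$pial)), 3)
  expect_identical(vertices(duralMesh(s0)), vertices(sub))

  # OFC variant drops the excluded sector's vertices from the hull input
  ofc <- duralSurface(pf$pial, "ofc_submesh", annot = pf$annot,
                      excludeLabels = 1L)
  expect_s4_class(duralMesh(ofc), "TriMesh")
  expect_error(duralSurface(pf$pial, "ofc_submesh"), "annotation")
})

test_that("electrodes project onto the dural surface along the mean normal", {
  ico <- ElecLoc:::icosphere(4)
  surf <- duralSurface(ico, "convex_hull")

  # electrode at the sphere center, direction toward a vertex: lands on
  # that vertex at radius 1
  dir <- vertices(ico)[7, ]
  p <- projectElectrodes(rbind(c(0, 0, 0)), surf, dir)
  expect_equal(sqrt(sum(p^2)), 1, tolerance = 1e-9)
  expect_false(any(attr(p, "missed")))

  # electrode already on the surface barely moves, and projection is
  # idempotent
  onsurf <- rbind(vertices(ico)[100, ])
  p1 <- projectElectrodes(onsurf, surf, dir / sqrt(sum(dir^2)))
  expect_lt(sqrt(sum((p1 - onsurf)^2)), 1e-6)

  # a 16x16 grid pulled 8 mm inside a head-sized hull projects onto it
  pf <- makePialFixture(nSubdiv = 3, bumpiness = 2, seed = 17)
  hull <- duralSurface(pf$pial, "smoothed_hull", smoothingIters = 10)
  n <- c(1, 0, 0)
  corners <- rbind(c(28, -12, -12), c(28, 12, -12),
                   c(28, -12, 12), c(28, 12, 12))
  g <- interpGrid(corners, 16, 16)
  proj <- projectElectrodes(g, hull, n)
  expect_false(any(attr(proj, "missed")))
  # on-surface within 1e-6 mm (closest-point oracle)
  cp <- ElecLoc:::.closestPointCpp(proj, vertices(duralMesh(hull)),
                                   triangles(duralMesh(hull)))
  expect_lt(max(sqrt(rowSums((proj - cp)^2))), 1e-6)
  # idempotence
  proj2 <- projectElectrodes(proj, hull, n)
  expect_lt(max(sqrt(rowSums((proj2 - proj)^2))), 1e-6)
  # row-major neighbor ordering preserved: every grid cell keeps its
  # orientation along the projection direction (no crossings)
  ok <- TRUE
  for (r in 1:15) for (co in 1:15) {
    i <- (r - 1) * 16 + co
    e1 <- proj[i + 1, ] - proj[i, ]
    e2 <- proj[i + 16, ] - proj[i, ]
    cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    if (sum(cr * proj[i, ]) <= 0) ok <- FALSE  # outward-facing cell
  }
  expect_true(ok)
  # expansion: projecting outward from inside a convex surface cannot
  # shrink the mean inter-electrode spacing
  sp <- function(m) mean(dist(m))
  expect_gte(sp(proj), sp(g))
})

test_that("depth contacts interpolate evenly between end electrodes", {
  l <- interpLine(rbind(c(0, 0, 0), c(0, 0, 10)), 3)
  expect_equal(l[2, ], c(0, 0, 5))
  expect_equal(interpLine(rbind(c(1, 2, 3), c(4, 5, 6)), 2),
               rbind(c(1, 2, 3), c(4, 5, 6)), ignore_attr = TRUE)
  # a 45 mm track with 10 contacts reproduces the 5 mm depth pitch
  l10 <- interpLine(rbind(c(0, 0, 0), c(0, 45, 0)), 10)
  gaps <- sqrt(rowSums(diff(l10)^2))
  expect_equal(gaps, rep(5, 9))
  expect_error(interpLine(rbind(c(0, 0, 0), c(1, 1, 1)), 1), "at least 2")
})
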