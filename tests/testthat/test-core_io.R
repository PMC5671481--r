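test_that("NIfTI volumes round-trip and are normalized to RAS", {
  a <- array(as.double(seq_len(4^3)), c(4, 4, 4))
  f <- tempfile(fileext = ".nii")
  writeVolume(BrainVolume(a, diag(4)), f)
  v <- readVolume(f)
  expect_equal(volData(v), a)
  expect_equal(volAffine(v), diag(4))
  expect_identical(volFrame(v), "scanner_ras")

  # LPS-oriented file: voxel order must be reordered so the affine is
  # RAS-positive, with identical voxel-to-world mapping (reference reader
  # RNifti is the oracle on the same 4^3 fixture)
  img <- RNifti::asNifti(a)
  lps <- diag(c(-1, -1, 1, 1))
  lps[1:3, 4] <- c(2, 2, -1)
  RNifti::qform(img) <- structure(lps, code = 2L)
  RNifti::sform(img) <- structure(lps, code = 2L)
  f2 <- tempfile(fileext = ".nii")
  RNifti::writeNifti(img, f2)
  v2 <- readVolume(f2)
  expect_true(all(diag(volAffine(v2)[1:3, 1:3]) > 0))
  ref <- RNifti::readNifti(f2)
  for (ijk in list(c(0, 0, 0), c(3, 2, 1), c(1, 3, 0))) {
    w_ref <- as.vector(RNifti::voxelToWorld(ijk + 1, ref))
    i_ours <- worldToVoxel(v2, w_ref)
    expect_equal(volData(v2)[rbind(round(i_ours) + 1)],
                 a[rbind(ijk + 1)], tolerance = 1e-9)
  }

  bad <- tempfile(fileext = ".nii")
  writeLines("not a nifti", bad)
  suppressWarnings(expect_error(readVolume(bad), "unreadable volume"))
  expect_error(readVolume(tempfile(fileext = ".nii")), "unreadable volume")
})

test_that("trivert containers round-trip losslessly", {
  tet <- unitTetrahedron()
  f <- tempfile()
  writeTrivert(tet, f)
  back <- readTrivert(f)
  expect_identical(vertices(back), vertices(tet))
  expect_identical(triangles(back), triangles(tet))

  ico <- convexHullMesh(vertices(ElecLoc:::icosphere(4)))
  f2 <- tempfile()
  writeTrivert(ico, f2)
  back2 <- readTrivert(f2)
  expect_identical(vertices(back2), vertices(ico))
  expect_equal(nrow(vertices(back2)), 2562)
  expect_equal(eulerCharacteristic(back2), 2)

  f3 <- tempfile()
  writeLines(c("trivert 1", "vert 3 tri 1",
               "0 0 0", "1 0 0", "0 1 0", "0 1 5"), f3)
  expect_error(readTrivert(f3), "malformed trivert")
})

test_that("voxel/world mapping is exact and invertible", {
  vol <- BrainVolume(array(0, c(4, 4, 4)), diag(4))
  expect_equal(voxelToWorld(vol, c(1, 2, 3)), c(1, 2, 3))

  aff <- diag(c(2, 2, 2, 1))
  aff[1:3, 4] <- c(-10, -10, -10)
  vol2 <- BrainVolume(array(0, c(11, 11, 11)), aff)
  expect_equal(voxelToWorld(vol2, c(5, 5, 5)), c(0, 0, 0))

  set.seed(11)
  A <- diag(4)
  A[1:3, 1:3] <- matrix(rnorm(9), 3) + diag(3) * 2
  A[1:3, 4] <- rnorm(3, sd = 20)
  vol3 <- BrainVolume(array(0, c(5, 5, 5)), A)
  pts <- matrix(runif(300, -10, 10), ncol = 3)
  back <- voxelToWorld(vol3, worldToVoxel(vol3, pts))
  expect_lt(max(abs(back - pts)), 1e-9)
})

test_that("surface RAS is scanner RAS recentered on the volume center", {
  ctr <- BrainVolume(array(0, c(9, 9, 9)),
                     {a <- diag(4); a[1:3, 4] <- -4; a})
  expect_equal(surfaceRASOffset(ctr), c(0, 0, 0))

  # even-dimension volume with corner-anchored affine: the center voxel
  # (dim-1)/2 falls half a voxel short of dim/2
  aff <- diag(4)
  aff[1:3, 4] <- -8
  vol <- BrainVolume(array(0, c(16, 16, 16)), aff)
  expect_equal(surfaceRASOffset(vol), rep(-0.5, 3))

  pts <- matrix(rnorm(30), ncol = 3)
  expect_equal(toScannerRAS(toSurfaceRAS(pts, vol), vol), pts)
})

test_that("electrode tables and xfm files round-trip", {
  tab <- ElectrodeTable(matrix(rnorm(12), 4, 3),
                        data.frame(short_id = paste0("AD", 1:4),
                                   long_id = paste0("LAmygdalaDepth", 1:4),
                                   device_type = "depth"),
                        zeroIndexed = FALSE)
  f <- tempfile()
  writeElectrodes(tab, f)
  back <- readElectrodes(f)
  expect_identical(elecMatrix(back), unname(elecMatrix(tab)))
  expect_identical(elecLabels(back)$short_id, elecLabels(tab)$short_id)
  expect_false(zeroIndexed(back))
  expect_false("anatomy" %in% names(elecLabels(back)))

  # with anatomy and a partially-warped block
  lab <- elecLabels(tab)
  lab$anatomy <- c("Left-Hippocampus", "Left-Hippocampus",
                   "Left-Amygdala", "Unknown")
  w <- matrix(rnorm(12), 4, 3)
  w[2, ] <- NA
  tab2 <- ElectrodeTable(elecMatrix(tab), lab, FALSE, warped = w)
  f2 <- tempfile()
  writeElectrodes(tab2, f2)
  back2 <- readElectrodes(f2)
  expect_identical(warpedMatrix(back2), unname(w))
  expect_identical(elecLabels(back2)$anatomy, lab$anatomy)

  t <- RigidTransform(c(4, -3, 2), c(3, -2, 1), center = c(1, 2, 3))
  f3 <- tempfile(fileext = ".xfm")
  writeXfm(t, f3)
  expect_equal(readXfm(f3), as.matrix(t), tolerance = 1e-15)
})

test_that("class validity catches malformed objects", {
  expect_error(TriMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       rbind(c(0, 1, 5))), "out of range")
  expect_error(TriMesh(diag(3), rbind(c(0, 1, 1))), "degenerate")
  expect_error(ElectrodeTable(matrix(0, 2, 3),
                              data.frame(short_id = c("a", "a"),
                                         long_id = c("x", "y"),
                                         device_type = "grid")),
               "short_id")
  expect_error(ElectrodeTable(matrix(0, 1, 3),
                              data.frame(short_id = "a", long_id = "x",
                                         device_type = "laser")),
               "device_type")
  expect_error(BrainVolume(array(0, c(1, 4, 4))), "at least 2")
  expect_error(BrainVolume(array(0, c(4, 4, 4)),
                           matrix(0, 4, 4)), "invertible")
  # rigid transform consistency between parameters and matrix
  t <- RigidTransform(c(1, 2, 3), c(10, 20, 30), center = c(5, 5, 5))
  R <- as.matrix(t)[1:3, 1:3]
  expect_equal(crossprod(R), diag(3), tolerance = 1e-12)
  expect_equal(det(R), 1, tolerance = 1e-12)
  expect_equal(as.vector(as.matrix(t) %*% c(5, 5, 5, 1))[1:3],
               c(5, 5, 5) + c(1, 2, 3))
})
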