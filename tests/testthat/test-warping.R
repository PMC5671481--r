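pf <- makePialFixture(nSubdiv = 3, bumpiness = 2, seed = 41)

test_that("affine application is exact and invertible", {
  pts <- matrix(rnorm(30), 10, 3)
  expect_equal(applyAffine(pts, diag(4)), pts)
  expect_equal(applyAffine(rbind(c(0, 0, 0)),
                           RigidTransform(c(1, 2, 3))),
               rbind(c(1, 2, 3)))
  set.seed(42)
  t <- RigidTransform(rnorm(3, sd = 10), rnorm(3, sd = 15),
                      center = rnorm(3, sd = 30))
  p1k <- matrix(rnorm(3000, sd = 50), 1000, 3)
  back <- applyAffine(applyAffine(p1k, t), solve(as.matrix(t)))
  expect_lt(max(abs(back - p1k)), 1e-9)
  expect_error(applyAffine(pts, matrix(0, 4, 4)), "singular")

  # electrode tables and meshes transform their coordinate block
  tab <- ElectrodeTable(pts[1:2, ],
                        data.frame(short_id = c("a", "b"),
                                   long_id = c("A", "B"),
                                   device_type = "depth"))
  expect_equal(elecMatrix(applyAffine(tab, t)),
               applyAffine(pts[1:2, ], t))
  expect_equal(vertices(applyAffine(pf$pial, t)),
               applyAffine(vertices(pf$pial), t))
})

test_that("snapping finds the nearest vertex and flags long snaps", {
  v <- vertices(pf$pial)
  idx <- snapToSurface(v[7, , drop = FALSE], pf$pial)
  expect_equal(as.integer(idx), 7L)
  expect_equal(attr(idx, "distance")[1], 0)

  set.seed(43)
  elecs <- matrix(rnorm(300, sd = 35), 100, 3)
  idx2 <- snapToSurface(elecs, pf$pial)
  expect_equal(as.integer(idx2), as.integer(bruteNearest(elecs, v)))

  # an electrode hovering far off the surface is flagged
  far <- rbind(v[1, ] * 2)      # 40 mm straight out from the surface
  idx3 <- snapToSurface(far, pf$pial, flagDist = 10)
  expect_true(attr(idx3, "flagged")[1])
})

test_that("surface warp through the sphere correspondence", {
  # subject == template: identity on snapped electrodes
  reg <- makeSphereRegFixture(pf)
  v <- vertices(pf$pial)
  w <- surfaceWarp(v[c(5, 100, 600), , drop = FALSE], reg)
  expect_equal(w, v[c(5, 100, 600), , drop = FALSE], ignore_attr = TRUE)

  # known rotation: electrode at subject vertex i maps to the rotated
  # vertex (analytic correspondence)
  rot <- c(25, 10, -5)
  regR <- makeSphereRegFixture(pf, rotation = rot)
  R <- as.matrix(RigidTransform(rotation = rot))[1:3, 1:3]
  picks <- c(3, 77, 411)
  wr <- surfaceWarp(v[picks, , drop = FALSE], regR)
  expect_equal(wr, v[picks, , drop = FALSE] %*% t(R),
               ignore_attr = TRUE, tolerance = 1e-9)

  # off-vertex electrode: snaps first, then maps; anatomy is preserved
  # under the identity correspondence
  off <- v[50, ] * 1.1
  w2 <- surfaceWarp(rbind(off), reg)
  expect_equal(as.vector(w2), v[as.integer(attr(w2, "subjVertex")), ])
  labN <- labelSurface(rbind(off), pf$pial, pf$annot, pf$lut)
  labW <- labelSurface(w2, pf$pial, pf$annot, pf$lut)
  expect_identical(as.vector(labN), as.vector(labW))
})

wf <- makeWarpFixture(seed = 47)

test_that("volume warp adds the interpolated displacement", {
  elecs <- rbind(c(0, 0, 0), c(10, -5, 3), c(-20, 12, -8))
  # zero field: identity
  wf0 <- makeWarpFixture(amplitude = 0, seed = 47)
  expect_equal(volumeWarp(elecs, wf0$field), elecs, ignore_attr = TRUE)
  expect_true(max(abs(wf0$field@displacement)) == 0)

  # uniform field: rigid shift
  uni <- WarpField(array(rep(c(2, 0, 0), each = 8^3), c(8, 8, 8, 3)),
                   ElecLoc:::centeredAffine(c(8, 8, 8), 10))
  expect_equal(volumeWarp(rbind(c(0, 0, 0), c(5, 5, 5)), uni),
               rbind(c(2, 0, 0), c(7, 5, 5)), ignore_attr = TRUE)

  # smooth fixture at off-grid points vs the analytic oracle
  set.seed(48)
  pts <- matrix(runif(300, -40, 40), 100, 3)
  w <- volumeWarp(pts, wf$field)
  expect_false(any(attr(w, "outside")))
  expect_lt(max(abs((w - pts) - wf$analytic(pts))), 0.01)

  # outside the mask: flagged and passed through
  expect_warning(wout <- volumeWarp(rbind(c(500, 0, 0)), wf$field),
                 "outside")
  expect_equal(as.vector(wout), c(500, 0, 0))
  expect_true(attr(wout, "outside")[1])
})

test_that("volume warp is linear in the field", {
  pts <- matrix(runif(60, -30, 30), 20, 3)
  d1 <- volumeWarp(pts, wf$field) - pts
  half <- WarpField(wf$field@displacement * 0.5, wf$field@affine)
  d05 <- volumeWarp(pts, half) - pts
  expect_equal(d05, 0.5 * d1, tolerance = 1e-12)
})

parc <- makeParcellationFixture(seed = 1)

labeledFixtureTable <- function() {
  ctr <- attr(parc, "centers")
  depthIds <- c(17L, 18L, 11L, 12L)
  depth <- voxelToWorld(parcVolume(parc),
                        ctr[match(depthIds, ctr[, 1]), 2:4])
  v <- vertices(pf$pial)
  surf <- v[c(20, 40, 60), ]
  tab <- ElectrodeTable(rbind(surf, depth), data.frame(
    short_id = c(paste0("G", 1:3), paste0("AD", 1:4)),
    long_id = c(paste0("Grid", 1:3), paste0("Depth", 1:4)),
    device_type = rep(c("grid", "depth"), c(3, 4))))
  labelElectrodes(tab, pf$pial, pf$annot, pf$lut, parc)
}

test_that("label-agreement QC reports identity warps as 100%", {
  tab <- labeledFixtureTable()
  qc <- checkWarpLabels(tab, elecMatrix(tab), pf$pial, pf$annot, pf$lut,
                        parc)
  expect_equal(attr(qc, "agreement"), 1)
  expect_true(all(qc$agree))

  # a depth electrode landing in a different structure is flagged first
  bad <- elecMatrix(tab)
  ctr <- attr(parc, "centers")
  bad[5, ] <- voxelToWorld(parcVolume(parc),
                           ctr[ctr[, 1] == 54, 2:4, drop = FALSE])
  qc2 <- checkWarpLabels(tab, bad, pf$pial, pf$annot, pf$lut, parc)
  expect_equal(attr(qc2, "agreement"), 6 / 7)
  expect_false(qc2$agree[1])
  expect_identical(qc2$short_id[1], "AD2")
  expect_identical(qc2$warped[1], "Right-Amygdala")

  # agreement equals a hand count on this small fixture
  expect_equal(sum(qc2$agree), 6)
  expect_error(checkWarpLabels(
    ElectrodeTable(matrix(0, 1, 3),
                   data.frame(short_id = "a", long_id = "b",
                              device_type = "grid")),
    matrix(0, 1, 3), pf$pial, pf$annot, pf$lut, parc), "anatomy")
})

test_that("warpAll dispatches by device type and honors subsets", {
  tab <- labeledFixtureTable()
  reg <- makeSphereRegFixture(pf)
  wf0 <- makeWarpFixture(amplitude = 0, seed = 47)

  out <- warpAll(tab, reg, wf0$field, templMesh = pf$pial,
                 templAnnot = pf$annot, templLUT = pf$lut,
                 templParc = parc)
  # identity resources: warped equals native everywhere
  expect_equal(warpedMatrix(out), elecMatrix(tab), ignore_attr = TRUE)
  expect_equal(attr(attr(out, "qc"), "agreement"), 1)

  # depth-only subset: surface rows get no warped coordinates
  dep <- warpAll(tab, reg, wf0$field, subset = "depth")
  expect_true(all(is.na(warpedMatrix(dep)[1:3, ])))
  expect_false(any(is.na(warpedMatrix(dep)[4:7, ])))

  # mixed warp equals the per-device operations applied alone
  rot <- c(12, -8, 5)
  regR <- makeSphereRegFixture(pf, rotation = rot)
  out2 <- warpAll(tab, regR, wf$field)
  expect_equal(warpedMatrix(out2)[1:3, ],
               unname(surfaceWarp(elecMatrix(tab)[1:3, ], regR)),
               ignore_attr = TRUE)
  expect_equal(warpedMatrix(out2)[4:7, ],
               unname(volumeWarp(elecMatrix(tab)[4:7, ], wf$field)),
               ignore_attr = TRUE)

  # drop list and manual override
  out3 <- warpAll(tab, reg, wf0$field, drop = "AD1",
                  override = list(G1 = c(1, 2, 3)))
  expect_true(all(is.na(warpedMatrix(out3)[4, ])))
  expect_equal(warpedMatrix(out3)[1, ], c(1, 2, 3))
})
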