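pf <- makePialFixture(nSubdiv = 3, bumpiness = 2, seed = 23)

test_that("surface labels come from the nearest annotated vertex", {
  # electrode exactly on a vertex gets that vertex's label
  v <- 57L
  lab <- labelSurface(vertices(pf$pial)[v, , drop = FALSE], pf$pial,
                      pf$annot, pf$lut)
  expect_identical(lab[1], pf$lut$name[match(pf$annot[v], pf$lut$id)])
  expect_equal(attr(lab, "distance")[1], 0)
  # a vertex annotated superiortemporal labels as superiortemporal
  stg <- which(pf$annot == pf$lut$id[pf$lut$name == "superiortemporal"])[1]
  lab2 <- labelSurface(vertices(pf$pial)[stg, , drop = FALSE], pf$pial,
                       pf$annot, pf$lut)
  expect_identical(lab2[1], "superiortemporal")

  # equidistant tie goes to the lowest vertex index
  mesh <- TriMesh(rbind(c(-1, 0, 0), c(1, 0, 0), c(0, 5, 0)),
                  rbind(c(0, 1, 2)))
  lab3 <- labelSurface(rbind(c(0, 0, 0)), mesh, c(10L, 20L, 30L))
  expect_identical(lab3[1], "10")
  expect_equal(attr(lab3, "vertex")[1], 1L)

  expect_error(labelSurface(rbind(c(0, 0, 0)), pf$pial, 1:3), "length")
})

test_that("surface labeling equals the exhaustive nearest-vertex scan", {
  set.seed(31)
  elecs <- matrix(rnorm(300, sd = 35), 100, 3)
  lab <- labelSurface(elecs, pf$pial, pf$annot, pf$lut)
  oracle_idx <- bruteNearest(elecs, vertices(pf$pial))
  oracle <- pf$lut$name[match(pf$annot[oracle_idx], pf$lut$id)]
  expect_identical(as.vector(lab), oracle)
  expect_identical(as.integer(attr(lab, "vertex")), as.integer(oracle_idx))
  # deterministic: repeated runs identical
  expect_identical(as.vector(labelSurface(elecs, pf$pial, pf$annot,
                                          pf$lut)),
                   as.vector(lab))
})

parc <- makeParcellationFixture(seed = 1)

test_that("depth labels come from the parcellated voxel", {
  ctr <- attr(parc, "centers")
  hipp <- voxelToWorld(parcVolume(parc),
                       ctr[ctr[, 1] == 17, 2:4, drop = FALSE])
  lab <- labelDepth(hipp, parc)
  expect_identical(lab[1], "Left-Hippocampus")
  expect_equal(attr(lab, "id")[1], 17L)

  # zero-labeled background and out-of-volume coordinates
  expect_identical(labelDepth(rbind(c(0, 0, 43)), parc)[1], "Unknown")
  expect_warning(out <- labelDepth(rbind(c(500, 0, 0)), parc), "outside")
  expect_identical(out[1], "Unknown")

  # half-voxel boundary behavior matches an exhaustive-rounding oracle
  vol <- parcVolume(parc)
  set.seed(5)
  pts <- matrix(runif(150, -40, 40), 50, 3)
  lab2 <- labelDepth(pts, parc)
  vox <- worldToVoxel(vol, toScannerRAS(pts, vol))
  oracle_ids <- vapply(seq_len(nrow(vox)), function(i) {
    v <- sign(vox[i, ]) * floor(abs(vox[i, ]) + 0.5)
    vol@data[v[1] + 1, v[2] + 1, v[3] + 1]
  }, 0)
  oracle <- ifelse(oracle_ids == 0, "Unknown",
                   parcLUT(parc)$name[match(oracle_ids, parcLUT(parc)$id)])
  expect_identical(as.vector(lab2), oracle)
})

test_that("elecs_all assembly follows montage order and naming", {
  strip <- matrix(rnorm(12), 4, 3)
  spec <- montageSpec("ad_strip", "strip", "AD", "LAmygdala{n}", 4L)
  tab <- makeElecsAll(spec, list(ad_strip = strip), zeroIndexed = FALSE)
  expect_identical(elecLabels(tab)$short_id, paste0("AD", 1:4))
  expect_identical(elecLabels(tab)$long_id, paste0("LAmygdala", 1:4))
  expect_identical(elecMatrix(tab), strip)
  expect_false("anatomy" %in% names(elecLabels(tab)))

  # zero-indexed numbering starts the channel count at 0
  tab0 <- makeElecsAll(spec, list(ad_strip = strip), zeroIndexed = TRUE)
  expect_identical(elecLabels(tab0)$short_id, paste0("AD", 0:3))

  expect_error(makeElecsAll(spec[0, ], list()), "empty")
  expect_error(makeElecsAll(spec, list(ad_strip = strip[1:3, ])),
               "3 coordinates but 4")

  # grid rows come first iff the grid is listed first; coordinate order
  # within each device is preserved exactly
  grid <- matrix(seq_len(256 * 3), 256, 3)
  depth <- matrix(-seq_len(30), 10, 3)
  spec2 <- montageSpec(c("hd_grid", "hipp_depth"), c("grid", "depth"),
                       c("G", "HD"), c("Grid{n}", "Depth{n}"),
                       c(256L, 10L))
  tab2 <- makeElecsAll(spec2, list(hd_grid = grid, hipp_depth = depth),
                       zeroIndexed = FALSE)
  expect_equal(length(tab2), 266)
  expect_identical(elecMatrix(tab2)[1:256, ], grid)
  expect_identical(elecMatrix(tab2)[257:266, ], depth)
  expect_identical(elecLabels(tab2)$device_type,
                   rep(c("grid", "depth"), c(256, 10)))

  dup <- montageSpec(c("a", "b"), c("strip", "strip"), c("S", "S"),
                     c("x{n}", "y{n}"), c(2L, 2L))
  expect_error(makeElecsAll(dup, list(a = strip[1:2, ], b = strip[3:4, ])),
               "duplicate short_id")
})

test_that("label revisions edit exactly the listed electrodes", {
  grid <- matrix(rnorm(256 * 3), 256, 3)
  spec <- montageSpec("hd_grid", "grid", "G", "Grid{n}", 256L)
  tab <- makeElecsAll(spec, list(hd_grid = grid), zeroIndexed = TRUE)
  lab <- elecLabels(tab)
  lab$anatomy <- rep("parstriangularis", 256)
  tab <- ElectrodeTable(elecMatrix(tab), lab, zeroIndexed = TRUE)

  # the worked example: electrode number 246 (zero-indexed) reassigned
  rev <- editLabels(tab, list(superiortemporal = c(246)))
  expect_identical(elecLabels(rev)$anatomy[247], "superiortemporal")
  expect_identical(elecLabels(rev)$anatomy[-247],
                   rep("parstriangularis", 255))
  expect_length(rev@provenance, 1)
  expect_identical(rev@provenance[[1]]$previous, "parstriangularis")

  # empty revision list leaves the table untouched
  expect_identical(elecLabels(editLabels(tab, list()))$anatomy,
                   lab$anatomy)

  # disjoint revisions commute
  r1 <- editLabels(editLabels(tab, list(superiortemporal = c(246))),
                   list(caudalmiddlefrontal = c(174)))
  r2 <- editLabels(editLabels(tab, list(caudalmiddlefrontal = c(174))),
                   list(superiortemporal = c(246)))
  expect_identical(elecLabels(r1)$anatomy, elecLabels(r2)$anatomy)

  expect_error(editLabels(tab, list(superiortemporal = c(400))),
               "out of range")
})

test_that("labelElectrodes routes devices to the right atlas", {
  ctr <- attr(parc, "centers")
  hipp <- voxelToWorld(parcVolume(parc),
                       ctr[ctr[, 1] == 17, 2:4, drop = FALSE])
  coords <- rbind(vertices(pf$pial)[10, ], hipp)
  tab <- ElectrodeTable(coords,
                        data.frame(short_id = c("G1", "AD1"),
                                   long_id = c("Grid1", "Depth1"),
                                   device_type = c("grid", "depth")))
  out <- labelElectrodes(tab, pf$pial, pf$annot, pf$lut, parc)
  expect_identical(elecLabels(out)$anatomy[1],
                   pf$lut$name[match(pf$annot[10], pf$lut$id)])
  expect_identical(elecLabels(out)$anatomy[2], "Left-Hippocampus")
})
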