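#' Prepare a subject directory
#'
#' Creates the standard subject layout (acpc/, CT/, elecs/ with
#' individual_elecs/, Meshes/ with subcortical/, mri/ with transforms/,
#' logs/) and persists the subject configuration (subject id, hemisphere,
#' zero-indexing) as JSON. Idempotent: a second run changes nothing.
#'
#' @param root parent directory (must be writable).
#' @param subj subject identifier.
#' @param hem hemisphere of implantation: `"lh"`, `"rh"` or (for a
#'   bilateral stereo-EEG case) `"stereo"`.
#' @param zeroIndexed electrode channel numbering starts at 0.
#' @return a `SubjectDir` handle (list with `root` and `config`).
#' @export
prepSubject <- function(root, subj, hem, zeroIndexed = TRUE) {
  if (!hem %in% c("lh", "rh", "stereo"))
    stop("hem must be one of 'lh', 'rh' or 'stereo'")
  sdroot <- file.path(root, subj)
  for (d in c("acpc", "CT", "elecs", file.path("elecs", "individual_elecs"),
              "Meshes", file.path("Meshes", "subcortical"),
              "mri", file.path("mri", "transforms"), "logs"))
    dir.create(file.path(sdroot, d), showWarnings = FALSE, recursive = TRUE)
  cfgPath <- file.path(sdroot, "config.json")
  cfg <- list(subj = subj, hem = hem, zero_indexed = zeroIndexed)
  if (!file.exists(cfgPath))
    jsonlite::write_json(cfg, cfgPath, auto_unbox = TRUE)
  subjectDir(sdroot)
}

#' @rdname prepSubject
#' @export
subjectDir <- function(root) {
  cfgPath <- file.path(root, "config.json")
  if (!file.exists(cfgPath)) stop("no config.json under ", root,
                                  "; run prepSubject first")
  structure(list(root = root,
                 config = jsonlite::read_json(cfgPath, simplifyVector = TRUE)),
            class = "SubjectDir")
}

#' @export
print.SubjectDir <- function(x, ...) {
  cat(sprintf("SubjectDir %s (subj %s, hem %s, zero_indexed %s)\n",
              x$root, x$config$subj, x$config$hem, x$config$zero_indexed))
  invisible(x)
}

sdPath <- function(sd, ...) file.path(sd$root, ...)

requireInputs <- function(sd, files, producers) {
  for (i in seq_along(files)) {
    if (!file.exists(sdPath(sd, files[i])))
      stop(sprintf("missing prerequisite %s (produced by stage '%s')",
                   files[i], producers[i]))
  }
}

logStage <- function(sd, stage, inputs, params, outputs) {
  rec <- list(stage = stage, time = format(Sys.time(), tz = "UTC"),
              inputs = lapply(inputs, function(f) {
                p <- sdPath(sd, f)
                list(path = f,
                     md5 = if (dir.exists(p)) NA_character_
                           else unname(tools::md5sum(p)))
              }),
              params = params, outputs = outputs)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE),
      "\n", sep = "",
      file = sdPath(sd, "logs", "pipeline.jsonl"), append = TRUE)
}

#' Run one pipeline stage on a subject directory
#'
#' Dispatches a named stage to the owning module, reading its declared
#' inputs from and writing its outputs to the standard locations; refuses
#' to run when an upstream output is missing, naming the file and the
#' producing stage. Every run appends a structured JSON line (stage,
#' input hashes, parameters, outputs) to `logs/pipeline.jsonl`.
#'
#' Stages: `register` (CT/CT.nii + mri/T1.nii -> CT/rCT.nii +
#' mri/transforms/ct2t1.xfm), `interp-grid` (elecs/<base>_corners.tsv ->
#' elecs/individual_elecs/<base>_orig.tsv), `project` (grid + pial ->
#' elecs/individual_elecs/<base>.tsv), `elecs-all` (elecs/montage.json +
#' device files -> elecs/elecs_all.tsv), `label` (elecs_all + pial/annot +
#' mri/aparc+aseg.nii -> anatomy column), `subcort` (mri/aparc+aseg.nii ->
#' Meshes/subcortical/), `warp` (elecs_all + Meshes/sphere_reg/ +
#' mri/transforms/warp_field.nii + template resources ->
#' elecs/elecs_all_warped.tsv + elecs/warp_qc.csv).
#'
#' @param sd a `SubjectDir` from [prepSubject()]/[subjectDir()].
#' @param stage stage name (see Details).
#' @param overrides named list of stage parameters (e.g. `nrows`, `ncols`,
#'   `basename`, `surfType`, `subset`); recorded verbatim in the log.
#' @return stage-dependent result, invisibly.
#' @export
runStage <- function(sd, stage, overrides = list()) {
  hem <- sd$config$hem
  meshHem <- if (hem == "stereo") "lh" else hem
  base <- overrides$basename %||% "hd_grid"
  out <- switch(stage,
    "register" = {
      requireInputs(sd, c("CT/CT.nii", "mri/T1.nii"),
                    c("(input data)", "(input data)"))
      t1 <- readVolume(sdPath(sd, "mri", "T1.nii"))
      ct <- readVolume(sdPath(sd, "CT", "CT.nii"))
      opts <- do.call(regOptions,
                      overrides[intersect(names(overrides),
                                          names(formals(regOptions)))])
      t <- registerRigid(t1, ct, opts = opts)
      writeVolume(resampleVolume(ct, t, t1), sdPath(sd, "CT", "rCT.nii"))
      writeXfm(t, sdPath(sd, "mri", "transforms", "ct2t1.xfm"))
      logStage(sd, stage, c("CT/CT.nii", "mri/T1.nii"), overrides,
               c("CT/rCT.nii", "mri/transforms/ct2t1.xfm"))
      t
    },
    "interp-grid" = {
      cornersFile <- file.path("elecs", paste0(base, "_corners.tsv"))
      requireInputs(sd, cornersFile, "(electrode identification)")
      corners <- readCoordTable(sdPath(sd, cornersFile))
      nrows <- overrides$nrows %||% 16L
      ncols <- overrides$ncols %||% 16L
      g <- interpGrid(corners, nrows, ncols)
      outFile <- file.path("elecs", "individual_elecs",
                           paste0(base, "_orig.tsv"))
      writeCoordTable(g, sdPath(sd, outFile))
      logStage(sd, stage, cornersFile,
               c(overrides, list(nrows = nrows, ncols = ncols)), outFile)
      g
    },
    "project" = {
      gridFile <- file.path("elecs", "individual_elecs",
                            paste0(base, "_orig.tsv"))
      cornersFile <- file.path("elecs", paste0(base, "_corners.tsv"))
      pialFile <- file.path("Meshes",
                            paste0(meshHem, "_pial_trivert.txt"))
      requireInputs(sd, c(gridFile, cornersFile, pialFile),
                    c("interp-grid", "(electrode identification)",
                      "(mesh conversion)"))
      g <- readCoordTable(sdPath(sd, gridFile))
      corners <- readCoordTable(sdPath(sd, cornersFile))
      pial <- readTrivert(sdPath(sd, pialFile))
      nrows <- overrides$nrows %||% 16L
      ncols <- overrides$ncols %||% 16L
      fr <- gridFrame(corners, nrows, ncols)
      mn <- meanNormal(fr)
      # orient outward: away from the pial centroid
      if (sum(mn * (colMeans(corners) - colMeans(pial@vertices))) < 0)
        mn <- -mn
      surfType <- overrides$surfType %||% "smoothed_hull"
      surf <- duralSurface(pial, kind = surfType)
      p <- projectElectrodes(g, surf, mn)
      outFile <- file.path("elecs", "individual_elecs",
                           paste0(base, ".tsv"))
      writeCoordTable(p, sdPath(sd, outFile))
      logStage(sd, stage, c(gridFile, cornersFile, pialFile),
               c(overrides, list(surfType = surfType)), outFile)
      p
    },
    "elecs-all" = {
      requireInputs(sd, "elecs/montage.json", "(montage definition)")
      mj <- jsonlite::read_json(sdPath(sd, "elecs", "montage.json"),
                                simplifyVector = TRUE)
      spec <- montageSpec(mj$device_name, mj$device_type, mj$short_prefix,
                          mj$long_template, mj$n_channels)
      coords <- lapply(spec$device_name, function(dn) {
        f <- file.path("elecs", "individual_elecs", paste0(dn, ".tsv"))
        requireInputs(sd, f, "project / (electrode identification)")
        readCoordTable(sdPath(sd, f))
      })
      names(coords) <- spec$device_name
      tab <- makeElecsAll(spec, coords,
                          zeroIndexed = isTRUE(sd$config$zero_indexed))
      writeElectrodes(tab, sdPath(sd, "elecs", "elecs_all.tsv"))
      logStage(sd, stage, "elecs/montage.json", overrides,
               "elecs/elecs_all.tsv")
      tab
    },
    "label" = {
      ins <- c("elecs/elecs_all.tsv",
               file.path("Meshes", paste0(meshHem, "_pial_trivert.txt")),
               file.path("Meshes", paste0(meshHem, ".annot.csv")),
               "Meshes/annot_lut.csv", "mri/aparc+aseg.nii",
               "mri/aseg_lut.csv")
      requireInputs(sd, ins, c("elecs-all", "(mesh conversion)",
                               "(atlas annotation)", "(atlas annotation)",
                               "(parcellation)", "(parcellation)"))
      tab <- readElectrodes(sdPath(sd, ins[1]))
      pial <- readTrivert(sdPath(sd, ins[2]))
      annot <- readAnnot(sdPath(sd, ins[3]))
      surfLUT <- readLUT(sdPath(sd, ins[4]))
      parcVol <- readVolume(sdPath(sd, ins[5]))
      parcVol@data <- array(as.integer(round(parcVol@data)), dim(parcVol@data))
      parc <- Parcellation(parcVol, readLUT(sdPath(sd, ins[6])))
      tab <- labelElectrodes(tab, pial, annot, surfLUT, parc)
      writeElectrodes(tab, sdPath(sd, "elecs", "elecs_all.tsv"))
      logStage(sd, stage, ins, overrides, "elecs/elecs_all.tsv")
      tab
    },
    "subcort" = {
      ins <- c("mri/aparc+aseg.nii", "mri/aseg_lut.csv")
      requireInputs(sd, ins, c("(parcellation)", "(parcellation)"))
      parcVol <- readVolume(sdPath(sd, ins[1]))
      parcVol@data <- array(as.integer(round(parcVol@data)), dim(parcVol@data))
      parc <- Parcellation(parcVol, readLUT(sdPath(sd, ins[2])))
      meshes <- getSubcort(parc, outDir = sdPath(sd, "Meshes",
                                                 "subcortical"))
      logStage(sd, stage, ins, overrides, "Meshes/subcortical/")
      meshes
    },
    "warp" = {
      ins <- c("elecs/elecs_all.tsv", "Meshes/sphere_reg",
               "mri/transforms/warp_field.nii", "mri/templ_aseg.nii",
               "mri/aseg_lut.csv", "Meshes/templ.annot.csv",
               "Meshes/annot_lut.csv")
      requireInputs(sd, ins, c("label", "(surface registration)",
                               "(volumetric warp)", "(template)",
                               "(parcellation)", "(template)",
                               "(atlas annotation)"))
      tab <- readElectrodes(sdPath(sd, ins[1]))
      reg <- readSphereReg(sdPath(sd, ins[2]))
      field <- readWarpField(sdPath(sd, ins[3]))
      tParcVol <- readVolume(sdPath(sd, ins[4]))
      tParcVol@data <- array(as.integer(round(tParcVol@data)),
                             dim(tParcVol@data))
      tParc <- Parcellation(tParcVol, readLUT(sdPath(sd, ins[5])))
      tAnnot <- readAnnot(sdPath(sd, ins[6]))
      tLUT <- readLUT(sdPath(sd, ins[7]))
      tab <- warpAll(tab, reg, field,
                     subset = overrides$subset %||% "all",
                     templMesh = reg@templPial, templAnnot = tAnnot,
                     templLUT = tLUT, templParc = tParc)
      writeElectrodes(tab, sdPath(sd, "elecs", "elecs_all_warped.tsv"))
      qc <- attr(tab, "qc")
      if (!is.null(qc))
        write.table(qc, sdPath(sd, "elecs", "warp_qc.csv"), sep = ",",
                    quote = FALSE, row.names = FALSE)
      logStage(sd, stage, ins, overrides,
               c("elecs/elecs_all_warped.tsv", "elecs/warp_qc.csv"))
      tab
    },
    stop("unknown stage: ", stage)
  )
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

labelColorMap <- function(labels, luts) {
  lut <- do.call(rbind, lapply(luts, function(l)
    l[, intersect(c("name", "r", "g", "b"), names(l)), drop = FALSE]))
  lut <- lut[!duplicated(lut$name), , drop = FALSE]
  i <- match(labels, lut$name)
  col <- ifelse(is.na(i), "#808080",
                grDevices::rgb(lut$r[i], lut$g[i], lut$b[i],
                               maxColorValue = 255))
  data.frame(label = labels, color = col, stringsAsFactors = FALSE)
}

plotElecsOnMesh <- function(mesh, coords, colors, main) {
  v <- mesh@vertices
  graphics::plot(v[, 2], v[, 3], pch = ".", col = "grey80", asp = 1,
                 xlab = "P-A (mm)", ylab = "I-S (mm)", main = main)
  hull <- grDevices::chull(v[, 2], v[, 3])
  graphics::polygon(v[hull, 2], v[hull, 3], border = "grey50")
  graphics::points(coords[, 2], coords[, 3], pch = 19, col = colors,
                   cex = 1.1)
}

#' Headless QC rendering
#'
#' Static 2D quality-control output replacing interactive inspection:
#' `recon_anatomy` draws the labeled electrodes (colored by anatomy) over a
#' sagittal silhouette of the pial mesh, with a legend CSV mapping labels
#' to colors; `warp_compare` shows native and warped electrodes side by
#' side; `depth_warps` renders one panel per depth electrode with native
#' and template parcellation slice crops and a crosshair at the electrode.
#' Output is deterministic given its inputs.
#'
#' @param sd a `SubjectDir`.
#' @param what `"recon_anatomy"`, `"warp_compare"` or `"depth_warps"`.
#' @return character vector of files written, invisibly.
#' @export
qcRender <- function(sd, what = c("recon_anatomy", "warp_compare",
                                  "depth_warps")) {
  what <- match.arg(what)
  hem <- sd$config$hem
  meshHem <- if (hem == "stereo") "lh" else hem
  pialFile <- file.path("Meshes", paste0(meshHem, "_pial_trivert.txt"))
  luts <- list()
  for (f in c("Meshes/annot_lut.csv", "mri/aseg_lut.csv"))
    if (file.exists(sdPath(sd, f))) luts <- c(luts, list(readLUT(sdPath(sd, f))))
  files <- character(0)
  if (what == "recon_anatomy") {
    requireInputs(sd, c("elecs/elecs_all.tsv", pialFile),
                  c("label", "(mesh conversion)"))
    tab <- readElectrodes(sdPath(sd, "elecs", "elecs_all.tsv"))
    if (!"anatomy" %in% names(tab@labels))
      stop("electrodes have no anatomy column; run the label stage first")
    pial <- readTrivert(sdPath(sd, pialFile))
    cm <- labelColorMap(tab@labels$anatomy, luts)
    png <- sdPath(sd, "elecs", paste0(meshHem, "_recon_anatomy.png"))
    grDevices::png(png, width = 800, height = 800)
    plotElecsOnMesh(pial, tab@coords, cm$color,
                    sprintf("%s electrodes by anatomy", meshHem))
    grDevices::dev.off()
    legend <- unique(cm)
    legendCsv <- sdPath(sd, "elecs", "recon_anatomy_legend.csv")
    write.table(legend, legendCsv, sep = ",", quote = FALSE,
                row.names = FALSE)
    files <- c(png, legendCsv)
  } else if (what == "warp_compare") {
    requireInputs(sd, c("elecs/elecs_all_warped.tsv", pialFile),
                  c("warp", "(mesh conversion)"))
    tab <- readElectrodes(sdPath(sd, "elecs", "elecs_all_warped.tsv"))
    pial <- readTrivert(sdPath(sd, pialFile))
    cm <- labelColorMap(tab@labels$anatomy %||%
                          rep("unlabeled", length(tab)), luts)
    png <- sdPath(sd, "elecs", "warped_recon_anatomy.png")
    grDevices::png(png, width = 1200, height = 600)
    graphics::par(mfrow = c(1, 2))
    plotElecsOnMesh(pial, tab@coords, cm$color, "native")
    w <- tab@warped
    ok <- stats::complete.cases(w)
    plotElecsOnMesh(pial, w[ok, , drop = FALSE], cm$color[ok], "warped")
    grDevices::dev.off()
    files <- png
  } else {
    requireInputs(sd, c("elecs/elecs_all_warped.tsv", "mri/aparc+aseg.nii",
                        "mri/templ_aseg.nii"),
                  c("warp", "(parcellation)", "(template)"))
    tab <- readElectrodes(sdPath(sd, "elecs", "elecs_all_warped.tsv"))
    native <- readVolume(sdPath(sd, "mri", "aparc+aseg.nii"))
    templ <- readVolume(sdPath(sd, "mri", "templ_aseg.nii"))
    dep <- which(tab@labels$device_type == "depth")
    png <- sdPath(sd, "elecs", "depth_warps_qc.png")
    grDevices::png(png, width = 600, height = max(1, length(dep)) * 300)
    graphics::par(mfrow = c(max(1, length(dep)), 2), mar = c(1, 1, 2, 1))
    for (i in dep) {
      for (side in 1:2) {
        vol <- if (side == 1) native else templ
        co <- if (side == 1) tab@coords[i, ] else tab@warped[i, ]
        ttl <- sprintf("%s %s", tab@labels$short_id[i],
                       c("native", "template")[side])
        if (any(is.na(co))) {
          graphics::plot.new(); graphics::title(paste(ttl, "(not warped)"))
          next
        }
        vox <- roundHalfAway(worldToVoxel(vol, toScannerRAS(co, vol)))
        z <- min(max(vox[3] + 1, 1), dim(vol@data)[3])
        graphics::image(vol@data[, , z], col = grDevices::hcl.colors(64),
                        axes = FALSE, main = ttl, useRaster = TRUE)
        d <- dim(vol@data)
        graphics::abline(v = (vox[1] + 1) / d[1],
                         h = (vox[2] + 1) / d[2], col = "red")
      }
    }
    grDevices::dev.off()
    files <- png
  }
  invisible(files)
}

#' Refine electrode coordinates to the local CT intensity maximum
#'
#' Headless stand-in for interactive artifact centering: each coordinate is
#' snapped to the brightest CT voxel within `radius` mm (ties to the first
#' voxel in scan order), centering picks on the electrode artifact.
#'
#' @param coords K x 3 approximate coordinates (scanner RAS mm).
#' @param ct [BrainVolume-class] CT.
#' @param radius search radius, mm (default 3).
#' @return K x 3 refined coordinates.
#' @export
refineElectrodes <- function(coords, ct, radius = 3) {
  coords <- rbind(coords)
  d <- dim(ct@data)
  vox <- worldToVoxel(ct, coords)
  voxmm <- sqrt(colSums(ct@affine[1:3, 1:3]^2))
  rv <- ceiling(radius / min(voxmm))
  out <- coords
  for (i in seq_len(nrow(coords))) {
    ctr <- roundHalfAway(vox[i, ])
    rng <- lapply(1:3, function(k)
      max(0, ctr[k] - rv):min(d[k] - 1, ctr[k] + rv))
    cand <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
    w <- voxelToWorld(ct, cand)
    keep <- sqrt(rowSums(sweep(w, 2, coords[i, ])^2)) <= radius
    if (!any(keep)) next
    cand <- cand[keep, , drop = FALSE]
    vals <- ct@data[cand + 1L]
    out[i, ] <- voxelToWorld(ct, cand[which.max(vals), ])
  }
  out
}

#' Populate a subject directory with the synthetic fixture study
#'
#' Writes a complete synthetic subject (head phantom volumes, pial fixture
#' mesh + annotation, grid corner and depth electrode files, montage,
#' blob parcellation, identity spherical registration and a smooth warp
#' field) into a prepared `SubjectDir`, so the full pipeline
#' (register, interp-grid, project, elecs-all, label, subcort, warp, qc)
#' can run end to end without scanner data.
#'
#' @param sd a `SubjectDir` from [prepSubject()].
#' @param seed RNG seed driving every generator.
#' @param gridDim phantom/parcellation grid (default 96^3, 1 mm).
#' @param displacement rigid transform applied to the synthetic CT.
#' @return `sd`, invisibly.
#' @export
populateFixtureSubject <- function(sd, seed = 1L,
                                   gridDim = c(96L, 96L, 96L),
                                   displacement =
                                     RigidTransform(c(4, -3, 2),
                                                    c(3, -2, 1))) {
  hem <- sd$config$hem
  meshHem <- if (hem == "stereo") "lh" else hem
  parc <- makeParcellationFixture(gridDim = gridDim, seed = seed)
  # depth electrodes at the centers of four blobs that fall inside the
  # phantom's brain ellipsoid
  ctr <- attr(parc, "centers")
  ctrWorld <- voxelToWorld(parc@volume, ctr[, 2:4])
  a <- c(32, 42, 36)
  rho <- sqrt((ctrWorld[, 1] / a[1])^2 + (ctrWorld[, 2] / a[2])^2 +
              (ctrWorld[, 3] / a[3])^2)
  depthIds <- ctr[order(rho), 1][1:4]
  depth <- t(vapply(depthIds, function(id) {
    w <- which(parc@volume@data == id, arr.ind = TRUE) - 1L
    voxelToWorld(parc@volume, colMeans(w))
  }, numeric(3)))
  pf <- makePialFixture(nSubdiv = 3L, bumpiness = 2, radius = 40,
                        seed = seed)
  # 4x4 grid corners on a patch pulled 8 mm inside the pial sphere
  dir4 <- rbind(c(1, -0.25, -0.2), c(1, 0.25, -0.2),
                c(1, -0.25, 0.25), c(1, 0.25, 0.25))
  dir4 <- dir4 / sqrt(rowSums(dir4^2))
  corners <- dir4 * 32
  spec <- phantomSpec(gridDim = gridDim,
                      electrodes = rbind(corners, depth),
                      displacement = displacement, seed = seed)
  ph <- makeHeadPhantom(spec)
  writeVolume(ph$t1, sdPath(sd, "mri", "T1.nii"))
  writeVolume(ph$ct, sdPath(sd, "CT", "CT.nii"))
  writeTrivert(pf$pial, sdPath(sd, "Meshes",
                               paste0(meshHem, "_pial_trivert.txt")))
  writeAnnot(pf$annot, sdPath(sd, "Meshes",
                              paste0(meshHem, ".annot.csv")))
  writeLUT(pf$lut, sdPath(sd, "Meshes", "annot_lut.csv"))
  writeAnnot(pf$annot, sdPath(sd, "Meshes", "templ.annot.csv"))
  writeCoordTable(corners, sdPath(sd, "elecs", "hd_grid_corners.tsv"))
  writeCoordTable(depth, sdPath(sd, "elecs", "individual_elecs",
                                "amygdala_depth.tsv"))
  jsonlite::write_json(
    list(device_name = c("hd_grid", "amygdala_depth"),
         device_type = c("grid", "depth"),
         short_prefix = c("G", "AD"),
         long_template = c("LGridElectrode{n}", "LAmygdalaDepth{n}"),
         n_channels = c(16L, 4L)),
    sdPath(sd, "elecs", "montage.json"))
  writeVolume(parc@volume, sdPath(sd, "mri", "aparc+aseg.nii"))
  writeVolume(parc@volume, sdPath(sd, "mri", "templ_aseg.nii"))
  writeLUT(parc@lut, sdPath(sd, "mri", "aseg_lut.csv"))
  writeSphereReg(makeSphereRegFixture(pf), sdPath(sd, "Meshes",
                                                  "sphere_reg"))
  wf <- makeWarpFixture(gridDim = c(48L, 48L, 48L), voxelSize = 2,
                        amplitude = 1, seed = seed)
  writeWarpField(wf$field, sdPath(sd, "mri", "transforms",
                                  "warp_field.nii"))
  invisible(sd)
}
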