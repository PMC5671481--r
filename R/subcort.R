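#' Default subcortical structure set
#'
#' The 23 structures extracted by default from an aseg-style parcellation:
#' bilateral nucleus accumbens, amygdala, caudate, lateral and inferior
#' lateral ventricles, globus pallidus, hippocampus, putamen, thalamus and
#' ventral diencephalon, plus the midline brain stem and third and fourth
#' ventricles. Ids and colors follow the FreeSurfer color lookup table
#' (hippocampus = 17).
#'
#' @return data.frame with columns id, name, hemisphere, r, g, b.
#' @export
subcortStructures <- function() {
  read.table(system.file("extdata", "subcort_structures.csv",
                         package = "ElecLoc"),
             header = TRUE, sep = ",", stringsAsFactors = FALSE)
}

#' Binary mask of one parcellation label
#'
#' @param parc a [Parcellation-class].
#' @param labelId integer label id (must exist in the LUT).
#' @return binary [BrainVolume-class] (1 inside the structure). An empty
#'   mask triggers a warning, not an error.
#' @export
structureMask <- function(parc, labelId) {
  if (!labelId %in% parc@lut$id)
    stop("unknown label id: ", labelId)
  vol <- parc@volume
  m <- array(as.numeric(vol@data == labelId), dim(vol@data))
  if (sum(m) == 0)
    warning("label ", labelId, " absent from the volume (empty mask)")
  BrainVolume(m, vol@affine, vol@frame)
}

#' Triangle mesh of a binary mask by iso-surface extraction
#'
#' Runs marching tetrahedra at iso-level 0.5 on the (optionally Gaussian
#' pre-smoothed) mask and maps the resulting vertices through the volume
#' affine into surface RAS mm. Solid blobs yield closed genus-0 surfaces
#' (Euler characteristic 2); `smoothSigma = 0` gives the raw blocky
#' surface.
#'
#' @param mask binary [BrainVolume-class].
#' @param smoothSigma Gaussian pre-smoothing sigma in voxels (default 1).
#' @param frameRef volume defining the surface-RAS offset (default the
#'   mask itself).
#' @return a [TriMesh-class] in surface RAS mm.
#' @export
maskToMesh <- function(mask, smoothSigma = 1, frameRef = mask) {
  if (sum(mask@data != 0) == 0) stop("empty mask")
  dat <- mask@data
  if (smoothSigma > 0)
    dat <- array(.gaussianSmoothCpp(as.vector(dat), dim(dat), smoothSigma),
                 dim(dat))
  mc <- .marchingTetraCpp(as.vector(dat), dim(dat), 0.5)
  if (nrow(mc$vertices) == 0)
    stop("iso-surface is empty (mask vanished after smoothing)")
  world <- voxelToWorld(mask, mc$vertices)
  TriMesh(toSurfaceRAS(world, frameRef), mc$triangles - 1L)
}

#' Extract meshes for all subcortical structures
#'
#' One iso-surface mesh per structure present in the parcellation volume;
#' absent structures are skipped with a warning. Meshes carry their LUT
#' color as attribute `color` and are optionally written as trivert files
#' (`<Name>_subcort_trivert.txt`) plus a structure table CSV under
#' `outDir`.
#'
#' @param parc a [Parcellation-class].
#' @param structures structure set data.frame (default
#'   [subcortStructures()]).
#' @param smoothSigma pre-smoothing passed to [maskToMesh()].
#' @param outDir optional output directory (created if missing).
#' @return named list of [TriMesh-class], one per structure found.
#' @export
getSubcort <- function(parc, structures = subcortStructures(),
                       smoothSigma = 1, outDir = NULL) {
  present <- unique(as.vector(parc@volume@data))
  out <- list()
  for (i in seq_len(nrow(structures))) {
    id <- structures$id[i]
    nm <- structures$name[i]
    if (!id %in% present) {
      warning("structure ", nm, " (id ", id, ") absent; skipped")
      next
    }
    lut <- parc@lut
    if (!id %in% lut$id) lut <- rbind(lut[, c("id", "name")],
                                      data.frame(id = id, name = nm))
    m <- array(as.numeric(parc@volume@data == id), dim(parc@volume@data))
    mask <- BrainVolume(m, parc@volume@affine, parc@volume@frame)
    mesh <- maskToMesh(mask, smoothSigma = smoothSigma,
                       frameRef = parc@volume)
    attr(mesh, "color") <- c(r = structures$r[i], g = structures$g[i],
                             b = structures$b[i])
    out[[nm]] <- mesh
  }
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out))
      writeTrivert(out[[nm]],
                   file.path(outDir, paste0(nm, "_subcort_trivert.txt")))
    keep <- structures$name %in% names(out)
    write.table(structures[keep, , drop = FALSE],
                file.path(outDir, "subcort_structures.csv"),
                sep = ",", quote = FALSE, row.names = FALSE)
  }
  out
}
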