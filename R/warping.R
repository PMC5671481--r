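#' Apply an affine transform to coordinates, electrodes or meshes
#'
#' Homogeneous application of a 4x4 matrix (e.g. a talairach-style affine
#' read with [readXfm()]) to a coordinate matrix, an
#' [ElectrodeTable-class] (coordinates transformed, labels kept) or a
#' [TriMesh-class] (vertices transformed).
#'
#' @param x K x 3 matrix, [ElectrodeTable-class] or [TriMesh-class].
#' @param t [RigidTransform-class] or 4x4 matrix.
#' @return object of the same type with transformed coordinates.
#' @export
applyAffine <- function(x, t) {
  M <- if (is(t, "RigidTransform")) t@matrix else as.matrix(t)
  if (abs(det(M)) < 1e-12) stop("singular transform matrix")
  tx <- function(coords) {
    coords <- rbind(coords)
    t(M %*% rbind(t(coords), 1))[, 1:3, drop = FALSE]
  }
  if (is(x, "ElectrodeTable")) methods::initialize(x, coords = tx(x@coords))
  else if (is(x, "TriMesh")) TriMesh(tx(x@vertices), x@triangles)
  else tx(x)
}

#' Snap electrodes to their nearest mesh vertices
#'
#' Surface electrodes must sit on a pial vertex before spherical-
#' correspondence warping. Returns the Euclidean-nearest vertex per
#' electrode (ties to the lowest index) with the snap distances; a large
#' snap distance signals the wrong-gyrus failure mode (e.g. an STG
#' electrode snapping across the Sylvian fissure) and is flagged.
#'
#' @param elecs K x 3 electrode coordinates.
#' @param mesh a [TriMesh-class].
#' @param flagDist snap distance (mm) above which an electrode is flagged.
#' @return integer vector of 1-based vertex indices with attributes
#'   `distance` (mm) and `flagged` (logical).
#' @export
snapToSurface <- function(elecs, mesh, flagDist = 10) {
  if (nrow(mesh@vertices) == 0) stop("empty mesh")
  nn <- .nearestVertexCpp(rbind(elecs), mesh@vertices)
  structure(nn$index, distance = nn$distance,
            flagged = nn$distance > flagDist)
}

#' Warp surface electrodes through a spherical correspondence
#'
#' Per electrode: snap to the nearest subject pial vertex, take that
#' vertex's unit-sphere coordinate, find the template sphere vertex at the
#' smallest great-circle (angular) distance, and return the corresponding
#' template pial vertex coordinate. Every output is therefore an exact
#' template vertex position.
#'
#' @param elecs K x 3 electrode coordinates (subject surface RAS mm).
#' @param reg a [SphereReg-class].
#' @return K x 3 template-space coordinates with attributes `subjVertex`
#'   and `templVertex` (1-based indices).
#' @export
surfaceWarp <- function(elecs, reg) {
  si <- snapToSurface(elecs, reg@subjPial)
  sph <- reg@subjSphere[si, , drop = FALSE]
  # max cosine = min angle; ties at equal cosine go to the lowest index
  cosang <- sph %*% t(reg@templSphere)
  tj <- max.col(cosang, ties.method = "first")
  structure(reg@templPial@vertices[tj, , drop = FALSE],
            subjVertex = as.integer(si), templVertex = tj)
}

#' Warp depth electrodes through a dense displacement field
#'
#' Adds the trilinearly interpolated displacement (mm) at each electrode's
#' position in the field's voxel grid. Electrodes outside the field's
#' validity mask are passed through unchanged and flagged.
#'
#' @param elecs K x 3 electrode coordinates (mm, in the field's world
#'   frame).
#' @param field a [WarpField-class].
#' @param flagOutside warn when electrodes fall outside the mask.
#' @return K x 3 warped coordinates with attribute `outside` (logical).
#' @export
volumeWarp <- function(elecs, field, flagOutside = TRUE) {
  elecs <- rbind(elecs)
  d <- dim(field@displacement)[1:3]
  vox <- t(solve(field@affine) %*% rbind(t(elecs), 1))[, 1:3, drop = FALSE]
  vi <- roundHalfAway(vox)
  inb <- vi[, 1] >= 0 & vi[, 1] < d[1] &
         vi[, 2] >= 0 & vi[, 2] < d[2] &
         vi[, 3] >= 0 & vi[, 3] < d[3]
  valid <- inb
  valid[inb] <- field@mask[cbind(vi[inb, 1], vi[inb, 2], vi[inb, 3]) + 1L]
  disp <- matrix(0, nrow(elecs), 3)
  for (k in 1:3)
    disp[, k] <- .trilinearCpp(field@displacement[, , , k], d, vox,
                               0)$values
  disp[!valid, ] <- 0
  if (flagOutside && any(!valid))
    warning(sum(!valid), " electrode(s) outside the warp field mask; ",
            "passed through unchanged")
  structure(elecs + disp, outside = !valid)
}

#' Label-agreement QC for warped electrodes
#'
#' Relabels each warped electrode in template space (surface devices via
#' the nearest template-mesh vertex annotation, depths via the template
#' parcellation voxel) and compares against the native anatomy labels.
#' Mismatches (the hippocampus-to-cerebellum style warp failure) are
#' listed first.
#'
#' @param table a labeled [ElectrodeTable-class] (native space).
#' @param warpedCoords K x 3 warped coordinates.
#' @param templMesh template pial [TriMesh-class].
#' @param templAnnot per-vertex label ids for `templMesh`.
#' @param templLUT lookup table for the template surface annotation.
#' @param templParc template [Parcellation-class] for depths.
#' @return data.frame (short_id, device_type, native, warped, agree),
#'   mismatches first, with attribute `agreement` = fraction agreeing.
#' @export
checkWarpLabels <- function(table, warpedCoords, templMesh, templAnnot,
                            templLUT, templParc) {
  lab <- table@labels
  if (!"anatomy" %in% names(lab))
    stop("table has no anatomy column; label it first")
  warpedCoords <- rbind(warpedCoords)
  k <- nrow(lab)
  warped <- character(k)
  surf <- lab$device_type %in% c("grid", "strip")
  ok <- stats::complete.cases(warpedCoords)
  if (any(surf & ok))
    warped[surf & ok] <- labelSurface(warpedCoords[surf & ok, , drop = FALSE],
                                      templMesh, templAnnot, templLUT)
  if (any(!surf & ok))
    warped[!surf & ok] <- labelDepth(warpedCoords[!surf & ok, , drop = FALSE],
                                     templParc)
  warped[!ok] <- NA_character_
  qc <- data.frame(short_id = lab$short_id, device_type = lab$device_type,
                   native = lab$anatomy, warped = warped,
                   agree = !is.na(warped) & warped == lab$anatomy,
                   stringsAsFactors = FALSE)
  qc <- qc[order(qc$agree), , drop = FALSE]
  rownames(qc) <- NULL
  structure(qc, agreement = mean(qc$agree))
}

#' Warp a full electrode table to template space
#'
#' Dispatches grid/strip rows to [surfaceWarp()] and depth rows to
#' [volumeWarp()], appends the warped coordinates as a parallel block
#' (native coordinates are never overwritten) and, when template label
#' resources are supplied, attaches the [checkWarpLabels()] QC report.
#' Electrodes listed in `drop` get no warped coordinate (the remedy for a
#' mis-warped electrode); `override` replaces individual warped
#' coordinates with manually chosen template-space positions.
#'
#' @param table a labeled [ElectrodeTable-class].
#' @param reg [SphereReg-class] for surface devices.
#' @param field [WarpField-class] for depth devices.
#' @param subset `"all"`, `"surface"` or `"depth"`.
#' @param templMesh,templAnnot,templLUT,templParc template resources for
#'   the QC report (all optional).
#' @param drop character vector of short_ids to exclude from warping.
#' @param override named list of short_id -> length-3 template coordinate.
#' @return the table with its `warped` block filled; attribute `qc` holds
#'   the label-agreement report when template resources were given.
#' @export
warpAll <- function(table, reg = NULL, field = NULL,
                    subset = c("all", "surface", "depth"),
                    templMesh = NULL, templAnnot = NULL, templLUT = NULL,
                    templParc = NULL, drop = character(0),
                    override = list()) {
  subset <- match.arg(subset)
  lab <- table@labels
  if (is.null(lab$device_type)) stop("device_type column required")
  k <- nrow(lab)
  warped <- matrix(NA_real_, k, 3)
  surf <- lab$device_type %in% c("grid", "strip")
  doSurf <- surf & subset != "depth" & !(lab$short_id %in% drop)
  doDepth <- !surf & subset != "surface" & !(lab$short_id %in% drop)
  if (any(doSurf)) {
    if (is.null(reg)) stop("surface warp requested but no SphereReg given")
    warped[doSurf, ] <- surfaceWarp(table@coords[doSurf, , drop = FALSE],
                                    reg)
  }
  if (any(doDepth)) {
    if (is.null(field)) stop("depth warp requested but no WarpField given")
    warped[doDepth, ] <- volumeWarp(table@coords[doDepth, , drop = FALSE],
                                    field)
  }
  for (nm in names(override)) {
    i <- match(nm, lab$short_id)
    if (is.na(i)) stop("override for unknown electrode ", nm)
    warped[i, ] <- override[[nm]]
  }
  out <- methods::initialize(table, warped = warped)
  if (!is.null(templMesh) && !is.null(templParc) &&
      "anatomy" %in% names(lab)) {
    attr(out, "qc") <- checkWarpLabels(table, warped, templMesh,
                                       templAnnot, templLUT, templParc)
  }
  out
}
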