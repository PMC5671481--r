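#' @import methods
#' @importFrom stats optim rnorm runif setNames aggregate
#' @importFrom utils read.table write.table head tail
#' @useDynLib ElecLoc, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("integerOrNULL", c("integer", "NULL"))

#' 3D scalar volume with a voxel-to-world affine
#'
#' A scalar grid plus a 4x4 affine mapping 0-based voxel indices (at voxel
#' centers) to world coordinates in mm. `frame` records whether world
#' coordinates are scanner RAS or surface RAS (scanner RAS shifted so the
#' volume's geometric center is the origin).
#'
#' @slot data 3D numeric array.
#' @slot affine 4x4 voxel-to-world matrix (mm, RAS).
#' @slot frame `"scanner_ras"` or `"surface_ras"`.
#' @export
setClass("BrainVolume",
  representation(data = "array", affine = "matrix", frame = "character"))

setValidity("BrainVolume", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3D array")
  if (any(d < 2L)) return("each axis needs at least 2 voxels")
  if (!all(dim(object@affine) == c(4L, 4L))) return("affine must be 4x4")
  det <- try(det(object@affine[1:3, 1:3]), silent = TRUE)
  if (inherits(det, "try-error") || !is.finite(det) || abs(det) < 1e-12)
    return("affine is not invertible")
  if (!object@frame %in% c("scanner_ras", "surface_ras"))
    return("frame must be 'scanner_ras' or 'surface_ras'")
  TRUE
})

#' @param data,affine,frame see slots.
#' @rdname BrainVolume-class
#' @export
BrainVolume <- function(data, affine = diag(4), frame = "scanner_ras") {
  new("BrainVolume", data = data, affine = affine, frame = frame)
}

#' Triangle mesh in surface RAS mm
#'
#' Vertices are an N x 3 coordinate matrix (surface RAS, mm); triangles are
#' an M x 3 matrix of 0-based vertex indices, matching the on-disk trivert
#' convention.
#'
#' @slot vertices N x 3 numeric matrix.
#' @slot triangles M x 3 integer matrix, 0-based.
#' @export
setClass("TriMesh",
  representation(vertices = "matrix", triangles = "matrix"))

setValidity("TriMesh", function(object) {
  if (ncol(object@vertices) != 3L) return("vertices must be N x 3")
  if (nrow(object@triangles) > 0) {
    if (ncol(object@triangles) != 3L) return("triangles must be M x 3")
    tr <- object@triangles
    if (min(tr) < 0 || max(tr) >= nrow(object@vertices))
      return("triangle index out of range")
    if (any(tr[, 1] == tr[, 2] | tr[, 1] == tr[, 3] | tr[, 2] == tr[, 3]))
      return("degenerate triangle (repeated vertex index)")
  }
  TRUE
})

#' @param vertices,triangles see slots; `triangles` are 0-based indices.
#' @rdname TriMesh-class
#' @export
TriMesh <- function(vertices, triangles) {
  mode(triangles) <- "integer"
  new("TriMesh",
      vertices = as.matrix(vertices),
      triangles = as.matrix(triangles))
}

#' Montage-ordered electrode table
#'
#' Mirrors the elecs_all layout: `coords` is the K x 3 elecmatrix in surface
#' RAS mm; `labels` carries one row per electrode with columns `short_id`,
#' `long_id`, `device_type` (grid/strip/depth) and, after anatomical
#' labeling, `anatomy`. A parallel `warped` coordinate block (template
#' space) is attached by [warpAll()]; rows not warped are `NA`.
#'
#' @slot coords K x 3 numeric matrix (elecmatrix).
#' @slot labels data.frame of per-electrode descriptors (eleclabels).
#' @slot zeroIndexed logical; whether channel numbering starts at 0.
#' @slot warped K x 3 matrix of template-space coordinates, or NULL.
#' @slot provenance list of recorded edits.
#' @export
setClass("ElectrodeTable",
  representation(coords = "matrix", labels = "data.frame",
                 zeroIndexed = "logical", warped = "matrixOrNULL",
                 provenance = "list"))

setValidity("ElectrodeTable", function(object) {
  k <- nrow(object@coords)
  if (ncol(object@coords) != 3L) return("coords must be K x 3")
  if (nrow(object@labels) != k) return("labels and coords row counts differ")
  need <- c("short_id", "long_id", "device_type")
  if (!all(need %in% names(object@labels)))
    return("labels needs short_id, long_id, device_type")
  if (anyDuplicated(object@labels$short_id)) return("short_id not unique")
  if (anyDuplicated(object@labels$long_id)) return("long_id not unique")
  if (!all(object@labels$device_type %in% c("grid", "strip", "depth")))
    return("device_type must be grid, strip or depth")
  if (!is.null(object@warped) &&
      !all(dim(object@warped) == c(k, 3L)))
    return("warped block must be K x 3")
  TRUE
})

#' @param coords,labels,zeroIndexed,warped see slots.
#' @rdname ElectrodeTable-class
#' @export
ElectrodeTable <- function(coords, labels, zeroIndexed = TRUE,
                           warped = NULL) {
  labels <- as.data.frame(labels, stringsAsFactors = FALSE)
  new("ElectrodeTable", coords = as.matrix(coords), labels = labels,
      zeroIndexed = zeroIndexed, warped = warped, provenance = list())
}

#' Six-parameter rigid-body transform
#'
#' Translation in mm, rotation as intrinsic x-y-z Euler angles in degrees
#' applied about `center` (world mm), with the derived 4x4 homogeneous
#' world-to-world matrix.
#'
#' @slot translation length-3 numeric, mm.
#' @slot rotation length-3 numeric, degrees (x, y, z).
#' @slot center length-3 numeric, rotation center in world mm.
#' @slot matrix derived 4x4 matrix.
#' @export
setClass("RigidTransform",
  representation(translation = "numeric", rotation = "numeric",
                 center = "numeric", matrix = "matrix"))

rigidMatrix <- function(translation, rotation, center = c(0, 0, 0)) {
  a <- rotation * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  R <- Rx %*% Ry %*% Rz
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- translation + center - R %*% center
  m
}

setValidity("RigidTransform", function(object) {
  if (length(object@translation) != 3L || length(object@rotation) != 3L ||
      length(object@center) != 3L)
    return("translation, rotation and center must have length 3")
  R <- object@matrix[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    return("rotation block not orthonormal")
  if (det(R) < 0) return("rotation block has negative determinant")
  ref <- rigidMatrix(object@translation, object@rotation, object@center)
  if (max(abs(ref - object@matrix)) > 1e-9)
    return("matrix inconsistent with parameters")
  TRUE
})

#' @param translation,rotation,center see slots.
#' @rdname RigidTransform-class
#' @export
RigidTransform <- function(translation = c(0, 0, 0),
                           rotation = c(0, 0, 0),
                           center = c(0, 0, 0)) {
  new("RigidTransform", translation = as.numeric(translation),
      rotation = as.numeric(rotation), center = as.numeric(center),
      matrix = rigidMatrix(translation, rotation, center))
}

#' Integer-labeled parcellation with lookup table
#'
#' An integer label volume (aseg/aparc+aseg style) plus a lookup table
#' mapping label ids to structure names and RGB colors, and optionally a
#' per-vertex annotation for a companion cortical mesh.
#'
#' @slot volume [BrainVolume-class] of integer labels.
#' @slot lut data.frame with columns id, name, r, g, b.
#' @slot annot integer vector of per-vertex label ids, or NULL.
#' @export
setClass("Parcellation",
  representation(volume = "BrainVolume", lut = "data.frame",
                 annot = "integerOrNULL"))

setValidity("Parcellation", function(object) {
  if (!all(c("id", "name") %in% names(object@lut)))
    return("lut needs id and name columns")
  ids <- unique(as.vector(object@volume@data))
  ids <- ids[ids != 0]
  if (!all(ids %in% object@lut$id))
    return("volume contains label ids missing from the lut")
  TRUE
})

#' @param volume,lut,annot see slots.
#' @rdname Parcellation-class
#' @export
Parcellation <- function(volume, lut, annot = NULL) {
  if (!is.null(annot)) annot <- as.integer(annot)
  new("Parcellation", volume = volume,
      lut = as.data.frame(lut, stringsAsFactors = FALSE), annot = annot)
}

#' Geometry of a rectangular electrode grid
#'
#' Derived from the four manually localized corner electrodes, given in
#' channel order (corner 1 = channel 1, corner 2 = channel ncols, corner 3 =
#' channel (nrows-1)*ncols+1, corner 4 = channel nrows*ncols). Holds the
#' four directed outline edges, the four sign-consistent corner normals and
#' their normalized mean, which is the projection direction for subdural
#' grids.
#'
#' @slot corners 4 x 3 matrix, mm.
#' @slot nrows,ncols grid dimensions.
#' @slot outline 4 x 3 matrix of directed edge vectors.
#' @slot cornerNormals 4 x 3 matrix of unit normals.
#' @slot meanNormal unit length-3 vector.
#' @export
setClass("GridFrame",
  representation(corners = "matrix", nrows = "integer", ncols = "integer",
                 outline = "matrix", cornerNormals = "matrix",
                 meanNormal = "numeric"))

setValidity("GridFrame", function(object) {
  if (abs(sqrt(sum(object@meanNormal^2)) - 1) > 1e-8)
    return("meanNormal not unit length")
  n2 <- rowSums(object@cornerNormals^2)
  if (any(abs(sqrt(n2) - 1) > 1e-8))
    return("corner normals not unit length")
  TRUE
})

#' Dural (projection target) surface
#'
#' A watertight envelope over the pial surface: the exact convex hull, a
#' subdivided and Taubin-smoothed hull, or the hull of a label-restricted
#' vertex subset (orbitofrontal variant excluding temporal-lobe labels).
#'
#' @slot mesh [TriMesh-class].
#' @slot kind `"convex_hull"`, `"smoothed_hull"` or `"ofc_submesh"`.
#' @export
setClass("DuralSurface",
  representation(mesh = "TriMesh", kind = "character"))

setValidity("DuralSurface", function(object) {
  if (!object@kind %in% c("convex_hull", "smoothed_hull", "ofc_submesh"))
    return("unknown dural surface kind")
  TRUE
})

#' Paired spherical registration of subject and template surfaces
#'
#' Subject and template pial meshes with per-vertex unit-sphere coordinates
#' (subject vertex i pairs with subjSphere row i, likewise for the
#' template), the correspondence used for surface electrode warping.
#'
#' @slot subjPial,templPial [TriMesh-class] pial surfaces.
#' @slot subjSphere,templSphere per-vertex unit-sphere coordinate matrices.
#' @export
setClass("SphereReg",
  representation(subjPial = "TriMesh", subjSphere = "matrix",
                 templPial = "TriMesh", templSphere = "matrix"))

setValidity("SphereReg", function(object) {
  if (nrow(object@subjSphere) != nrow(object@subjPial@vertices))
    return("subject sphere/pial vertex counts differ")
  if (nrow(object@templSphere) != nrow(object@templPial@vertices))
    return("template sphere/pial vertex counts differ")
  r1 <- sqrt(rowSums(object@subjSphere^2))
  r2 <- sqrt(rowSums(object@templSphere^2))
  if (max(abs(c(r1, r2) - 1)) > 1e-6)
    return("sphere coordinates not unit length")
  TRUE
})

#' @param subjPial,subjSphere,templPial,templSphere see slots. Sphere
#'   coordinates are renormalized to unit length.
#' @rdname SphereReg-class
#' @export
SphereReg <- function(subjPial, subjSphere, templPial, templSphere) {
  nrm <- function(m) m / sqrt(rowSums(m^2))
  new("SphereReg", subjPial = subjPial, subjSphere = nrm(as.matrix(subjSphere)),
      templPial = templPial, templSphere = nrm(as.matrix(templSphere)))
}

#' Dense displacement field (native to template), mm
#'
#' A 3-component displacement sampled on a voxel grid, with a validity
#' mask. Applied to depth electrodes by [volumeWarp()]; producing such a
#' field (combined volumetric/surface registration) is upstream of this
#' package.
#'
#' @slot displacement 4D array (X x Y x Z x 3), mm.
#' @slot affine 4x4 voxel-to-world matrix of the sampling grid.
#' @slot mask logical 3D array of valid voxels.
#' @export
setClass("WarpField",
  representation(displacement = "array", affine = "matrix", mask = "array"))

setValidity("WarpField", function(object) {
  d <- dim(object@displacement)
  if (length(d) != 4L || d[4] != 3L)
    return("displacement must be X x Y x Z x 3")
  if (!all(dim(object@mask) == d[1:3]))
    return("mask dimensions differ from displacement grid")
  if (any(!is.finite(object@displacement[rep(object@mask, 3)])))
    return("non-finite displacement inside mask")
  TRUE
})

#' @param displacement,affine,mask see slots; `mask` defaults to all-valid.
#' @rdname WarpField-class
#' @export
WarpField <- function(displacement, affine = diag(4), mask = NULL) {
  if (is.null(mask))
    mask <- array(TRUE, dim = dim(displacement)[1:3])
  new("WarpField", displacement = displacement, affine = affine,
      mask = mask)
}
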