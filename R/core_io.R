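#' Read a NIfTI-1 volume, normalized to RAS voxel order
#'
#' Loads a NIfTI-1 file, reorders the data so the voxel axes run
#' left-to-Right, posterior-to-Anterior, inferior-to-Superior (positive
#' diagonal affine directions), and returns a [BrainVolume-class] in the
#' scanner-RAS frame. Voxel indices are 0-based and map through the affine
#' at voxel centers.
#'
#' @param path path to a `.nii`/`.nii.gz` file.
#' @return A [BrainVolume-class].
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("unreadable volume: file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable volume: ", path,
                                           " (", conditionMessage(e), ")"))
  if (length(dim(img)) != 3L)
    stop("unreadable volume: expected a 3D image: ", path)
  xf <- RNifti::xform(img)
  if (attr(xf, "code") > 0 && RNifti::orientation(img) != "RAS")
    RNifti::orientation(img) <- "RAS"
  # RNifti xforms place 0-based voxel (0,0,0) at the translation column,
  # matching this package's voxel convention
  aff <- structure(as.matrix(RNifti::xform(img))[1:4, 1:4], dimnames = NULL)
  dat <- array(as.numeric(img), dim = dim(img))
  BrainVolume(dat, aff, frame = "scanner_ras")
}

#' Write a volume as NIfTI-1
#'
#' @param vol a [BrainVolume-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path) {
  img <- RNifti::asNifti(vol@data)
  aff <- vol@affine
  RNifti::pixdim(img) <- sqrt(colSums(aff[1:3, 1:3]^2))
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Voxel/world coordinate conversion
#'
#' Maps 0-based voxel indices through the volume affine (`voxelToWorld`) or
#' back (`worldToVoxel`; fractional voxel coordinates are returned).
#'
#' @param vol a [BrainVolume-class].
#' @param ijk,xyz length-3 vector or N x 3 matrix.
#' @return matrix (or vector, matching the input shape) of coordinates.
#' @export
voxelToWorld <- function(vol, ijk) {
  v <- is.null(dim(ijk))
  ijk <- rbind(ijk)
  out <- t(vol@affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
  if (v) drop(out) else out
}

#' @rdname voxelToWorld
#' @export
worldToVoxel <- function(vol, xyz) {
  v <- is.null(dim(xyz))
  xyz <- rbind(xyz)
  out <- t(solve(vol@affine) %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
  if (v) drop(out) else out
}

#' Surface-RAS offset of a volume
#'
#' Surface RAS is scanner RAS recentered on the volume's geometric center
#' (the FreeSurfer c_ras convention): subtracting the returned offset from
#' scanner-RAS coordinates yields surface-RAS coordinates. The offset is
#' the world coordinate of the center voxel `(dim - 1) / 2`.
#'
#' @param vol a [BrainVolume-class].
#' @return length-3 numeric vector, mm.
#' @export
surfaceRASOffset <- function(vol) {
  voxelToWorld(vol, (dim(vol@data) - 1) / 2)
}

#' Convert coordinates between scanner RAS and surface RAS
#'
#' @param coords K x 3 matrix or length-3 vector.
#' @param vol the reference [BrainVolume-class].
#' @return coordinates in the other frame, same shape as the input.
#' @export
toSurfaceRAS <- function(coords, vol) {
  off <- surfaceRASOffset(vol)
  if (is.null(dim(coords))) coords - off
  else sweep(coords, 2, off)
}

#' @rdname toSurfaceRAS
#' @export
toScannerRAS <- function(coords, vol) {
  off <- surfaceRASOffset(vol)
  if (is.null(dim(coords))) coords + off
  else sweep(coords, 2, off, "+")
}

fmtNum <- function(x) sprintf("%.17g", x)

#' Read/write trivert mesh containers
#'
#' The trivert container stores the two arrays of a triangle mesh under the
#' names `vert` (vertex coordinates, surface RAS mm, float64) and `tri`
#' (0-based triangle indices), here as a plain-text file:
#' a `trivert 1` header line, a `vert <N>` / `tri <M>` count line, then N
#' coordinate rows and M index rows. Round trips are lossless (coordinates
#' written with 17 significant digits).
#'
#' @param mesh a [TriMesh-class].
#' @param path file path (conventionally `*_trivert.txt`).
#' @return `readTrivert` returns a [TriMesh-class].
#' @export
writeTrivert <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("trivert 1",
               sprintf("vert %d tri %d", nrow(mesh@vertices),
                       nrow(mesh@triangles))), con)
  writeLines(apply(mesh@vertices, 1,
                   function(r) paste(fmtNum(r), collapse = " ")), con)
  if (nrow(mesh@triangles) > 0)
    writeLines(apply(mesh@triangles, 1, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname writeTrivert
#' @export
readTrivert <- function(path) {
  ln <- readLines(path)
  if (length(ln) < 2L || !startsWith(ln[1], "trivert"))
    stop("malformed trivert: ", path)
  cnt <- as.integer(strsplit(ln[2], "\\s+")[[1]][c(2, 4)])
  nv <- cnt[1]; nt <- cnt[2]
  if (length(ln) < 2 + nv + nt) stop("malformed trivert: ", path)
  vert <- matrix(as.numeric(unlist(strsplit(ln[3:(2 + nv)], "\\s+"))),
                 ncol = 3, byrow = TRUE)
  tri <- if (nt > 0)
    matrix(as.integer(unlist(strsplit(ln[(3 + nv):(2 + nv + nt)], "\\s+"))),
           ncol = 3, byrow = TRUE)
  else matrix(integer(0), 0, 3)
  if (nt > 0 && (min(tri) < 0 || max(tri) >= nv))
    stop("malformed trivert: triangle index out of range in ", path)
  TriMesh(vert, tri)
}

#' Read/write plain coordinate tables
#'
#' Tab-separated x/y/z coordinate lists (mm), used for manually identified
#' electrode and grid-corner files.
#'
#' @param coords K x 3 matrix.
#' @param path file path.
#' @return `readCoordTable` returns a K x 3 matrix.
#' @export
writeCoordTable <- function(coords, path) {
  coords <- rbind(coords)
  df <- data.frame(x = fmtNum(coords[, 1]), y = fmtNum(coords[, 2]),
                   z = fmtNum(coords[, 3]))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCoordTable
#' @export
readCoordTable <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  unname(as.matrix(df[, c("x", "y", "z")]))
}

#' Read/write electrode tables
#'
#' Serializes an [ElectrodeTable-class] as tab-separated text with the
#' elecmatrix coordinates (columns x/y/z), the eleclabels descriptor columns
#' (short_id, long_id, device_type, and anatomy once labeled), the
#' zero-indexing flag, and, when present, the warped coordinate block
#' (columns xw/yw/zw, `NA` for rows without a warp).
#'
#' @param table an [ElectrodeTable-class].
#' @param path file path.
#' @return `readElectrodes` returns an [ElectrodeTable-class].
#' @export
writeElectrodes <- function(table, path) {
  lab <- table@labels
  df <- data.frame(short_id = lab$short_id, long_id = lab$long_id,
                   device_type = lab$device_type,
                   stringsAsFactors = FALSE)
  if ("anatomy" %in% names(lab)) df$anatomy <- lab$anatomy
  df$x <- fmtNum(table@coords[, 1])
  df$y <- fmtNum(table@coords[, 2])
  df$z <- fmtNum(table@coords[, 3])
  if (!is.null(table@warped)) {
    w <- table@warped
    fw <- function(v) ifelse(is.na(v), "NA", fmtNum(v))
    df$xw <- fw(w[, 1]); df$yw <- fw(w[, 2]); df$zw <- fw(w[, 3])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# elecstable 1",
               paste("# zero_indexed", table@zeroIndexed)), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' @rdname writeElectrodes
#' @export
readElectrodes <- function(path) {
  hdr <- readLines(path, n = 2)
  zi <- TRUE
  if (length(hdr) >= 2 && startsWith(hdr[2], "# zero_indexed"))
    zi <- as.logical(sub("# zero_indexed ", "", hdr[2]))
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  coords <- unname(as.matrix(df[, c("x", "y", "z")]))
  labcols <- intersect(c("short_id", "long_id", "device_type", "anatomy"),
                       names(df))
  warped <- NULL
  if (all(c("xw", "yw", "zw") %in% names(df)))
    warped <- unname(as.matrix(df[, c("xw", "yw", "zw")]))
  ElectrodeTable(coords, df[, labcols, drop = FALSE], zeroIndexed = zi,
                 warped = warped)
}

#' Read/write plain-text affine transforms
#'
#' The talairach.xfm dialect: a short header, then `Linear_Transform =`
#' followed by three whitespace-separated rows of the upper 3 x 4 block,
#' terminated by `;`.
#'
#' @param m a 4x4 matrix or [RigidTransform-class].
#' @param path file path.
#' @return `readXfm` returns a 4x4 matrix.
#' @export
writeXfm <- function(m, path) {
  if (is(m, "RigidTransform")) m <- m@matrix
  rows <- apply(m[1:3, ], 1, function(r) paste(fmtNum(r), collapse = " "))
  rows[3] <- paste0(rows[3], ";")
  writeLines(c("MNI Transform File",
               "% written by ElecLoc", "",
               "Transform_Type = Linear;",
               "Linear_Transform =", rows), path)
  invisible(path)
}

#' @rdname writeXfm
#' @export
readXfm <- function(path) {
  ln <- readLines(path)
  i <- grep("Linear_Transform", ln)
  if (length(i) == 0) stop("no Linear_Transform block in ", path)
  body <- paste(ln[(i[1] + 1):length(ln)], collapse = " ")
  vals <- as.numeric(strsplit(gsub(";", "", trimws(body)), "\\s+")[[1]])
  if (length(vals) < 12 || any(!is.finite(vals[1:12])))
    stop("malformed xfm file: ", path)
  rbind(matrix(vals[1:12], nrow = 3, byrow = TRUE), c(0, 0, 0, 1))
}

#' Read a color lookup table
#'
#' CSV with columns `id,name,r,g,b` in the style of the FreeSurfer color
#' lookup table.
#'
#' @param path CSV path.
#' @return data.frame with columns id, name, r, g, b.
#' @export
readLUT <- function(path) {
  read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
}

#' @rdname readLUT
#' @param lut data.frame with columns id, name, r, g, b.
#' @export
writeLUT <- function(lut, path) {
  write.table(lut, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write per-vertex annotations
#'
#' CSV sidecar with columns `vertex_id` (0-based) and `label_id`, paired
#' with a LUT for label names.
#'
#' @param annot integer vector of label ids, one per vertex.
#' @param path CSV path.
#' @return `readAnnot` returns an integer vector ordered by vertex.
#' @export
writeAnnot <- function(annot, path) {
  write.table(data.frame(vertex_id = seq_along(annot) - 1L,
                         label_id = annot),
              path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAnnot
#' @export
readAnnot <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",")
  as.integer(df$label_id[order(df$vertex_id)])
}

#' Read/write dense displacement fields as 4D NIfTI
#'
#' Three displacement components (mm) in the 4th dimension; voxels outside
#' the validity mask are stored as NaN.
#'
#' @param field a [WarpField-class].
#' @param path `.nii` path.
#' @return `readWarpField` returns a [WarpField-class].
#' @export
writeWarpField <- function(field, path) {
  d <- field@displacement
  bad <- !field@mask
  if (any(bad)) for (k in 1:3) {
    comp <- d[, , , k]; comp[bad] <- NaN; d[, , , k] <- comp
  }
  img <- RNifti::asNifti(d)
  aff <- field@affine
  # RNifti regenerates ND pixdims on write, so set them explicitly
  RNifti::pixdim(img) <- c(sqrt(colSums(aff[1:3, 1:3]^2)), 1)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeWarpField
#' @export
readWarpField <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L || dim(img)[4] != 3L)
    stop("warp field must be a 4D NIfTI with 3 components: ", path)
  aff <- structure(as.matrix(RNifti::xform(img))[1:4, 1:4], dimnames = NULL)
  d <- array(as.numeric(img), dim = dim(img))
  mask <- apply(is.finite(d), 1:3, all)
  d[!is.finite(d)] <- 0
  WarpField(d, aff, mask)
}

#' Read/write a spherical registration directory
#'
#' A [SphereReg-class] is stored as four plain-text arrays in a directory:
#' `subj_pial_trivert.txt`, `templ_pial_trivert.txt` (trivert meshes) and
#' `subj_sphere.tsv`, `templ_sphere.tsv` (per-vertex unit-sphere
#' coordinates).
#'
#' @param reg a [SphereReg-class].
#' @param dir directory path (created if missing).
#' @return `readSphereReg` returns a [SphereReg-class].
#' @export
writeSphereReg <- function(reg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeTrivert(reg@subjPial, file.path(dir, "subj_pial_trivert.txt"))
  writeTrivert(reg@templPial, file.path(dir, "templ_pial_trivert.txt"))
  writeCoordTable(reg@subjSphere, file.path(dir, "subj_sphere.tsv"))
  writeCoordTable(reg@templSphere, file.path(dir, "templ_sphere.tsv"))
  invisible(dir)
}

#' @rdname writeSphereReg
#' @export
readSphereReg <- function(dir) {
  SphereReg(readTrivert(file.path(dir, "subj_pial_trivert.txt")),
            readCoordTable(file.path(dir, "subj_sphere.tsv")),
            readTrivert(file.path(dir, "templ_pial_trivert.txt")),
            readCoordTable(file.path(dir, "templ_sphere.tsv")))
}
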