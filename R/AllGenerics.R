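#' Accessors for ElecLoc classes
#'
#' Small accessor generics: `volData`/`volAffine`/`volFrame` for
#' [BrainVolume-class]; `vertices`/`triangles` for [TriMesh-class]
#' (`triangles(x, one_based = TRUE)` returns R-style indices);
#' `elecMatrix`/`elecLabels`/`zeroIndexed`/`warpedMatrix` for
#' [ElectrodeTable-class]; `parcVolume`/`parcLUT`/`parcAnnot` for
#' [Parcellation-class]; `duralMesh` for [DuralSurface-class];
#' `meanNormal` for [GridFrame-class].
#'
#' @param x an ElecLoc object.
#' @param ... passed to methods.
#' @return The corresponding slot (possibly converted; see above).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
#' @rdname accessors
#' @export
setGeneric("volAffine", function(x) standardGeneric("volAffine"))
#' @rdname accessors
#' @export
setGeneric("volFrame", function(x) standardGeneric("volFrame"))
#' @rdname accessors
#' @export
setGeneric("vertices", function(x, ...) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setGeneric("triangles", function(x, ...) standardGeneric("triangles"))
#' @rdname accessors
#' @export
setGeneric("elecMatrix", function(x) standardGeneric("elecMatrix"))
#' @rdname accessors
#' @export
setGeneric("elecLabels", function(x) standardGeneric("elecLabels"))
#' @rdname accessors
#' @export
setGeneric("zeroIndexed", function(x) standardGeneric("zeroIndexed"))
#' @rdname accessors
#' @export
setGeneric("warpedMatrix", function(x) standardGeneric("warpedMatrix"))
#' @rdname accessors
#' @export
setGeneric("parcVolume", function(x) standardGeneric("parcVolume"))
#' @rdname accessors
#' @export
setGeneric("parcLUT", function(x) standardGeneric("parcLUT"))
#' @rdname accessors
#' @export
setGeneric("parcAnnot", function(x) standardGeneric("parcAnnot"))
#' @rdname accessors
#' @export
setGeneric("duralMesh", function(x) standardGeneric("duralMesh"))
#' @rdname accessors
#' @export
setGeneric("meanNormal", function(x) standardGeneric("meanNormal"))

#' @rdname accessors
setMethod("volData", "BrainVolume", function(x) x@data)
#' @rdname accessors
setMethod("volAffine", "BrainVolume", function(x) x@affine)
#' @rdname accessors
setMethod("volFrame", "BrainVolume", function(x) x@frame)
#' @rdname accessors
setMethod("vertices", "TriMesh", function(x) x@vertices)

#' @param one_based return 1-based (R) rather than 0-based indices.
#' @rdname accessors
setMethod("triangles", "TriMesh", function(x, one_based = FALSE) {
  if (one_based) x@triangles + 1L else x@triangles
})

#' @rdname accessors
setMethod("elecMatrix", "ElectrodeTable", function(x) x@coords)
#' @rdname accessors
setMethod("elecLabels", "ElectrodeTable", function(x) x@labels)
#' @rdname accessors
setMethod("zeroIndexed", "ElectrodeTable", function(x) x@zeroIndexed)
#' @rdname accessors
setMethod("warpedMatrix", "ElectrodeTable", function(x) x@warped)
#' @rdname accessors
setMethod("parcVolume", "Parcellation", function(x) x@volume)
#' @rdname accessors
setMethod("parcLUT", "Parcellation", function(x) x@lut)
#' @rdname accessors
setMethod("parcAnnot", "Parcellation", function(x) x@annot)
#' @rdname accessors
setMethod("duralMesh", "DuralSurface", function(x) x@mesh)
#' @rdname accessors
setMethod("meanNormal", "GridFrame", function(x) x@meanNormal)

#' @describeIn BrainVolume-class grid dimensions.
#' @param x a `BrainVolume`.
#' @export
setMethod("dim", "BrainVolume", function(x) dim(x@data))

#' @describeIn ElectrodeTable-class number of electrodes.
#' @export
setMethod("length", "ElectrodeTable", function(x) nrow(x@coords))

#' @describeIn RigidTransform-class the 4x4 homogeneous matrix.
#' @param x a `RigidTransform`.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "RigidTransform", function(x, ...) x@matrix)

setMethod("show", "BrainVolume", function(object) {
  d <- dim(object@data)
  vox <- sqrt(colSums(object@affine[1:3, 1:3]^2))
  cat(sprintf("BrainVolume %dx%dx%d voxels, %.3gx%.3gx%.3g mm, frame %s\n",
              d[1], d[2], d[3], vox[1], vox[2], vox[3], object@frame))
})

setMethod("show", "TriMesh", function(object) {
  cat(sprintf("TriMesh with %d vertices, %d triangles\n",
              nrow(object@vertices), nrow(object@triangles)))
})

setMethod("show", "ElectrodeTable", function(object) {
  k <- nrow(object@coords)
  cat(sprintf("ElectrodeTable with %d electrodes (%s)%s%s\n", k,
              paste(sprintf("%d %s", table(object@labels$device_type),
                            names(table(object@labels$device_type))),
                    collapse = ", "),
              if ("anatomy" %in% names(object@labels)) ", labeled" else "",
              if (!is.null(object@warped)) ", warped" else ""))
  if (k > 0) {
    print(head(cbind(object@labels,
                     as.data.frame(object@coords) |>
                       setNames(c("x", "y", "z"))), 4))
    if (k > 4) cat(sprintf("... and %d more rows\n", k - 4))
  }
})

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf(
    "RigidTransform t = (%.3f, %.3f, %.3f) mm, r = (%.3f, %.3f, %.3f) deg\n",
    object@translation[1], object@translation[2], object@translation[3],
    object@rotation[1], object@rotation[2], object@rotation[3]))
})

setMethod("show", "Parcellation", function(object) {
  ids <- setdiff(unique(as.vector(object@volume@data)), 0)
  cat(sprintf("Parcellation with %d labeled structures on a %s grid%s\n",
              length(ids), paste(dim(object@volume@data), collapse = "x"),
              if (is.null(object@annot)) "" else
                sprintf(", %d-vertex annotation", length(object@annot))))
})

setMethod("show", "GridFrame", function(object) {
  cat(sprintf("GridFrame %dx%d, mean normal (%.3f, %.3f, %.3f)\n",
              object@nrows, object@ncols, object@meanNormal[1],
              object@meanNormal[2], object@meanNormal[3]))
})

setMethod("show", "DuralSurface", function(object) {
  cat(sprintf("DuralSurface (%s): ", object@kind))
  show(object@mesh)
})

setMethod("show", "SphereReg", function(object) {
  cat(sprintf("SphereReg: subject %d vertices, template %d vertices\n",
              nrow(object@subjSphere), nrow(object@templSphere)))
})

setMethod("show", "WarpField", function(object) {
  d <- dim(object@displacement)
  cat(sprintf("WarpField on %dx%dx%d grid, max |d| = %.3f mm\n",
              d[1], d[2], d[3], max(abs(object@displacement))))
})
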