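#' Anatomical labels for surface electrodes by nearest pial vertex
#'
#' Each electrode takes the annotation name of its Euclidean-nearest mesh
#' vertex (ties broken by lowest vertex index). The distance to the chosen
#' vertex is attached for QC.
#'
#' @param elecs K x 3 electrode coordinates (surface RAS mm, typically the
#'   projected coordinates).
#' @param mesh pial [TriMesh-class].
#' @param annot per-vertex label ids (length = vertex count).
#' @param lut lookup table data.frame (id, name) naming the annotation ids;
#'   if NULL, the raw ids are returned as character.
#' @return character vector of K anatomy names with attributes `vertex`
#'   (chosen 1-based vertex indices) and `distance` (mm).
#' @export
labelSurface <- function(elecs, mesh, annot, lut = NULL) {
  if (nrow(mesh@vertices) == 0) stop("empty mesh")
  if (length(annot) != nrow(mesh@vertices))
    stop("annotation length does not match the mesh vertex count")
  elecs <- rbind(elecs)
  nn <- .nearestVertexCpp(elecs, mesh@vertices)
  ids <- annot[nn$index]
  nm <- if (is.null(lut)) as.character(ids)
  else lut$name[match(ids, lut$id)]
  structure(nm, vertex = nn$index, distance = nn$distance)
}

#' Anatomical labels for depth electrodes from a parcellation volume
#'
#' Converts each electrode's surface-RAS coordinate to scanner RAS, maps it
#' to the nearest voxel (round half away from zero on fractional indices),
#' and returns the lookup-table name of that voxel's label id. Id 0 and
#' out-of-volume coordinates yield `"Unknown"` (the latter with a warning).
#'
#' @param elecs K x 3 electrode coordinates (surface RAS mm).
#' @param parc a [Parcellation-class].
#' @param volFrameRef [BrainVolume-class] defining the surface-RAS offset
#'   (defaults to the parcellation volume itself).
#' @return character vector of K anatomy names, attribute `id` holds the
#'   voxel label ids.
#' @export
labelDepth <- function(elecs, parc, volFrameRef = parcVolume(parc)) {
  elecs <- rbind(elecs)
  vol <- parc@volume
  scanner <- toScannerRAS(elecs, volFrameRef)
  vox <- roundHalfAway(worldToVoxel(vol, scanner))
  d <- dim(vol@data)
  inb <- vox[, 1] >= 0 & vox[, 1] < d[1] &
         vox[, 2] >= 0 & vox[, 2] < d[2] &
         vox[, 3] >= 0 & vox[, 3] < d[3]
  if (any(!inb))
    warning(sum(!inb), " electrode(s) outside the parcellation volume")
  ids <- integer(nrow(vox))
  if (any(inb))
    ids[inb] <- vol@data[cbind(vox[inb, 1], vox[inb, 2], vox[inb, 3]) + 1L]
  nm <- ifelse(ids == 0, "Unknown",
               parc@lut$name[match(ids, parc@lut$id)])
  nm[is.na(nm)] <- "Unknown"
  structure(nm, id = ids)
}

roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Montage specification for assembling elecs_all
#'
#' One row per device, in recording-montage order.
#'
#' @param device_name device names (e.g. `"hd_grid"`).
#' @param device_type `"grid"`, `"strip"` or `"depth"` per device.
#' @param short_prefix short-id prefix (e.g. `"G"` gives G1, G2, ...).
#' @param long_template long-id template containing `{n}` for the channel
#'   number (e.g. `"L256GridElectrode{n}"`).
#' @param n_channels channel count per device.
#' @return data.frame of class `MontageSpec`.
#' @export
montageSpec <- function(device_name, device_type, short_prefix,
                        long_template, n_channels) {
  df <- data.frame(device_name = device_name, device_type = device_type,
                   short_prefix = short_prefix,
                   long_template = long_template,
                   n_channels = as.integer(n_channels),
                   stringsAsFactors = FALSE)
  stopifnot(all(df$device_type %in% c("grid", "strip", "depth")),
            all(df$n_channels >= 1))
  class(df) <- c("MontageSpec", "data.frame")
  df
}

#' Assemble the montage-ordered electrode table
#'
#' Concatenates per-device coordinate arrays in montage order and generates
#' the eleclabels descriptors: short ids as prefix + channel number, long
#' ids from the `{n}` template, channel numbers starting at 0 or 1
#' according to `zeroIndexed`. The anatomy column is absent until
#' [labelElectrodes()] adds it.
#'
#' @param spec a [montageSpec()] data.frame.
#' @param deviceCoords named list of K_d x 3 coordinate matrices, one entry
#'   per `device_name`.
#' @param zeroIndexed channel numbering starts at 0 (default) or 1.
#' @return an [ElectrodeTable-class].
#' @export
makeElecsAll <- function(spec, deviceCoords, zeroIndexed = TRUE) {
  if (nrow(spec) == 0) stop("empty montage specification")
  missing <- setdiff(spec$device_name, names(deviceCoords))
  if (length(missing))
    stop("missing device coordinates: ", paste(missing, collapse = ", "))
  coords <- NULL
  labs <- NULL
  for (i in seq_len(nrow(spec))) {
    cc <- rbind(deviceCoords[[spec$device_name[i]]])
    if (nrow(cc) != spec$n_channels[i])
      stop(sprintf("device %s: %d coordinates but %d channels declared",
                   spec$device_name[i], nrow(cc), spec$n_channels[i]))
    chan <- seq_len(nrow(cc)) - as.integer(zeroIndexed)
    labs <- rbind(labs, data.frame(
      short_id = paste0(spec$short_prefix[i], chan),
      long_id = vapply(chan, function(n)
        gsub("{n}", n, spec$long_template[i], fixed = TRUE), ""),
      device_type = spec$device_type[i], stringsAsFactors = FALSE))
    coords <- rbind(coords, cc)
  }
  if (anyDuplicated(labs$short_id))
    stop("duplicate short_id across devices")
  ElectrodeTable(coords, labs, zeroIndexed = zeroIndexed)
}

#' Label all electrodes in a table
#'
#' Surface devices (grid, strip) are labeled by nearest pial vertex against
#' the surface annotation; depth devices by parcellated-volume voxel. Adds
#' the `anatomy` column.
#'
#' @param table an [ElectrodeTable-class].
#' @param mesh pial [TriMesh-class] for surface labeling.
#' @param annot per-vertex label ids for `mesh`.
#' @param surfLUT lookup table for the surface annotation.
#' @param parc [Parcellation-class] for depth labeling.
#' @param volFrameRef reference volume for the surface-RAS offset.
#' @return the table with a filled `anatomy` column.
#' @export
labelElectrodes <- function(table, mesh, annot, surfLUT, parc,
                            volFrameRef = parcVolume(parc)) {
  lab <- table@labels
  anatomy <- character(nrow(lab))
  surf <- lab$device_type %in% c("grid", "strip")
  if (any(surf))
    anatomy[surf] <- labelSurface(table@coords[surf, , drop = FALSE],
                                  mesh, annot, surfLUT)
  if (any(!surf))
    anatomy[!surf] <- labelDepth(table@coords[!surf, , drop = FALSE],
                                 parc, volFrameRef)
  lab$anatomy <- anatomy
  methods::initialize(table, labels = lab)
}

#' Apply manual corrections to anatomy labels
#'
#' Electrodes on a boundary between regions are occasionally mislabeled;
#' corrections are supplied as a revision list mapping the correct anatomy
#' name to the electrode numbers to fix (interpreted under the table's
#' zero-indexing flag). Only the listed rows change; each edit is appended
#' to the table's provenance log.
#'
#' @param table a labeled [ElectrodeTable-class].
#' @param revisions named list: `list(superiortemporal = c(246))`.
#' @return the revised table.
#' @export
editLabels <- function(table, revisions) {
  if (!"anatomy" %in% names(table@labels))
    stop("table has no anatomy column; label it first")
  lab <- table@labels
  off <- as.integer(table@zeroIndexed)
  prov <- table@provenance
  for (nm in names(revisions)) {
    idx <- as.integer(revisions[[nm]]) + off
    if (any(idx < 1 | idx > nrow(lab)))
      stop("electrode index out of range for label ", nm)
    prov[[length(prov) + 1]] <- list(
      action = "edit_labels", anatomy = nm,
      rows = as.integer(revisions[[nm]]),
      previous = lab$anatomy[idx], time = format(Sys.time()))
    lab$anatomy[idx] <- nm
  }
  methods::initialize(table, labels = lab, provenance = prov)
}
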