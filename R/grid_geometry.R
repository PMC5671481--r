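#' Bilinear interpolation of a full grid from its four corners
#'
#' High-density grids are localized by their four corner electrodes only;
#' the remaining channels are filled in by bilinear interpolation between
#' the corners at evenly spaced intervals. Corners are given in channel
#' order: corner 1 = channel 1, corner 2 = channel `ncols`, corner 3 =
#' channel `(nrows-1)*ncols + 1`, corner 4 = channel `nrows*ncols` (the
#' 16 x 16 / 256-channel convention). Output rows are in row-major channel
#' order and reproduce the corners exactly.
#'
#' @param corners 4 x 3 matrix of corner coordinates (mm), channel order.
#' @param nrows,ncols grid dimensions (>= 2).
#' @return `nrows * ncols` x 3 coordinate matrix in channel order.
#' @export
interpGrid <- function(corners, nrows, ncols) {
  corners <- as.matrix(corners)
  stopifnot(nrow(corners) == 4, nrows >= 2, ncols >= 2)
  checkCornersNondegenerate(corners)
  u <- rep((seq_len(nrows) - 1) / (nrows - 1), each = ncols)
  v <- rep((seq_len(ncols) - 1) / (ncols - 1), times = nrows)
  outer(( 1 - u) * (1 - v), corners[1, ]) +
    outer((1 - u) * v, corners[2, ]) +
    outer(u * (1 - v), corners[3, ]) +
    outer(u * v, corners[4, ])
}

checkCornersNondegenerate <- function(corners) {
  e1 <- corners[2, ] - corners[1, ]
  e2 <- corners[3, ] - corners[1, ]
  cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  scale <- max(sqrt(sum(e1^2)), sqrt(sum(e2^2)))
  if (scale == 0 || sqrt(sum(cr^2)) < 1e-9 * scale^2)
    stop("degenerate grid: corners are collinear")
  invisible(TRUE)
}

#' Grid outline vectors, corner normals and mean normal
#'
#' Builds the projection frame of a subdural grid from its four corners:
#' the four directed edges of the corner quadrilateral (traversed C1, C2,
#' C4, C3), one unit normal per corner (cross product of that corner's
#' incoming and outgoing edges), signs flipped to lie in a common
#' half-space, and their normalized mean, which serves as the projection
#' direction.
#'
#' @inheritParams interpGrid
#' @return a [GridFrame-class].
#' @export
gridFrame <- function(corners, nrows, ncols) {
  corners <- as.matrix(corners)
  stopifnot(nrow(corners) == 4)
  checkCornersNondegenerate(corners)
  # quadrilateral cycle in spatial order: C1 -> C2 -> C4 -> C3 -> C1
  cyc <- c(1, 2, 4, 3)
  quad <- corners[cyc, , drop = FALSE]
  edges <- quad[c(2, 3, 4, 1), ] - quad
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  normals <- matrix(0, 4, 3)
  for (i in 1:4) {
    prev <- edges[((i - 2) %% 4) + 1, ]
    nxt <- edges[i, ]
    n <- cross3(prev, nxt)
    nn <- sqrt(sum(n^2))
    if (nn < 1e-12) stop("degenerate grid: collinear corner edges")
    normals[i, ] <- n / nn
  }
  ref <- normals[1, ]
  for (i in 2:4)
    if (sum(normals[i, ] * ref) < 0) normals[i, ] <- -normals[i, ]
  mn <- colMeans(normals)
  mn <- mn / sqrt(sum(mn^2))
  # undo the cycle so row i describes corner i (channel order)
  ord <- order(cyc)
  new("GridFrame", corners = corners, nrows = as.integer(nrows),
      ncols = as.integer(ncols), outline = edges[ord, , drop = FALSE],
      cornerNormals = normals[ord, , drop = FALSE], meanNormal = mn)
}

#' Dural projection surface from a pial mesh
#'
#' The projection target for subdural electrodes displaced by postoperative
#' brain shift: the convex hull of the pial vertices (`"convex_hull"`), the
#' hull subdivided to a maximum edge length and Taubin-smoothed
#' (`"smoothed_hull"`, the default target), or the hull of the vertex
#' subset whose annotation labels are not in an exclusion set
#' (`"ofc_submesh"`, used for orbitofrontal grids where the temporal lobe
#' must not capture the projection).
#'
#' @param pial a [TriMesh-class] pial surface.
#' @param kind `"smoothed_hull"`, `"convex_hull"` or `"ofc_submesh"`.
#' @param smoothingIters Taubin smoothing iterations for the smoothed hull.
#' @param maxEdge subdivision edge-length target, mm.
#' @param annot per-vertex label ids (required for `"ofc_submesh"`).
#' @param excludeLabels label ids to drop for `"ofc_submesh"` (e.g. the
#'   temporal-lobe labels).
#' @return a [DuralSurface-class].
#' @export
duralSurface <- function(pial, kind = c("smoothed_hull", "convex_hull",
                                        "ofc_submesh"),
                         smoothingIters = 30L, maxEdge = 3,
                         annot = NULL, excludeLabels = NULL) {
  kind <- match.arg(kind)
  verts <- pial@vertices
  if (kind == "ofc_submesh") {
    if (is.null(annot) || length(annot) != nrow(verts))
      stop("ofc_submesh needs a per-vertex annotation")
    keep <- !(annot %in% excludeLabels)
    if (sum(keep) < 4) stop("too few vertices after label exclusion")
    verts <- verts[keep, , drop = FALSE]
  }
  hull <- convexHullMesh(verts)
  mesh <- if (kind == "convex_hull") hull
  else {
    m <- subdivideToEdge(hull, maxEdge)
    taubinSmooth(m, smoothingIters)
  }
  new("DuralSurface", mesh = mesh, kind = kind)
}

#' Project electrodes along a common direction onto a dural surface
#'
#' Moves each electrode along the `+direction` ray (typically the grid's
#' mean normal) to its first intersection with the surface, correcting the
#' inward displacement caused by brain shift. Rays that miss the surface
#' fall back to the nearest point on the surface and are flagged.
#'
#' @param elecs K x 3 electrode coordinates, mm.
#' @param surface a [DuralSurface-class] (or [TriMesh-class]).
#' @param direction unit length-3 projection direction.
#' @return K x 3 matrix of on-surface coordinates, with attribute
#'   `missed` (logical K) marking fallback electrodes.
#' @export
projectElectrodes <- function(elecs, surface, direction) {
  elecs <- rbind(elecs)
  if (is(surface, "DuralSurface")) surface <- surface@mesh
  nd <- sqrt(sum(direction^2))
  stopifnot(abs(nd - 1) < 1e-6)
  hit <- .rayMeshCpp(elecs, direction, surface@vertices,
                     surface@triangles, tmin = -1e-6)
  out <- elecs + outer(ifelse(is.na(hit$t), 0, hit$t), direction)
  missed <- is.na(hit$t)
  if (any(missed)) {
    out[missed, ] <- .closestPointCpp(elecs[missed, , drop = FALSE],
                                      surface@vertices, surface@triangles)
  }
  structure(out, missed = missed)
}

#' Evenly spaced points between two electrode positions
#'
#' Linear interpolation between the first and last contact of a depth
#' electrode whose intermediate contacts cannot be resolved individually.
#'
#' @param endpoints 2 x 3 matrix (first and last contact, mm).
#' @param n number of contacts (>= 2), endpoints included.
#' @return n x 3 coordinate matrix.
#' @export
interpLine <- function(endpoints, n) {
  endpoints <- as.matrix(endpoints)
  stopifnot(nrow(endpoints) == 2)
  if (n < 2) stop("need at least 2 points")
  s <- (seq_len(n) - 1) / (n - 1)
  outer(1 - s, endpoints[1, ]) + outer(s, endpoints[2, ])
}
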