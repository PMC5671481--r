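#' Options for NMI rigid registration
#'
#' Knobs of the intensity-based registration: joint-histogram size and
#' smoothing, interpolation scheme, optimizer tolerances and the coarse-to-
#' fine pyramid.
#'
#' @param nBins histogram bins per intensity axis (>= 8).
#' @param histSigma Gaussian sigma (in bins) applied to the joint histogram.
#' @param interpolation `"trilinear"` or `"nearest"` sampling of the moving
#'   volume.
#' @param xtol,ftol optimizer tolerances (relative).
#' @param pyramid integer downsampling factors, strictly decreasing to 1.
#' @param maxSamples cap on fixed-voxel samples per pyramid level; levels
#'   with more voxels are randomly subsampled (seeded).
#' @param sampleSeed seed for the voxel subsample.
#' @param clipQuantiles intensity quantiles clipped before min-max binning
#'   (robust to CT metal artifacts).
#' @param maxit optimizer iteration cap per level.
#' @return a validated list of class `RegOptions`.
#' @export
regOptions <- function(nBins = 32L, histSigma = 1, interpolation = "trilinear",
                       xtol = 1e-4, ftol = 1e-4, pyramid = c(4L, 2L, 1L),
                       maxSamples = 200000L, sampleSeed = 1L,
                       clipQuantiles = c(0.01, 0.99), maxit = 500L) {
  stopifnot(nBins >= 8L,
            interpolation %in% c("trilinear", "nearest"),
            all(diff(pyramid) < 0), pyramid[length(pyramid)] == 1L)
  structure(list(nBins = as.integer(nBins), histSigma = histSigma,
                 interpolation = interpolation, xtol = xtol, ftol = ftol,
                 pyramid = as.integer(pyramid),
                 maxSamples = as.integer(maxSamples),
                 sampleSeed = as.integer(sampleSeed),
                 clipQuantiles = clipQuantiles, maxit = as.integer(maxit)),
            class = "RegOptions")
}

# robust intensity bounds for binning
intensityBounds <- function(x, clip) {
  q <- stats::quantile(x, clip, names = FALSE, na.rm = TRUE)
  if (q[2] <= q[1]) q <- range(x, na.rm = TRUE)
  if (q[2] <= q[1]) q[2] <- q[1] + 1
  q
}

binIndex <- function(x, bounds, nBins) {
  s <- (x - bounds[1]) / (bounds[2] - bounds[1]) * nBins
  pmax(0L, pmin(nBins - 1L, as.integer(floor(s))))
}

# sample the moving volume at fixed-frame world points under transform t
sampleMoving <- function(moving, t, worldPts, interpolation) {
  Minv <- solve(as.matrix(t))
  mw <- t(Minv %*% rbind(t(worldPts), 1))[, 1:3, drop = FALSE]
  vox <- t(solve(moving@affine) %*% rbind(t(mw), 1))[, 1:3, drop = FALSE]
  if (interpolation == "nearest")
    vox <- round(vox)
  r <- .trilinearCpp(moving@data, dim(moving@data), vox, 0)
  list(values = r$values, inside = r$inside)
}

#' Joint intensity histogram of two volumes under a rigid transform
#'
#' Bins the fixed volume's intensities against the moving volume sampled at
#' the transformed fixed voxel positions. Intensities are rescaled to
#' `[0, nBins)` per volume by min-max after clipping to the configured
#' quantiles; an optional Gaussian smoothing (sigma `histSigma` bins) is
#' applied to the counts.
#'
#' @param fixed,moving [BrainVolume-class] pair (scanner RAS).
#' @param t [RigidTransform-class] mapping moving world to fixed world.
#' @param opts a [regOptions()] list.
#' @param samples optional integer vector of fixed voxel (linear, 1-based)
#'   indices to use; default all voxels.
#' @return `nBins` x `nBins` matrix of (smoothed) counts; fixed bins index
#'   rows. Attribute `n_overlap` carries the raw overlapping-sample count.
#' @export
jointHistogram <- function(fixed, moving, t = RigidTransform(),
                           opts = regOptions(), samples = NULL) {
  n <- opts$nBins
  fdat <- as.vector(fixed@data)
  if (is.null(samples)) samples <- seq_along(fdat)
  d <- dim(fixed@data)
  idx0 <- samples - 1L
  ijk <- cbind(idx0 %% d[1],
               (idx0 %/% d[1]) %% d[2],
               idx0 %/% (d[1] * d[2]))
  worldPts <- voxelToWorld(fixed, ijk)
  sm <- sampleMoving(moving, t, worldPts, opts$interpolation)
  keep <- sm$inside
  if (!any(keep)) stop("no overlap under transform")
  if (mean(keep) < 0.1)
    warning("volumes overlap for fewer than 10% of fixed samples")
  fb <- binIndex(fdat[samples][keep],
                 intensityBounds(fdat, opts$clipQuantiles), n)
  mb <- binIndex(sm$values[keep],
                 intensityBounds(as.vector(moving@data), opts$clipQuantiles),
                 n)
  counts <- tabulate(fb + n * mb + 1L, nbins = n * n)
  h <- matrix(as.numeric(counts), n, n)
  if (opts$histSigma > 0)
    h <- matrix(.gaussianSmoothCpp(as.vector(h), c(n, n, 1L),
                                   opts$histSigma), n, n)
  structure(h, n_overlap = sum(keep))
}

#' Normalized mutual information of a joint histogram
#'
#' `(H(A) + H(B)) / H(A, B)` with Shannon entropies in nats over the
#' normalized histogram; 1 for independent intensities, 2 for a perfectly
#' dependent (diagonal) histogram.
#'
#' @param hist 2D non-negative count matrix.
#' @return scalar in `[1, 2]`.
#' @export
nmi <- function(hist) {
  s <- sum(hist)
  if (!(s > 0)) stop("all-zero histogram")
  p <- hist / s
  ent <- function(q) {
    q <- q[q > 0]
    -sum(q * log(q))
  }
  hab <- ent(p)
  if (hab == 0) return(2)
  (ent(rowSums(p)) + ent(colSums(p))) / hab
}

# Powell-style derivative-free minimizer: cyclic bounded line
# minimizations per parameter over a fixed schedule of geometrically
# contracting search spans. The scheduled contraction forces progressive
# refinement even where the objective valley is shallow and coupled (the
# rotation parameters of an NMI cost), where improvement-based stopping
# rules quit early.
contractingSearch <- function(fn, p, span0, minSpan, ftolAbs, xtol) {
  fbest <- fn(p)
  span <- span0
  lastGain <- Inf
  while (span >= minSpan) {
    f0 <- fbest
    for (j in seq_along(p)) {
      ls <- stats::optimize(function(v) {
        q <- p
        q[j] <- v
        fn(q)
      }, interval = c(p[j] - span, p[j] + span),
      tol = max(xtol * span, 1e-3 * span))
      if (ls$objective < fbest) {
        p[j] <- ls$minimum
        fbest <- ls$objective
      }
    }
    lastGain <- f0 - fbest
    span <- span / 2
  }
  list(par = p, value = fbest, converged = lastGain <= 10 * ftolAbs)
}

downsampleVolume <- function(vol, factor) {
  # mild smoothing even at full resolution: averages voxel noise, which
  # otherwise ripples the NMI cost through interpolation
  if (factor == 1L) {
    dat <- array(.gaussianSmoothCpp(as.vector(vol@data), dim(vol@data),
                                    0.5), dim(vol@data))
    return(BrainVolume(dat, vol@affine, vol@frame))
  }
  dat <- array(.gaussianSmoothCpp(as.vector(vol@data), dim(vol@data),
                                  0.45 * factor), dim(vol@data))
  d <- dim(dat)
  ix <- seq(1, d[1], by = factor)
  iy <- seq(1, d[2], by = factor)
  iz <- seq(1, d[3], by = factor)
  S <- diag(c(factor, factor, factor, 1))
  BrainVolume(dat[ix, iy, iz, drop = FALSE], vol@affine %*% S, vol@frame)
}

#' Rigid CT-to-MRI registration by normalized mutual information
#'
#' Finds the 6-DOF transform (translation mm, intrinsic x-y-z Euler angles
#' about the fixed volume's center) maximizing the NMI between the fixed
#' volume and the transformed moving volume, with a derivative-free simplex
#' search run coarse-to-fine over a resolution pyramid, each level warm-
#' started from the previous.
#'
#' @param fixed,moving [BrainVolume-class] pair in scanner RAS (typically
#'   T1 fixed, CT moving).
#' @param init initial [RigidTransform-class] (default identity). Poor
#'   initial alignment (tens of mm / tens of degrees) is the classic
#'   failure mode; the result then carries `converged = FALSE`.
#' @param opts a [regOptions()] list.
#' @param verbose print per-level NMI.
#' @return A [RigidTransform-class] mapping moving world to fixed world,
#'   with attributes `nmi` (final value), `converged` and `log` (per-level
#'   start/end NMI).
#' @export
registerRigid <- function(fixed, moving, init = RigidTransform(),
                          opts = regOptions(), verbose = FALSE) {
  center <- as.numeric(surfaceRASOffset(fixed))
  p <- c(init@translation, init@rotation)
  logrec <- NULL
  converged <- TRUE
  for (f in opts$pyramid) {
    fx <- downsampleVolume(fixed, f)
    mv <- downsampleVolume(moving, f)
    nvox <- prod(dim(fx@data))
    samples <- seq_len(nvox)
    # seeded subsampling buys speed at the coarse levels; the finest
    # level always uses the full grid so the optimum is noise-free
    if (f > 1L && nvox > opts$maxSamples) {
      rs <- .Random.seed_get()
      set.seed(opts$sampleSeed)
      samples <- sort(sample.int(nvox, opts$maxSamples))
      .Random.seed_set(rs)
    }
    d <- dim(fx@data)
    idx0 <- samples - 1L
    ijk <- cbind(idx0 %% d[1],
                 (idx0 %/% d[1]) %% d[2],
                 idx0 %/% (d[1] * d[2]))
    worldPts <- voxelToWorld(fx, ijk)
    fvals <- as.vector(fx@data)[samples]
    fBounds <- intensityBounds(as.vector(fx@data), opts$clipQuantiles)
    mBounds <- intensityBounds(as.vector(mv@data), opts$clipQuantiles)
    fb <- binIndex(fvals, fBounds, opts$nBins)
    n <- opts$nBins
    obj <- function(par) {
      t <- rigidMatrix(par[1:3], par[4:6], center)
      Minv <- solve(t)
      mw <- t(Minv %*% rbind(t(worldPts), 1))[, 1:3, drop = FALSE]
      vox <- t(solve(mv@affine) %*% rbind(t(mw), 1))[, 1:3, drop = FALSE]
      if (opts$interpolation == "nearest") vox <- round(vox)
      r <- .trilinearCpp(mv@data, dim(mv@data), vox, 0)
      ov <- mean(r$inside)
      if (ov < 0.1) return(1 + (0.1 - ov))
      keep <- r$inside
      mb <- binIndex(r$values[keep], mBounds, n)
      counts <- tabulate(fb[keep] + n * mb + 1L, nbins = n * n)
      h <- matrix(as.numeric(counts), n, n)
      if (opts$histSigma > 0)
        h <- matrix(.gaussianSmoothCpp(as.vector(h), c(n, n, 1L),
                                       opts$histSigma), n, n)
      -nmi(h)
    }
    nmi0 <- -obj(p)
    # convergence is judged on NMI's excess over 1 (its informative part)
    fit <- contractingSearch(obj, p, span0 = max(3 * f, 2),
                             minSpan = 0.05,
                             ftolAbs = opts$ftol * max(nmi0 - 1, 0.01),
                             xtol = opts$xtol)
    if (!fit$converged) converged <- FALSE
    p <- fit$par
    nmi1 <- -fit$value
    logrec <- rbind(logrec,
                    data.frame(level = f, nmi_start = nmi0, nmi_end = nmi1,
                               tx = p[1], ty = p[2], tz = p[3],
                               rx = p[4], ry = p[5], rz = p[6]))
    if (verbose)
      message(sprintf("pyramid /%d: NMI %.4f -> %.4f", f, nmi0, nmi1))
  }
  if (!converged)
    warning("registration did not converge; returning best transform found")
  out <- RigidTransform(p[1:3], p[4:6], center)
  attr(out, "nmi") <- logrec$nmi_end[nrow(logrec)]
  attr(out, "converged") <- converged
  attr(out, "log") <- logrec
  out
}

# save/restore the RNG state without disturbing the caller
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

#' Resample a volume onto another volume's grid
#'
#' Pull-resampling through the inverse transform: each output voxel on
#' `like`'s grid takes the moving volume's intensity at the inversely
#' mapped position. Out-of-field voxels are 0.
#'
#' @param moving [BrainVolume-class] to resample (e.g. the CT).
#' @param t [RigidTransform-class] or 4x4 matrix, moving world to fixed
#'   world.
#' @param like [BrainVolume-class] providing the output grid and affine.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return [BrainVolume-class] on `like`'s grid.
#' @export
resampleVolume <- function(moving, t, like, interpolation = "trilinear") {
  d <- dim(like@data)
  idx0 <- seq_len(prod(d)) - 1L
  ijk <- cbind(idx0 %% d[1],
               (idx0 %/% d[1]) %% d[2],
               idx0 %/% (d[1] * d[2]))
  world <- voxelToWorld(like, ijk)
  M <- if (is(t, "RigidTransform")) t@matrix else t
  mw <- t(solve(M) %*% rbind(t(world), 1))[, 1:3, drop = FALSE]
  vox <- t(solve(moving@affine) %*% rbind(t(mw), 1))[, 1:3, drop = FALSE]
  if (interpolation == "nearest") vox <- round(vox)
  r <- .trilinearCpp(moving@data, dim(moving@data), vox, 0)
  BrainVolume(array(r$values, d), like@affine, like@frame)
}

#' Maximum-intensity-projection slab
#'
#' Per-pixel maximum over `sliceIndex` plus/minus `halfWidth` slices along
#' the chosen axis (clipped to the volume); the display used to make CT
#' electrode artifacts conspicuous. `halfWidth = 0` returns the plain
#' slice.
#'
#' @param vol a [BrainVolume-class].
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @param sliceIndex 1-based slice index along `axis`.
#' @param halfWidth slab half-width in slices (default 15).
#' @return 2D matrix over the remaining two axes.
#' @export
mipSlab <- function(vol, axis, sliceIndex, halfWidth = 15L) {
  d <- dim(vol@data)
  stopifnot(axis %in% 1:3, sliceIndex >= 1, sliceIndex <= d[axis])
  lo <- max(1L, sliceIndex - halfWidth)
  hi <- min(d[axis], sliceIndex + halfWidth)
  sl <- switch(axis,
               vol@data[lo:hi, , , drop = FALSE],
               vol@data[, lo:hi, , drop = FALSE],
               vol@data[, , lo:hi, drop = FALSE])
  apply(sl, setdiff(1:3, axis), max)
}
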