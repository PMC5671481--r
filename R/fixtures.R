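# deterministic generators: every fixture is a pure function of its
# parameters and seed, with the caller's RNG state left untouched

withSeed <- function(seed, expr) {
  state <- .Random.seed_get()
  on.exit(.Random.seed_set(state))
  set.seed(seed)
  expr
}

#' Specification of a synthetic head phantom
#'
#' Parameters of the paired T1/CT phantom: grid and voxel size, brain
#' ellipsoid semi-axes, skull shell thickness and intensity, electrode
#' artifact positions/radius/intensity (default radius 1.17/2 mm, the
#' diameter of high-density grid contacts), additive noise level, the known
#' rigid displacement applied to the CT, and a mandatory seed.
#'
#' @param gridDim voxel grid dimensions (default 96^3).
#' @param voxelSize isotropic voxel size, mm.
#' @param brainSemiAxes brain ellipsoid semi-axes, mm.
#' @param skullThickness,skullIntensity skull shell geometry/brightness.
#' @param electrodes K x 3 electrode positions, mm, in the T1 frame
#'   (default: a 2 x 3 patch near the right surface plus a 4-contact
#'   depth track).
#' @param electrodeRadius,electrodeIntensity CT artifact size/brightness.
#' @param noiseSigma additive Gaussian noise sd (intensity units).
#' @param displacement [RigidTransform-class] displacing the CT.
#' @param seed RNG seed (mandatory).
#' @return a list of class `PhantomSpec`.
#' @export
phantomSpec <- function(gridDim = c(96L, 96L, 96L), voxelSize = 1,
                        brainSemiAxes = c(32, 42, 36),
                        skullThickness = 4, skullIntensity = 1000,
                        electrodes = NULL, electrodeRadius = 1.17 / 2,
                        electrodeIntensity = 3000, noiseSigma = 4,
                        displacement = RigidTransform(), seed) {
  if (missing(seed)) stop("phantomSpec requires a seed")
  if (is.null(electrodes)) {
    a <- brainSemiAxes
    patch <- as.matrix(expand.grid(x = 0.92 * a[1],
                                   y = c(-8, 0, 8), z = c(-5, 5)))
    patch <- patch * cbind(sqrt(1 - (patch[, 2] / a[2])^2 -
                                (patch[, 3] / a[3])^2), 1, 1)
    depth <- interpLine(rbind(c(-6, -10, -6), c(-22, 8, 6)), 4)
    electrodes <- rbind(as.matrix(patch), depth)
  }
  structure(list(gridDim = as.integer(gridDim), voxelSize = voxelSize,
                 brainSemiAxes = brainSemiAxes,
                 skullThickness = skullThickness,
                 skullIntensity = skullIntensity,
                 electrodes = as.matrix(electrodes),
                 electrodeRadius = electrodeRadius,
                 electrodeIntensity = electrodeIntensity,
                 noiseSigma = noiseSigma, displacement = displacement,
                 seed = as.integer(seed)),
            class = "PhantomSpec")
}

centeredAffine <- function(gridDim, voxelSize) {
  aff <- diag(c(rep(voxelSize, 3), 1))
  aff[1:3, 4] <- -voxelSize * (gridDim - 1) / 2
  aff
}

gridWorldCoords <- function(gridDim, affine) {
  idx0 <- seq_len(prod(gridDim)) - 1L
  ijk <- cbind(idx0 %% gridDim[1],
               (idx0 %/% gridDim[1]) %% gridDim[2],
               idx0 %/% (gridDim[1] * gridDim[2]))
  t(affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

#' Synthetic T1/CT head phantom with known ground truth
#'
#' Builds a T1-like volume (gray/white contrast ellipsoids inside a dark
#' skull shell) and a CT-like volume (bright skull ring, spherical
#' electrode artifacts) on a centered RAS grid. The CT content is rendered
#' displaced by the spec's rigid transform, so registering CT to T1 should
#' recover exactly that transform; all ground truth is returned. Identical
#' specs give byte-identical volumes.
#'
#' @param spec a [phantomSpec()].
#' @return list with `t1`, `ct` ([BrainVolume-class]), `trueTransform`
#'   (CT world to T1 world, [RigidTransform-class]) and `trueElecs`
#'   (K x 3, T1 scanner RAS mm).
#' @export
makeHeadPhantom <- function(spec) {
  gd <- spec$gridDim
  aff <- centeredAffine(gd, spec$voxelSize)
  a <- spec$brainSemiAxes
  rho <- function(w) sqrt((w[, 1] / a[1])^2 + (w[, 2] / a[2])^2 +
                          (w[, 3] / a[3])^2)
  er <- rho(spec$electrodes)
  if (any(er > 1))
    stop("electrode position(s) outside the brain ellipsoid")
  skull0 <- 1.06
  skull1 <- skull0 + spec$skullThickness / mean(a)
  # tissue boundaries ramp over ~1.2 mm (scanner point-spread realism;
  # hard step edges would alias on the voxel grid)
  wRamp <- 1.2 / mean(a)
  ramp <- function(t) pmin(1, pmax(0, 0.5 + t / wRamp))
  mix <- function(v, target, t) v * (1 - t) + target * t
  # lateral ventricles: prominent CSF landmarks whose offset from the
  # midline anchors rotations about every axis
  ventSemi <- c(0.16, 0.38, 0.22)   # fractions of the brain semi-axes
  ventRho <- function(w, s) {
    sqrt(((w[, 1] / a[1] - s * 0.36) / ventSemi[1])^2 +
         ((w[, 2] / a[2] - 0.12) / ventSemi[2])^2 +
         ((w[, 3] / a[3] - 0.18) / ventSemi[3])^2)
  }
  t1model <- function(w) {
    r <- rho(w)
    v <- 15 * ramp(skull1 - r)                # scalp/CSF band
    v <- mix(v, 25, ramp(skull1 - r) * ramp(r - skull0))  # skull, dark
    v <- mix(v, 80, ramp(1 - r))              # gray matter
    v <- mix(v, 110, ramp(0.65 - r))          # white matter
    for (s in c(-1, 1))
      v <- mix(v, 18, ramp(1 - ventRho(w, s)))  # CSF-dark ventricles
    v
  }
  ctmodel <- function(w) {
    r <- rho(w)
    v <- 40 * ramp(skull1 - r)                # soft tissue
    for (s in c(-1, 1))
      v <- mix(v, 12, ramp(1 - ventRho(w, s)))
    v <- mix(v, spec$skullIntensity,
             ramp(skull1 - r) * ramp(r - skull0))
    # metal artifacts bloom beyond the physical contact: render each as a
    # Gaussian blob slightly wider than the contact radius
    sig <- spec$electrodeRadius + 0.5
    for (i in seq_len(nrow(spec$electrodes))) {
      d2 <- (w[, 1] - spec$electrodes[i, 1])^2 +
            (w[, 2] - spec$electrodes[i, 2])^2 +
            (w[, 3] - spec$electrodes[i, 3])^2
      v <- pmax(v, spec$electrodeIntensity * exp(-0.5 * d2 / sig^2))
    }
    v
  }
  world <- gridWorldCoords(gd, aff)
  M <- spec$displacement@matrix
  worldCT <- t(M %*% rbind(t(world), 1))[, 1:3, drop = FALSE]
  withSeed(spec$seed, {
    t1 <- array(t1model(world) + rnorm(nrow(world), 0, spec$noiseSigma), gd)
    ct <- array(ctmodel(worldCT) +
                  rnorm(nrow(world), 0, spec$noiseSigma), gd)
  })
  list(t1 = BrainVolume(t1, aff), ct = BrainVolume(ct, aff),
       trueTransform = spec$displacement, trueElecs = spec$electrodes)
}

# region names for the sector annotation, borrowed from the coarse
# gyral atlas vocabulary
sectorNames <- c("superiortemporal", "precentral", "postcentral",
                 "parstriangularis", "rostralmiddlefrontal",
                 "caudalmiddlefrontal", "supramarginal", "lateraloccipital",
                 "superiorfrontal", "middletemporal", "inferiorparietal",
                 "fusiform")

#' Deformed-sphere pial surface fixture
#'
#' An icosphere (radius `radius` mm) radially perturbed by smooth
#' low-frequency noise ("gyri"), paired with its exact spherical
#' registration: the sphere coordinate of every vertex is the unperturbed
#' unit icosphere vertex. The annotation partitions vertices into angular
#' sectors named after gyral atlas regions.
#'
#' @param nSubdiv icosphere subdivision level (>= 2).
#' @param bumpiness radial perturbation amplitude, mm (0 = perfect
#'   sphere).
#' @param radius base radius, mm.
#' @param nSectors number of annotation sectors (<= 12).
#' @param seed RNG seed.
#' @return list with `pial` ([TriMesh-class]), `sphere` (N x 3 unit
#'   coordinates), `annot` (integer ids) and `lut`.
#' @export
makePialFixture <- function(nSubdiv = 3L, bumpiness = 2, radius = 40,
                            nSectors = 8L, seed = 1L) {
  stopifnot(nSubdiv >= 2, nSectors >= 1, nSectors <= length(sectorNames))
  ico <- icosphere(nSubdiv)
  s <- ico@vertices
  r <- rep(radius, nrow(s))
  if (bumpiness > 0) {
    withSeed(seed, {
      for (k in 1:6) {
        d <- rnorm(3)
        d <- d / sqrt(sum(d^2))
        f <- runif(1, 2, 5)
        ph <- runif(1, 0, 2 * pi)
        r <- r + bumpiness / sqrt(6) * cos(f * (s %*% d) + ph)
      }
    })
  }
  pial <- TriMesh(s * as.vector(r), ico@triangles)
  az <- atan2(s[, 2], s[, 1])                 # (-pi, pi]
  sector <- pmin(nSectors,
                 1L + as.integer(floor((az + pi) / (2 * pi) * nSectors)))
  lut <- data.frame(id = seq_len(nSectors),
                    name = sectorNames[seq_len(nSectors)],
                    r = (seq_len(nSectors) * 53) %% 256,
                    g = (seq_len(nSectors) * 101) %% 256,
                    b = (seq_len(nSectors) * 197) %% 256)
  list(pial = pial, sphere = s, annot = as.integer(sector), lut = lut)
}

#' Blob parcellation fixture
#'
#' One ellipsoidal blob per requested structure at deterministic lattice
#' positions inside the grid, labeled with the structure's LUT id
#' (hippocampus = 17). Overlapping blobs are an error.
#'
#' @param gridDim voxel grid (default 96^3, 1 mm).
#' @param voxelSize isotropic voxel size, mm.
#' @param structures structure table (default [subcortStructures()]).
#' @param semiAxes blob semi-axes in voxels.
#' @param seed accepted for interface symmetry; the layout is
#'   deterministic.
#' @return a [Parcellation-class] (scanner-RAS centered affine).
#' @export
makeParcellationFixture <- function(gridDim = c(96L, 96L, 96L),
                                    voxelSize = 1,
                                    structures = subcortStructures(),
                                    semiAxes = c(6, 7, 5), seed = 1L) {
  aff <- centeredAffine(gridDim, voxelSize)
  lab <- array(0L, gridDim)
  n <- nrow(structures)
  if (n > 0) {
    ncell <- ceiling(n^(1 / 3))
    if (any(2 * semiAxes + 2 >= min(gridDim) / ncell))
      stop("blobs do not fit in the grid without overlap")
    centers <- as.matrix(expand.grid(
      x = seq_len(ncell), y = seq_len(ncell), z = seq_len(ncell)))
    centers <- (centers - 0.5) / ncell  # cell centers in [0,1]
    centers <- sweep(centers, 2, gridDim - 1, "*")
    d <- dim(lab)
    idx0 <- seq_len(prod(d)) - 1L
    ijk <- cbind(idx0 %% d[1],
                 (idx0 %/% d[1]) %% d[2],
                 idx0 %/% (d[1] * d[2]))
    for (i in seq_len(n)) {
      ctr <- centers[i, ]
      r2 <- ((ijk[, 1] - ctr[1]) / semiAxes[1])^2 +
            ((ijk[, 2] - ctr[2]) / semiAxes[2])^2 +
            ((ijk[, 3] - ctr[3]) / semiAxes[3])^2
      hit <- r2 <= 1
      if (any(lab[hit] != 0)) stop("overlapping parcellation blobs")
      lab[hit] <- structures$id[i]
    }
  }
  out <- Parcellation(BrainVolume(lab, aff), structures[, c("id", "name",
                                                            "r", "g", "b")])
  if (n > 0) attr(out, "centers") <-
    cbind(structures$id, centers[seq_len(n), , drop = FALSE])
  out
}

#' Smooth synthetic displacement field with its closed form
#'
#' A low-frequency sinusoidal displacement (wavelengths of order the grid
#' extent) sampled on the voxel grid, returned together with the analytic
#' displacement function for oracle evaluation.
#'
#' @param gridDim voxel grid (default 64^3).
#' @param voxelSize isotropic voxel size, mm.
#' @param amplitude displacement amplitude, mm (must be < extent / 10).
#' @param seed RNG seed for frequencies/phases.
#' @return list with `field` ([WarpField-class]) and `analytic`
#'   (function mapping a K x 3 world-mm matrix to K x 3 displacements).
#' @export
makeWarpFixture <- function(gridDim = c(64L, 64L, 64L), voxelSize = 1.5,
                            amplitude = 2, seed = 1L) {
  extent <- min(gridDim * voxelSize)
  if (amplitude >= extent / 10)
    stop("amplitude must be below one tenth of the grid extent")
  aff <- centeredAffine(gridDim, voxelSize)
  pars <- withSeed(seed, {
    lapply(1:3, function(k)
      list(w = runif(3, -1, 1) * 2 * pi / extent,
           phase = runif(1, 0, 2 * pi)))
  })
  analytic <- function(xyz) {
    xyz <- rbind(xyz)
    out <- matrix(0, nrow(xyz), 3)
    if (amplitude == 0) return(out)
    for (k in 1:3)
      out[, k] <- amplitude * sin(xyz %*% pars[[k]]$w + pars[[k]]$phase)
    out
  }
  world <- gridWorldCoords(gridDim, aff)
  disp <- analytic(world)
  WarpFieldObj <- WarpField(array(disp, c(gridDim, 3L)), aff)
  list(field = WarpFieldObj, analytic = analytic)
}

#' Spherical registration fixture from a pial fixture
#'
#' Builds a [SphereReg-class] whose template pial surface is the subject
#' pial under a known rotation (identity by default) while both surfaces
#' share the same spherical parameterization — so an electrode snapped to
#' subject vertex i must come back at the rotated position of vertex i,
#' an analytically known correspondence for warp tests.
#'
#' @param pialFix output of [makePialFixture()].
#' @param rotation length-3 Euler angles, degrees.
#' @return a [SphereReg-class].
#' @export
makeSphereRegFixture <- function(pialFix, rotation = c(0, 0, 0)) {
  R <- rigidMatrix(c(0, 0, 0), rotation)[1:3, 1:3]
  templPial <- TriMesh(pialFix$pial@vertices %*% t(R),
                       pialFix$pial@triangles)
  SphereReg(pialFix$pial, pialFix$sphere, templPial, pialFix$sphere)
}
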