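---
title: "Localizing, labeling and warping intracranial electrodes with ElecLoc"
author: "ElecLoc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing, labeling and warping intracranial electrodes with ElecLoc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ElecLoc)
```

# The problem

Electrocorticography (ECoG) and stereo-EEG record from electrodes placed on
or in a patient's brain. Relating those recordings to anatomy requires
knowing, for every contact, where it sits on the patient's cortical surface
or in which subcortical structure, and where the same contact falls on a
common template brain so that subjects can be compared. The raw materials
are a preoperative T1 MRI (which carries the anatomy: pial surface meshes
and a labeled parcellation volume derived from it), a postoperative CT
(which carries the electrodes as bright metal artifacts), manually
identified contact coordinates, and — for template work — a spherical
registration of the subject's cortical surface plus a dense volumetric
displacement field.

ElecLoc implements the computational chain between these inputs: rigid
CT-to-MRI coregistration, grid interpolation, dural-surface projection,
anatomical labeling, subcortical mesh extraction, template warping with
label-agreement QC, and a subject-directory pipeline driver. Everything is
testable without a scanner or a surface-reconstruction suite through
deterministic synthetic fixtures.

# Coordinate conventions

Volumes carry a 4x4 affine mapping **0-based voxel indices at voxel
centers** to world millimetres, normalized on reading so the voxel axes run
right/anterior/superior (RAS). Two world frames appear:

* **scanner RAS** — the frame of the NIfTI affine;
* **surface RAS** — scanner RAS recentered on the volume's geometric
  center (the world coordinate of voxel `(dim - 1) / 2`), the frame in
  which surface meshes and electrode tables live.

`surfaceRASOffset()`, `toSurfaceRAS()` and `toScannerRAS()` convert between
the two; every cross-frame step in the package goes through them
explicitly, and volumes carry a frame tag so the tests can assert that no
arithmetic mixes frames.

# CT-to-MRI registration

Cross-modal alignment maximizes normalized mutual information,

$$\mathrm{NMI}(A, B) = \frac{H(A) + H(B)}{H(A, B)},$$

with Shannon entropies (nats) over a joint intensity histogram: 32 bins per
axis after clipping each volume to its 1st–99th intensity percentiles
(CT metal artifacts otherwise compress the intensity scale) and min–max
rescaling, with a 1-bin Gaussian smoothing of the counts. NMI is 1 for
independent intensities and 2 for a deterministic relationship, and is
invariant to any per-volume relabeling of intensity bins — the property
that makes it usable across modalities.

The transform has six parameters: translation in mm and intrinsic x–y–z
Euler angles in degrees, applied about the fixed volume's center (this
decouples rotations from translations in the search). The search is a
Powell-style derivative-free scheme: cyclic bounded line minimizations
(golden-section/Brent via `optimize()`) per parameter, over a fixed
schedule of geometrically contracting search spans. We chose the scheduled
contraction after observing that improvement-based stopping rules
terminate early in this cost landscape: the NMI valley along the rotation
axes is shallow (changes of order $10^{-4}$ per degree) and coupled across
parameters, while the informative dynamic range of NMI sits on a pedestal
of 1. For the same reason the convergence report is judged against
NMI $-$ 1 rather than NMI. The search runs coarse-to-fine over a
downsampling pyramid (factors 4, 2, 1; Gaussian pre-smoothing proportional
to the factor, and a mild half-voxel smoothing even at full resolution to
average voxel noise, which otherwise ripples the cost through
interpolation), warm-starting each level. Coarse levels evaluate NMI on a
seeded subsample of at most 200,000 fixed voxels for speed; the finest
level always uses the full grid, so the optimum is free of sampling
noise. On the 96³ phantom the whole registration takes about two minutes
on one core.

A registration that starts tens of millimetres or degrees away may
converge to a wrong basin — the classic poor-initial-conditions failure.
The result therefore carries a `converged` flag and a per-level NMI log;
the remedy, as in interactive practice, is a rough manual pre-alignment
passed as `init`.

`resampleVolume()` produces the registered CT by pull-resampling through
the inverse transform on the T1 grid, and `mipSlab()` provides the
maximum-intensity-projection display (current slice ± 15 slices by
default) that makes electrode artifacts conspicuous.

# Grids, dural projection

High-density grids (e.g. 16 × 16 contacts at 4 mm pitch) cannot be picked
contact-by-contact in a clinical CT. Instead the four corners are
identified, in channel order — corner 1 is channel 1, corner 2 is channel
`ncols`, corner 3 is channel `(nrows-1)*ncols + 1` — and `interpGrid()`
fills the rest bilinearly:

$$p(r, c) = (1-u)(1-v)\,C_1 + (1-u)v\,C_2 + u(1-v)\,C_3 + uv\,C_4,
\qquad u = \tfrac{r}{n_r - 1},\; v = \tfrac{c}{n_c - 1}.$$

Postoperative brain shift leaves subdural contacts imaged *inside* the
preoperative pial surface. `gridFrame()` builds the four outline edge
vectors of the corner quadrilateral, one unit normal per corner (cross
product of adjacent edges, signs made mutually consistent), and their
normalized mean; `projectElectrodes()` then moves every contact along that
mean normal to its first intersection with a dural surface
(Möller–Trumbore ray/triangle intersection; smallest non-negative hit,
ties to the lowest triangle index; rays that miss fall back to the nearest
surface point and are flagged).

The dural surface itself is a smoothed convex hull of the pial vertices:
the exact 3D hull (quickhull), subdivided until no edge exceeds 3 mm, then
Taubin-smoothed (λ = 0.5, μ = −0.53, 30 iterations by default — the
shrinkage-corrected variant of Laplacian smoothing, so the envelope does
not collapse inward). For orbitofrontal grids the hull is built from the
vertex subset excluding a caller-supplied temporal-lobe label set, so the
projection lands on the orbital surface rather than the temporal lobe.
Strip and subtemporal electrodes are deliberately *not* auto-projected;
their shift is corrected manually, and the pipeline exposes projection per
device.

# Anatomical labeling

Surface devices (grids, strips) take the label of the Euclidean-nearest
pial vertex in the annotation (ties to the lowest vertex index; labeling
uses the *projected* coordinates, matching the pipeline order). Depth
electrodes take the label of the parcellation voxel they fall in: surface
RAS → scanner RAS → fractional voxel → round-half-away-from-zero; label id
0, and coordinates outside the volume, yield `"Unknown"`. Depth electrodes
landing in white matter return the white-matter label verbatim — no
nearest-gray fallback is attempted, and users should review such rows. In
practice a coarse gyral atlas is used for surfaces and a finer one for
depths; both are plain id → name lookup tables here, and anatomy strings
are copied verbatim from the annotation (no case normalization).

`makeElecsAll()` assembles the montage-ordered table (coordinates plus
short id, long id, device type per row), `labelElectrodes()` fills the
anatomy column, and `editLabels()` applies manual corrections from a
revision list (`list(superiortemporal = c(246))`), recording each edit in
the table's provenance log. Channel numbering respects the subject's
zero-indexing flag (default zero-indexed).

# Template warping

Surface electrodes warp through a spherical correspondence: snap the
contact to its nearest subject pial vertex, look up that vertex's
unit-sphere coordinate, find the template sphere vertex at the smallest
great-circle distance (angular rather than chordal distance — numerically
equivalent at these mesh densities, angular chosen on principle; ties to
the lowest index), and return the matching template pial vertex. Every
warped surface contact is therefore an exact template vertex. Pial (not
dural) vertices define the correspondence for strips buried in sulci.
Large snap distances are flagged: an electrode floating far above the
surface can snap across a fissure to the wrong gyrus.

Depth electrodes add a trilinearly interpolated displacement from a dense
field (the product of an upstream combined volumetric/surface
registration; computing such a field is outside this package's scope).
Contacts outside the field's validity mask pass through unchanged and are
flagged.

`warpAll()` dispatches by device type, honors surface-only/depth-only
subsets, stores warped coordinates as a parallel block (native coordinates
are never overwritten, so native/template comparisons remain possible),
and accepts a drop list and per-electrode manual overrides — the two
remedies for a mis-warped electrode. `checkWarpLabels()` relabels each
warped contact in template space and reports per-electrode agreement with
the native anatomy, mismatches first; a hippocampal depth electrode landing
in cerebellar cortex is the canonical failure this catches.

# Subcortical meshes

`getSubcort()` extracts one triangle mesh per subcortical structure from
an integer parcellation: binary mask, optional Gaussian pre-smoothing
(σ = 1 voxel by default; the raw mask gives a blocky surface useful for
geometric oracles), then iso-surfacing at level 0.5 and mapping through
the affine to surface RAS. The default structure set is the 23 standard
structures — bilateral accumbens, amygdala, caudate, lateral and inferior
lateral ventricles, pallidum, hippocampus, putamen, thalamus and ventral
diencephalon, plus brain stem and third and fourth ventricles (left and
right ventricles meshed separately) — with ids and colors from the
standard color lookup table (hippocampus = 17).

Iso-surfacing is implemented as marching tetrahedra: each cell splits into
six tetrahedra around its main diagonal, a conforming decomposition (both
cells sharing a face use the same diagonal), so the result is watertight
with consistent outward orientation — solid blobs give Euler
characteristic 2, and mesh volume converges to the voxel volume with
resolution. We preferred this variant of the marching-cubes family because
it has no ambiguous cases and needs no case tables; the contract
(closed oriented iso-surface at level 0.5) is the same.

# Synthetic fixtures: what they do and do not show

The `fixtures` generators are pure functions of their parameters and seed
(byte-identical on repeat, caller's RNG state untouched):

* `makeHeadPhantom()` — paired T1/CT on a 96³, 1 mm grid by default:
  gray/white contrast ellipsoids (semi-axes 32/42/36 mm — three distinct
  axes, since a rotationally symmetric brain would leave one rotation
  unidentifiable) inside a bright skull shell, CT electrode artifacts as
  Gaussian blobs slightly wider than the 1.17 mm contact diameter, additive
  Gaussian noise (σ = 4), and the CT rendered under a known rigid
  displacement. Tissue boundaries ramp over ~1.2 mm rather than stepping:
  real scans are band-limited by the scanner point-spread function, and
  hard synthetic edges alias on the voxel grid in a way that visibly
  biases intensity-based registration — an artifact of naive phantoms, not
  of scans.
* `makePialFixture()` — an icosphere (radius 40 mm) radially perturbed by
  smooth low-frequency noise as a stand-in for gyri, paired with its exact
  spherical registration (the unperturbed icosphere) and an angular-sector
  annotation named after gyral atlas regions.
* `makeParcellationFixture()` — one ellipsoidal blob per subcortical
  structure on a deterministic lattice, standard ids.
* `makeWarpFixture()` — a low-frequency sinusoidal displacement field
  sampled on a 64³ grid at 1.5 mm, returned with its closed form; the
  spacing keeps trilinear interpolation error below 0.01 mm at the 2 mm
  default amplitude, so the field itself never limits warp accuracy tests.

Passing tests on these fixtures demonstrates the geometry and bookkeeping:
exact coordinate conventions, oracle-equivalent labeling, watertight
surfaces, sub-half-millimetre registration recovery under realistic
contrast and noise. They do not demonstrate robustness to bias fields,
beam hardening, motion, real gyral geometry, or segmentation errors —
phenomena the generators deliberately omit. Real-data use still requires
the interactive QC pause points the pipeline mirrors (registration
overlay, label review, warp comparison).

# Numerical choices and degenerate inputs

* Ties everywhere (nearest vertex, nearest sphere vertex, first ray hit)
  break toward the lowest index, making every lookup deterministic.
* `interpGrid()` refuses collinear corners; `gridFrame()` refuses
  degenerate corner edges; hulls require 4 non-coplanar points.
* Projection accepts ray hits from t ≥ −10⁻⁶ mm so that electrodes
  already on the surface are fixed points; projection is idempotent to
  10⁻⁶ mm.
* Trilinear sampling outside a volume returns the fill value and is
  reported; depth labels outside the parcellation are `"Unknown"` with a
  warning, never an error.
* The registration subsample (coarse pyramid levels above 200,000
  voxels) uses a fixed internal seed, so repeated runs are identical.
* Problem sizes in the test suite (48³–96³ phantoms, subdivision-3
  icospheres, 100-electrode oracle comparisons) were chosen so the full
  suite exercises every path in a few minutes on one core; they are stated
  here as the package's reference conditions.

# Pipeline and QC

`prepSubject()` creates the standard subject layout (acpc/, CT/, elecs/
with individual_elecs/, Meshes/ with subcortical/, mri/ with transforms/,
logs/) and persists the subject configuration. `runStage()` runs one named
stage (`register`, `interp-grid`, `project`, `elecs-all`, `label`,
`subcort`, `warp`) against the standard file locations, refuses to start
when an upstream product is missing (naming the file and the stage that
makes it), and appends a JSON log line with input hashes and verbatim
parameters — enough to re-run any stage identically. `qcRender()` writes
static PNG/CSV quality-control output (electrodes colored by anatomy over
a mesh silhouette; native-versus-warped comparisons; per-depth-electrode
slice panels with crosshairs), replacing interactive 3D inspection in
headless settings; PNG + CSV were chosen over PDF since the content, not
the container, is the contract. A thin command-line wrapper
(`exec/elecloc`) exposes the same stages from a shell. Interactive
electrode picking is out of scope by design; `refineElectrodes()` offers
the headless equivalent of centering a pick on the CT artifact (local
intensity maximum within 3 mm).

# Known limitations

* Rigid registration only; CT scans needing nonrigid correction are out
  of scope.
* Rotation recovery is resolution-limited: on coarse phantoms (2 mm
  voxels) the NMI cost constrains rotations only to about a degree.
* The dural envelope is a smoothed convex hull; it cannot represent
  concave dural regions (e.g. the interhemispheric fissure), where manual
  correction remains necessary.
* Depth labels are taken verbatim from the parcellation voxel — no
  partial-volume or nearest-gray reasoning.
* Spherical and volumetric registrations are consumed, never computed.
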