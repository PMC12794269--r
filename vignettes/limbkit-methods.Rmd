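---
title: "limbkit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{limbkit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(limbkit)
```

This vignette documents the numerical methods behind `limbkit`, the
assumptions they make, the parameters that matter, and the design
choices taken where several defensible options existed. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Coordinate and data model

All volume operations act on a `voxel_grid`: a 3D numeric array plus a
per-axis physical spacing and an origin, both in micrometres. The
physical position of voxel index `(i, j, k)` (1-based) is
`origin + (i-1, j-1, k-1) * spacing` — voxel *centres*, not corners,
sit on the lattice. Meshes (`surface_mesh`) always carry physical
coordinates, so staging and registration are independent of the
acquisition grid. Transforms are either homogeneous 4×4 matrices
(`affine4`, last row exactly `(0,0,0,1)`) or thin-plate-spline warps
(`tps_warp`); both apply to points, meshes and — by inverse-mapped
resampling — whole volumes, and both serialize to JSON so the ledger
can reference them by path.

## The experiment ledger

Reproducibility is enforced structurally: `pipeline.log` is a
plain-text, append-only file of
`ISO8601-timestamp<TAB>key<TAB>JSON-value` lines. Values round-trip
through JSON; reads return the last-written value of a key. The format
was chosen over a binary store so that a ledger is diffable, greppable
and survives partial writes (a truncated final line invalidates only
itself). There is deliberately no in-place update or deletion: a rerun
with different parameters appends, and the history of choices remains
visible.

## Volume cleaning

The cleaning stage applies, in a fixed documented order: spacing
calibration → intensity windowing → mirroring (left limbs) → Gaussian
smoothing → Fourier low-pass → optional resampling. The order matters
(windowing before smoothing suppresses background speckle *before* it
can be blurred into the tissue), and a regression test pins it.

**Intensity windowing.** Values below `v0` become 0 and values above
`v1` are clamped to `v1`; in-window values pass through unchanged. A
display-oriented implementation would map the window through a
colormap; `limbkit` deliberately keeps intensities on their original
scale because downstream analysis (probes, histograms, isovalues) is
quantitative.

**Mirroring.** Left limbs are flipped about the first stored array
axis (the sagittal plane under the acquisition convention; the axis is
overridable) so that all samples live in a right-handed reference
frame. The flip is a pure index reversal — an exact involution.

**Gaussian smoothing.** Separable discrete Gaussian, sigma in voxel
units, default `(6, 6, 6)`, kernel truncated at `4*sigma` and
renormalized, reflect padding at the boundaries. The kernel is applied
as a banded matrix product per axis, so total intensity is conserved
for interior-supported signals. The effective impulse-response standard
deviation is 6 voxels to well within 1 % (the truncation bias is
~0.04 %); the acceptance script measures it directly.

**Low-pass filter.** An ideal (hard) radial mask in normalized
frequency: after a 3D FFT, bins with radial frequency
`sqrt(fx² + fy² + fz²) > cutoff` (cycles/voxel) are zeroed; bins at
exactly the cutoff are kept, and DC is untouched. Default cutoff 0.05
cycles/voxel. Frequencies are normalized per axis by the voxel count,
i.e. the filter works in cycles/voxel rather than cycles/µm; with
anisotropic spacing a physical-units interpretation would scale the
axes differently, and the configuration keeps the units explicit so a
physical variant can be layered on top if needed.

**Resampling.** Trilinear interpolation at the new voxel centres. The
new lattice is *endpoint-aligned* (first and last voxel centres
coincide with the old ones): this preserves physical extent exactly,
reproduces affine intensity fields exactly (trilinear interpolation is
exact on them), and makes same-shape resampling the identity. The
alternative — pixel-area alignment — places boundary samples half a
voxel outside the old centre lattice, where values must be
extrapolated; endpoint alignment avoids that entirely.

## Surface extraction

**Isovalue.** The automatic isovalue is the mean of strictly positive
voxels. Cleaned volumes set sub-threshold voxels to 0, so zeros encode
"background" and excluding them targets the tissue mode; a flag
includes zeros for uncleaned data.

**Marching cubes.** The per-cell case table is *generated* rather than
transcribed: marching squares runs on each cube face (face cycles
oriented counter-clockwise seen from outside), cut edges bounding each
run of inside corners are paired into directed segments, segments link
into closed loops, and loops are fan-triangulated. The ambiguous
diagonal face case is resolved by always isolating the inside corners
— a rule that depends only on the shared face's values and therefore
agrees between neighbouring cells, which makes extracted surfaces of
interior features watertight by construction. Winding is fixed so
closed surfaces around high-intensity regions have positive enclosed
volume. Vertices are placed by linear interpolation along cell edges
and shared through a global edge index, then mapped to physical
coordinates. Accuracy on analytic bodies (sphere area/volume, torus
topology) is asserted in the tests at 2 %, with observed errors around
0.02–0.4 % depending on resolution; the error shrinks at least
quadratically with the spacing.

**Decimation.** Iterative quadric edge collapse (area-weighted plane
quadrics, optimal collapse position from the 3×3 normal system with
midpoint/endpoint fallback). With `preserve_volume` (default), the
collapse position is projected onto the plane of zero local volume
change — the swept volume is affine in the new position, so the
constraint is exact — and the cost additionally penalises residual
volume change (`alpha`) and triangle-normal deviation (`beta`);
collapses that would flip a surviving triangle or violate the manifold
link condition are rejected. The queue is lazy: candidates are
re-evaluated when popped, so stale priorities cost ordering accuracy
only, and an exhausted queue triggers a refresh sweep, which guarantees
the target count is reached whenever collapses remain feasible.
Tie-breaks are deterministic (cost, then vertex indices). The default
`target_reduction = 0.995` retains 0.5 % of the triangles; with volume
preservation the enclosed volume of a closed decimated sphere matches
the original at machine precision in the tests (the 5 % tolerance in
the test suite is a loose upper bound).

## Staging geometry

Ordered AER landmarks are interpolated by a cubic spline with
chord-length parameterization (one spline per coordinate, exact
polynomial-reproducing end conditions), resampled uniformly in the
chord parameter. The landmark plane is fitted by total least squares
(smallest singular vector of the centred points) with a fixed sign
convention (non-negative z, then y, then x) so results are
reproducible under point permutations. The reorientation to the
canonical dorsal-view direction `(0, 0, -1)` is the minimal-angle
Rodrigues rotation; the antiparallel input rotates 180° about the x
axis by convention. The 2D payload for the staging service is the
reoriented points with z dropped.

The staging service itself is remote prior work; `limbkit` ships a
client with pluggable JSON field names and a deterministic mock whose
responses are keyed by a hash of the point list. Offline analyses use
the mock; any service failure (non-2xx, unparseable body, non-finite
stage) raises an error and never writes a default stage to the ledger.

## Registration

**Similarity estimation** uses the closed-form SVD solution for
`min Σ‖sRp+t−q‖²` with determinant correction, so reflective
correspondence sets still produce a proper rotation. The interface
carries a `with_scale` flag (default on): the rigid 6-DOF and
7-parameter similarity variants are the same estimator with the scale
fixed or free.

**ICP** alternates point-to-triangle closest-point correspondence with
a rigid (default) or similarity update, rejecting pairs beyond 3× the
median distance. The mean closest-point distance is non-increasing
across accepted iterations (a worsening step terminates, keeping the
last accepted state). The iteration cap defaults to 500 with a
1e-6 µm mean-distance tolerance: convergence of plain closest-point
ICP is linear, and a few hundred iterations are what desk-scale meshes
need to reach the tolerance — the tests recover a 5°/2 µm perturbation
to ~2e-4°/µm.

**Thin-plate splines** use the 3D biharmonic kernel `U(r) = r` (not
the 2D `r² log r`): the data are 3D and the 3D fundamental solution is
the appropriate minimiser of the second-derivative energy. The linear
system enforces orthogonality of the kernel weights to the affine
monomials; `lambda = 0` interpolates the landmarks exactly, `lambda >
0` ridge-regularizes the kernel block (and for coplanar landmarks the
minimum-norm solution resolves the inherently rank-deficient affine
part). The bending energy is the kernel quadratic form `−Σ wᵀKw`
(non-negative on the constraint subspace; zero exactly when the
landmark relation is affine).

**Warping volumes** uses inverse mapping: each output voxel centre is
pulled through the inverse transform and sampled trilinearly, with
out-of-domain samples set to 0. Affine inverses are exact. TPS warps
have no closed-form inverse; the default approximation fits the
reverse-direction TPS (exact for affine relations, adequate for the
smooth morphs the pipeline produces), and a fixed-point refinement
mode iterates `p ← p − (W(p) − x)` for stricter inversion.

**Reference registry.** Stage lookup rounds half-up to the nearest
integer stage in the registry (ties cannot occur on integers). The
bundled `make_reference_set()` writes *synthetic placeholder* meshes
whose size grows linearly with stage — a stand-in for a real staged
reference database, suitable for exercising the registration code, not
a biological model.

## Analysis operators

Slabs use half-open `[lo, hi)` voxel index ranges; a thickness-1 slab
equals the orthogonal slice under either reduction. Oblique slices
sample all channels on one shared orthonormal in-plane lattice (basis
chosen deterministically from the least-aligned coordinate axis) so
multi-channel images are comparable sample-by-sample. Line probes use
evenly spaced points and trilinear sampling, which reproduces affine
intensity fields exactly. Multi-isosurface extraction spaces levels
linearly over the requested range and caps the count at 10; empty
levels are skipped and recorded rather than raised, because interior
levels of a windowed volume may legitimately be void. All operators
are pure — input grids are never modified.

## The phantom generator

The phantom emulates the geometry, not the optics, of a cleared-tissue
light-sheet acquisition: a half-ellipsoid paddle (the limb bud)
protruding along +x on a 160×140×48 grid at 0.65×0.65×2.0 µm spacing,
intensity 100 inside and 0 outside, with multiplicative speckle noise
`(1 + 0.05·N(0,1))` by default — multiplicative rather than additive
because cleared-tissue texture scales with signal. Expression channels
are a proximodistal gradient, a bilobed double-Gaussian, and a torus
("donut") around the proximodistal axis, all with known analytic
surfaces and volumes (`(2/3)πabc` for the paddle) and AER landmarks
placed exactly on the ideal distal rim. Everything is fully interior
to the grid so extracted surfaces are closed, and all randomness flows
through a single seed (the generator saves and restores the session
RNG state). What the phantom does *not* model — point-spread
anisotropy, attenuation with depth, stripe artifacts, autofluorescence
— means passing tests demonstrate correctness of the numerics, not
robustness to real microscope pathology.

Tests run on a smaller 110×96×40 phantom at 1×1×2 µm for speed; the
acceptance measurements use a 97³ impulse volume and 200-voxel
sinusoid volumes. These sizes were chosen as the smallest grids on
which the measured quantities are resolution-independent to well
within the asserted tolerances.

## File formats

Intermediate volumes use an XML ImageData (`.vti`-style) container
with base64-encoded Float64 payloads — lossless and deterministic
(byte-identical rewrites), with spacing and origin in attributes.
TIFF stacks are read page-major (z) with rows as y; because the TIFF
layer stores 32-bit samples on a `[0, 1]` scale, integer-valued stacks
are written as raw UInt32 values (exact round-trip) and general data
with a recorded power-of-two scale (round-trip to ~1e-9 relative).
Meshes use ASCII PLY or legacy-VTK polydata with full double
precision; per-vertex scalars (e.g. distance maps) travel as a
`quality` property.

## Known limitations

- Marching cubes uses face-consistent linear interpolation without an
  asymptotic decider; very under-resolved saddle regions can produce
  geometrically (not topologically) crude patches.
- The TPS volume inverse is approximate away from affine; strong,
  highly local morphs should use the fixed-point mode.
- ICP is single-resolution and assumes a rough initial alignment
  (landmark seeds or an explicit init matrix) for large displacements.
- The staging client's live-HTTP mode shells out to `curl` and is not
  exercised offline; the mock defines the reference schema.
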