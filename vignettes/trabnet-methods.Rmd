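---
title: "Methods: curvature-based analysis of trabecular microstructures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curvature-based analysis of trabecular microstructures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

trabnet analyses trabecular-bone-like binary voxel volumes through the
curvature of their surfaces. The chain is:

1. **Synthetic microstructure** — Gaussian-random-field (GRF) cubes with
   controllable volume fraction, feature size and anisotropy, plus analytic
   fixtures (spheres, cylinders, plates, tori, lattices) with closed-form
   morphometrics.
2. **Surface and curvature** — a triangle mesh of the bone–marrow interface
   and per-vertex principal curvatures $K_1 \ge K_2$, with Gaussian
   curvature $K = K_1 K_2$ and mean curvature $H = (K_1 + K_2)/2$.
3. **Projection images** — the curvature field collapsed to a 2D grid at
   the voxel resolution: each in-plane bin holds the sum of the curvature
   values of the vertices falling in it, over all of the $n$ one-voxel
   layers along the projection axis, divided by $n$.
4. **Measurements** — six histomorphometric parameters (BV/TV, BS, Tb.Th,
   SMI, DA, Conn.D), eight plate/rod geometric parameters (PN, RN, PA, PT,
   RD, RL, NND$_{PP}$, NND$_{RR}$), and the homogenized apparent stiffness
   tensor (nine orthotropic constants in GPa).
5. **CNN regression** — a convolutional network mapping the 4-channel
   curvature projection image of a cube to any of the three target sets,
   trained with MSE loss on min-max-normalized targets.

All physical lengths are millimetres (a 35 µm voxel has `spacing = 0.035`);
curvatures are 1/mm, areas mm², stiffnesses GPa.

# The synthetic generator: what it emulates and what it does not

Real trabecular RVEs (cubes dissected from cadaveric micro-CT scans) are
not distributable, so every stage is exercised on synthetic structures. The
generator smooths standard-normal white noise with an anisotropic Gaussian
kernel (`correlation_length` voxels per axis, stretched by
`anisotropy_scales`), thresholds at the exact sample quantile that leaves
`target_bvtv` of the voxels solid, and keeps the largest 26-connected
component. This reproduces the statistical knobs the analysis cares about —
volume fraction, feature size, elongation/anisotropy, and a bicontinuous
plate–rod morphology at intermediate volume fractions — but **not** the
anatomy of real bone: no cortical shell, no preferential load-aligned
arcades, no marrow-space gradients, and a smoother interface than a real
segmented scan. Passing tests on GRF cubes therefore demonstrate that the
measurement and learning machinery is correct and self-consistent, not that
the same accuracy numbers would be observed on cadaveric data.

The default study conditions for the learning experiments are 300 cubes of
64³ voxels at 35 µm, with per-sample draws of BV/TV in [0.10, 0.40]
(spanning osteoporotic to dense trabecular bone), correlation length in
[2, 5] voxels (feature sizes of roughly 0.1–0.35 mm), and a z-axis stretch
in [1, 2.5]. Exclusion mirrors specimen screening: cubes with BV/TV < 0.05
or with a largest component under 64 voxels are dropped with a recorded
reason (the quantitative cut-offs are package choices; published specimen
exclusions are qualitative).

# Surface extraction and curvature estimation

The occupancy field, optionally Gaussian-smoothed, is sampled at voxel
centres, padded with one background layer (so cut structures are capped
exactly on the bounding box), and triangulated by marching tetrahedra at
iso-level 0.5. Marching tetrahedra was chosen over classic marching cubes
because it is case-table-free, orientation-consistent and watertight by
construction; the denser triangulation is harmless downstream.

Per-vertex curvature uses finite differences of vertex normals along edges:
each face fits its second fundamental form by least squares from the three
edge-wise normal differences in a local face frame; face tensors are
averaged to vertices with corner-angle weights and eigen-decomposed to
$K_1 \ge K_2$. The sign convention is bone-convex positive (a solid bone
sphere has $K_1, K_2 > 0$); flipping the mesh orientation negates both.

Two numerical choices matter on voxel data:

* **Normals.** On binary isosurfaces, face-averaged normals carry
  staircase noise that dominates the anisotropic part of the curvature
  tensor. When a smoothing sigma is given, trabnet instead evaluates the
  analytic gradient of the Gaussian-convolved occupancy exactly at each
  vertex position — a smooth normal field free of grid interpolation
  artefacts. Meshes read from STL fall back to face-averaged normals.
* **Smoothing scale.** The pre-smoothing sigma must be large enough to
  suppress voxelization terraces (whose width grows like $\sqrt{2r}$
  voxels on a feature of radius $r$ voxels) yet small against the feature
  itself. The analytic fixtures (feature radii 14–40 voxels) use
  $\sigma = 3$–$3.5$; trabecular-scale structures (feature radii 2–6
  voxels) use $\sigma = 1$, the pipeline default. With these choices the
  sphere and cylinder fixtures reproduce their analytic curvatures within
  5% and the Gauss–Bonnet sums close within 5%.

Cut-plane vertices (within one voxel of the bounding box by default) are
excluded from curvature statistics, surface areas and SMI; the exclusion
depth grows to $2\sigma$ when the mesh was smoothed, because smoothing
rounds the cut rim over that distance. Projections, following the
projection equation's "sum everything" reading, use all vertices by
default.

# Projection images

The projection bins live on the volume's voxel grid (a 6 mm cube at 35 µm
gives the 172×172 grid and $n = 172$ layers; a 64³ cube gives 64×64 and
$n = 64$). Bin intervals are half-open in physical coordinates, boundary
vertices go to the higher bin, and empty bins are exact zeros. The
operation is linear in the curvature field and conserves
$\sum_{\text{bins}} \times n = \sum_{\text{vertices}}$ to rounding. For CNN
input the four kinds (k1, k2, K, H) are stacked as channels;
`projection_stack()` can min-max rescale each channel per image (recording
the ranges), but the experiment pipeline keeps raw values and normalizes
channel-wise over the training split instead — see the CNN section. The
projection axis defaults to z and is configurable; all four channels share
one axis.

# Histomorphometry

* **BV/TV** — exact voxel count ratio.
* **BS** — mesh area with cut-plane triangles excluded.
* **Tb.Th** — mean over bone voxels of the local thickness map: the
  diameter of the largest inscribed sphere covering each voxel, computed
  from the exact Euclidean distance transform with sphere centres at voxel
  centres and exact pruning of redundant spheres. Centre-constrained
  spheres systematically read jagged cylindrical struts 1–2 voxels thin
  (axis-aligned slabs are exact to one voxel); the bias shrinks with
  resolution and is shared by standard implementations of this definition.
* **SMI** — $6 \cdot BV \cdot S'/S^2$ with $S'$ from offsetting the mesh
  vertices half a voxel along their normals. Offsetting the mesh rather
  than dilating the voxel volume avoids re-triangulation noise in the
  derivative. Plates ≈ 0, rods ≈ 3, spheres ≈ 4.
* **DA** — mean intercept length along 512 quasi-uniform (spherical
  Fibonacci) directions, 128 random line origins per direction, sampled at
  half-voxel steps; the MIL tensor is fitted as
  $1/\mathrm{MIL}(n)^2 = n^\top M n$ by least squares, and
  $DA = 1 - \text{shortest}/\text{longest}$ ellipsoid semi-axis (BoneJ
  convention, bounded [0, 1); the long/short ratio is available as an
  option). Deterministic for a fixed seed; the fit errors out if the
  ellipsoid is not positive definite.
* **Conn.D** — $(1 - \chi)/V$ with $\chi$ counted on the cubical complex
  of the union of closed voxels (vertices − edges + faces − cubes), which
  matches 26-connectivity of the solid phase and is additive over
  components.

# Plate–rod decomposition

Full individual-trabecula segmentation (digital topological classification
with iterative arc/surface decomposition) is **not** reproduced. The
package's surrogate classifies bone voxels directly by local geometry:

1. every bone voxel inherits the centre of the maximal inscribed sphere
   covering it, so rim voxels see the same thickness direction as their
   plate or rod interior;
2. the thickness direction at that centre is the smallest-variance
   principal axis of the occupancy in a box scaled to the local thickness
   (robust where the nearest-background direction is ambiguous, e.g. plate
   edges), with mirror continuation at the RVE faces;
3. the bilateral extent of the structure is probed along 8 directions
   spanning the plane perpendicular to the thickness direction; a
   direction is "extended" when the extent exceeds twice the local
   thickness, and a voxel is plate-like when at least 4 of 8 directions
   are extended (an ideal straight rod can reach at most 3);
4. majority-vote smoothing, then 26-connected regions of one class become
   the individual trabeculae; regions under 27 voxels are absorbed into
   their dominant neighbour. The labels partition the solid phase exactly.

Plate thickness is the mean local thickness over the plate's voxels, plate
area its volume divided by that thickness, rod diameter the mean local
thickness, rod length the extent of the rod's voxels along their principal
axis (exact for straight struts, an underestimate for strongly curved
ones), and the nearest-neighbour distances are centroid-to-centroid within
a class. Thresholds (2× thickness, 4/8 votes) are geometric constants of
the plate/rod dichotomy, not tuned quantities: an infinite plate extends in
all in-plane directions, an infinite circular rod only within ±22.5° of its
axis (a 45° chord of a circular section is 1.41 diameters, safely below 2).

# Micro-FE homogenization

Each bone voxel becomes six congruent first-order tetrahedra sharing the
voxel diagonal (one trilinear hexahedron in `element = "hex"` mode), with
the isotropic tissue law E = 15 GPa, ν = 0.3. "Uniform boundary
conditions" are implemented as kinematic-uniform: all nodes on the RVE
bounding box are prescribed $u = \varepsilon^0 x$ for each of the six
canonical unit strains (three uniaxial, three engineering shears), and the
interior is solved matrix-free by Jacobi-preconditioned conjugate
gradients to a relative residual of 1e-8 (configurable). Column $j$ of the
6×6 Voigt stiffness is the volume-average stress of case $j$ (element
stress integrals divided by the full RVE volume, which scales bone stress
by the bone fraction); the matrix is symmetrized with the asymmetry norm
recorded. Floating fragments, which cannot carry load, are removed before
meshing with a logged count. For a fully dense cube the affine solution is
exact, so the homogenized tensor reproduces the isotropic law to solver
precision — the package's strongest self-check. The 6-tet split's slight
orientation bias is bounded by the hex cross-check (5% on porous GRF
cubes). Fabric rotation uses the Bond transformation of the Voigt matrix
onto the MIL ellipsoid eigenvectors; orthotropic projection zeroes the
couplings outside the orthotropic pattern and reports the Frobenius norm
of the discarded part, so both the pure rotation and the projected tensor
are available. Default problem sizes are 16³–64³ (about 25k–1.6M
tetrahedra); the full 172³ scan scale is supported but long-running.

# CNN regression

The three tuned presets are: histomorphometric (kernel 3×3, pool 2×2,
filters 8-16-32, dense 128-64, 6 outputs, dropout 0.3, 200 epochs),
geometric (kernel 5×5, filters 16-16-64, 8 outputs, dropout 0.4, 300
epochs) and stiffness (kernel 3×3, filters 16-32-64, 9 outputs, dropout
0.5, 250 epochs), all with learning rate 1e-4 and MSE loss. Choices the
architecture table leaves open are fixed as: Adam optimizer, ReLU hidden
activations with a linear output layer, batch size 16, dropout on the
dense hidden layers only, and He initialization. The implementation is the
package's own (im2col convolutions through BLAS, verified against
finite-difference gradients); training is fully deterministic under the
config seed, covering the split, initialization, shuffling and dropout.

Targets are min-max normalized with statistics computed on the 80% training
split only and reused for the 20% test split — test ranges never leak into
training. Projection inputs are normalized the same way: per-channel min-max
over the training split (per-image rescaling is available in
`projection_stack()` but discards cross-sample amplitude, which carries most
of the volume-fraction and thickness signal). Because projected curvature
has unbounded heavy tails — near-pinch-off necks reach local curvatures of
thousands per mm — each channel is winsorized at its training 0.5%/99.5%
quantiles before rescaling; without this a handful of spikes set the
channel range and squash the informative amplitudes into a sliver of
[0, 1]. The experiment pipeline
excludes cut-plane vertices from the projections by default: the clipped
caps and rims are artificial surfaces whose curvature spikes say nothing
about the microstructure. Training in the pipeline uses minibatches of 8
and dihedral-8 augmentation — every histomorphometric, geometric and
stiffness-magnitude target is exactly invariant under in-plane rotations
and flips of the projection, so each training image is presented under a
random symmetry each epoch, and predictions are averaged over the eight
transforms at evaluation time. Evaluation reports per-target $R^2$ (squared Pearson correlation
of prediction vs truth, matching the field's reporting convention) with
two-sided correlation-test p-values, after denormalizing to native units.

On the default 300-cube synthetic experiment the package asserts test
$R^2 \ge 0.8$ for BV/TV and BS, $\ge 0.5$ for Tb.Th, and that DA ranks
below BV/TV — the qualitative ordering seen on real data (surface-coupled
quantities easiest, anisotropy hardest), at thresholds the synthetic
conditions can support. These are properties of the synthetic experiment,
not reproductions of cadaveric-data accuracy.

# Degenerate inputs and error behaviour

Uniform volumes cannot be meshed; empty volumes cannot be measured;
constant regression targets cannot be normalized (the offending target is
named); single-sample test sets have no correlation; non-manifold meshes
are rejected before curvature; an MIL fit that is not positive definite and
a non-converged PCG solve raise errors rather than returning numbers.
Vertices exactly on bin boundaries go to the higher-index bin; the top
boundary closes the last bin.

# Known limitations

* GRF cubes lack real-bone anatomy (see above); accuracy numbers on them
  do not transfer to scans.
* Local thickness underestimates jagged cylindrical struts by 1–2 voxels.
* Rod length via principal-axis extent underestimates curved rods.
* The plate/rod surrogate is not bit-compatible with published ITS
  implementations and reports no plate/rod volume fractions.
* Kinematic-uniform boundary conditions give an apparent (upper-bound)
  stiffness; periodic homogenization is out of scope.
* Only single-axis projections are implemented; volumetric (3D) curvature
  distributions are not.
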