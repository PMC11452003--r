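---
title: "Shape-aware post-processing of multi-label muscle segmentations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-aware post-processing of multi-label muscle segmentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muscleshape)
```

## The problem

Deep segmenters of lower-limb muscles in MRI produce label maps whose
*overlap* with the reference is good (Dice around 0.8) but whose *surfaces*
are locally unreliable: blank regions (voxels inside a muscle left
unassigned) and mis-segmentations (voxels of muscle A labelled as muscle B,
or spurious islands away from the muscle) inflate worst-case and average
surface distances far more than they dent the Dice coefficient. Generic
post-processors operate on the label map alone; none of them knows what a
muscle *looks like*.

This package implements a shape-aware alternative: learn, per muscle, a
statistical shape model (SSM) from reference segmentations, and replace each
predicted mask by the model's **mean shape** rigidly aligned (iterative
closest point) and then deformably registered (nodal-grid free-form
deformation) onto that prediction. Because the output *is* a deformed copy
of the mean shape, interior holes and detached islands are impossible by
construction, and the surface inherits the anatomical smoothness of the
training ensemble. Two classical post-processors — a slice-wise 2D
morphological pipeline and a fully connected conditional random field (CRF)
— are provided as comparators, along with the four standard evaluation
metrics and a paired Wilcoxon signed-rank test.

## The shape model

Each training mask contributes $m$ *correspondence particles*
$x_k \in \mathbb{R}^{3m}$ constrained to its surface (the zero level set of
its signed distance field). Correspondences across the $N$ subjects are
optimized by minimizing

$$Q = H(Z) \;-\; \sum_{k=1}^{N} H(x_k),$$

where $H(Z)$ is the (Gaussian-model) entropy of the ensemble
$\{x_1,\dots,x_N\}$ in shape space — minimizing it makes corresponding
particles move coherently, compacting the shape-space distribution — and
$H(x_k)$ is a Parzen-window estimate of each particle set's entropy on its
own surface — maximizing it spreads particles uniformly. The gradient flow
alternates a per-surface repulsion sweep and an ensemble compaction sweep;
each sweep is accepted only if it lowers $Q$ (with step halving otherwise),
so the recorded energy trace is non-increasing. Every step ends with a
Newton projection along the SDF gradient back to the surface.

Implementation choices a maintainer should know about:

* **Alignment.** Pose is removed by rigid transforms only — no scaling,
  since muscle size is a real biological signal. Each shape is first placed
  by centroid and principal axes (with the identity rotation kept as a
  candidate: near-axisymmetric shapes have degenerate transverse moments and
  a moments-only fit can return an arbitrary large rotation), then refined
  by ICP against the surface of the evolving ensemble mean. Aligned signed
  distance fields are obtained by *trilinear resampling of the native-frame
  SDF* through the rigid transform — signed distance is rigid-invariant, and
  this avoids the half-voxel surface jitter that nearest-neighbour mask
  resampling would inject into the shape statistics.
* **Initialization.** One particle set is split-and-relaxed on the surface
  of the *mean* SDF (power-of-two splitting from a single seed point), then
  projected onto every member surface. Identical shapes therefore receive
  identical particles, and the projection displacements are half the
  inter-subject spread rather than the full spread from an extreme member.
* **Entropy estimates.** $H(Z)$ uses a Gaussian model,
  $\tfrac12 \sum_i \log(\lambda_i + \alpha)$, through the $N \times N$ dual
  of the covariance; $\alpha$ defaults to $10^{-3}$ of the mean eigenvalue
  (plus a tiny absolute floor) so the estimate stays finite at rank
  deficiency. $H(x_k)$ uses leave-one-out Parzen windows with a per-particle
  bandwidth set to the distance to the ~6th nearest neighbour. The repulsion
  step moves each particle along the kernel-weighted mean of *unit*
  directions away from its neighbours, capped at two voxels: unit directions
  make freshly split, nearly coincident particles separate at bandwidth
  speed, and the cap keeps the dynamics stable when the adaptive bandwidth
  approaches the shape diameter at small $m$.
* **PCA.** The model keeps at most $N-1$ modes (the rank of the centered
  ensemble), computed through the dual eigenproblem.
* **Mean mask.** The mean correspondence vector is voxelized by warping the
  ensemble member nearest the mean with a biharmonic radial-basis
  interpolant (mean particles → member particles, evaluated on the common
  frame, classified by the member's SDF). Averaging the aligned SDFs and
  thresholding at zero is available as `method = "mean_sdf"`. The RBF route
  is restricted to the particle bounding box plus a margin and keeps the
  largest connected component, because far-field RBF extrapolation is
  meaningless.

## The registration

The deformable step estimates displacements on an isotropic hexahedral node
grid with nodal spacing `ns` voxels (default 5, the published sensitivity
optimum for 1 mm muscle masks), minimizing

$$\sum_x \big(\tilde F(x) - \tilde M(x + u(x))\big)^2
  \;+\; \lambda \sum_{\text{nodes}} \lVert \Delta u \rVert^2 ,$$

with $\tilde F, \tilde M$ Gaussian-smoothed (σ = 1 voxel) versions of the
binary masks — raw binary SSD has zero gradient almost everywhere — dense
$u$ by trilinear interpolation between nodes, and $\Delta$ the node-graph
Laplacian. The optimizer is gradient descent with a backtracking line
search; a two-level node-grid schedule (a first pass at twice the nodal
spacing initializes the fine grid) is the default because it recovers bulk
offsets in a fraction of the iterations a single-level descent needs, and
reaches clearly better optima on shift-recovery phantoms. The node grid
covers the union bounding box of both masks plus one nodal spacing; the
computation is restricted to that box.

`auto_lambda()` concretizes "automatically optimised smoothing" as: scan the
candidate grid in ascending order and return the smallest λ whose dense map
has a strictly positive Jacobian determinant everywhere (no folding). The
*default* candidate grid is $\{1, 10, 100\}$: at desk scale, values below 1
let the NS=5 field chase single-voxel boundary noise without ever folding —
the fold test cannot reject smooth noise-chasing — which measurably degrades
the warped mean. Any grid (e.g. $10^{-2}\dots10^2$) can be passed when the
target is trusted to be clean.

`apply_displacement()` backward-maps the moving mask's *signed distance
field* through the dense field and classifies by sign. An earlier draft
warped the σ = 1-smoothed binary mask and re-thresholded at 0.5, but that
convention systematically deletes structures thinner than about 1.5 voxels
— the tapered end caps of elongated muscles — and makes even the zero
field a lossy identity; the SDF convention is exact under zero and
integer-voxel fields and preserves thin caps. The negated sampled SDF (an
inside-depth) plays the role of the soft value when multi-label
recomposition resolves voxels claimed by several labels (deepest claim
wins, ties to the lowest label id).

## The comparators

The 2D pipeline follows the published parameterization exactly: per label
and per axial slice, erosion by a discrete disk
$\{(di,dj): di^2+dj^2 \le r^2\}$ with $r=3$, 8-connected component
labelling, retention of the single largest component, dilation by the same
disk, hole filling, and a uniform 5×5 zero-padded convolution thresholded at
0.5. The convolution is computed in exact integer counts so the
threshold-at-0.5 decision can never be flipped by floating-point noise. The
published table orders dilation before hole filling while the accompanying
prose fills first; this implementation follows the table and exposes the
order as a parameter.

The CRF is the fully connected model with Gaussian pairwise kernels
(appearance + smoothness), Potts label compatibility, and synchronous
mean-field updates initialized at the unary distribution. Inference is exact
$O(n^2)$ message passing, capped at 4096 pixels per slice — correctness over
speed at desk scale; the permutohedral-lattice approximation of large-scale
implementations is deliberately out of scope. Defaults are the published
weights $W^{(1)}=\theta_\alpha=\theta_\beta=10$, $W^{(2)}=\theta_\gamma=1$
with 5 iterations (the cited reference's convention; the source does not
state a count). Slices are processed independently in 2D, matching the
slice-wise origin of the probability maps.

## Morphological conventions

`cleanup_3d()` — the rough opening applied to every predicted mask before
any post-processor — uses the radius-r ball of the *Chebyshev* metric (a
$(2r+1)^3$ box). The Euclidean discrete ball of radius 1 is the 6-neighbour
cross, and opening with a cross clips the corners of any cuboid; the box
element leaves fat convex bodies exactly unchanged while still deleting
specks and sheets thinner than the element, which is the behaviour wanted
from a rough cleanup. Erosion treats the outside of the array as foreground
(and dilation as background), so shapes touching the border are not eaten.

The signed distance field places its zero level at the interface between
boundary foreground voxels and the adjacent background (inside/outside
distances pulled back by half the smallest voxel step), so thresholding the
field at zero reproduces the mask exactly. Surface voxels are foreground
voxels with at least one background 6-neighbour, the same convention the
surface-distance metrics use.

## What the phantoms emulate

`generate_shape_family()` builds elongated, tapered tubes along the third
axis whose per-slice radius is a shared arch profile plus a per-subject
low-order cosine perturbation (at most 4 harmonics), optionally bent by a
smooth centerline offset — the variability is low-dimensional by design so
a shape model can recover it. The default grid is 64×64×96 voxels at 1 mm:
desk-scale, but elongated like the axial stacks the method targets.

`corrupt_prediction()` reproduces the segmenter error taxonomy: spherical
voids (blank regions), spurious blobs placed 2–5 voxels outside the label
(mis-segmentation; close enough to exercise cleanup and largest-component
logic), reassignment of part of the contact zone between adjacent labels,
and a **smooth boundary displacement** — the surface is moved by a
2-voxel-correlation Gaussian random field scaled by the stated amplitude.
Boundary errors of real segmenters are coherent notches, not independent
voxel flips; i.i.d. salt-and-pepper in a band would be annihilated by any
opening and would caricature the problem. The noise correlation length is
deliberately *shorter* than the default nodal spacing, so the registration
cannot chase it — rejecting sub-grid noise while following anatomy is
precisely the mechanism that makes the mean-shape method work. Default
magnitudes (three radius-4 voids, three radius-3 blobs, amplitude-1.5
boundary field) are chosen so corrupted phantoms sit near Dice 0.78–0.83
with surface errors roughly twice to several times what a good
post-processor leaves — the regime the method addresses.

What the phantoms do **not** emulate: MRI texture and bias fields, fat
infiltration, inter-muscle contact over large flat interfaces,
multi-component muscles, and anisotropic acquisition. Passing phantom tests
therefore demonstrates the pipeline's mechanics and its directional benefits
on this error model, not clinical performance.

## Problem sizes and numerical conventions

The test-suite and the acceptance script run at the generator defaults
(64×64×96 voxels, 10 training subjects, 256 particles, 30 optimization
sweeps, 12–50 corrupted test subjects), which a laptop core handles in
minutes. Degenerate inputs are first-class: empty masks raise typed errors
where an answer would be meaningless (`signed_distance`, surface metrics) or
pass through harmlessly where it is (`cleanup_3d`); an empty prediction for
a label is skipped with a warning — ICP needs a target, and instantiating a
muscle from the mean at a guessed pose would fabricate anatomy. Dice of two
empty masks is defined as 1 and flagged. Ties in the largest-component rule
and in multi-label overlap resolution are broken deterministically (scan
order / lowest label id). All randomness flows through explicit integer
seeds, and every generator is a pure function of (spec, seed).

## Known limitations

* The correspondence optimizer is a surrogate gradient flow with
  per-sweep acceptance, not a faithful reproduction of any particular
  SSM package's scheduling; on noisy ensembles it converges to
  correspondence quality sufficient for the mean shape, not to a
  publication-grade minimum-description-length model.
* Rigid ICP can lock onto the wrong axial offset for strongly periodic
  radius profiles; the deformable step recovers small locks (a few voxels)
  but not gross ones. Near-symmetric flips of elongated shapes are
  indistinguishable by surface RMS, so the mean-shape pipeline re-ranks the
  converged ICP basins by volumetric overlap with the prediction before
  committing to a pose.
* On a *clean* prediction the warped mean cannot beat the subject-to-mean
  shape distance: the nodal field does not express radius variation finer
  than the nodal spacing, so replacing a perfect mask costs a few DSC
  points while the surface metrics stay excellent — the same trade the
  method makes on real cohorts, where its Dice is at par and its gains are
  in Hausdorff and average surface distance.
* The fold-free λ selection is a heuristic; it guards against invalid maps,
  not against fitting artefacts of a trusted-but-wrong target.
* Exact CRF inference is quadratic in pixels per slice and capped; large
  slices must be tiled by the caller.
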