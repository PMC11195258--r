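---
title: "Bootstrapping dense 3D instance segmentation from sparse 2D annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrapping dense 3D instance segmentation from sparse 2D annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Dense 3D instance segmentation of brain neuropil — every axonal, dendritic
and glial process in a serial-section EM volume assigned its own id — is the
substrate for connectomic and ultrastructural analysis, and the training
data it requires is its main bottleneck: conventional 3D models want densely
annotated, proofread volumes that take hundreds to thousands of expert
hours. `bootseg` implements a workflow that starts instead from *sparse 2D*
annotations — a handful of objects outlined on a single section — and
bootstraps its way to a dedicated 3D model:

1. **Sparse to dense in 2D.** A 2D network is trained on the sparsely
   annotated sections to predict dense per-section local shape descriptors
   (LSDs). Supervision is restricted to annotated voxels by a masked
   weighted mean-squared-error loss, so unlabeled areas contribute nothing;
   the network generalizes into them from what the labeled areas teach.
2. **Stacked dense 2D to dense 3D.** The per-section predictions are
   stacked and fed to a lightweight 3D network that outputs direct-neighbor
   3D affinities. This network never sees raw images: it is trained once,
   purely on synthetic instance labels generated on the fly, which makes it
   dataset- and modality-agnostic.
3. **Post-processing.** Affinities are turned into an instance segmentation
   by seeded watershed over-segmentation, a region adjacency graph (RAG)
   scored by mean boundary affinity, and hierarchical agglomeration.
4. **Bootstrapping.** The segmentation of a second volume, used as-is
   (no masking, no proofreading), trains a 3D multi-task network (MTLSD:
   affinities plus 3D descriptors as an auxiliary task) — the kind of
   dedicated model one would normally train on expert dense ground truth.
   Using two volumes avoids feeding a model its own volume-specific biases.
5. **Evaluation.** Skeleton-based split/merge edit counts (an adapted
   min-cut metric, MCM), variation of information (VOI), and descriptor
   error maps that highlight likely segmentation errors for targeted
   proofreading.

## Local shape descriptors

For a voxel $v$ inside object $L$, Gaussian weights
$w(u) = \exp\!\big(-\sum_a (u_a - v_a)^2\,\mathrm{vs}_a^2 / (2\sigma_a^2)\big)$
are accumulated over same-label voxels $u$ within the $3\sigma$ box
($\mathrm{vs}$ is the voxel size in nm; anisotropy is handled in world
units). The descriptor collects

* the **mean offset** to the local center of mass, mapped per axis from
  $[-\sigma_a, \sigma_a]$ to $[0,1]$ (clipped);
* the **coordinate variances** about that mean, divided by $\sigma_a^2$;
* the pairwise **Pearson correlations**, mapped from $[-1,1]$ to $[0,1]$;
* the local **size**: the Gaussian mass relative to an unbounded
  same-label region.

Background voxels carry the all-zero vector. In 2D (per section) this gives
6 channels over $(y,x)$; in 3D, 10 channels over $(z,y,x)$. The
implementation computes all moments by separable convolution per label and
is tested to agree with literal per-voxel summation to $10^{-5}$; the
truncation at $3\sigma$ per axis discards under 1.2% of the Gaussian mass
while bounding the cost.

Near a boundary the offset channels point away from it and the variances
drop in the normal direction, so descriptor discontinuities carry exactly
the boundary evidence the stacked-2D→3D network needs; the size channel
additionally flags thin processes. Affinity targets are binary: channel $d$
at voxel $p$ is 1 iff $p$ and $p + \mathrm{offset}_d$ carry the same
positive label, with the direct neighborhood
$(-1,0,0), (0,-1,0), (0,0,-1)$; entries whose partner falls outside the
volume are 0 and masked out of the loss.

## Masked loss and class balance

All networks minimize
$L = \sum w\,(p - t)^2 / \max(\sum w, 10^{-8})$, summed over heads with
unit head weights. Weights are 0 outside the annotation mask (and on
out-of-bounds affinity entries), which makes the gradient with respect to
unsupervised predictions exactly zero — the property that lets sparse
annotation work at all. For affinity heads the two classes are heavily
imbalanced (space-filling tissue is mostly interior, so most bonds are 1);
the 3D trainers therefore rescale in-mask weights inversely to class
frequency, normalized to mean 1. Without this the networks settle on the
base rate and never commit to boundaries.

## The synthetic training distribution

`generate_labels()` draws the dense, space-filling, elongated morphology the
stacked-2D→3D network must expect, with no real data:

1. $N$ seed points uniform in the volume, $N$ uniform in `num_objects`;
2. a noise potential: white noise smoothed at scale `smoothness` (nm),
   anisotropically stretched by per-axis factors drawn from `elongation`;
3. regions grown from the seeds by a seeded watershed in the
   topographic-distance sense: the flood expands in order of accumulated
   noise cost (Dijkstra), with per-axis step costs
   $\mathrm{vs}_a / \mathrm{stretch}_a$, so stretched axes are cheap to
   traverse and objects elongate along them. (Flooding by raw potential
   value instead lets a single low-lying seed claim nearly the whole
   volume — the accumulated-cost flood keeps all $N$ regions non-empty and
   roughly volume-balanced.)
4. `perturb_iterations` rounds of random per-object dilation or erosion
   roughen the boundaries (erosion hands voxels to the smallest adjacent
   id; objects disconnected by a perturbation are reconnected by
   reassigning minor components), and
5. an optional `gap_thickness`-voxel erosion leaves background shells
   between objects.

Defaults (`voxel_size` 10 nm isotropic, `num_objects` 20–30 per
$64^3$–$64{\times}96^2$ volume, `smoothness` 100 nm, z-elongation 1–3 vs
1–1.5 laterally, 2–6 perturbation rounds, no gaps) were chosen once to
resemble densely packed neurites at this resolution.

`simulate_stacked_predictions()` then mimics what a real 2D network emits:
clean per-section 2D descriptors degraded independently per section by a
random integer $(y,x)$ shift up to `jitter_max` (inter-section jitter),
Gaussian blur, additive channel noise, clipping, and whole-section dropout
(missing/failed sections). Defaults — noise s.d. 0.1, blur 0.5 voxel,
dropout 2%, jitter 0 — were calibrated once against the per-section error
actually produced by desk-scale 2D models on held-out synthetic volumes.
Integer-voxel jitter is off by default: per-section predictions are
computed from aligned rasters, so a geometric shift is not part of their
error, and training the 3D network against shifted inputs contradicts the
aligned z-affinity targets (it measurably destroys the z channel). The
parameter remains available for modeling poorly registered stacks.

What this emulates — and what it does not: the generator reproduces dense
packing, irregular boundaries, anisotropic elongation and degraded
section-wise predictions, but not branching topologies, organelle texture,
staining artifacts or alignment errors of real serial-section EM. Passing
the scaled-down pipeline tests therefore demonstrates that the machinery is
correct and that the bootstrap logic closes end to end, not that the tiny
networks would segment real neuropil.

## Networks

A compact U-Net implemented in the package (same-padded convolutions +
ReLU, max-pool downsampling, nearest-neighbor upsampling with skip
concatenation, sigmoid heads): 2D models use $(1,3,3)$ kernels on single
sections, 3D models $(3,3,3)$ with optionally anisotropic pooling. The
method is architecture-agnostic; depth, features and pooling are
configuration. The optimizer is Adam (default rate $5\times10^{-5}$; the
synthetic demo uses $1$–$3\times10^{-3}$, appropriate for its few hundred
iterations), with optional decoupled weight decay. Augmentations are y/x
flips, y/x transposition, z-flips (3D), and intensity jitter / additive
noise on raw inputs only; targets are recomputed from the transformed
labels. Sparse 2D training samples patches by rejection until at least 5%
of the patch is annotated (at most 100 draws).

Two training-design points matter more than architecture size:

* **Train/inference consistency.** Every trainer samples a *context
  window*: the supervised core patch plus a margin of at least the model's
  receptive field, filled with real data (zeros only beyond the volume,
  exactly like the inference canvas), with loss weights zero outside the
  core. Without this, same-padded networks learn border-contaminated
  functions on small patches and then misbehave under tiled inference.
  Inference itself is overlap-tiled: tiles are taken with a
  receptive-field margin (rounded up to the downsampling grid) from a
  zero-padded canvas and only tile cores are kept, so tiled and
  whole-volume inference agree to floating-point precision.
* **Capacity control under sparse supervision.** A network trained on a
  handful of annotated instances of a single section will happily memorize
  them; at desk scale the effective cure is a *small receptive field*
  (the demo's 2D model is depth 1, 8 base features, RF ≈ 9 px), which
  forces a local geometric computation that transfers to unseen objects
  and volumes, helped by noise augmentation and weight decay. Class
  balancing of affinity targets (inverse in-mask class frequency, mean 1)
  is on by default in the 3D trainers: space-filling tissue makes bonds
  ~90% positive and an unbalanced MSE settles on the base rate instead of
  committing to boundaries.

## Post-processing

The boundary indicator at a voxel is the mean of the *valid* affinity
entries touching it. Voxels above `boundary_threshold` form the foreground;
an anisotropy-aware Euclidean distance transform is computed inside it, and
its local maxima (default footprint $3\times9\times9$, plateaus merged into
single seeds) seed a watershed on the negative distance. Flood steps and
plateau connectivity only cross faces whose affinity exceeds the threshold
— the *fragment coherence* rule — which guarantees fragments never span a
0-affinity face (with a channel-mean mask alone, two objects meeting at a
flat face would stay connected and could never be separated downstream).

Fragments become RAG nodes (centroids in world nm); each edge's score is
the mean affinity over all face voxel-pairs joining the two fragments.
Agglomeration processes edges in decreasing score order, merging while the
score is at least `merge_threshold`; after a merge the cluster-pair score is
recomputed as the mean over the original face pairs (equivalently the
face-count-weighted mean of the constituent edges), with ties broken by the
(smaller, larger) representative fragment ids, so results are exactly
reproducible. The incremental implementation is tested against a
recompute-everything reference on random graphs.

Finally, voxels left unsegmented (the thin boundary band below the
foreground threshold) are absorbed layer-by-layer into the neighboring
segment behind their strongest above-threshold bond. With binary
ground-truth affinities the excluded band is ~2–3% of the volume and would
otherwise dominate both VOI and skeleton-node dropout; after absorption the
pipeline reconstructs its own ground truth exactly (VOI 0, zero edits),
which is the calibration the recovery tests assert. Voxels with no
above-threshold bond at all stay 0.

`grid_search()` evaluates `segment()` over user grids of both thresholds
against a reference (VOI sum or MCM edits per object), returning the full
ranked table and the argmin — the best-in-grid segmentation is what the
bootstrap reports, mirroring how post-processing parameters are explored in
practice.

## Evaluation

*Ground-truth filtering*: labels with fewer than 500 voxels (strictly) are
removed and the remaining foreground is relabeled by face-connected
components.

*Skeletonization* (the package's own reconstruction, since skeletons are
only an evaluation vehicle): distance-ordered homotopic thinning with
26-connected foreground and endpoint preservation reduces each object to a
center line; skeleton voxels become nodes at voxel-center world
coordinates, 26-adjacency gives candidate edges, a minimum spanning
structure removes transitive shortcuts, and terminal twigs shorter than
`prune_length` (default 10× the minimum voxel size) are pruned.

*Adapted min-cut metric*: skeleton nodes map to the segment at their voxel
(nodes on background are dropped and logged). Split edits per skeleton are
the number of connected components of the subgraph keeping only
same-segment edges, minus one. Merge edits are counted per segment hosting
several skeletons as the number of *cut operations* — a proofreader's
single split action, not the number of cut edges — needed to separate all
skeleton pairs in the fragment graph restricted to that segment, with unit
edge capacities. For small restricted graphs the minimum over all
orders and minimum-cut choices is computed exactly (branch-and-memoize,
verified against exhaustive search); larger graphs use sequential pairwise
separation in skeleton-id order. A pair of skeletons sharing a fragment
cannot be separated by edge cuts; it counts one edit and is logged. Totals
are reported raw, per ground-truth object, and per micron of skeleton path.

*VOI*: over voxels with positive ground truth,
$\mathrm{VOI}_\mathrm{split} = H(\mathrm{seg}\mid\mathrm{gt})$ and
$\mathrm{VOI}_\mathrm{merge} = H(\mathrm{gt}\mid\mathrm{seg})$ in bits from
the joint label histogram.

*Descriptor error maps*: the per-voxel Euclidean norm across channels of
(predicted descriptors − descriptors recomputed from the evaluated
segmentation). Thresholding and binary opening with a world-unit ball
(radius in voxels of the finest axis) removes the speckle caused by
voxel-level boundary disagreement while preserving the extended blobs that
mark real split/merge errors — the mask a proofreading tool would jump to.

## The synthetic demonstration

`demo_bootstrap()` builds the entire two-volume study from the generator:
two $64\times96\times96$ label volumes (10 nm voxels), raw images rendered
as per-object constant shading with darkened boundaries and Gaussian noise
(a minimal learnable image→descriptor task), and a sparse annotation
covering ~30% of the instances of a single section of volume 1. Training
budgets are a few hundred iterations per network with small models —
problem sizes chosen so the full bootstrap exercises every stage at desk
scale. Descriptor scale, patch sizes and iteration counts are recorded in
the demo config; every stochastic stage draws its sub-seed from the master
seed via a counter-based splitting rule (`derive_subseed()`), so the whole
run is reproducible bit for bit at fixed thread settings.

## Numerical choices and degenerate inputs

* Gaussian support truncated at $3\sigma$; correlations defined as 0.5
  (mapped) when either variance vanishes; all descriptor channels clipped
  to $[0,1]$.
* Loss guard $\varepsilon = 10^{-8}$ makes an all-masked patch a no-op.
* Watershed ties broken by insertion order (FIFO) with a fixed neighbor
  order; agglomeration ties by representative ids; every stage is
  deterministic given its seed.
* An all-zero affinity field yields an empty (all-0) segmentation with a
  logged note; an object thinner than one voxel everywhere skeletonizes to
  a single node; degenerate synthetic draws are retried with fresh
  sub-seeds (at most 5 times).
* Labels are stored as unsigned 64-bit in Zarr/N5 (ids up to $2^{53}$
  round-trip exactly through R doubles); TIFF label export is 16-bit.

## Limitations

* The supported containers are Zarr v2 (uncompressed chunks), N5 (raw
  compression), single-block layouts on write, plus multi-page TIFF with a
  JSON geometry sidecar; HDF5 input is not supported in this build.
* The generator does not produce branching, tube-like or organelle-bearing
  morphologies; conclusions from synthetic runs are about machinery, not
  biology.
* Networks run on CPU at desk scale; the training engine is intentionally
  compact (no batching across patches, no elastic augmentation).
* Post-processing is in-memory; volumes must fit in RAM (no blockwise
  processing).
* A single bootstrap round is implemented; iterative refinement is a
  configuration extension, not a loop the package runs.
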