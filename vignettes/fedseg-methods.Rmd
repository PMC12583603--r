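---
title: "Methods: federated self-configuring segmentation in fedseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: federated self-configuring segmentation in fedseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and numerical choices
behind `fedseg`: what exactly is computed, which parameters matter, what
the synthetic benchmark does and does not emulate, and where the design
was genuinely open.

## The pipeline

A self-configuring segmentation pipeline has three phases: *preparation*
(summarize the dataset into a fingerprint, derive a training plan and
hence an architecture), *training*, and *evaluation*. `fedseg` federates
the first two phases across simulated clients that never share raw
images:

* **FFE** federates preparation: local fingerprints are concatenated into
  a global fingerprint and redistributed, so all clients plan against the
  same data summary. With a shared resource budget the derived plans are
  byte-identical, and training proceeds with classical FedAvg (full-state
  weighted averaging after every round).
* **AsymFedAvg** federates training only: each client plans from its own
  fingerprint, and each round the server averages exactly those layers
  that occur in every client's state dictionary under the same name with
  the same parameter shape. Everything else remains local.

## Fingerprints

A fingerprint holds `shapes_after_crop` (per-case shape after cropping to
the minimal axis-aligned bounding box of nonzero image intensity — the
upstream convention; an all-zero image degenerates to its full extent),
`spacings` (mm per voxel, same axis order as the array), and an intensity
summary (mean, sd, 0.5th/99.5th percentiles). Aggregation is ordered list
concatenation; `n_cases` is the sum. It is associative up to list order
and the single-fingerprint aggregate is the identity.

Intensity statistics are computed over at most 10^4 voxel intensities per
fingerprint, subsampled deterministically (given a seed) from inside each
case's nonzero crop, with a per-case quota of `cap / n_cases`. Pooling at
aggregation concatenates the retained samples and recomputes the summary;
exact percentile pooling over all voxels would require transmitting them,
which the bounded subsample approximates while keeping the exchanged
object small. Whether intensity statistics belong in the *exchanged*
fingerprint at all is left open upstream; extraction therefore takes
`include_intensity = FALSE` to restrict the exchange to spatial
characteristics. Spatial planning never depends on the intensity block.

## The planner

`make_plan(fingerprint, budget)` approximates the upstream
self-configuration heuristics with integer-stable arithmetic:

| quantity | rule | default constants |
|---|---|---|
| target spacing | per-axis *lower* median of spacings | — |
| median shape | per-axis lower median of shapes rescaled to target spacing | — |
| patch size | median shape, scaled isotropically to fit `max_patch_voxels`, rounded up per axis to a multiple of 2^poolings (iterated to a fixed point) | — |
| poolings per axis | halvings until the axis would fall below 4 | bottleneck min 4 |
| stages | max over axes of poolings + 1 | — |
| features per stage | min(32 · 2^i, cap) | base 32; cap 512 (2D), 320 (3D) |
| batch size | clip(round(12 · 512² / patch voxels), 2, `max_batch`) | anchor 12 @ 512² |

The bottleneck minimum of 4 is the single constant that reproduces the
published per-patch stage counts (256 → 7 stages, 320 → 7, 512 → 8). The
lower-median convention (rather than interpolation) keeps plans identical
across platforms, which the FFE guarantee depends on. Because the
divisibility rounding happens after the budget clip, a plan's patch can
exceed the voxel budget by less than one rounding step; the budget is a
sizing heuristic, not a hard allocator. Batch sizes keep only the
inverse-scaling shape of the upstream GPU-memory model (which is not
published as a formula), anchored at 12 samples for a 512×512 patch; the
published per-center batch sizes are therefore not claimed to be
reproduced. Kernel sizes are fixed at 3 (conv) and 2 (pooling) on all
axes — architecture divergence across sites is exercised through stage
count and patch size, not anisotropic kernels.

## The network and its naming schema

`build_architecture(plan)` emits a U-Net as an ordered, shape-annotated
layer list under a fixed naming schema:
`encoder.stages.<i>.{convs,norms}.<j>.{weight,bias}`,
`decoder.stages.<d>.upconv.{weight,bias}`,
`decoder.stages.<d>.{convs,norms}.<j>.{weight,bias}`, `head.{weight,bias}`.
Each stage is two 3×3 conv + instance-norm + leaky-ReLU (slope 0.01)
blocks; downsampling is a stride-2 entry conv per stage (stride 1 on axes
whose pooling budget is exhausted); the decoder mirrors with
kernel-equals-stride transposed convs and skip concatenation; a 1×1 head
maps to class scores.

Decoder stages are indexed from the bottleneck outward
(`decoder.stages.0` deepest). This convention decides which decoder
layers shape-match across models of different depth: with the feature cap
active, the deepest decoder stages of a 7- and an 8-stage model coincide
in shape and are shared, while the cap-free shallow stages diverge.
Instance norm carries affine weight/bias only (instance norm has no
running statistics); those affine parameters live in the state dictionary
and participate in aggregation like any other layer. Deep supervision is
omitted — it multiplies the naming surface without adding anything to the
federation mechanisms under study.

Training is Dice + cross-entropy (equally weighted, batch Dice over
foreground classes), SGD with Nesterov momentum 0.99, and polynomial
learning-rate decay `lr0 (1 − e/E)^0.9` with `lr0 = 0.01`, computed from
the *global* epoch counter so federated clients stay in lockstep. All
are overridable via `train_hyperparams()`. Momentum buffers are kept
local to each client and never exchanged; whether optimizer state should
survive aggregation is unstated upstream, and keeping it local is the
conservative reading (the exchanged object remains exactly the state
dictionary). Patches are sampled with a 1/3 forced-foreground rate.
The forward/backward passes run through im2col + BLAS GEMM kernels
(compiled, double precision); gradients are verified against finite
differences in the test suite.

## Aggregation semantics

The printed definition of the aggregate is the unweighted mean over the
nodes containing a layer, while the experimental protocol describes
dataset-size-proportional weighting with an equal-center variant. These
are reconciled as a *restricted-renormalized weighted mean*: for layer
`l` with contributors K_l, weights are restricted to K_l and renormalized
to sum to 1; uniform weights recover the plain mean exactly.

Two readings of the matching rule are shipped because the source
definitions are in genuine tension: the matching function requires a
layer to be present in *all* nodes, yet the aggregate is indexed over
"the nodes that contain the layer", which suggests per-layer subsets.
`compatible_layers(mode = "strict")` (default) implements the universal
reading; `mode = "partial"` aggregates any layer on which ≥ 2 clients
agree in name and shape. Neither is asserted to be the source's intent;
layers with conflicting shapes are excluded in both modes.

Summation runs in ascending client order with no pairwise tree, so
aggregation is bitwise reproducible, and with identical architectures
AsymFedAvg reproduces FedAvg parameter-for-parameter (the two are
implemented independently and the equality is asserted bitwise in the
tests). `fedavg()` on identical inputs is a fixed point only up to
floating-point rounding of the weights (1/3 is not representable), which
is why that property is tested at 1e-14 rather than bitwise.

## Metrics

DSC is `2|A∩B| / (|A|+|B|)` per label with the both-empty → 1,
one-empty → 0 convention, plus an unweighted mean over foreground labels
(the multi-label summary convention is unstated upstream, so the
unweighted mean is used and per-label values are always reported).

HD95 uses boundary voxels (≥ 1 background face-neighbor, array border
counted as background), voxel-center-to-voxel-center Euclidean distances
scaled by spacing, directed nearest-neighbor distances pooled from both
directions, and the linear-interpolation 95th percentile — the common
medpy-style variant; an exhaustive all-pairs oracle pins the definition
down in the tests. The empty-prediction convention is also unstated
upstream: both-empty scores 0, exactly-one-empty returns a configurable
penalty defaulting to the physical diagonal of the mask extent, flagged
with an `empty` attribute so it can be reported distinctly.

## The synthetic benchmark

The generator emulates the cross-center heterogeneity that the federated
mechanisms target: matrix size, voxel spacing, intensity profile and
lesion morphology. Lesions are random rotated ellipses parameterized in
millimetres, so spacing differences induce genuine resolution shift (a
4 mm lesion is 8 px at 0.5 mm spacing but under 3 px at 1.5 mm), not mere
rescaling. Images are Gaussian background noise, a foreground intensity
offset, and a smooth multiplicative bias field. Every case is a pure
function of (center seed, case index); changing one center's seed leaves
the others untouched.

Preset conditions (chosen once as a realistic desk-scale miniature of
multi-center cohorts): `heterogeneous3` is a low/high-resolution split —
64 px @ 1.5 mm, 96 px @ 1.0 mm, and 160 px @ 0.5 mm with a brighter
foreground and stronger bias field at the fine-resolution site; 25 cases
per center; background N(0.25, 0.12²), foreground N(0.55, 0.15²) (0.65 at
the fine site), bias amplitude 0.2–0.3, 1–3 lesions of 4–12 mm.
`heterogeneous4` adds a 2× spacing gap with unequal dataset sizes
(15/40/25/10), making proportional vs equal-center weighting meaningful.
`homogeneous3` keeps all three centers identical so the FedAvg-reduction
path is exercised.

Each preset carries per-center resource budgets as the simulated local
hardware. At desk scale the patch budget is the binding constraint, so
budget differences (8² vs 16² voxel patches) are what produce distinct
2- vs 3-stage architectures for the asymmetric path; per-client resource
configuration is an explicit feature of the federated setting being
modeled. At realistic budgets the same presets produce 5- and 6-stage
architectures from the data alone.

What passing tests show — and do not. The benchmark demonstrates the
*mechanisms*: plan identity under FFE, exact aggregation semantics,
asymmetric sharing, and the qualitative ordering (federated ≥ local mean
held-out DSC; an off-diagonal deficit when a coarse-resolution model is
evaluated on the fine-resolution center). Gaussian-noise ellipse phantoms
are trivially separable compared to breast MRI or fetal ultrasound;
absolute DSC/HD95 values here say nothing about real-data performance,
and no claim is made that they do.

## Federation orchestration

Clients are simulated in-process behind an explicit message-passing
surface: the orchestrators exchange only fingerprint and state objects,
and every exchange is appended to an audit trail that the tests inspect —
raw images never cross the boundary by construction. Aggregation happens
after every epoch (1 epoch per round by default, configurable), and
evaluation always uses the final round's checkpoint. Re-planning
mid-federation is not supported: datasets are assumed static for the life
of a run. A networked transport could replace the in-process loop without
touching the algorithms, which is the reason the boundary is explicit.

The end-to-end experiment (`run_benchmark_experiment`) uses a single
80/20 train/held-out split per center rather than 5-fold
cross-validation; the folds harness would multiply runtime fivefold
without changing what the desk-scale benchmark can demonstrate. Problem
sizes used by the shipped experiment: 3 centers × 25 cases, 30 rounds ×
1 epoch × 8 iterations × batch 2, three seeds, 2–3-stage networks on
8²–16² patches.

## Numerical choices and degenerate inputs

* Lower medians everywhere a median enters a plan (integer stability).
* He-normal initialization (fan-in = k²·c_in), zero biases, unit norm
  scales; deterministic given a seed.
* Instance-norm epsilon 1e-5; leaky-ReLU slope 0.01.
* `lr = 0` performs no update (exact zero-step identity); non-finite loss
  aborts with "diverged".
* All-zero images fingerprint at full extent; empty mask patches carry
  only background CE signal (batch Dice guards the denominator with
  eps = 1e-5).
* Canonical JSON (sorted keys, full precision) for every exchanged
  artifact, so byte-identical files ⇔ equal objects; checkpoints carry an
  MD5 checksum verified on read.
* Every random draw flows from one run seed through named substreams
  (data, init, training, fingerprint subsampling), so any component can
  be replayed in isolation.

## Limitations

* Networks are 2D only; the fingerprint, planner and metrics are
  dimension-generic, and 3D plans are produced but not instantiable as
  networks.
* Augmentation is absent (patch sampling only); no post-processing
  selection, ensembling, cascades or region-based losses.
* The batch-size rule is a shape-preserving stand-in for a GPU-memory
  model, not a reproduction of it.
* CPU training limits the benchmark to small patches and shallow
  networks; the architecture-divergence regime is entered via budgets at
  this scale (see above).
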