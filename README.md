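# fedseg

Federated, self-configuring medical image segmentation at desk scale.

Multi-institutional segmentation models are usually trained by pooling
images in one place, which modern privacy regulation makes difficult.
Federated learning (FL) sidesteps pooling — only model weights cross the
institutional boundary — but self-configuring segmentation pipelines break
the central FL assumption: because each site's dataset has different voxel
spacings, matrix sizes and intensity distributions, self-configuration
gives each site a *different* network architecture, and classical FedAvg
cannot average parameter tensors of different shapes.

`fedseg` is a self-contained R framework that implements and studies the
two mechanisms that resolve this conflict, together with everything needed
to exercise them without any external dataset:

* **Federated fingerprint extraction (FFE).** Each site computes a dataset
  *fingerprint* — the list of case shapes after cropping to the nonzero
  bounding box, the list of voxel spacings, and bounded intensity
  statistics. The server concatenates the local fingerprints into a global
  fingerprint *z* and redistributes it; every site then derives its
  training plan from *z*, so sites with comparable hardware obtain
  *identical* architectures and standard FedAvg applies.

* **Asymmetric federated averaging (AsymFedAvg).** Sites keep the
  architectures derived from their own local fingerprints. With the model
  state dictionary of node *k* written as S<sup>k</sup> = {(l, θ<sub>l</sub><sup>k</sup>)},
  the layer-matching set

  &nbsp;&nbsp;&nbsp;&nbsp;C = { l : l present in every node's model with identical dim(θ<sub>l</sub>) }

  is averaged each round, θ̂<sub>l</sub> = Σ<sub>k∈K<sub>l</sub></sub> w̃<sub>k</sub> θ<sub>l</sub><sup>k</sup>
  (w̃ renormalized over the contributing nodes K<sub>l</sub>; uniform
  weights give the plain mean), and sent back; layers outside C evolve
  only locally. Weights are dataset-size proportional by default, or
  uniform ("equal center").

Around these, the package provides a simplified self-configuring planner
(target spacing, patch size, stage count, features per stage, batch size
from a fingerprint plus a resource budget), a dynamic 2D U-Net built from
a plan with a canonical layer-naming schema (the substrate the matching
function operates on — training runs on CPU via compiled im2col/GEMM
kernels), four training modes (local / centralized / FFE / AsymFedAvg)
over in-process simulated clients, Dice (DSC) and 95th-percentile
Hausdorff distance (HD95) evaluation with cross-center matrices, and a
synthetic multi-center generator whose presets emulate realistic
cross-site heterogeneity (2x spacing gaps, 64–160 px matrices, shifted
intensity profiles).

## Worked example

Three synthetic centers with a low/high-resolution split; each center's
own fingerprint and hardware budget yield its own architecture:

```r
library(fedseg)
bm <- make_benchmark("heterogeneous3", "demo_data", seed = 42, n_cases = 8)
clients <- lapply(seq_along(bm$dirs), function(i)
  fed_client_from_dir(bm$dirs[i], budget = bm$budgets[[i]]))

fps   <- lapply(clients, function(cl) fingerprint_from_cases(cl$cases))
plans <- lapply(seq_along(clients), function(i) make_plan(fps[[i]], clients[[i]]$budget))
print(plans[[1]]); print(plans[[3]])
#> <fedseg_plan> 2D
#>   target spacing : [1.5, 1.5] mm
#>   median shape   : [64, 64]
#>   patch size     : [8, 8]
#>   stages         : 2 (features 32-64)
#>   batch size     : 4
#> <fedseg_plan> 2D
#>   target spacing : [0.5, 0.5] mm
#>   median shape   : [160, 160]
#>   patch size     : [16, 16]
#>   stages         : 3 (features 32-64-128)
#>   batch size     : 4
```

The low-resolution center plans a 2-stage network, the high-resolution
centers 3-stage networks — classical FedAvg could not average these.
Asymmetric aggregation trains them jointly anyway, sharing the 18 layers
whose names and shapes coincide (both encoder stages plus the head):

```r
cfg <- fed_config("asymfedavg", n_rounds = 30, seed = 42,
                  hyperparams = train_hyperparams(total_epochs = 30,
                                                  iterations_per_epoch = 8,
                                                  batch_size = 2))
run <- run_asymfedavg(clients, cfg)
tail(round_log_table(run), 2)
#>    round mean_loss compat_size
#> 29    29 0.8369541          18
#> 30    30 0.7826656          18

evaluate_cases(run$states[[2]], clients[[2]]$cases[7:8], run$plans[[2]])
#>         case       dsc     hd95
#> 1 midres_007 0.9679487 1.000000
#> 2 midres_008 0.9123867 2.897056
```

`mean_loss` is the per-round average Dice+cross-entropy training loss;
`compat_size` the number of aggregated layers (constant, since the
architectures are fixed); `dsc` is per-case mean foreground Dice overlap
in [0, 1] and `hd95` the 95th-percentile symmetric surface distance in
millimetres (lower is better). With the global-fingerprint route instead
(`run_ffe`), all three clients would derive one identical 3-stage plan
and aggregate every layer.

`run_benchmark_experiment()` packages the full comparison — local vs FFE
vs AsymFedAvg on a heterogeneous 3-center benchmark with held-out
evaluation and a cross-center DSC matrix.

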