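# elgcot3d

Semantic segmentation of single cotton-plant 3D point clouds into organ
classes (stem, leaf, boll) with a lightweight hierarchical network, written
entirely in R with compiled neighborhood kernels.

Cotton scans are hard: leaf layers occlude each other, bolls look like
curled leaves, and organs differ in size by orders of magnitude — while
field deployment (drones, portable scanners) demands small models.  This
package provides:

* **ELG3D encoder stages** — instead of a plain sample–group–max
  "set abstraction" stage, each multi-scale neighborhood is processed by
  three operators in parallel and fused residually:
  * EdgeConv: shared map of the edge feature `[f_i, f_j − f_i]`, max
    aggregation;
  * local attention: learned scalar scores, softmax over the neighborhood,
    weighted sum of values;
  * graph convolution: one `D^{-1/2}(A+I)D^{-1/2} X W` propagation on the
    per-center star graph;
  plus a mini-PointNet base path, elementwise residual fusion per scale,
  and a 1×1 cross-scale unification map.
* **A cotton-specific enhancement module** on the decoder output:
  multi-branch multi-scale extraction (k-nearest-neighbor branches,
  k ∈ {1, 8, 16}), channel and spatial attention with exportable gates for
  heatmaps, and a depthwise-separable convolution whose parameter cost is
  under half of a standard convolution.
* **MuSGD** — a hybrid optimizer coupling a momentum buffer `m_t = β m_{t−1} + g_t`
  with an RMSProp-style accumulator `v_t = μ v_{t−1} + g_t²` and weight
  decay, updating `p ← p − η m_t / (√v_t + ε)`; plus cosine annealing and
  three point-cloud augmentations (random Z rotation, ≤10 % point dropout,
  50 % mirror flip).
* **An analytic efficiency profiler** (parameters and per-layer FLOPs,
  1 MAC = 1 FLOP, stated in every report) and the ablation variants A–E as
  buildable configurations, with the multi-scale-grouping hierarchical
  baseline included as the comparison anchor.
* **A procedural cotton-plant generator** (parametric stem / serrated
  leaves / bolls, surface-area sampling, sensor jitter, view-dependent
  self-occlusion) so every stage is testable with no downloads.
* Segmentation metrics (per-class IoU, mIoU, OA, precision/recall/F1 from
  a global confusion matrix), PLY and ASCII point-cloud I/O, train/val/test
  splitting, and a small command-line layer (`inst/cli/elgcot3d.R`).

## Worked example

```r
library(elgcot3d)

# 1. a labeled synthetic dataset of cotton-like plants
plants <- generate_dataset(synthetic_plant_config(n_points = 512),
                           n_samples = 8, seed = 11)
sp <- split_dataset(names(plants), c(0.7, 0.2, 0.1), seed = 1)

# 2. the reference lightweight network vs the baseline
model    <- build_elgcot3d(seed = 1)
baseline <- build_pointnet2_baseline(seed = 1)
compare_models(model, baseline, n_points = 2048)
#> ELGCot3D @ 2048 points: 0.801 M params, 1.514 GFLOPs
#> convention: 1 MAC = 1 FLOP; elementwise/pool/distance ops = 1 per output element
#> # A tibble: 8 × 3
#>   module params     flops
#>   <chr>   <dbl>     <dbl>
#> 1 enc1    32636 143867904
#> 2 enc2   237320 865923072
#> 3 enc3   199680  25722880
#> 4 enh     59430 373228096
#> 5 fp1    197376  25493504
#> 6 fp2     49536  25886720
#> 7 fp3     16768  36438016
#> 8 head     8579  17719296
#> vs PointNet++ MSG baseline: params -54.2%, FLOPs -69.3%
```

The reference network assembles to **0.801 M trainable parameters** and
**1.51 GFLOPs** for one 2048-point cloud — inside the published budget of
0.86 M / 2.41 GFLOPs — and reduces parameters/FLOPs by **54 % / 69 %**
against the in-repo baseline (published reductions: ≥ 50.1 % / 50.7 %).

Training and inference at desk scale:

```r
# overfit-sanity demonstration: fit the reduced model to all 8 plants
fit <- train(build_model(reduced_elgcot3d_config(n_points = 512), seed = 3),
             train_set = plants, val_set = plants,
             musgd_cfg = musgd_config(eta = 0.01),
             schedule_cfg = schedule_config(eta_max = 0.01, T = 60),
             epochs = 60, batch_size = 1, seed = 5)
fit
#> trained ELGCot3D (reduced): 60 epochs, final loss 0.1899, val mIoU 0.820, OA 0.924
autoplot(fit)                     # loss / mIoU / OA curves

seg <- segment_points(fit$model, plants[[sp$test_ids[1]]])
table(true = pc_labels(plants[[sp$test_ids[1]]]), pred = seg$predicted_labels)
#>     pred
#> true   0   1   2
#>    0  56  12   1
#>    1   6 345  10
#>    2   0  15  67
glance(evaluate(fit$model, plants[sp$test_ids]))
#> # A tibble: 1 × 3
#>    miou    oa n_points
#>   <dbl> <dbl>    <int>
#> 1 0.795 0.920     1024
autoplot(evaluate(fit$model, plants[sp$test_ids]))  # confusion heatmap
write_point_cloud(seg$cloud, "labeled.ply",
                  attention = seg$attention$point_gates)  # heatmap scalar
```

The fit reaches 0.92 overall accuracy on its training plants (classes 0–2
are stem, leaf, boll); the confusion table shows the residual errors sit at
leaf–boll and leaf–stem junctions, the morphologically ambiguous regions.
Training draws every random quantity — shuffling, rotation/dropout/flip
augmentations, head dropout — from seeds derived per epoch, so the same
call reproduces this history exactly.

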