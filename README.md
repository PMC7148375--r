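# ioucseg

Volumetric brain-tumor segmentation from multimodal MR with an
IOU-constrained 3D symmetric fully convolutional network, for researchers
who want the full method — network, loss, auto-context cascade,
post-processing and evaluation — as inspectable, tested R code that runs
end-to-end on a single CPU.

Gliomas occupy roughly one voxel per thousand of a brain MR volume. Under
that imbalance, per-voxel losses collapse toward "predict background
everywhere". The core of this package is a class-weighted soft-Jaccard
(IOU-constraint) loss over predicted probabilities $X_{cv}$ and one-hot
labels $Y_{cv}$ ($C$ classes, $V$ voxels):

$$L_{IOU} = 1 - \frac{1}{C}\,
  \frac{\sum_{c=1}^{C} \gamma_c^{-2} \sum_{v=1}^{V} X_{cv} Y_{cv}}
       {\sum_{c=1}^{C} \gamma_c^{-2} \sum_{v=1}^{V}
        (X_{cv} + Y_{cv} - X_{cv} Y_{cv})},
  \qquad \gamma_c = \sum_{v=1}^{V} Y_{cv},$$

whose $1/\gamma_c^2$ weights let a 30-voxel tumor class counterbalance a
32 000-voxel background. The probabilities come from a five-level
symmetric 3D encoder–decoder: a coarse block layer (3³ convolutions +
2×2×2 max pooling), four bottlenecked 3D residual groups, and a refinement
decoder that restores resolution by trilinear upsampling with
adapter-layer (1³ convolution + pixel-wise addition) fusion of encoder
features. A second, auto-context stage re-segments using the first stage's
probability maps plus integral-volume 3D Haar-like features as extra input
channels; an adaptive connected-component filter then deletes spurious
regions smaller than one tenth of the largest component. Evaluation
reports Dice, recall, precision and Hausdorff distance (mm) over the
nested whole/core/enhancing tumor regions.

All numerical primitives — 3D convolution and its gradients, pooling,
interpolation, integral volumes, Hausdorff distances, the loss and its
analytic gradient — are implemented natively (R + Rcpp/Armadillo) and
verified against brute-force oracles in the test suite. A synthetic
multimodal phantom generator (nested-ellipsoid tumors, modality-specific
contrasts, one-per-thousand foreground) makes every stage testable with no
external data.

## Worked example

```r
library(ioucseg)

# a small cohort of multimodal phantoms (32^3, tumor fraction 1e-3)
cohort <- generate_cohort(16, phantom_spec(noise_sd = 0.05, seed = 1),
                          split = 0.75)

fit <- sfcnn_fit(cohort$train,
                 config   = sfcnn_config(base_filters = 4),
                 schedule = train_schedule(max_epochs = 20,
                                           augment_rotate180 = TRUE),
                 loss     = "iou",
                 val      = cohort$test, seed = 1)
print(fit)
#> IOU-constrained 3D segmentation network (1624345 params, base filters 4)
#> loss: iou   epochs run: 20   final loss: 0.86508

pred <- predict(fit, cohort$test[[1]]$stack)
segmentation_metrics(cohort$test[[1]]$labels, pred$labels)
#>      region      dice  recall precision hd_mm
#> 1     whole 0.7500000 0.65625 0.8750000     1
#> 2      core 0.7368421 1.00000 0.5833333     1
#> 3 enhancing 0.0000000 0.00000 0.0000000    NA
```

The printed fit shows the loss trajectory summary; the metrics table gives
per-region overlap (Dice/recall/precision, unitless in [0, 1]) and the
symmetric Hausdorff distance in millimetres for one held-out subject. At
this desk scale a tumor is only ~30 voxels, so whole-tumor and core
overlap are solid while the enhancing region — a handful of voxels — is
missed entirely on this subject (its Hausdorff distance is reported as
missing, never as 0). The two-stage cascade
(`cascade_fit()`, `predict()` on the result) and the config-driven
pipeline (`cli_synth()`, `cli_train()`, `cli_predict()`,
`cli_evaluate()`, plus the `inst/cli/ioucseg.R` shell dispatcher) wrap the
same machinery; see the methods vignette for the model, its assumptions
and every tunable default.

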