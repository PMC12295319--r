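# patchfuse

Attention-weighted decision fusion for classifying hematoxylin-and-eosin
(H&E) histopathology image patches — for computational-pathology
researchers and methods developers who want a fully inspectable, offline,
deterministic implementation of a two-branch fusion classifier, from
architecture and exact parameter accounting through training protocol,
multiclass metrics, cross-validation bookkeeping and Grad-CAM
interpretability.

## The model

Two convolutional backbones process the same 224×224×3 patch. Per branch,
a feature map $A \in \mathbb{R}^{H\times W\times C}$ passes through:

1. **spatial attention** — a 1×1 convolution with sigmoid yields a mask
   $M \in (0,1)^{H\times W\times 1}$, multiplied element-wise into $A$;
2. **global average pooling** — the refined map becomes $g \in \mathbb{R}^C$;
3. **classification head** — dense(1024, ReLU) → dropout(0.5) →
   dense(c, softmax) gives the branch prediction $p$.

A fusion layer maps the concatenation $[p_a\,|\,p_b\,|\,g_a\,|\,g_b]$
through dense + softmax to two instance-specific weights $w$ on the
simplex, and the final prediction is the weighted sum

$$\hat{y} = w_1\,p_a + w_2\,p_b .$$

The package assembles this architecture for InceptionV3 / Xception /
MobileNet branch pairs with exact parameter accounting (46,879,070 /
27,253,502 / 28,194,806 parameters for the three pairings at $c = 3$,
$h = 1024$), and trains desk-scale instances on a built-in `tiny` backbone
with a hand-verified backpropagation stack written in base R. Evaluation
covers per-class one-vs-rest rates, multi-category Matthews correlation,
Cohen's kappa, misclassification, fold-mean confusion matrices, and paired
statistical model comparison. A synthetic H&E-palette texture generator
makes every feature testable without downloading any data.

## Worked example

```r
library(patchfuse)
library(dplyr)

# exact parameter accounting for the largest pairing
total_parameter_count(fusion_config("inceptionv3", "xception", num_classes = 3))
#> [1] 46879070

# a deterministic synthetic 3-class set and a desk-scale fusion model
ds  <- generate_dataset(default_texture_specs(), c(40, 40, 40), seed = 1, size = 32)
fit <- train_model(
  build_fusion_model(fusion_config("tiny", "tiny", 3, head_width = 16, seed = 1)),
  ds,
  training_config(learning_rate = 3e-3, max_epochs = 10, batch_size = 16,
                  patience = 8, unfrozen_top_layers = 2, seed = 1))
glance(fit)
#> # A tibble: 1 × 6
#>   epochs best_epoch stopped_early best_val_loss final_train_acc final_val_acc
#>    <int>      <int> <lgl>                 <dbl>           <dbl>         <dbl>
#> 1     10          9 FALSE                 0.262           0.873             1

pred <- predict(fit$model, ds)
cm   <- confusion_matrix(ds$labels, pred$class, 3, ds$class_names)
glance(metric_report(cm)) |> select(accuracy, mcc, kappa, misclassification_rate)
#> # A tibble: 1 × 4
#>   accuracy   mcc kappa misclassification_rate
#>      <dbl> <dbl> <dbl>                  <dbl>
#> 1      100   1     1                        0

colMeans(pred$weights)    # per-instance fusion weights, averaged
#> [1] 0.509 0.491
```

The fused model separates the three texture classes perfectly after ten
epochs (accuracy 100%, MCC and kappa 1), and the learned fusion weights
hover near 0.5/0.5 — both identically-shaped branches are equally
informative here. With one branch degraded, the weights migrate to the
reliable branch (see `train_fusion_gate()` and the test suite's recovery
scenario).

Grad-CAM heatmaps for any trained model come from `gradcam()`, with
`overlay()` / `write_gradcam_png()` for superimposed exports and
`localization_score()` for IoU scoring against ground-truth masks.
Experiments over image trees (`load_patch_dataset()`), 85/15 splits,
5-fold cross-validation and model comparisons run through
`run_experiment()`, `crossval()` and `compare_models()`. A thin CLI over
these functions lives at `inst/cli/patchfuse.R`.

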