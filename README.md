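# oomil — ordinal multi-instance learning with key-instance selection

`oomil` is an R implementation of weakly supervised three-class
classification of grayscale images that carry only an image-level
ordinal label — the setting of screening mammography, where a study is
graded normal < benign < cancer but no region-level annotation exists.

Each image is treated as a **bag** of patch **instances** under the
ordinal multi-instance assumptions: every instance has a hidden ordinal
grade, no instance's grade exceeds the bag label, and the bag label
equals the strongest grade present. Training alternates two steps per
bag:

1. a small CNN scores every patch and each patch's loss against the
   *bag* label is computed;
2. the k minimum-loss patches (default k = 4) are taken as the bag's
   **key instances**, assigned the bag label, and trained with one Adam
   step on the mean of their losses.

The default loss is an all-threshold ordinal penalty on the scalar
score s with trainable cutpoints b1 < b2 partitioning the score axis
into the three ordered class regions:

    L(s, y) = sum_{c in {0,1}} softplus( z_c * (s - b_{c+1}) ),
    z_c = +1 if y <= c, else -1

so adjacent-class confusions never cost more than distant ones.
Prediction thresholds the score at the fitted cutpoints. A squared-error
scalar variant, a softmax cross-entropy baseline, and an ordered
binary-decomposition baseline (one boundary scorer per class cut,
combined by vote counting) are included for comparison, along with the
paper-style diagnostics: per-epoch key-instance precision
(`kid_stats()`) and bag montages with correct/incorrect selections
outlined in red/blue (`render_selection()`).

Because the real mammography corpus cannot be redistributed, the package
ships a synthetic generator (`synth_config()`, `generate_dataset()`)
producing mammogram-shaped images with graded lesion blobs and full
instance-level ground truth, so every stage — bag construction,
training, selection, evaluation — is testable offline.

## Worked example

A reduced-scale run (32-px patches, the native grid-cell size of the
synthetic images; 64-unit hidden layer) that trains in a few minutes on
one CPU:

```r
library(oomil)

scfg <- synth_config(n_bags_per_class = 30, seed = 101)
bags <- build_bags(generate_dataset(scfg), bag_build_config(patch_side = 32))
test <- make_instance_test_set(scfg, 30, patch_side = 32)

spec <- network_spec(input_side = 32, fc1_units = 64)
cfg  <- train_config(k = 4, epochs = 14, seed = 1)
fit  <- train(build_network(spec, seed = 1), ordinal_cutpoints(), bags, cfg)

evaluate(fit$net, fit$cuts, test)
#> <oomil_metrics> (macro_ovr)
#>   accuracy    1.0000
#>   per-class   1.0000 / 1.0000 / 1.0000
#>   sensitivity 1.0000  specificity 1.0000
#>   precision   1.0000  F1 1.0000

tail(kid_stats(fit$history, bags, k = 4), 3)
#>    epoch   mean_s precision
#> 12    12 3.983333 0.9958333
#> 13    13 3.983333 0.9958333
#> 14    14 3.983333 0.9958333
```

`accuracy` is instance-level accuracy on lesion-centered (classes 1, 2)
and tissue (class 0) crops; `precision` is the fraction of selected key
instances in positive bags whose hidden grade equals the bag label — the
quantity that should rise over epochs as selection locks onto the true
lesions. On this easy synthetic data the model separates the three
classes completely; the interesting output is the trajectory, not the
endpoint.

The full 224×224 architecture (feature maps 220 → 110 → 108; parameter
counts 260 / 1,820 / 116,640,500 / 501) is available as
`network_spec()`'s default and is what the architecture tests check;
training at that scale is supported but slow on a CPU.

A thin command-line interface over the same functions lives at
`inst/cli/oomil.R` (subcommands `synth`, `make-bags`, `train`, `eval`).

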