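# moseg

Multi-organ segmentation and annotation-uncertainty analysis for
volumetric whole-body mouse scans.

Delineating organs in whole-body mouse imaging (micro-CT, light-sheet
microscopy of cleared tissue) is a prerequisite for quantitative work —
organ volumetry, biomarker uptake, localizing cancer metastases — but
manual annotation takes hours per scan, and expert annotations carry
subjective bias: two independent experts can disagree substantially,
especially for low-contrast organs such as the spleen. `moseg`
implements, in R with compiled numerical kernels:

* a **U-Net-style encoder–decoder** that segments organs slice-wise on
  coronal sections (two 3×3 conv + batchnorm + ReLU per encoding unit,
  2×2 max-pooling, bilinear upsampling with skip connections, per-class
  sigmoid outputs, channels doubling 32 → 1024 at the six-level default),
  trained with the **soft-Dice loss**
  `1 − mean_c (2Σpt + ε)/(Σp + Σt + ε)`, `ε = 1e-5`, and Adam with a
  plateau learning-rate scheduler;
* **subject-level (leave-one-mouse-out) cross-validation** with a
  run-time no-leakage audit, optional **ensembles combined by voxel-wise
  median**, and softmax binarization against a synthetic background
  score;
* a **disagreement-prediction mode**: trained on the agreement and XOR
  of two annotators' labels, the network also outputs a heatmap of where
  humans are likely to disagree;
* **evaluation metrics**: ε-smoothed Dice, percentile Hausdorff surface
  distance (HD50/HD95), center-of-mass displacement, union-reference
  Dice, disagreement Dice;
* **organ volumetry** with intersubject / interannotator /
  intraannotator variability decompositions (population-sd convention),
  and **metastasis-to-organ allocation** with count-error reporting;
* a **phantom generator** producing synthetic cohorts — mice scanned at
  several timepoints with rigid posture jitter, organs of differing
  contrast including a low-contrast spleen analog, two annotators with
  structured bias plus noise, and known metastasis points — so the whole
  pipeline is testable end to end without external data;
* NIfTI I/O (via RNifti), a cohort manifest format, and a thin CLI
  (`inst/cli/moseg`) with YAML configs.

## Worked example

Build a synthetic cohort, train one cross-validation fold, and evaluate
on the held-out mouse (a few minutes on one CPU core):

```r
library(moseg)

spec   <- phantom_spec(seed = 1)        # 6 mice x 2 scans, 4 organs
cohort <- build_cohort(spec)

net_cfg   <- net_config(names(cohort$code_table),
                        levels = 3, base_channels = 8)
train_cfg <- train_config(epochs = 12, initial_lr = 1e-2,
                          ensemble_size = 1, seed = 7)
split <- split_cv(cohort, fold = 1, seed = 7)
fit   <- train_model(cohort, split, net_cfg, train_cfg)

ids  <- sapply(cohort$subjects, `[[`, "id")
scan <- cohort$subjects[[which(ids == split$test_mice)]]$scans[[1]]
maps <- predict_volume(fit$net, scan$image, code_table = cohort$code_table)
seg  <- binarize_softmax(maps)
evaluate_segmentation(seg$labels, scan$labels[[1]], ref2 = scan$labels[[2]])
```

```
   organ code      dice hd50_um  hd95_um    com_um union_dice missing_reason
1  heart    1 0.9892851       0   0.0000 151.81758  0.9899281           <NA>
2  liver    2 0.9668342       0 240.0000  43.34600  0.9673276           <NA>
3 kidney    3 0.9681574       0 240.0000  74.11485  0.9702616           <NA>
4 spleen    4 0.7699294     240 415.6922  52.17852  0.7846461           <NA>
```

Read per organ: the overlap with annotator 1's reference (`dice`), the
median and 95th-percentile surface distance in micrometers, the
centroid displacement, and the Dice when a voxel counts as correct if it
matches *either* annotator (`union_dice`). The three high-contrast
organs are segmented at Dice 0.97–0.99 with surface errors at or below
one voxel (240 µm); the spleen analog — whose contrast sits below the
noise floor by construction — lands near 0.77, reproducing the
qualitative pattern that low-contrast organs are the hard ones.

Organ volumetry with annotator-variability decomposition:

```r
tab <- cohort_volumes(cohort)
variability_report(tab)[, c("organ", "intersubject_rel",
                            "interannotator_rel", "intraannotator_rel")]
```

```
   organ intersubject_rel interannotator_rel intraannotator_rel
1  heart       0.04941102        0.002570230       0.0013059546
2  liver       0.04772964        0.001390505       0.0007692156
3 kidney       0.04780577        0.003434066       0.0016722408
4 spleen       0.04618193        0.489668826       0.0025917927
```

The spleen's annotator-2 boundary bias makes its interannotator
variability (49 %) dwarf both the intraannotator (0.3 %) and
intersubject (5 %) components — the constructed analog of the empirical
finding that disagreement between annotators, not within one annotator,
dominates organ-volume uncertainty.

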