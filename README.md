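# nhfmri

Network homogeneity (NH) analysis of longitudinal resting-state fMRI for
two-arm treatment studies, with a fully synthetic, seeded cohort
generator so that every stage — temporal preprocessing, group-ICA
network mask, per-voxel NH, Gaussian-random-field (GRF) cluster-corrected
inference, and leave-one-out SVM/SVR evaluation of cluster-mean NH
against clinical reduction ratios — is testable end to end without any
patient data.

It is written for researchers who study resting-state network coherence
in clinical cohorts (e.g. default-mode network alterations under
treatment) and want the statistical machinery of that literature as
reusable, tested R functions rather than a one-off script stack.

## The statistic

For a voxel *i* inside a network mask of *N* voxels,

    NH(i) = (1 / (N - 1)) * sum over j != i of  cor(x_i, x_j)

— the mean Pearson correlation between the voxel's time series and all
other in-network series. `compute_nh()` evaluates this in O(N·t) via
standardised-series row sums; the literal pairwise definition is kept as
a reference path and the two agree to 1e-10. Treatment response is the
PANSS reduction ratio `RR = (baseline - week8) / baseline`, predicted
from baseline cluster-mean NH by leave-one-out support-vector
regression; patients and controls are discriminated by leave-one-out
SVM on the same features with a nested, leakage-free hyperparameter
grid search.

## Worked example

Simulate a cohort with two planted 30-voxel NH deficits (patient
loading 0.3 vs control 0.9), run the corrected baseline inference, and
classify patients from controls with the strongest cluster's mean NH:

```r
library(nhfmri)

cfg <- sim_config(seed = 7, grid_dims = c(12, 14, 12), n_timepoints = 120,
                  n_per_group = c(control = 8, patient_dpp = 8,
                                  patient_dt = 8),
                  network_fraction = 0.15)
res <- cohort_nh_maps(cfg, timepoints = "baseline", preprocess = FALSE)
inf <- baseline_group_inference(res$maps, res$subjects,
                                res$ground_truth$true_network_mask,
                                arm = "DPP",
                                affine = res$ground_truth$affine)
as.data.frame(inf$clusters)[, c("sign", "size_voxels", "peak_stat",
                                "corrected_p")]
```

    sign size_voxels peak_stat  corrected_p
       1           3      4.90     7.68e-04
       1           2      6.25     4.68e-03
       ...
      -1          30    -12.87     6.66e-16
      -1          30    -13.65     6.66e-16

Both planted deficits are recovered exactly (the 30-voxel clusters with
strongly negative T); the scattered 1–3-voxel positive clusters are the
compensatory shift that within-mask standardisation induces outside a
deficit. Feeding the strongest cluster's per-subject mean NH to the
LOO SVM:

```r
feats <- extract_cluster_means(res$maps[grepl("ctrl|dpp", names(res$maps))],
                               inf$clusters)
best <- feats[feats$cluster_id == which.min(inf$clusters$peak_stat), ]
labels <- res$subjects$group[match(best$subject_id, res$subjects$subject_id)]
loo_svm_classify(best$mean_nh, labels, grid = svm_grid(by = 4),
                 seed = 1, positive = "patient", inner_k = 3)$metrics
```

       accuracy sensitivity specificity
            100         100         100

With the planted effect size, the held-out subjects separate perfectly;
accuracy, sensitivity and specificity are percentages from the pooled
LOO confusion counts.

`run_pipeline(list(seed = 1), outdir = "out")` chains all stages
(simulate → ICA mask → NH → inference → SVM/SVR) with checksum-based
stage skipping, and `make_report("out")` renders the cluster table
(with explicit "No cluster" rows), classifier metrics, SVR summary and
planted-cluster Dice overlap. A thin CLI wrapper ships in
`inst/scripts/nh-pipeline`.

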