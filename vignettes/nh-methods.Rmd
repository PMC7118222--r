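---
title: "Network homogeneity analysis of longitudinal resting-state fMRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network homogeneity analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the statistic

In resting-state fMRI, the default-mode network (DMN) — medial prefrontal
cortex, posterior cingulate cortex, precuneus, lateral parietal and
temporal cortex, cerebellum Crus II — shows coordinated low-frequency
activity whose internal coherence is altered in psychotic disorders.
**Network homogeneity (NH)** quantifies that coherence per voxel: for a
voxel $i$ inside a network mask of $N$ voxels,

$$\mathrm{NH}(i) = \frac{1}{N-1} \sum_{j \ne i} r\!\left(x_i, x_j\right),$$

the mean Pearson correlation between its time series and every other
in-network series.  `compute_nh()` implements this with an $O(Nt)$
reformulation (row sums of the correlation matrix via standardised
series), shipped as the production path; the literal pairwise average is
retained as `method = "pairwise"` and the two agree to $10^{-10}$ or
better in the test suite.  Zero-variance series contribute correlation 0
by convention (logged in the map object) so no `NaN` propagates.  Raw
correlations are averaged, not Fisher-z transforms; z-averaging is
available behind a flag (`fisher_z = TRUE`) but is not the definition.

The package implements the full analysis around that statistic for a
two-arm longitudinal treatment study (drug-plus-psychotherapy, DPP,
versus drug-only, DT, plus once-scanned healthy controls): temporal
preprocessing, a group-ICA-derived network mask, voxel-wise inference
with Gaussian-random-field (GRF) cluster correction, and leave-one-out
(LOO) support-vector classification and regression of cluster-mean NH
features against clinical reduction ratios,

$$\mathrm{RR} = \frac{\mathrm{PANSS}_{\text{baseline}} -
\mathrm{PANSS}_{\text{week 8}}}{\mathrm{PANSS}_{\text{baseline}}}.$$

Because no patient data ship with the package, every stage is exercised
on a seeded synthetic cohort whose generative structure is known
(`sim_config()`, `generate_cohort()`), so recovery of planted effects is
a testable claim rather than an illustration.

## The synthetic cohort generator

The generator is first-class, tested code and its defaults define the
emulated study conditions: a 20×24×20 grid of 3 mm voxels, 240 volumes
at TR = 2 s, 20 controls (baseline only, mirroring the single control
scan), 20 DPP and 21 DT patients scanned at baseline and week 8.  The
true network covers 12% of the grid as a compact multi-focal geometry
(the real templates behind published DMN masks are not reproducible, so
an arbitrary but fixed geometry stands in).  For an in-network voxel $v$
of subject $s$ at time $t$:

$$x_v(t) = \lambda_{s,c(v)}\, g(t) + \ell_v(t) + \varepsilon_v(t),$$

with $g$ a shared network signal, $\ell_v$ a private local signal
(SD 0.5) and $\varepsilon_v$ noise (SD 1); all three are stationary
AR(1) processes with lag-1 coefficient 0.3, the simplest temporally
autocorrelated BOLD-like noise model.  Out-of-network voxels carry noise
only; weak white-matter and CSF series are mixed into every voxel so
confound regression has something real to remove.  The loading
$\lambda$ encodes the planted effects: two 30-voxel clusters with
patients at 0.3 versus controls at 0.9 at baseline, the first restored
to 0.9 at week 8 in the DPP arm only.  On top of the group level, each
subject carries a persistent loading trait (SD 0.1, identical at both
timepoints) in every planted cluster: without it, cross-subject NH
variation would be pure measurement noise and "baseline NH predicts
treatment response" would be unlearnable from data measured through a
different preprocessing path than the one the coupling was generated
against.  Expected in-cluster NH is
provably monotone in $\lambda$ (and verified by simulation), so lower
loading means lower NH.  Motion is a slowly mean-reverting bounded
random walk with occasional transient spikes whose framewise
displacement exceeds the 0.2 mm scrubbing threshold by construction
(spike signs alternate with frame parity so adjacent spikes cannot
cancel).  Patients' reduction ratios are linearly coupled to their
*measured* baseline mean NH in the first planted cluster, calibrated at
generation time to a population correlation of 0.9 with RR mean 0.55
and SD 0.08 (the scale of the reported clinical course); PANSS subscale
scores are drawn at the reported scale, their sum is required to exceed
the 75-point inclusion threshold, and week-8 scores are back-computed
from the ratios.

What the generator does **not** emulate: haemodynamic response shape,
physiological noise spectra, EPI distortion, spatial autocorrelation of
the noise (voxel noise is spatially white), scanner drift beyond what
detrending removes, and site/session effects.  Passing recovery tests
therefore demonstrates correctness of the analysis machinery under a
known generative model, not performance on real scanner data.

## Temporal preprocessing

The chain is fixed and matches the emulated protocol: drop the first 10
volumes; exclude subjects exceeding 2 mm translation or 2° rotation on
any axis at any frame; linear detrend; band-pass 0.01–0.08 Hz;
regress Friston-24 motion expansion plus white-matter and CSF series
(26 columns; the global signal is never removed); scrub frames with
FD > 0.2 mm.  Choices the protocol leaves open, decided here:

* **FD variant.** Power-style FD with a 50 mm head radius — the
  dominant convention in the DPABI/REST ecosystem:
  $\mathrm{FD}_t = \sum |\Delta d| + 50 \sum |\Delta \theta|$.
* **Filter.** A frequency-domain filter with an ideal pass band and a
  10% raised-cosine roll-off per edge: reproducible and free of
  order/ripple choices; pass-band sinusoids retain ≥ 90% amplitude and
  stop-band (≥ 2× the upper edge) ≤ 10%.
* **Censor-after-filter.** Scrubbing is applied last; runs with fewer
  than 20 surviving frames are flagged unusable.
* **Friston-24 lag fill.** Frame 0 of the lagged regressors is 0; any
  constant is absorbed by the intercept.
* Rank-deficient confound designs go through the QR pseudo-inverse and
  warn, never silently produce `NaN`.

Whether frames adjacent to spikes should also be censored (the
"1-back/2-forward" rule) is left out: only the literal FD > 0.2 mm rule
is implemented.

## Network mask by group ICA

Baseline runs of all groups are temporally concatenated after per-run
PCA (30 components), reduced again to a group subspace (20 by default;
both exposed in the configuration), and unmixed by a fixed-point
symmetric FastICA with tanh contrast written in this package.  Maps are
z-scored over grid voxels; the component maximising spatial correlation
with a binary template is selected, sign-aligned, and thresholded at
z ≥ 1.96 — standard group-ICA practice when the original selection
protocol is not available.  A network rarely lives in a single
component: subnetworks, and in particular regions whose coupling to the
network *differs across subjects* (exactly the deficit regions a
case-control study cares about), separate into their own independent
components.  `derive_network_mask()` therefore merges secondary
components into the mask when their suprathreshold voxels fall
predominantly inside the template (≥ 50% precision, ≥ 10 voxels) — the
group-ICA analogue of assembling a DMN mask from its anterior and
posterior components.  Without this union, a strong planted deficit
region is expelled from the primary component (its z sits near 0 there
while exceeding 10 in its own component) and would silently drop out of
the analysis mask.  On synthetic cohorts the planted network is
recovered with map–truth correlation > 0.99 and Dice 1.0 at these
defaults; note that the ideal in-network z value is
$\sqrt{(1-f)/f}$ for network fraction $f$, so masks of networks
covering much more than ~20% of the field cannot clear a 1.96 threshold
even in principle — the threshold is a tunable for a reason.

## Group inference and GRF cluster correction

NH maps are standardised within the mask per subject (common practice;
raw maps are always retained) and fed to an ordinary-least-squares GLM
per voxel with mean-centred age and mean-FD covariates.  Baseline
patient-versus-control contrasts run per arm; the repeated-measures
group×time interaction is realised as a two-sample comparison of
within-subject (week 8 − baseline) difference maps, whose F equals the
squared two-sample T on a two-level factor (asserted numerically).
Controls, scanned once, enter only baseline contrasts.

Cluster correction follows the stationary GRF expected-cluster-count
approximation: the map is thresholded at the one-tail p < 0.001
quantile (two-sided inference as two one-sided passes, signs reported
separately), 26-connected clusters are labelled, and a cluster of $k$
voxels receives

$$p_{\mathrm{FWE}} = 1 - \exp\!\left(-E_m\, e^{-\beta k^{2/3}}\right),
\qquad \beta = \left(\frac{\Gamma(5/2)\,E_m}{E_n}\right)^{2/3},$$

where $E_m$ is the expected cluster count (EC density × resels) and
$E_n$ the expected suprathreshold voxel count.  Smoothness is estimated
from standardised GLM residuals by the variance of spatial first
differences, $\mathrm{FWHM} = \sqrt{4\ln 2/\hat\lambda}$ per axis —
slightly upward-biased on spatially white fields (≈ 1.18 voxels instead
of 1.0), a known property of the estimator that the tests budget for.
Clusters with $p_{\mathrm{FWE}} < 0.05$ are reported.  Two safeguards
back the approximation: an empirical family-wise error of at most 0.08
at nominal 0.05 over 200 null simulations with 6 mm smoothed noise on
the default grid, and agreement of the GRF critical cluster extent with
a subject-relabelling permutation null (95th percentile of the maximal
cluster size) within a factor of two.  Non-stationarity correction is
deliberately omitted at desk scale.

## Classification and regression evaluation

Cluster-mean NH features (one dimension per cluster, as in the emulated
analyses) feed a LIBSVM RBF classifier via e1071.  The LOO protocol
holds out one subject, standardises features with training-fold
statistics, picks (C, γ) by an inner cross-validated grid search on the
training fold only (no leakage; the grid is powers of two,
C ∈ 2^−5..15, γ ∈ 2^−15..3, stride configurable), and predicts the
held-out subject; pooled predictions give accuracy, sensitivity and
specificity as percentages.  Inner folds are derived from the held-out
subject's feature values rather than its position, so results are
invariant to subject ordering.  A transparent linear soft-margin SVM
(`train_svm_primal()`, SMO on the dual with an exact piecewise-linear
bias step) serves as the reference implementation; its objective is
checked against a generic convex-QP solution to 10⁻⁶.

SVR uses ε-insensitive regression under the same protocol, with the
target standardised per training fold so the ε tube is scale-free.  The
report compares the Pearson correlation between LOO predictions and
actual RR against the Bonferroni threshold 0.05/16 (4 regions × 4 PANSS
domains).  **The significance test is one-sided for positive
correlation.**  Under a null coupling, LOO predictions are markedly
*anti*-correlated with the target (median r ≈ −0.2 at n = 19, 5th
percentile ≈ −0.7 in our simulations — the familiar LOO artifact); a
two-sided test would reward that failure mode as "significant".  Only a
positive predicted-versus-actual correlation is evidence of predictive
value; the two-sided p is also reported.  The same artifact appears in
classification: under permuted labels, LOO accuracy is biased *below*
chance (a degenerate fit predicts the training majority, which is the
opposite of the held-out label), so the null property asserted in the
tests is the absence of optimism — accuracy ≤ 65% in ≥ 90% of
replicates and mean ≤ 55% — rather than a symmetric window around 50%.

## Pipeline, determinism and problem sizes

`run_pipeline()` orchestrates simulate → mask → nh → infer → ml from one
configuration and one master seed, writing per-stage artifacts and a
manifest of output checksums; unchanged stages are skipped and a
corrupted intermediate reruns exactly the downstream stages.  All study
constants (10 dropped volumes, 0.01–0.08 Hz, FD 0.2 mm, 2 mm/2°, voxel
p 0.001, cluster p 0.05, 0.05/16) are named configuration defaults.
Every random draw derives from the master seed through labelled
per-subject, per-stream child seeds, so a subset of subjects can be
analysed bit-identically to a full run, and whole runs are reproducible
end to end.

Problem sizes used by the test suite were chosen to keep a full run at
desk scale while preserving the study conditions where they matter:
detection and coupling-recovery suites run the default grid and group
sizes (n = 20/group for the baseline contrast, n = 19 for SVR
recovery) over 25 seeds; the GRF calibration uses 200 null simulations;
module tests use 500–600-voxel grids and short runs.  Per-run BOLD
volumes are regenerated on demand (`cohort_nh_maps()`) instead of held
in memory, so peak memory stays near one run.  One caveat found while
scaling down: with 60-frame runs, band-passing to 0.01–0.08 Hz leaves
so few effective samples that NH estimates are too noisy for reliable
10-voxel cluster detection — desk-scale integration tests therefore
compute NH on generator output directly, while full-length (240-frame)
runs detect cleanly through the complete preprocessing chain.

## Known limitations

* The GRF correction assumes a stationary, reasonably smooth field;
  on unsmoothed desk-scale maps it leans on the permutation oracle for
  reassurance rather than theory.
* The ICA selection step needs a template; with none, the component
  with the largest network-like structure must be picked manually.
* Clinical scores are generated as independent Gaussians apart from the
  planted NH–RR coupling; correlation analyses against cognitive scores
  exercise machinery, not biology.
* LOO error bars are optimistic relative to truly independent samples;
  the package reports LOO metrics because that is the protocol being
  emulated, and flags the caveat here instead of pretending otherwise.
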