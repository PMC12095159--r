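---
title: "Autoantibody profiling on protein arrays: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autoantibody profiling on protein arrays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwabs)
```

# Overview

`pwabs` implements an analysis pipeline for proteome-wide autoantibody
screening (PWAbS): serum IgG reactivity measured against thousands of
displayed human proteins on a microarray, one array per subject. The
pipeline runs from per-spot fluorescence through to disease classification
and clinical-trait association:

1. **Quantification** — control-spot normalization of fluorescence into
   arbitrary units (AU).
2. **Differential screen** — volcano selection of autoantibodies elevated in
   disease groups versus cognitively normal controls.
3. **Classifier bench** — a 14-model cross-validated bench for the binary
   task (AD vs the rest) with consensus feature selection.
4. **Three-class network** — a small fully connected net for CNI / AD / DLB.
5. **Clinical association** — starred Spearman matrices, MMSE-subscale
   profiles, age/sex-adjusted regression.
6. **Cross-reactivity** — correlated antibody pairs checked for shared
   antigen sequence by global alignment.

Because raw patient-level array data of this kind are typically not
deposited, the package ships a first-class synthetic-cohort generator with a
ground-truth ledger, so every stage can be tested for parameter recovery.

# Quantification model

Each array carries antigen spots plus positive and negative control spots.
The autoantibody level for antigen $g$ in subject $i$ is

$$\mathrm{AU}_{ig} = \frac{F_{ig} - F^{-}_{i}}{F^{+}_{i} - F^{-}_{i}} \times 100,$$

where $F^{-}_i$ and $F^{+}_i$ are the subject's negative- and
positive-control intensities. AU is 0 at the negative-control level and 100
at the positive-control level; values outside $[0, 100]$ are legitimate and
retained. Choices the formula leaves open:

* **Control aggregation.** Arrays carry several control spots; we take the
  per-subject *median* of each control class, which tolerates a single bad
  spot. (How the original arrays laid out controls is not public; the
  defaults here are conventions.)
* **Duplicate antigen spots** are averaged (arithmetic mean).
* **SAL**, the sum of autoantibody levels, is the unclipped row sum —
  clipping negative AU would bias this gross-autoreactivity statistic
  upward.
* Degenerate controls ($F^+ \le F^-$) abort quantification naming the
  subject, rather than silently producing nonsense.

# Differential screen

Per antigen and contrast (AD vs CNI, DLB vs CNI) the screen computes a
two-sided Mann-Whitney p-value and a fold change, and flags an antigen
*elevated* when $p < 0.05$ **and** fold change $\ge 2$ — both defaults
configurable. Conventions worth stating because the underlying definitions
are genuinely open:

* **Fold change** is the ratio of group arithmetic means computed on AU
  clipped below at zero, with an $\varepsilon = 1$ AU denominator floor.
  Negative AU makes a raw ratio ill-behaved (sign flips); clipping plus the
  floor keeps FC finite and non-negative. Ratio-of-means is the common
  volcano convention; medians are not used.
* **One-directional selection.** The p-value is two-sided but the FC
  condition only passes case-elevated antigens, so the screen selects
  elevations, and the conjunction makes it conservative under the null
  (a fraction well below 5% of antigens is flagged on null data).
* **No multiplicity correction by default** — selection deliberately uses
  raw p-values with the FC guard; `bh_adjust()` offers Benjamini-Hochberg
  where FDR control is wanted instead.

`venn_counts()` / `venn_union()` give the inclusion-exclusion arithmetic of
the two panels, and `pca_embed()` embeds subjects on the selected panel
after centering and scaling each antigen to unit variance (AU scales vary
widely across antigens; zero-variance columns are dropped with a warning).
PC signs are fixed by making each component's largest-magnitude loading
positive, so embeddings are reproducible.

# Statistical primitives

`stats_core` functions are self-contained implementations, cross-checked in
the test suite against enumeration oracles and the base-R reference
implementations:

* **Mann-Whitney U**: exact p by full enumeration of the
  $\binom{n_1+n_2}{n_1}$ rank assignments when both groups have $\le 8$
  observations and the data are tie-free (the study's group sizes of 8–9
  make exactness cheap and relevant); otherwise the normal approximation
  with tie and continuity corrections. Two-sided by default throughout.
* **Spearman**: Pearson correlation of mid-ranks (ties handled by average
  ranks), p from the $t$ approximation on $n-2$ degrees of freedom;
  constant inputs yield a flagged `NA` rather than a number.
* **Fisher's exact 2×2**: two-sided p as the sum of same-margin table
  probabilities not exceeding the observed one.
* **ROC-AUC** is rank-based (ties count half) and exactly equals
  $U/(n_1 n_0)$; **PR-AUC** is average precision (step integral), which
  differs from trapezoidal integration and is stated explicitly for that
  reason.
* **OLS** solves by QR, reports per-coefficient SE, $t$ and p on $n-k$
  degrees of freedom, and refuses rank-deficient designs naming the
  dependent columns.

# Classifier bench

The bench mirrors a 14-row model comparison across linear, kernel, tree and
Bayes families. Model *fitting* is delegated to established packages
(glmnet, e1071, randomForest, rpart, xgboost); folds, scaling, metrics,
importances and consensus are computed by this package. Design points:

* **Penalization at $p \gg n$.** With tens of subjects and hundreds of
  antigens, unpenalized logistic regression and unconstrained least squares
  are degenerate. Logistic rows use ridge-penalized fits (small fixed
  $\lambda$, tunable), and the linear-regression row uses the SVD
  minimum-norm solution.
* **Boosting variants.** Four gradient-boosting rows are provided:
  depth-wise boosting, leaf-wise (loss-guided) growth, a slow-learning-rate
  deep variant, and a stump ensemble — spanning the behavior of the common
  boosting toolkits while staying on one backend.
* **Scaling is fit per training fold** and applied to the held-out fold.
  Fitting scalers globally would leak test information; the suite carries a
  leak canary (a feature constant on training rows and label-aligned on
  held-out rows) that stays at chance under the honest pipeline and is
  driven to AUC 1 by a deliberately leaky fit.
* **Scores.** Probability models are thresholded at 0.5 for
  accuracy/precision/recall/F1. Regression-style and margin models emit raw
  predictions min-max rescaled using the training fold's score range.
* **Importances** follow the family contract: $|$coefficient$|$ for linear
  models, split gain (or split frequency where gain is unavailable) for
  trees, and the absolute standardized mean class difference for naive
  Bayes. The reported vector comes from a final fit on the full data after
  CV.
* **Consensus selection** keeps models with mean CV ROC-AUC above the gate
  (default 0.96, exclusive), takes each qualifier's top-10 features by
  importance magnitude (ties broken by stable feature order) and selects
  features appearing in at least `min_models` lists. "More than two
  algorithms" is ambiguous between $\ge 2$ and $\ge 3$; the default is
  `min_models = 2` (twelve consensus features out of four qualifying models
  is only arithmetically possible at $\ge 2$), with a knob to change it.
* **Hyperparameter search** is a bounded, seeded random search whose first
  candidate is always the default configuration, so the argmax can never be
  worse than the default on the same folds.

# Three-class network

The CNI / AD / DLB classifier is a fully connected net: two rectified
hidden layers of 8 and 4 units, an affine 3-logit output with row softmax,
softmax cross-entropy loss, Adam (lr 0.001, $\beta_1 = 0.9$,
$\beta_2 = 0.999$, $\varepsilon = 10^{-8}$), 150 epochs of minibatch 16
with per-epoch shuffling, evaluated by 3-fold CV. It is implemented
directly in R matrix arithmetic — at cohort scale (tens of subjects, tens
to hundreds of features) a fold trains in well under a second, and a
framework dependency would buy nothing. Choices the recipe leaves open:

* inputs are z-scored per training fold;
* weights start from seeded uniform draws in
  $\pm\sqrt{6/(\mathrm{fan_{in}}+\mathrm{fan_{out}})}$, biases at zero;
* no early stopping, weight decay or dropout (none are part of the recipe);
* class order is fixed as class 1 = CNI, class 2 = AD, class 3 = DLB.

Evaluation pools held-out softmax probabilities: confusion at argmax,
one-vs-rest ROC-AUC and PR-AUC per class via `stats_core`, per-class
precision/recall/F1, and per-epoch train/validation loss curves.

# Clinical association

`trait_correlations()` computes pairwise-complete Spearman correlations
between selected autoantibodies and traits with significance stars
(* p<0.05, ** p<0.01, *** p<0.001; strict inequalities). Binary traits are
rank-coded automatically; cells with fewer than 3 complete pairs or a
constant vector are marked not-computable rather than zero.
`adjusted_regression()` fits complete-case OLS, univariate
(trait ~ antibody) and adjusted (trait ~ age + sex + antibody) with sex
coded 0 = male / 1 = female. Group summaries use the Tukey box convention
(hinges at quartiles, whiskers at 1.5 IQR).

# Cross-reactivity

One antibody binding several displayed proteins shows up as correlated AU
columns. Pairs with Spearman $\rho > 0.5$ (strict) are globally aligned by
Needleman-Wunsch under identity scoring (match 1, mismatch 0, linear gap
−1) with deterministic traceback (diagonal > up > left). Percent identity
is identical residues over *alignment length* by default; the
shorter-sequence denominator is available because reported identity
figures depend on this convention. Missing sequences make a pair
*unresolved*, not an error.

# Synthetic cohort generator

The generator emulates the cohort structure this analysis assumes, and its
defaults are the package's study conditions:

* 18 AD / 8 DLB / 9 CNI subjects (35 arrays); female fractions 0.824 /
  0.625 / 0.333; ages uniform 70–90 in all groups (age-matched design);
* a scaled-down panel of 300 antigens (the full 13,455-clone scale is one
  config field away) with 30 planted elevations — 10 AD-only, 10 DLB-only,
  10 shared — at fourfold AU elevation in affected groups;
* a lognormal AU background (meanlog $\log 8$, sdlog 0.8), 8 positive and 8
  negative control spots per array jittered at 5% CV around expected levels
  of 10,000 and 100 fluorescence units, and 10% multiplicative per-spot
  noise;
* clinical traits drawn from per-group baselines (MMSE-family, HDSR, CGA7,
  GDS15, Barthel, back pain) with configurable linear coupling to
  designated driver antigens — by default the MMSE family is negatively
  coupled to the first planted AD antigen, most strongly in the Recall
  subscale, so subscale-profile recovery is testable.

Latent truth lives on the AU scale; spot fluorescence is back-computed
through each array's own median controls as
$F = F^- + \mathrm{AU}/100\,(F^+ - F^-)$ *before* noise, so quantification
inverts generation exactly at zero noise — a tested property, and the
reason the generator and the quantifier can check each other.

What the generator does **not** emulate: spatial array artifacts,
batch/plate effects, antigen-specific dynamic ranges, heavy-tailed
cross-reactive blocks, or missing spots. Passing recovery tests therefore
demonstrates correctness of the analysis machinery under the stated
statistical model, not performance on real sera.

# Problem sizes and numerical choices

The test and acceptance workloads run at desk scale, chosen as the sizes at
which every statistical property is already exercised: 300-antigen panels
for screen operating characteristics, a 229-antigen / 35-subject bench task
with 10 planted drivers, 90-subject three-cluster data (6-σ offsets) for
the network, and a 200-subject leak canary (Monte-Carlo sd of the
chance-level AUC ≈ 0.045). Exact Mann-Whitney enumeration is capped at
group sizes of 8; beyond that the corrected normal approximation takes
over. All randomness flows from one master seed through fixed per-stage
offsets, so any stage can be reproduced in isolation; `run_all()` writes a
manifest of per-stage parameters, seeds and MD5 hashes, and two runs with
one seed are byte-identical.

# Known limitations

* The screen's raw-p selection at thousands of antigens is intentionally
  permissive (mirroring common volcano practice); use `bh_adjust()` when
  calibrated discovery lists matter.
* Fold-change and identity conventions are choices, stated above; numbers
  produced under different conventions are not directly comparable.
* The bench's fixed small penalties are sensible at $p \gg n$ but are not a
  substitute for per-model tuning; the random-search hook is bounded and
  seeded rather than exhaustive.
* Synthetic recovery results bound what can be claimed about real data (see
  the generator's non-goals above).
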