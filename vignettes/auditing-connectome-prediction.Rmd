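---
title: "Auditing cross-population generalization of connectome-based prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing cross-population generalization of connectome-based prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fairconn)
```

## The problem

Predictive models that map resting-state functional connectivity (RSFC) to
behavioral phenotypes are typically trained on cohorts dominated by one
population. When such a model is applied to an under-represented group, its
accuracy can differ systematically, and the difference can be invisible to
some accuracy metrics while glaring in others. `fairconn` implements a
complete audit of this phenomenon: matched-pair test-set construction so
that group comparisons are not confounded by demographics or data quality,
kernel ridge prediction with training-side confound control, group-wise
accuracy and bias metrics, permutation inference, training-population
composition experiments, and recovery of the brain-behavior association
patterns that explain the accuracy differences.

Because the cohorts such audits are run on are access-restricted, the
package ships a synthetic-data generator that reproduces the statistical
structure the analyses assume. Every claim the package makes is exercised,
end to end, on generated cohorts with known ground truth.

## The generative model

A configuration (`synth_config()`) fixes two unit-norm, mean-zero edge
weight patterns $w_{maj}, w_{min}$ over the $p = \binom{R}{2}$ edges of an
$R$-ROI connectome, with Pearson correlation exactly equal to
`pattern_similarity`. Subject $i$'s vectorized Fisher-z FC is

$$c_i = \mu + A z_i + D^{1/2}\varepsilon_i + \Gamma x_i,$$

a low-rank (rank `latent_rank`, variance share `latent_share`) plus
diagonal covariance shared across groups, optionally loaded by the
confounds $x_i$ (an age-like and a motion-like standard normal and a
binary gender-like variable). The behavioral score is

$$y_i = c_i^\top w_{g(i)} + \gamma^\top x_i + s\,[g(i) = \text{minority}]
        + \epsilon_i .$$

Group differences therefore live *only* in the weight pattern, the mean
shift $s$, the variance ratio, and the confound loadings; there is no
incidental distribution shift. Minority noise is rescaled so the
population variance ratio between groups equals `group_variance_ratio`
exactly (an infeasible target raises an error rather than being clamped);
with `noise_sd = 0` scores are exactly $c^\top w$. In behavior suites
(`generate_behavior_suite()`), each behavior's noise is rescaled to hold
the signal-to-noise ratio constant across behaviors, so behaviors differ
in their patterns, not their predictability.

Default scales are desk-sized and deliberate: 40 ROIs (780 edges), 400
majority + 100 minority subjects, edge standard deviation 0.15 in Fisher-z
units (realistic for z-transformed FC), noise set for a population
R-squared of 0.5 (`noise_sd_for_r2()` computes the exact value from
$w^\top\Sigma w$). The 419-ROI scale is available but not the default.
Families (sizes 1-3, 60/30/10%) never straddle sites, giving the grouping
structure that the family-aware splits and block permutations need. The
generator emulates second-order structure and grouping only: it does not
simulate hemodynamics, parcellation geometry, scanner effects, or
non-Gaussian score distributions, so passing tests demonstrate the
*procedures* are correct and calibrated, not that any real cohort is
bias-free.

`ground_truth_association()` returns the closed-form population covariance
$\Sigma_0 w_g + \Gamma V_x(\Gamma^\top w_g + \gamma)$ between each edge and
the score — the oracle that recovered association maps are compared with.

Time series: `generate_timeseries()` emits Gaussian frames whose
population correlation equals the subject's assigned FC (projected to the
nearest valid correlation matrix by eigenvalue clipping at $10^{-4}$ when
needed), with motion spikes that inflate the signal (driving DVARS) and
set FD from its clean-baseline 0 to `fd_spike`.

## Quality control and connectivity

Censoring follows the standard motion-scrubbing recipe: a frame is bad
when FD or DVARS exceeds its threshold (presets: `"hcp"` 0.2 mm / 75,
`"abcd"` 0.3 mm / 50), the bad set is dilated one frame back and two
forward, surviving contiguous segments shorter than five frames are
censored, and a run loses all credibility when strictly more than half its
frames are censored ("more than half" is read as a strict inequality, so
exactly half survives). DVARS at the first frame is defined as 0 — the
differenced quantity does not exist there and the frame must not censor
itself. Correlations are computed over uncensored frames only, clipped to
$\pm(1-10^{-7})$ before `atanh` (the degenerate $r = \pm 1$ case is
otherwise undefined), Fisher z-transformed and averaged across usable runs
— unweighted by default, with frame-count weighting behind a switch, since
the convention is not fixed by common practice. Edge vectorization is
strictly-lower-triangular column-major; the ordering is written into every
FC file's JSON sidecar.

## Matched designs

Cost between two subjects is the sum over matching variables (confounds
plus the behavior) of absolute differences after z-scoring each continuous
variable over the union of the two groups; raw sums across incommensurate
units would be scale-dependent. Categorical variables (gender) must agree
exactly: a mismatch sets the entry to a large sentinel that the assignment
solver reports as unmatchable. A 0/1 numeric difference would instead be
dominated by the continuous variables after standardization.

The assignment itself is the Jonker-Volgenant shortest-augmenting-path
variant of the Hungarian algorithm, implemented natively and verified
against exhaustive search.

Two designs are supported:

* **Single-cohort scheme** (`select_matched_splits_hcp()`): a pre-pass
  flags minority subjects whose minimal attainable cost exceeds the 90th
  percentile in at least 80% of behaviors (the threshold behind
  "consistently hard to match" is not canonical; both knobs are
  arguments). Each split randomly partitions the remaining minority into
  family-preserving folds, then draws candidate majority sets — whole
  families, mirroring each fold's categorical composition, since a
  draw that cannot match gender counts is infeasible by construction —
  and keeps, over `n_iter` draws, the one minimizing the maximum per-fold
  matching cost. Unmatched majority, excluded minority and other groups
  are distributed into folds, families intact at every step. Defaults
  (10,000 iterations, 40 splits) reflect the full design; tests and the
  replicate studies run 5-40 iterations and 1-2 splits, which is where
  the composition-aware draws matter.
* **Multisite scheme** (`select_matched_design_abcd()`): iterative
  Hungarian matching within each site — each round drops the unmatchable
  minority subjects and the single highest-cost pair's minority member,
  stopping after 100 rounds or when the round-over-round decrease in
  total matching cost falls below 5%. Because each drop removes at least
  a $1/k$ share of a $k$-pair total, the 5% rule only terminates
  naturally when sites hold a few dozen pairs; a floor (stop at two
  pairs) prevents small sites from draining to zero. Sites are then
  merged into 10 folds by deterministic largest-first greedy packing
  (ties by site id), and training/testing enumerates all
  $\binom{10}{3} = 120$ ways of holding out three folds.

Match quality is checked by paired t tests per variable and split with
Benjamini-Hochberg correction across the whole family; zero-variance
differences report $t = 0, p = 1$ with a warning rather than failing
mid-pipeline.

## Prediction

The predictor is kernel ridge regression with the Pearson-correlation
kernel between vectorized connectomes: $(K + \lambda I)\alpha = y$, so a
test subject's prediction is the similarity-weighted combination of
training scores. No intercept is fitted — exactly the stated dual form —
so systematic shifts between training and test score levels flow into the
predictions, which is part of the phenomenon under audit. Linear ridge
regression (primal form, computed through the dual when edges outnumber
subjects; the two are algebraically identical) is the auxiliary model, and
the linear-kernel equivalence is tested.

Confounds are regressed from the behavior and from every edge by OLS
fitted on training subjects only and applied to both sides;
whole-sample residualization would leak test information (a tripwire test
plants a confound that predicts only test scores and asserts no accuracy
gain). The penalty is chosen by grouped inner cross-validation (families
or sites never split; one eigendecomposition per inner fold makes the
grid nearly free), maximizing inner predictive COD, ties to the smaller
penalty. The default grid is 15 log-spaced values in $[10^{-3}, 10^3]$
scaled by training size; the replicate studies fix $\lambda = 5$ instead,
because their endpoints are group *contrasts* at a fixed model class, not
absolute accuracy.

Training-population arms (`subsample_training_population()`) equalize the
two groups site by site (the smaller group's count wins, with random
trimming) and train on minority only, majority only, or both.

## Metrics and their dissociation

For each matched group, predictive COD is $1 - \mathrm{SSE}_g/\mathrm{SST}$
with population (1/N) denominators, where SST is the variance of the
*pooled matched training scores of both groups* — deliberately not
group-specific, so the yardstick is shared (an option extends the pool to
the whole training set). Pearson accuracy, prediction shift (the squared
mean signed error), the behavioral variance (population denominator, for
consistency with SST), and mean-centered Levene's W complete the set.
Single-cohort results average metrics over the 10 folds of each split;
multisite results report all 120 divisions unaveraged.

The central algebraic fact the audit turns on: adding a pure shift
$\delta$ to one group's centered predictions changes that group's COD by
exactly $-\delta^2/\mathrm{SST}$ and its Pearson accuracy not at all.
Correlation is blind to systematic over- or under-prediction of a group;
predictive COD is not. Both are therefore always reported together.

## Inference

Predictability is tested by permuting predictions under exchangeability
blocks: whole families move only among same-size families, with
within-family shuffling. An optional outer stratification keeps
cross-validated predictions inside their own train/test division — the
predictions of different divisions carry different model offsets and are
not exchangeable across divisions. P-values use the add-one estimator and
are never exactly zero.

Group differences use a label-shuffling test on the matched pairs. Two
shuffles are implemented, and the choice is a measured one. Swapping
labels *within* each pair looks natural but is anticonservative: the
pairing was itself chosen by similarity matching, which makes pair members
non-exchangeable — in a minimal experiment (no model at all, pairs built
by assignment on one variable), within-pair flips reject a true null at
0.38 when candidate pools are equal-sized, 0.16 at 2:1, and still 0.07 at
4:1. The default is therefore the *global* shuffle — group labels permuted
across all pair members, within division strata — which relies on the
matched design having equalized the groups and measures 0.045 over 400
null replicates. The within-pair variant remains available
(`pairwise = TRUE`).

A second dependence worth knowing about: pooling predictions across
cross-validation divisions makes them mutually dependent (fold A's
predictions are a function of fold B's scores and vice versa; at two folds
this doubles the variance of the pooled accuracy), which no permutation of
the pooled vector can represent. The calibration study therefore evaluates
both tests on a single held-out division, where predictions are a fixed
function of independent training data and permutation inference is exact.
`run_experiment()`'s pooled inference across 10 folds follows the
conventional procedure and is documented as approximate.

A behavior counts as predictable when its whole-test-set accuracy survives
the block permutation test after FDR correction across behaviors and its
split-averaged accuracy is positive in at least one matched group; the
headline subset additionally requires mean Pearson accuracy strictly above
0.15. Group-difference tests are FDR-corrected across the predictable set.

## Association patterns

The model's learned brain-behavior association is the Haufe-style
inversion: the covariance (population denominator, both arguments
demeaned) between training-subject edge values and in-sample predictions —
for linear ridge this equals the training covariance times the primal
weights, which is tested as an identity. True group-wise patterns use the
original test scores of the matched pair members, per group. Maps are
computed per division and averaged for reporting (the aggregation is not
canonical; per-division maps remain accessible). Pattern validity is the
edge-wise Pearson correlation between learned and true maps, and the audit
relates the group difference in validity to the group difference in COD
across behaviors.

## The replicate studies

Three standing experiments define what "works" means here, at scales
chosen to complete on one CPU in minutes:

* `study_null_calibration()` — 500 cohorts of 160 + 80 subjects, 12 ROIs;
  group-difference nulls share one generative process exactly; the
  predictability null sets the population R-squared to $10^{-6}$. Both
  procedures must reject at 3-7% at the 5% level, 1000 permutations.
* `study_bias_recovery()` — 50 cohorts at the default 400 + 100 scale, 40
  ROIs, 6 behaviors with pattern similarity 0.3, three training arms. The
  full-training arm should favor the majority group in at least 90% of
  cohorts, and the minority-only arm should beat the majority-only arm on
  minority accuracy in at least 80%.
* `study_similarity_relation()` — 50 cohorts with behaviors graded over
  similarities 0.05-0.95; the cross-behavior correlation between the
  validity difference and the COD difference should be positive in at
  least 90% of cohorts.

The per-replicate pipeline inside the studies is deliberately lean — one
matched split, two folds, fixed penalty — because the quantities of
interest are contrasts and rejection rates, not absolute accuracy. The
rare cohort draw whose minority signal variance makes exact variance
targeting infeasible is redrawn at a deterministically shifted seed.

## Known limitations

* The latent FC model is a stand-in for — not an estimate of — real RSFC
  covariance structure; real-data accuracy levels will differ.
* The pooled multi-fold predictability test is mildly anticonservative by
  construction (cross-fold dependence); exact inference requires a single
  held-out division, as in the calibration study.
* Within-pair label flipping is retained for comparison but should not be
  used for inference on similarity-matched pairs.
* Kernel ridge has no intercept; on data whose training score level
  differs from the test group's, prediction shift is expected and is
  itself one of the reported metrics.

## A minimal session

```{r example, eval = FALSE}
cfg <- experiment_config(
  synth = synth_config(n_majority = 150, n_minority = 50, n_roi = 12,
                       seed = 4),
  pattern_similarities = c(0.2, 0.5, 0.8),
  n_folds = 5, n_splits = 2, n_iter = 10, inner_folds = 3, n_perm = 200,
  seed = 2)
res <- run_experiment(cfg, out_dir = "audit_demo")
tidy(res)          # per-behavior inference table
glance(res)        # one-line summary
autoplot(dplyr::filter(res$accuracy, behavior == "y_1"))
```
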