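---
title: "Methods: connectome-based prediction of social attention and trait communities"
author: "socialcpm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectome-based prediction of social attention and trait communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# What the package models

`socialcpm` implements a complete analysis chain for relating task-based
functional brain connectivity to individual differences in behavior:

1. **Behavioral scoring.** Performance on a one-back selective attention
   task is summarized as signal-detection sensitivity d' with the
   log-linear correction.
2. **Connectome construction.** Node timecourses (framewise averages over
   an atlas parcellation) are correlated pairwise; Fisher-z-transformed
   correlations are vectorized over the upper triangle into edge features
   (35,778 edges for a 268-node whole-brain atlas).
3. **Connectome-based predictive modeling (CPM).** Cross-validated edge
   selection and network-strength regression predict behavior from edges;
   a permutation test assesses significance; edges selected in nearly all
   cross-validation models form a robust mask that can be carried into
   second-stage predictions of trait scores.
4. **Bootstrap exploratory graph analysis (bootEGA).** Questionnaire items
   are reduced to latent trait communities via a regularized
   partial-correlation network and Louvain community detection, with a
   parametric bootstrap quantifying the stability of the structure, and
   standardized network scores per community and participant.

Because the kind of data this pipeline consumes is rarely publicly
deposited, the package ships a synthetic-data generator whose outputs have
the statistical structure each stage assumes, with planted ground truth.
Every stage is tested against that truth.

# Behavioral scoring

In the one-back task each image is judged "same" or "different" relative
to the previous image. A *hit* is a "same" response when the correct
answer is same; a *false alarm* is a "same" response when the correct
answer is different. Sensitivity is

$$d' = \Phi^{-1}(\text{hit rate}) - \Phi^{-1}(\text{false-alarm rate}),$$

with the log-linear correction applied unconditionally: 0.5 is added to
the hit and false-alarm counts and 1 to the signal and noise trial counts.
This keeps d' finite at perfect or zero proportions. We apply the
correction to every subject rather than only at extreme proportions:
conditional application would make d' non-monotone across subjects with
neighboring counts.

Two scoring decisions are not forced by the d' definition and are made
explicit here:

* The first image of each block has no predecessor, so it generates no
  scorable trial.
* A missing response is treated as "different": under the definitions
  above, only "same" responses can hit or false-alarm, so a non-response
  can do neither.

# Connectome construction

"z-scored Pearson correlation" is interpreted as the Fisher r-to-z
transform `atanh(r)`, the standard variance-stabilizing normalization in
connectomics. The alternative reading — standardizing the correlation
distribution within subject — would make a fixed selection threshold on
*r* incoherent, so it is not used. The matrix diagonal (z of r = 1 is
infinite) is never written or consumed.

Edge vectorization walks the strictly-upper triangle in **row-major**
order with 1-based node ids: (1,2), (1,3), ..., (1,n), (2,3), ... This
convention is fixed package-wide (`edge_index_map()`), is embedded in the
"n{i}_n{j}" column headers of every edge file, and is what makes an edge
mask computed on one dataset applicable to another. Note that R's own
`upper.tri()` indexing is column-major; the package never exposes that
order.

# Connectome-based predictive modeling

For each of `n_iterations` (default 100) random splits of subjects into
`k_folds` folds (default 10; fold sizes differ by at most one), and for
each fold:

1. **Residualization.** The behavioral target is regressed on the
   confounds (e.g. head motion summarized as mean framewise displacement;
   in second-stage models, the other trait scores) using *training
   subjects only*; the training coefficients are then applied to the
   held-out subjects. This honors per-fold residualization without leaking
   test information.
2. **Edge selection.** Each edge is Pearson-correlated with the
   residualized target in the training set; edges with r strictly above
   +0.2 form the positive tail and strictly below -0.2 the negative tail
   (the default threshold 0.2 balances accuracy against feature sparsity).
   Selection uses Pearson correlation; the rank correlation appears only
   in the accuracy metric.
3. **Network strength.** Each subject's edge values are summed within each
   tail.
4. **Linear model.** Ordinary least squares of the training target on
   network strength, applied to held-out subjects' strengths.

Accuracy per iteration is the Spearman correlation between observed
(residualized) and predicted scores across all subjects; the model's
headline number is the median accuracy over iterations.

**Model mode.** The default `combined` mode fits one model with positive
and negative strength as two predictors, giving a single predicted score
per subject — matching a single reported accuracy per model. Because
"linear models were fit" is also consistent with one simple regression per
tail, a `separate_tails` mode is provided (per-tail predictions are
averaged for the overall accuracy). The two agree closely on the synthetic
benchmarks; `combined` is the default because the pipeline reports one
prediction per subject.

**Degenerate folds.** A tail that selects no edges (or has constant
strength in training) contributes strength 0 and drops out of the model;
a fold where both tails are empty predicts the training mean. This keeps
the procedure total on null data, where selection can legitimately return
nothing.

**Permutation test.** Behavioral scores are shuffled against the
connectomes and one full k-fold cross-validation is run per randomization
(default 1000). Confound rows move with the shuffled behavior: the
behavior-confound relation is a property of the behavioral variable, and
only the brain-behavior link is the hypothesis under test. The p-value
counts null accuracies at or above the median observed accuracy. By
default the guarded convention (1 + count)/(1 + N) is used, which keeps
p > 0 and the test valid; the raw count/N convention is available with
`guard = FALSE` for exact replication of the counting rule.

**Robust edges.** Selection frequency is averaged over folds within an
iteration and then over iterations, per tail. Edges at or above the
robustness fraction (default 0.97) form the robust mask. Frequencies are
tracked per tail with a pooled option, since "selected in at least 97% of
models" can be read either way.

**Masked (second-stage) mode.** With a mask, selection is restricted to
the mask's edges; everything else is unchanged. This is how a network
identified against task performance is re-used to predict trait scores,
with the remaining traits as covariates so only unique trait variance is
modeled. Tests verify that zeroing all out-of-mask edges leaves masked
predictions bit-identical.

**Seeding.** Fold assignment uses a seeded uniform shuffle followed by
contiguous chunking; iteration i uses seed + i. Results are deterministic
given the seed. Reproducibility across languages or RNG implementations is
not promised — the statistical claims, not bit patterns, are the contract.

# Bootstrap exploratory graph analysis

Item correlations use **pairwise deletion** (each entry computed over
participants observed on both items). Pairwise deletion can yield an
indefinite matrix; the nearest positive-semidefinite correlation matrix is
substituted when needed and the repair is reported. Pearson correlations
are used on the ordinal responses rather than polychorics: the parametric
bootstrap draws replicates from a multivariate normal with the estimated
correlations, which is the Pearson-consistent model; polychoric input is a
possible extension.

The network model is the **graphical lasso**: an L1-penalized Gaussian
likelihood estimate of the inverse covariance, whose standardized negative
off-diagonal is the sparse regularized partial-correlation network. The
package implements the blockwise coordinate-descent algorithm (with exact
zeros preserved) in compiled code and selects the penalty by the extended
Bayesian information criterion with tuning gamma = 0.5 over a 100-point
logarithmic penalty path down to 1% of the maximum absolute off-diagonal
correlation — the de facto defaults in network psychometrics, both
configurable. The test suite checks the solution against the
Karush-Kuhn-Tucker optimality conditions of the penalized likelihood and
against closed-form cases (block-diagonal inputs yield no cross-block
edges).

Communities are found by the **Louvain** modularity heuristic on absolute
edge weights (modularity is defined for nonnegative weights; edge signs
remain in the network itself). The effective sample size behind a
pairwise-deletion correlation matrix is taken as the mean pairwise
joint-observation count.

**bootEGA** draws `n_boot` (default 500) replicate samples of the original
size from a multivariate normal with the estimated item correlations, runs
the network + Louvain step on each, takes the entrywise **median** of the
replicate networks as the typical network, and defines final membership by
Louvain on that typical network. Item stability is the proportion of
replicates in which an item lands in each community after aligning
replicate community labels to the final partition by maximum-overlap
one-to-one (Hungarian) assignment; surplus replicate communities map to
their best-overlap final community. Replicates that fail (more than 5%
aborts the run) subtract mass from the stability rows, which is reported.
A Walktrap cross-check of community membership, reported alongside Louvain
in some applications of this method, is noted here but not implemented.

**Network scores.** Each community member item is weighted by its
within-community strength (sum of absolute typical-network weights to the
other members), normalized to sum to one; uniform weighting is available.
A participant's raw score is the weighted sum of observed member items
with within-item mean imputation; a participant missing an entire
community is NA. Scores are standardized to mean 0, SD 1. On synthetic
data the scores correlate about 0.9 with the generating latents, the
practical ceiling given ordinal discretization and item noise.

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated:

* **Edge datasets** (`simulate_cpm_dataset()`): behavior is standard
  normal; each planted edge is `effect_size * behavior` plus scaled noise
  so its population correlation with behavior is exactly the effect size;
  other edges are independent noise; a motion-like confound correlates
  with behavior at -0.30 by default, the size typical of motion-
  performance coupling in attention tasks. Defaults are 67 subjects and
  268 nodes, a typical single-site imaging study. The signal is planted
  directly on edge values (not via node timecourses) because CPM consumes
  edge vectors and direct planting gives exact ground truth;
  `simulate_node_timeseries()` provides a latent-signal timecourse mode
  for integration tests of the connectivity stage.
* **Task trials** (`simulate_task_trials()`): 6 blocks per condition,
  alternating attend-faces/attend-houses, 10 images per block with 4 or 5
  "same" trials among the 9 scorable ones; responses come from an
  equal-variance Gaussian observer with an unbiased criterion at d'/2.
* **Questionnaires** (`simulate_questionnaire()`): by default 1357
  participants, 3 latent communities correlated at 0.5, 8 items per
  community loading at 0.65, 5 ordinal categories cut at equal-probability
  thresholds, 10% missing completely at random. Item count per community
  (8) is a realistic subscale length; the instruments' item wording and
  scale-specific response formats are deliberately not reproduced.
  Missingness is MCAR because only the deletion rule, not a missingness
  mechanism, is specified for this kind of analysis.
* **Trait scores** (`simulate_trait_scores()`): traits with pairwise
  correlation 0.8 (matching the strong covariate correlations typical of
  overlapping trait instruments) of which exactly one equals the
  behavioral target, for specificity checks of masked second-stage CPM.

What the generator does **not** emulate: temporal autocorrelation and
physiological artifacts of fMRI noise, site or scanner effects,
non-Gaussian behavioral distributions, informative missingness, and
instrument-specific item content. Passing tests therefore demonstrate that
the algorithms are correct and calibrated under their own assumptions, not
that any particular real dataset will yield signal.

# Numerical choices and edge cases

* Sample correlations exactly at the selection threshold are excluded
  (strict inequality); zero-variance edges are unselectable.
* Asymmetry beyond 1e-10 is an error in `vectorize_upper()`; residual
  orthogonality after confound regression holds to 1e-8.
* Rank-deficient confound matrices are an error naming the collinear
  columns, not a silent drop.
* The graphical lasso uses warm starts along the descending penalty path;
  penalties whose precision estimate is not positive definite are skipped
  in EBIC selection.
* Ties in Spearman accuracy use average ranks (R's default), so tied
  predictions are handled deterministically.
* Accuracy is undefined if predictions are constant across subjects
  (possible on null data with empty masks in every fold); such iterations
  yield NA accuracy and are visible in the result rather than imputed.

# Problem sizes used in validation

The shipped tests validate at desk scale, chosen to keep the full suite
within minutes while leaving the statistical checks well-powered: null
calibration uses 100 replicate datasets of 60 subjects x 40 nodes with 5
CV iterations and 200 permutations each; planted-edge recovery uses 20
seeds of 100 subjects x 50 nodes with 30 planted edges; specificity uses
20 seeds of the three-trait design; bootEGA recovery uses 10 seeds of
1000 participants x 24 items with 100 bootstrap replicates. Full-scale
runs (35,778 edges, 100 iterations, 1000 permutations, 500 replicates)
use the same code paths with larger settings.

# Known limitations

* Only the default atlas-free workflow is provided: the package consumes
  already-extracted node timecourses or edge matrices, never image files.
* The permutation test's observed statistic (median accuracy over many
  fold splits) is less variable than a single-split null accuracy, making
  the p-value mildly conservative near the tail; the calibration test
  bounds the rejection rate at the nominal level rather than asserting
  exact uniformity in the extreme tail.
* Ridge or partial-correlation CPM variants, confirmatory factor analysis
  of the item structure, and Walktrap community detection are out of
  scope.
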