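---
title: "Brain-age modelling from resting-state functional connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-age modelling from resting-state functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Resting-state fMRI yields, for each subject, a multivariate time series
over a set of brain regions (nodes). The pairwise Pearson correlations
of these series — the *functional connectome* — change systematically
across the lifespan: connectivity within several association networks
weakens with age, some cross-network coupling strengthens, and a number
of edges follow U- or inverted-U-shaped trajectories. `fcage`
implements a complete protocol for studying these effects and for the
inverse problem: predicting a subject's chronological age from their
connectome ("brain age"), whose residual against true age is a
candidate marker of atypical ageing.

The pipeline has six stages:

1. **Connectome construction.** For subject $i$ with node time series
   $X_i$, compute the Pearson correlation matrix, apply the Fisher
   transform $z = \operatorname{atanh}(r)$ edgewise, and vectorize the
   upper triangle in canonical row-major order into a column of the
   cohort edge matrix $D \in \mathbb{R}^{m \times n}$ ($m$ edges, $n$
   subjects). Node-level fractional amplitude of low-frequency
   fluctuations (fALFF) summarizes temporal dynamics: the ratio of
   summed amplitude-spectrum bins in $[0.01, 0.1]$ Hz to those in
   $[0.01, 0.25]$ Hz after linear detrending.
2. **Cross-subject components.** An *uncentered* PCA of $D$ (via the
   eigendecomposition of $D^\top D$, equivalently the SVD of $D$)
   expresses every subject's connectome as a weighted sum of shared
   component matrices. Because columns are not centred, the leading
   component captures the connectivity pattern common to all subjects;
   it is compared against the *multi-subject matrix* (the connectome of
   all subjects' standardized series concatenated in time). The
   component whose subject coefficients correlate most strongly with
   age is compared against the *age-effect matrix* of edgewise
   age–connectivity correlations and against the planted age pattern of
   the synthetic generator.
3. **Lifespan models.** Each edge, network summary, and node fALFF is
   regressed on age (linear) and on age plus centred age squared
   (quadratic), with sex, head motion (mean framewise displacement) and
   total intracranial volume as covariates. A trajectory is classified
   (linear-increase/decrease, U, inverted-U) only if both the age term
   and the overall model survive Benjamini–Hochberg FDR control within
   their family; significant quadratic terms take precedence.
4. **Feature extraction.** Three feature families feed the predictors:
   *network* features (the first $L$ uncentered-PCA coefficients, with
   out-of-sample coefficients obtained by least-squares projection),
   *edge* features (a supervised reduction described below), and
   *temporal* features (node fALFF).
5. **Prediction.** OLS, lasso (`glmnet`, $\lambda$ by inner CV on MAE)
   and support-vector regression (`e1071`, kernel/cost by inner CV)
   are evaluated by $K$-fold cross-validation (pooled Pearson $r$ and
   MAE in years) and by external validation: models trained on the
   entire internal cohort applied to an independently acquired cohort.
   Steiger's z compares dependent correlations between models; a
   pooled-variance z-test checks errors across groups; the error–age
   correlation quantifies age-dependent bias.
6. **Edge significance.** For linear models on supervised-reduced
   features, coefficients are mapped back to per-edge weights through
   the reduction's linear back-map, and each weight is tested against
   an empirical null obtained by permuting ages, refitting the
   reduction and model each time with hyperparameters frozen at their
   real-fit values; $p = (1 + \#\{|\beta_b| \ge |\beta|\})/(B+1)$.

## The supervised edge reduction

With $m \gg n$ edges, OLS is infeasible on raw edges and unsupervised
PCA may discard age-relevant directions. The supervised reduction is a
partial-least-squares sequence (PLS1 via NIPALS): standardize $X$
(subjects × edges) and $y$ (age); take the unit loading
$p_1 \propto X^\top y$ — the direction maximizing covariance with age —
project $u_1 = X p_1$, regress $X$ and $y$ on $u_1$, deflate, and
repeat for $l$ components. The training projections are mutually
orthogonal and the deflation conserves Frobenius energy, both of which
are enforced by tests. A linear model fitted on the components maps
back to edge space through $R = P (C^\top P)^{-1}$, giving one weight
per edge for the permutation test.

Crucially, the reduction *uses ages*. Fitting it on the whole cohort
before cross-validation leaks held-out ages into the features. The
package therefore supports two modes: `"strict"` (default — features
refit inside every training fold) and `"paper"` (whole-cohort fitting,
provided because it is a common practice in the literature). An
acceptance test documents that the whole-cohort mode is optimistic: over
20 simulated cohorts it inflates cross-validated $r$ by ~0.5 on small
cohorts.

## The synthetic cohort generator

Real repository-scale fMRI cannot ship inside a package, so every claim
is tested against a generator with planted, recoverable structure. For
subject $i$ with age $a_i$, the target Fisher-z connectome is

$$Z_i = B + (a_i - \bar a)\,A + (a_i - \bar a)^2\,C + E_i,$$

where $B$ is a modular baseline (stronger within-network blocks), $A$
holds planted linear age slopes (declining within-network edges,
strengthening cross-network edges), $C$ holds planted quadratic edges,
and $E_i$ is edge noise. $Z_i$ is mapped back through the inverse
Fisher transform and projected to the nearest positive-semidefinite
correlation matrix (eigenvalue clipping with diagonal renormalization).

Time series realize both the correlation and the spectral targets: each
node mixes a Butterworth-band-passed low-frequency component with
correlated broadband noise, $\sqrt{w}\,s_{\text{low}} +
\sqrt{1-w}\,s_{\text{broad}}$, and the per-node weight $w$ is solved
numerically so that the *expected estimated* fALFF (including
filter-shape and detrending effects, using the squared-magnitude
amplitude profile of the zero-phase filter) matches a planted
age-dependent target. Because only the broadband part carries the
target correlations, they are pre-boosted by
$1/\sqrt{(1-w_i)(1-w_j)}$ (clamped, then re-projected) so the
empirical full-band correlations are unbiased for the targets.

Known limits, deliberate and documented:

- Correlation targets are recovered with multiplicative attenuation
  (mean ratio ≈ 0.78 at the reference conditions) due to finite scans
  and the PSD projection; signs and significance-based trajectory
  classes recover essentially perfectly, so recovery tests assert
  those.
- Paired cohorts share ground truth and differ only in acquisition
  (volumes, TR, sampling noise). There is no site/protocol domain
  shift; as a consequence external validation — trained on the full
  internal cohort — can slightly *exceed* pooled out-of-fold internal
  accuracy, the reverse of what site effects produce on real data.
  This is reported honestly by the test suite rather than patched in
  the generator.
- Metadata are simple: sex ~ Bernoulli(1/2), lognormal motion mildly
  correlated with age, Gaussian TIV with a sex offset.

## Numerical choices

- Fisher transform clips $|r|$ at $1 - 10^{-7}$ before `atanh`.
- Uncentered PCA via `eigen(crossprod(D))`; component signs fixed by
  making each component's largest-magnitude entry positive.
- Mass-univariate lifespan fits share one QR decomposition of the
  design across all units.
- fALFF requires the total band to lie below Nyquist: at TR = 2.5 s
  (Nyquist 0.2 Hz < 0.25 Hz) it refuses to compute, so external
  validation of temporal features is structurally impossible and the
  pipeline skips it.
- The permutation p-value uses the add-one estimator and refuses
  $B$/$\alpha$ combinations that cannot resolve $\alpha$.
- All stochastic steps (generation, folds, permutations) take explicit
  seeds and restore the caller's RNG state.

## Problem sizes

The package's reference conditions — chosen to keep the full pipeline
in minutes on one CPU while leaving every planted effect detectable —
are an internal cohort of 200 subjects, 50 nodes in 10 networks, 400
volumes at TR 0.645 s, and an external cohort of 80 subjects, 260
volumes at TR 2.5 s. At these sizes the full pipeline (components,
lifespan models, the 3 × 3 feature-by-model prediction grid with 10-fold
CV, external validation) runs in about three minutes, plus ~1 minute
for a permutation test at $B = 500$.

## A minimal session

```{r example}
library(fcage)

cfg <- pipeline_config(
  generator_internal = generator_config(seed = 7),
  generator_external = generator_config(n_subjects = 80, n_volumes = 260,
                                        tr_seconds = 2.5, seed = 8,
                                        cohort_label = "external"),
  K = 10, L = 50, l = 20, permutation_B = 500, seed = 7)
run <- run_pipeline(cfg, out_dir = "fcage-run")
run$report$metric_grid
run$report$pc1_multisubject_r
```
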