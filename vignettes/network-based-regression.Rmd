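---
title: "Network-based regression: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based regression: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netbridge)
```

# Overview

`netbridge` links network psychometrics to network neuroscience in three
stages:

1. **Unique-variance regressors.** Correlated behavioural trait scores
   (the motivating example is the three ADI-R autism domains: Social,
   Communication, RRBI) are residualized so that each regressor carries
   only the variance not shared with the other traits.
2. **Connectome-based predictive modelling (CPM).** Each residualized
   trait is related to functional connectome edges: edges whose Pearson
   correlation with the trait passes a p-value threshold are summed into
   positive and negative brain scores, and the trait is regressed on the
   two scores. Analysis parameters (parcellation resolution, edge metric,
   global-signal channel, threshold) are tuned by nested shuffle-split
   cross-validation; stable edges are retained by a consensus rule and
   inference uses a permutation test of the cross-validated performance.
3. **Joint networks.** The trait scores and their total brain scores
   become nodes of (a) a Gaussian graphical model selected by the
   extended BIC, with bootstrap edge stability, and (b) a Bayesian
   network learned by constraint-based algorithms under several
   conditional-independence tests.

# Residualization: two schemes, on purpose

The unique variance of trait $A$ given traits $B, C$ is the residual
$\epsilon$ of

$$y_A = \beta_B X_B + \beta_C X_C + X_{Intercept} + \epsilon.$$

`residualize_full()` implements exactly this: every trait is regressed on
*all* others. Its residuals are orthogonal to every other original trait
but are generally **not** orthogonal to each other.

`residualize_sequential()` instead orthogonalizes in a stated order
(Gram–Schmidt): trait $k$ is regressed only on traits earlier in the
order, the first trait is kept unchanged. Its residual columns are
mutually orthogonal.

Both are provided because the two constructions genuinely disagree for
correlated traits, and the published residual-correlation table for the
ADI-R domains (the worked example reproduced by our acceptance tests) is
consistent only with the sequential scheme in order RRBI →
Communication → Social: the RRBI residual is identical to RRBI
(correlation 1.00) and the Communication residual retains correlation
0.93 with Communication and 0.56 with Social. The full scheme, by
contrast, matches the regression equation as written. Neither is declared
"correct"; `sequential` is the default because it reproduces the printed
table.

Two numerical notes:

* With the sample correlation matrix forced exactly to the printed
  values, the Social-residual/Social correlation recomputes to
  $\sqrt{1 - R^2} \approx 0.7356$ versus the printed 0.73. The printed
  inputs are rounded to two decimals, so comparisons use a ±0.01
  tolerance on that entry.
* Residual correlations are also computable from the correlation matrix
  alone by Schur-complement algebra; the test suite uses that closed form
  as an independent oracle against the data-level computation.

Missing scores are handled by complete cases *per regression* (the
traits entering a given fit), recorded in the fitted model's `n_used`.

# Synthetic data: a stated world

No subject-level data are shipped; the generators in `synth_spec()` /
`make_behaviour()` / `make_edge_table()` / `make_timeseries()` /
`make_confounds()` emulate the statistical structure the pipeline
assumes:

* **Trait scores** with a prescribed correlation matrix. Default: the
  printed three-domain matrix (0.66 / 0.38 / 0.36) at $n = 172$, the
  study's sample size. With `exact_corr` (default) a centred Gaussian
  draw is QR-orthonormalized and recoloured with the Cholesky factor of
  the target, so the *sample* correlation equals the target to $10^{-10}$
  — table reproduction is deterministic, not asymptotic.
* **Edge tables** of standardized Gaussian edges with planted effects:
  a planted edge is $\rho\,z(t) + \sqrt{1-\rho^2}\,\varepsilon$, so its
  population correlation with trait $t$ is exactly $\rho$.
* **Time series** i.i.d. multivariate normal rows under a given ROI
  covariance (so Pearson connectomes converge to its correlation form).
* **Confounds**: age uniform on [10, 21] years (the study's inclusion
  window), a categorical site label (19 sites by default, resampled until
  every site is occupied), lognormal FD (mm) and DVARS (%), normal ICV
  and grey-matter volumes (mm³). The source analysis specifies no
  generative model for any of this; these distributions are fixture
  conventions chosen once for plausibility, not claims about the ABIDE
  cohorts.

All generators take an explicit integer seed and restore the caller's RNG
state; identical spec + seed is bit-identical output. A green test on
this world establishes that the *pipeline machinery* behaves as
specified; it cannot establish anything about real rsfMRI data, which
have site effects, autocorrelated time series and non-Gaussian tails the
generators deliberately omit.

# Connectomes

`connectome_pearson()` is the plain correlation matrix.
`connectome_partial()` derives partial correlations from the precision
matrix, $\rho_{ij} = -\kappa_{ij}/\sqrt{\kappa_{ii}\kappa_{jj}}$, using a
Schäfer–Strimmer analytic shrinkage of the correlation toward the
identity by default (the reference analysis delegated this to a library
without naming the regularization; shrinkage keeps the estimate well
posed when timepoints do not greatly exceed ROIs). `shrinkage = "none"`
exposes the direct inverse for oracle tests. `connectome_tangent()`
models each subject as a deviation from the group average: the reference
is the geometric (Karcher) mean of the subjects' covariances (fixed-point
iteration, tolerance $10^{-8}$, max 200 iterations; a log-Euclidean
reference is available), and each subject maps to
$\log(C_g^{-1/2} C\, C_g^{-1/2})$. The embedding of the reference itself
is the zero matrix and the map is invertible on its image — both are
asserted in the acceptance suite.

Edges are vectorized in the row-major upper triangle ($i < j$), named
`ROIi_ROIj`. `regress_confounds()` removes age, age², acquisition site
(k−1 dummy coding), FD, DVARS, ICV and grey-matter volume from every edge
by OLS; residuals are exactly orthogonal to the design, and the
projection is idempotent. The regression is fit on the full sample, which
follows the reference pipeline but leaks distributional information
across cross-validation folds; a train-only variant (`fit_rows`) exists
behind a logged warning. `filter_rois()` excludes an ROI when its minimal
coverage fraction falls *strictly* below 0.5 — exactly 50% coverage is
kept, the boundary convention implied by "less than 50%" exclusion.

# CPM

Edge selection uses the two-sided p-value of the t transform
$t = r\sqrt{(n-2)/(1-r^2)}$ with $n-2$ df (the reference analysis never
names its test; this is the standard choice). The model is

$$y = \beta_{Brain+} S_+ + \beta_{Brain-} S_- + X_{Intercept} + \epsilon$$

with $S_\pm$ the summed weights of the positively/negatively associated
edges. Tuning runs the same seeded 80/20 shuffle splits (default 10)
for every grid cell; the inner 10-fold CV inside each training set is
recorded as a diagnostic, while the deployed per-split model is refit on
the full training 80% — the reading that keeps one model per outer split,
which the consensus rule presupposes. Ties in the best cell go to the
smaller ROI resolution, then the stricter threshold.

Consensus retains edges selected with the same sign in at least
`min_count` of the splits (default 7 of 10); sign conflicts are excluded
and logged. The permutation test re-runs the *entire* pipeline —
including edge selection — on row-permuted scores (no selection leak;
a frozen-selection variant exists), with the add-one estimator
$p = (1 + \#\{null \ge observed\})/(1 + B)$, valid under exchangeability;
$B$ defaults to 5,000 as in the reference analysis and is reduced to
199 in tests. If every outer split of a run yields an undefined held-out
correlation (empty selection and intercept-only prediction), the
statistic is undefined and the p-value is reported as `NA` rather than
silently extreme.

`total_brain_score()` is $\beta_{Brain+} S_+ + \beta_{Brain-} S_-$
without the intercept: downstream network estimation is
correlation-based and shift-invariant, and on training data the score
correlates with the outcome exactly at the model's multiple R.

# Gaussian graphical models

The selected network is an *unregularized* GGM: `glasso_path()` (an
in-package block coordinate-descent graphical lasso; 100 log-spaced
penalties from $\lambda_{max}$ down to $0.01\lambda_{max}$) proposes
candidate supports, each is refit as a constrained maximum-likelihood
model, the EBIC-best is refined by `stepwise_select()` (greedy
single-edge additions/removals, largest EBIC decrease first,
lexicographic tie-break, stop at a local minimum).

The constrained MLE (`fit_ggm_support()`) uses the modified-regression
iterative algorithm; at convergence the fitted covariance equals the
input on the diagonal and on every support edge, and the precision is
exactly zero elsewhere (the Dempster conditions, asserted at $10^{-8}$).

$$\mathrm{EBIC} = -2L + E\log n + 4E\gamma\log p$$

with edge count $E$; the model-independent $2\pi$ likelihood constant is
dropped, leaving all comparisons unchanged, and $\gamma = 0$ recovers
BIC. $\gamma$ defaults to 0.5, the conventional value for this estimator
family (the reference analysis is silent). `bootstrap_network()`
resamples subjects (default $B = 1000$; 100–200 in tests), re-runs the
full estimation per replicate, and reports per-edge medians and
2.5/97.5 percentile intervals; an edge is "significant" when its interval
excludes zero. The reference figure caption says "2.5% and 98.5%ile",
which we read as a typo for 97.5; its "bootstrap p value < 0.05" is not
defined further, and interval exclusion is our declared proxy. Replicates
whose fit fails are dropped and counted; more than 10% failures rejects
the run.

# Bayesian networks

All scores are treated as jointly Gaussian, so every
conditional-independence test reduces to the partial correlation $r$ of
$x, y$ given $Z$: exact t (df $n-|Z|-2$), Fisher-Z
($\mathrm{atanh}(r)\sqrt{n-|Z|-3}$), Monte-Carlo permutation of
residualized scores, and the Gaussian mutual information
$MI = -\tfrac12\ln(1-r^2)$ with $G = 2n\,MI \sim \chi^2_1$. Tests with
insufficient degrees of freedom report non-rejection with a warning —
the skip behaviour constraint learners need. All four are calibrated
under independence (acceptance criterion: uniform p-values by KS test).

Five learners are implemented: Grow-Shrink, IAMB, Fast-IAMB (speculative
batch growing), Inter-IAMB (shrinking interleaved into growing) and
MMPC (parents-children discovery with worst-case-association forward
phase). Conventions the reference leaves unstated, fixed here and
documented: AND-rule symmetry correction; exhaustive separating-set
search within the candidate sets, keeping the separator with the largest
p-value; v-structure orientation for unshielded triples whose separator
excludes the middle node, conflicts resolved in favour of the smaller
separating p-value and logged; Meek rules 1–4 to a fixed point (except
MMPC, whose scope ends at skeleton plus v-structures); orientations that
would close a directed cycle are refused; candidate sets iterate in
sorted label order so node order never affects results; $\alpha$
defaults to 0.05. The test suite checks the learned graphs against a
brute-force oracle that enumerates all DAGs, groups them by d-separation
signature, and intersects orientations over the Markov equivalence
class.

`consensus_structure()` keeps edges identical in type and orientation
across all runs and itemizes every disagreement, mirroring the
cross-algorithm consistency argument of the motivating study.

# Pipeline and reproducibility

`run_pipeline()` chains QC (exclude when FD > 0.5 mm or DVARS > 5%,
strict comparisons, missing metrics excluded with reason), confound
regression, residualization, per-trait CPM, total brain scores, the
six-column joint table (traits then brain scores), the three GGMs
(behaviour-only, brain-only, combined) and the Bayesian-network
consensus. Stage seeds derive from the master seed by an exact
polynomial hash of the stage label, so stages re-run in isolation
reproduce the full run; reports contain no timestamps and are
byte-identical across re-runs (an acceptance criterion). A trait whose
CPM model selects no edges has a constant (zero) total brain score; such
nodes are dropped from network estimation with a note in the report
rather than producing undefined correlations.

Config files are YAML (`run_config()` documents the field list); the CLI
(`cli_main()`, launcher in `inst/cli/netbridge.R`) exposes `simulate`,
`residualize`, `cpm`, `network`, `dag`, `run` and `report` verbs.

# Known limitations

* The synthetic world is Gaussian and exchangeable; site labels carry no
  scanner effect, time series no autocorrelation, and traits no floor or
  ceiling effects. Green tests validate machinery, not neurobiology.
* The published headline numbers (held-out correlations around
  0.05–0.23, permutation p ≈ 0.01–0.02, the anatomical edge tables)
  depend on the ABIDE/ABIDE-II cohorts and are not reproducible from
  synthetic fixtures; they are deliberately outside the acceptance
  surface, which rests on the fully determined worked example and on
  property-based criteria.
* Image preprocessing (registration, nuisance regression, parcellation
  extraction, FreeSurfer volumetrics) is out of scope; inputs begin at
  ROI time series or precomputed connectomes and coverage fractions.
* Score-based structure learning and alternative predictive models
  (ridge, SVR, specification curves) are intentionally not provided.
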