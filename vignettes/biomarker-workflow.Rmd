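---
title: "A two-phase plasma-miRNA classification workflow with hormone-use effect modification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-phase plasma-miRNA classification workflow with hormone-use effect modification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Endometriosis is diagnosed surgically, often after years of delay, and
circulating microRNAs are a candidate non-invasive biomarker. In adolescents
and young adults most disease is early-stage (rASRM I/II) and a large
fraction of patients take exogenous hormones, which themselves perturb
circulating miRNA levels. This package implements, end to end, a two-phase
case-control biomarker workflow in which hormone use at blood draw is
treated as an effect modifier throughout:

1. a small **discovery phase** (10 cases / 10 controls) profiling ~754
   plasma miRNAs by qPCR arrays in technical duplicate;
2. an **internal replication phase** (54 cases / 108 controls, frequency
   matched on age and hormone use) assaying a ~63-probe bead-array panel,
   split 2:1 into training and testing sets, with feature selection and a
   neural-network classifier built on the training set and validated on the
   testing set.

Because studies of this design rarely release individual-level data, the
package also contains a first-class synthetic cohort generator that plants
hormone-stratum-specific effects, so every stage is testable and the whole
pipeline can be exercised at study scale from a seed.

## Discovery-phase statistics

`collapse_duplicates()` averages technical duplicates that agree within
`max_discordance` (default 1 cycle) and discards discordant pairs.
`qc_filter()` sets measurements with Ct > 34 missing (the rule is strictly
"greater than": Ct = 34.0 is retained) and drops miRNAs missing in more than
half the samples; commercial qPCR analysis software typically applies a
single exclusion rule, and the per-measurement / per-miRNA distinction here
is this package's documented refinement. `flag_outliers()` is a reproducible stand-in for
interactive outlier review: a per-miRNA, per-group Grubbs test at
$\alpha = 0.05$, repeated until no flag; it can be switched off
(`outlier_flagging = FALSE`). Missing values are imputed with the miRNA mean
within the (group $\times$ hormone-use) cell, falling back to the miRNA
grand mean.

`global_normalize()` computes $\Delta Ct_{gs} = Ct_{gs} - \overline{Ct}_{s}$
against the per-sample mean, removing plate loading shifts exactly (the
normalized values are invariant to adding a constant to a whole sample
column).

**Reference stability.** `normfinder_stability()` implements the
model-based decomposition: for gene $i$ in group $g$ with group mean
$a_{ig}$, within-group variance $v_{ig}$ and group size $n_g$, the
group-bias term is the two-way interaction residual

$$d_{ig} = a_{ig} - \bar a_{i\cdot} - \bar a_{\cdot g} + \bar a_{\cdot\cdot},
\qquad
\rho_i = \frac1G \sum_g \left(|d_{ig}| + \sqrt{v_{ig}/n_g}\right),$$

with lower $\rho$ meaning a better normalization reference. This is the
unshrunk estimator; the published algorithm's empirical-Bayes shrinkage of
$d_{ig}$ changes the numerical values but not the ranking properties the
workflow relies on, and the bias and standard-error components are returned
so a shrinkage variant can be layered on. With a single group, $\rho$
reduces to the per-gene standard error. `select_references()` takes the $k$
(default 5) smallest-$\rho$ miRNAs, ties broken lexicographically.

**Relative quantification.** `ddct_fold_change()` computes
$\Delta\Delta Ct$ as the case-minus-control difference of
reference-adjusted $\Delta Ct$ means and the expression ratio
$R = 2^{-\Delta\Delta Ct}$. Ratios are displayed in the signed convention
($R \ge 1 \mapsto R$, $R < 1 \mapsto -1/R$), so magnitudes are always at
least 1 and swapping the groups flips the sign. The convention itself is a
display choice this package adopts to match how such tables are usually
printed; it has no computational consequences.

**Candidate selection.** `stratified_ttests()` runs two-sided
pooled-variance (Student's) t-tests separately among hormone users and
non-users (Welch by config). `discovery_selection_rule()` admits a miRNA if
$p < 0.005$ in either stratum, or $p \le 0.05$ in both. Whether the
underlying tests are computed on $\Delta Ct$ or on reference-adjusted values
is immaterial for the pooled t-test (the reference adjustment is a
per-sample shift that cancels); this package tests the reference-adjusted
values. `assemble_panel()` concatenates the candidates with literature
additions and positive/negative control probes into the replication panel.

## Replication-phase feature selection

`preprocess_mfi()` takes raw bead-array fluorescence, optionally subtracts
the mean blank-well background per probe (off by default, since the
upstream workflow describes only a shift-and-log procedure), replaces
values at or below zero by 0.001, and log10-transforms. Pooled-QC wells are
summarized as a per-probe CV; they never enter the analysis table.

`univariate_tests()` applies the same pooled t-test kernel on log10 MFI,
training set only, with fold change $10^{\bar x_{case} - \bar x_{control}}$
in the signed convention, and `holm_sidak_adjust()` applies the step-down
correction $p^{adj}_{(i)} = 1 - (1 - p_{(i)})^{m - i + 1}$ with a running
maximum. `pca_separation()` reports the AUC of PC1 scores against the
labels (folded at 0.5 because a principal axis has arbitrary sign) and the
agreement of a 2-means clustering with case status.

`cfs_select()` implements correlation-based feature selection: the merit of
a subset of $k$ features is
$$\mathrm{merit} = \frac{k\,\bar r_{cf}}{\sqrt{k + k(k-1)\bar r_{ff}}},$$
with $\bar r_{cf}$ the mean absolute feature-class correlation
(point-biserial, as the features are continuous and the class binary) and
$\bar r_{ff}$ the mean absolute pairwise correlation. Candidates are the
probes with raw $p \le 0.15$ in the training-set univariate screen (the
gate uses raw p-values, computed once on the full training set). The search
is exhaustive up to 15 candidates and best-first with a stall limit of 5
beyond that. Selection runs in each of 10 group-stratified CV folds;
features chosen in at least half the folds are kept. The hormone-use
covariate is forced into every evaluated subset and into the final feature
set regardless of merit. The fold-aggregation rule is this package's
choice (the upstream description says only "CFS was performed with 10-fold
cross validation"); majority voting was chosen for determinism and
stability over union (too permissive) and intersection (too brittle).

## Model construction

`ensemble_search()` draws random single-hidden-layer perceptron
architectures: hidden size uniform on
$[\lceil n/3 \rceil, \lfloor 1.5n \rfloor]$ for $n$ input variables, hidden
activation uniform over linear, logistic, tanh and exponential, logistic
output. Each network is trained by BFGS (`stats::optim`) on an L2-penalized
binomial cross-entropy from seeded small-uniform initial weights
($\pm 0.5/\sqrt{\text{fan-in}}$), with one automatic restart at a five-fold
smaller scale if the loss diverges. The loss function and the
training-ranking metric are not pinned down by the upstream description
(they are internals of a commercial package); penalized cross-entropy and
training AUC are this package's choices, the latter consistent with the
validation metric. Inputs are standardized to training mean/sd; binary 0/1
covariates pass through unstandardized. The study-scale sweep is 15,000
networks with the 50 best (by training AUC) retained; tests and examples
use a few hundred networks, which the interfaces expose as ordinary
parameters.

`select_final()` scores the retained networks on the testing split and
returns the testing-AUC maximizer (ties: higher training AUC, then lower
network index). **Selecting the final model on the testing set is
optimistically biased.** The procedure is implemented as published rather
than second-guessed, and the bias is quantified rather than hidden: under a
full-null simulation the selected model's testing AUC averages roughly
0.55-0.60 at this study's testing-set size, because the argmax over ~50
near-null AUCs (null SE $\approx 0.08$ at 18 cases / 36 controls) sits
about one SE above chance. Readers of the headline AUC should carry that
calibration with them.

## Evaluation

`roc_auc()` computes the AUC both as the tie-corrected rank statistic and
as the trapezoidal area under the threshold-sweep curve and insists the two
agree to 1e-12. `hanley_mcneil_test()` provides the analytic SE
($Q_1 = A/(2-A)$, $Q_2 = 2A^2/(1+A)$) and the z-test against AUC = 0.5.
`confusion_at_threshold()` classifies at a probability cutoff (default 0.5,
ties count positive) and attaches exact Clopper-Pearson intervals
(`binomial_ci()`); Wilson-type intervals cannot be distinguished from exact
ones at the printed precision of typical reports, and the exact interval
was chosen as the conservative default. With the published confusion counts
(26/20/10/52 training, 15/15/3/21 testing) these functions reproduce
sensitivity/specificity of 72.2%/72.2% and 83.3%/58.3%, and an AUC of 0.77
at 18/36 gives $z \approx 3.71$, $p \approx 2\times10^{-4}$, consistent
with the printed bound $p < 0.001$. The Hanley-McNeil 95% interval at
$A = 0.77$ is $0.77 \pm 0.143$, wider than typical software-printed
intervals at that AUC; the package reports its own interval and does not
attempt to reproduce intervals whose method is unknown.

## The synthetic cohort generator

`simulate_cohort()`, `simulate_ct_matrix()` and `simulate_mfi_matrix()`
emulate the study's data-generating shape:

* cohorts with a 1:2 case:control ratio, hormone use Bernoulli with the
  same rate in both groups (frequency matching by construction; 0.5 in the
  discovery phase, 0.78 in replication, matching the reported rates), ages
  uniform on the recruitment range;
* discovery Ct values with per-miRNA baselines U(18, 33), a per-sample
  loading shift N(0, 0.5) that global normalization must remove, planted
  effects that lower case Ct by the log2 fold change within the specified
  hormone stratum, technical-duplicate scatter, and missingness; values
  above 34 are generated, not truncated -- the QC filter owns that rule;
* replication MFI values log-normal around per-probe baselines with the
  planted effect scaled by $\log_{10} 2$, pooled-QC replicate wells (5% of
  study wells), water-blank wells, and negative-control probes whose
  background-corrected readout scatters around zero and is frequently
  negative -- which is how the assay actually produces the negative values
  that the 0.001-shift rule handles. (Corrupting random high-expression
  wells with negatives would misrepresent the assay physics; a uniform
  injection rate exists as a parameter for unit tests and defaults to 0.)

Noise defaults are chosen for testability, not estimated from data (no
usable variance estimates are published for this design): Ct measurement sd
0.20 cycles and duplicate-difference sd 0.20 cycles, so duplicates agree
within ~0.5 cycles as ordinary qPCR QC expects, and log10-MFI sd 0.15
(~40% CV on raw fluorescence). At those values a planted |log2 FC| = 1
effect gives a within-stratum standardized difference of ~4 at the
discovery phase's 5-vs-5 stratum sizes, which is what makes a 10+10
discovery cohort workable at a p < 0.005 threshold -- mirroring the fact
that the real discovery phase reported only large fold changes
(|FC| $\ge$ 2).

The default planted pattern is five effects: two confined to hormone users,
two to non-users, one in both strata, signs mixed, echoing the three
categories of the discovery-phase candidate table.

**What passing tests do and do not show.** The generator's effects are
cleanly confined to a stratum and probes are independent given the class;
real plasma miRNAs are correlated, effects leak across strata, and
platform effects between qPCR and bead arrays are not modeled. Parameter
recovery on this generator therefore demonstrates that the pipeline's
machinery is correct and calibrated, not that the study's biological
findings replicate. One structural consequence is worth stating plainly:
at a 78% hormone-use rate, an effect confined to non-users has a marginal
case-control shift of only 22% of its within-stratum size, so marginal
selectors (the univariate gate, CFS merit) systematically miss such probes
even when they carry real signal -- exactly the situation that motivated
forcing hormone use into the model in the first place, and the reason the
interaction-capable network can classify well even when univariate
replication statistics look null.

## Determinism and numerics

Every stochastic stage is a pure function of its parameters and an integer
seed; the pipeline fans one master seed out into named per-stage seeds
recorded in the run report. Model JSON serialization uses 17 significant
digits, which round-trips IEEE doubles exactly. The exponential activation
is clamped at $|u| \le 30$ before exponentiation; predicted probabilities
are clipped to $[10^{-12}, 1-10^{-12}]$ inside the loss. Degenerate cases
are defined, not left to chance: a t-test on two zero-variance groups with
equal means returns p = 1; strata too small to test are flagged missing; a
stratum with a single sample goes to the training set with a warning; CFS
with no candidates returns the forced covariates with a warning.

## Problem sizes used by the test suite

The packaged tests run the full pipeline at study shape (754 discovery
miRNAs, 162 replication samples) with ensembles of 200 networks, 10
replicates for the recovery and null-calibration suites, and 200 replicates
for the family-wise-error check of the univariate screen. These sizes give
stable pass/fail behaviour for the properties being checked while keeping
the suite quick; the study-scale 15,000-network sweep is exposed through
`run_config(n_networks = 15000L)` and `analysis/04_model.R`.

## Known limitations

* The real study's plasma dataset is not public, so no numerical result
  that depends on the measured data (in particular the headline testing
  AUC) can be reproduced here; only its procedure and its printed,
  input-computable numbers can.
* The Normfinder estimator is unshrunk (see above).
* CFS uses point-biserial class correlations; the symmetric-uncertainty
  variant on discretized features is not implemented.
* The sweep treats "iteratively optimized" hidden sizes as uniform random
  sampling over the stated range, the natural reading for a 15,000-network
  construction; a grid sweep would visit each size deterministically but
  the published count is far larger than the grid, implying repeated
  random restarts either way.
* Selection of the final model on the testing set is reproduced as
  published; a held-out third split would be required for an unbiased
  estimate of the selected model's AUC.
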