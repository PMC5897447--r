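---
title: "Additive Gaussian process modelling of longitudinal serum proteomes"
author: "serogp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Additive Gaussian process modelling of longitudinal serum proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serogp)
```

## The problem

Serum proteomics of infants poses a particular inference problem: protein
levels change rapidly and non-linearly with age, individuals differ in their
baseline levels (confounded with preparation batch when each child's samples
are processed together), and cohort designs add subject-constant covariates
such as gender and living environment plus a seasonal sampling phase. With a
handful of children sampled at roughly 3, 6, 12, 18, 24 and 36 months,
parametric mixed models require a functional form for the age trend that is
rarely known. `serogp` instead models each protein's log2 trajectory as an
additive Gaussian process (GP) and asks, per protein, *which covariates
earn their place in the model* under cross-validated predictive density.

## The model

For one protein, let \(y_i\) be the standardised log2 intensity of sample
\(i\) with covariates age \(a_i\) (months), season phase \(s_i\)
(month-of-year), gender \(g_i\), location \(\ell_i\) and subject \(u_i\).
The full model is

\[
y_i = f_{\mathrm{age}}(a_i) + f_{\mathrm{seas}}(s_i) + f_{\mathrm{gen}}(g_i)
    + f_{\mathrm{loc}}(\ell_i) + f_{\mathrm{id}}(u_i)
    + f_{\mathrm{age \times id}}(a_i, u_i) + \varepsilon_i ,
\qquad \varepsilon_i \sim N(0, \sigma^2),
\]

with independent zero-mean GP priors per component:

* **age** — squared exponential,
  \(k(a, a') = v\, e^{-(a - a')^2 / 2\lambda^2}\): smooth non-parametric
  trends;
* **season** — periodic kernel on month-of-year,
  \(k(s, s') = v\, e^{-2 \sin^2(\pi (s - s') / 12)/\lambda^2}\), period fixed
  at 12 months;
* **gender / location / id** — block-constant categorical kernels
  \(k = v\,\mathbf 1[\text{same level}]\), i.e. random level offsets;
* **age × id** — the product of an SE kernel on age and the subject
  indicator: each child's smooth deviation from the shared age trend.

Because a sum of kernels is the kernel of a sum of functions, exact GP
arithmetic gives both the marginal likelihood and, after fitting, the
decomposition of the posterior mean into per-component contribution curves
(`contributions()`) whose empirical variances yield the variance shares
(`variance_shares()`) used to rank, say, individual against age-associated
variation. The contributions sum to the full posterior mean by construction;
the test suite asserts this to 1e-8.

## Fitting

`agp()` standardises the response (mean 0, sd 1 over non-missing values),
drops missing observations (no value is ever imputed anywhere in the
package), and maximises the log marginal likelihood over the log-scale
hyperparameters with L-BFGS-B from five random restarts by default.
Gradients are analytic; the dense \(O(n^3)\) likelihood/gradient kernel is
compiled (RcppArmadillo). Box constraints keep lengthscales in \([0.5, 100]\)
months and variances in \([10^{-6}, 10]\) on the standardised scale. The
Cholesky factorisation is attempted without jitter first — so the reported
likelihood is exactly that of the stated covariance in the regular case — and
under failure a diagonal jitter escalates tenfold from 1e-8 to at most 1e-4
before a numerical error is raised. Fits are deterministic given (data, seed,
number of restarts).

## Covariate selection

The four optional covariates (age, season, gender, location) give \(2^4 =
16\) candidate models (`enumerate_models()`); every candidate keeps the
subject component and the noise term, and candidates containing age also
carry age × id, so the interaction is tied to the age effect rather than
being a seventeenth toggle. Two cross-validation schemes score a candidate on
the standardised scale, both with hyperparameters held at their full-data
optima:

* **LOOCV** (`loocv_mlpd()`), by the exact closed-form leave-one-out
  identities, detects *time-varying* effects (age, season): a held-out
  observation is predicted from the remaining ones, including the same
  child's neighbours.
* **SCV** (`scv_mlpd()`) holds out entire subjects, so *subject-constant*
  effects (gender, location) must generalise to unseen children; the held-out
  child's id component contributes only prior variance because its
  categorical kernel has zero cross-covariance with other subjects. Folds are
  leave-one-subject-out up to 20 subjects, stratified k-fold beyond that.

For covariate \(c\), \(\Delta\mathrm{MLPD}_c\) is the best score among models
containing \(c\) minus the best among models lacking it, under the scheme
appropriate to \(c\). A covariate is called significant when
\(\Delta\mathrm{MLPD}_c \ge \delta\) **and** its variance share in the best
model is at least \(\rho\). The defaults \(\delta = 0.05\) nats and \(\rho =
0.01\) are this package's documented operating point; the type-I simulation
in the acceptance suite (100 seeded pure-noise proteins at the study design)
verifies that any covariate is flagged for at most 10% of null proteins at
these defaults. The "best model" is the LOOCV-top candidate with ties broken
towards the smaller covariate set; combining the two CV schemes into a single
ranking is a design choice the data cannot settle, and LOOCV is used because
every candidate is scored by it.

Candidates are fitted in size order and each model's restart set reuses the
optimum of its sub-model lacking the last covariate, which keeps training log
marginal likelihoods effectively monotone under nesting (asserted in the
suite) and speeds up the 16-model sweep. In `select_proteome()` each protein
derives its seed from the master seed and the protein identifier, making
results invariant to row and column order.

## Processing of quantification tables

`read_protein_groups()` parses MaxQuant-style `proteinGroups` exports (the
intensity-column prefix is configurable, default `"LFQ intensity "`).
Filtering follows fixed rules with *strict* removal thresholds, so boundary
cases are kept: reverse-database and modification-site-only identifications
are removed, as are proteins with fewer than 2 unique peptides or nonzero
intensity in fewer than 25% of runs; technical replicates collapse to the
median of nonzero values (all-zero triples become missing); values are then
log2-transformed; and proteins quantified in fewer than 50% of samples are
removed. Cord-blood and follow-up samples are filtered separately, because
the neonatal proteome differs enough that the two are best treated as
separate regimes. Child-specific Z-scores use the sample (n−1) standard
deviation; a constant or length-<2 trajectory yields missing Z-scores (never
zeros) with a warning. Paired fold changes between batch-mates are
\(2^{|\Delta \log_2|}\) — direction-agnostic magnitudes — summarised by
medians over shared age bins and then over pairs. Age bins
\(\{\text{cord}, 3, 6, 12, 18, 24, 36\}\) assign samples to the nearest
nominal age within ±1.5 months, matching the cohort's sampling schedule.

## Rank-based cord-blood comparison

Cord and follow-up batches are compared on within-sample ranks (1 = most
abundant, ties averaged), which are invariant to monotone transforms and
hence robust to batch-level intensity calibration. For subjects with both a
cord and a 3-month sample, proteins are ranked by the within-pair difference;
a protein's rank product is the geometric mean of its per-pair ranks, in both
directions. Significance uses the percentage of false prediction (pfp): the
expected number of null proteins at least as extreme — computed exactly when
the data are complete and the \(m^k\) grid is small, otherwise by B = 10,000
seeded permutations of the within-pair ranks — divided by the observed count,
then made monotone in rank-product order by a reverse cumulative minimum.
With missing values, each pair ranks only its observed proteins and the
permutation null preserves the missingness pattern; proteins observed in
fewer than two pairs are dropped. Per-subject Spearman correlations between
cord and each follow-up bin are tested two-sided, pooled into a single family
for Benjamini–Hochberg adjustment, and flagged at q < 0.1. SRM validation
tables are normalised by summing transition intensities per protein and
dividing by the endogenous reference A1BG in the same sample.

## The synthetic cohort

`simulate_design()` emulates the study scale: 15 children (11 + 4 across two
locations), six follow-up samples at jittered nominal ages (sd 0.3 months),
balanced genders, batches of two children, uniformly distributed birth months
driving the season phase, cord samples for all but one child, and 10%
missingness. `simulate_protein()` draws every active component from the same
kernel family the fitter assumes (the well-specified regime), stores the
additive truth exactly, and treats cord samples as their own regime: subject
offset + per-protein cord offset + noise, not an age-0 extrapolation. The
age lengthscale default is 6 months, so that drawn trajectories concentrate
their change in the first year of life, as real age-associated serum proteins
do; a longer lengthscale over a 3–36-month window would make most draws
nearly flat. Because component draws come from their priors, a drawn age
curve's *realized* spread across the design varies around its nominal value —
occasionally a "true" age protein is born essentially flat, which is exactly
the behaviour a power simulation should expose.

What the generator does **not** emulate: intensity-dependent missingness
(dropout here is uniform), peptide-level quantification noise, retention-time
drift, or depletion-column artefacts. Passing tests therefore demonstrate
correctness of the statistical machinery under the assumed additive model,
not robustness to every failure mode of real LC-MS/MS data; a
misspecification check (e.g. sigmoidal age trends) can be built by passing
custom values through `simulate_protein()`'s effect configuration.

## Pipeline and scale choices

`run_pipeline()` chains simulate → ingest → select → summarize → cordcompare,
writing TSV reports and a JSON manifest (package and R versions, seeds,
thresholds, per-stage protein counts; no timestamps, so reruns are
byte-identical). The default synthetic dataset holds 24 proteins with the
class mix 40% age / 10% location / 20% id-dominated / 30% null; this keeps a
complete default run, including the 16-model sweep for every protein, to
roughly a minute while exercising every stage. The heatmap clustering of
average Z-score profiles uses Ward linkage on Euclidean distances cut at k =
6 clusters — the number of trajectory families typically described for early
childhood — and is flagged as an interpretive choice, not an estimate.

## Numerical choices and limitations

* MLPD values are reported on the standardised response scale; they are
  comparable across models of one protein, not across proteins.
* Ties in best-model selection go to the smaller covariate set (parsimony);
  LOOCV differences below 1e-4 nats count as ties, which keeps the chosen
  label free of meaningless decorations and stable under reorderings of the
  input.
* The SE kernel with a free lengthscale can, at type-II maximum likelihood,
  trade places with the noise term (short-lengthscale age × id components
  absorbing residual variance); the CV-based selection layer, not the
  marginal likelihood alone, is what confers robustness to this.
* Hyperparameter uncertainty is ignored (type-II ML, not full Bayes);
  per-fold re-optimisation inside CV is deliberately avoided for
  tractability, which can slightly favour larger models.
* The rank-product pfp is an FDR-type estimate and can exceed 1; values are
  clipped only by the monotonisation step.
* Proteins with fewer than 8 observations or 2 subjects are skipped with a
  logged reason rather than fitted.
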