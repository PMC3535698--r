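---
title: "Decision fusion of miRNA target predictions: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision fusion of miRNA target predictions: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirfuse)
```

## The fusion model

`mirfuse` treats the six upstream predictors (TargetScan, miRanda, PicTar,
mirTarget, PITA, Diana-microT) as noisy sensors of a latent target
indicator y. Two observations drive the design:

1. **Scores disagree but are individually informative.** Each tool's score
   distribution differs between true targets and non-targets, so each score
   carries class evidence — but on its own scale and with its own shape.
2. **Missingness is informative.** Tools only report pairs passing internal
   cutoffs, so *whether* tool i reports a score at all (the indicator
   s_i) depends on the class: a pair scored by a conservative tool such as
   mirTarget is, before even looking at the score, more likely a target.

The model is a naive-Bayes-structured Bayesian network: given y, the tool
observations (s_i, x_i) are independent, and

p(y = 1 | x) ∝ p(y = 1) ∏_i p(x_i | y),  with
p(x_i | y) = Σ_{s_i∈{0,1}} p(x_i | s_i, y) p(s_i | y).

A reported score is impossible under s_i = 0 and a missing one impossible
under s_i = 1, so exactly one term of the marginalization survives. Each
tool therefore needs three ingredients: a positive-class score density, a
negative-class score density, and the reporting-rate pair
(tpr = p(s=1|y=1), fpr = p(s=1|y=0)).

**Assumptions.** Conditional independence given y is the key simplification;
tools that share features (seed matching, conservation) are positively
correlated even within a class, so the fused posterior is typically
overconfident in absolute value even when its *ranking* is good. The model
also assumes one score per (miRNA, gene) pair per tool — any per-site
aggregation (e.g. taking a tool's best site score per UTR) is the score
provider's job — and that each tool's performance is the same for all
miRNAs, which is what justifies estimating one rate pair per tool from a
single reference miRNA.

## Conditional score densities

Each tool × class density is a parametric family fitted by maximum
likelihood on the non-missing scores of that class:

| tool | positive class | negative class |
|---|---|---|
| TargetScan | reflected Gamma | reflected Gamma |
| miRanda | Negative Binomial | Negative Binomial |
| PicTar | Gamma | Gamma |
| mirTarget | 2-component Gaussian mixture | shifted Exponential |
| PITA | Gaussian | Gaussian |
| Diana-microT | shifted Exponential | shifted Exponential |

The assignment is configuration (`default_family_map()`), not code, so other
tools or re-mappings need no package change. Family-specific choices:

* **Reflected Gamma** (TargetScan context scores are negative, piled up
  against a maximum near 0): the sample is flipped at a reflection point
  r = max(x) + ε with ε = 1e-9 × sample range, and a Gamma is fitted to
  r − x. The ε keeps the best training score strictly inside the support;
  r is stored in the model and reused at prediction time. The Gamma MLE is
  solved exactly via the profile likelihood (the shape solves
  log a − ψ(a) = log mean − mean log, a strictly decreasing function, by
  `uniroot`; the scale is mean/shape), which needs no starting values.
* **PicTar uses the Gamma without reflection** — its scores are right-skewed
  positive, so flipping is unnecessary; reflection is a per-tool property of
  the family map.
* **Negative Binomial on real-valued miRanda scores**: NB needs counts, so
  scores are shifted to a zero minimum, multiplied by a configurable scale
  (default 1; miRanda alignment scores are already near-integer) and rounded.
  Shift and scale are recorded and applied identically to new scores; the
  reported "density" is the probability mass per unit of the original score
  axis (mass × scale). Parameters come from `MASS::fitdistr`.
* **Gaussian**: closed-form MLE with the 1/n standard deviation. At the
  fitted sample sizes the 1/n-vs-1/(n−1) distinction is far below every
  other source of error.
* **Two-component Gaussian mixture** (mirTarget's SVM scores are bimodal in
  positives): EM with deterministic initialization — means at the 25th/75th
  percentiles, both sds at half the sample sd, equal weights — stopping when
  the log-likelihood gain falls below 1e-8 or at 500 iterations. If a
  component collapses (sd < 1e-6 × range) the fit restarts from seeded random
  pairs of data points, at most 5 times, then errors. Components are ordered
  by ascending mean so the parameterization is identifiable.
* **Shifted Exponential**: the shift is the sample minimum (mirTarget and
  Diana-microT scores do not start at 0); the rate is the closed-form MLE
  1/mean(x − shift).

**Out-of-support scores.** At prediction time a score can fall outside a
fitted support (beyond the reflection point, below a shift). Rather than
propagate a zero likelihood — which would make one tool veto the other five
— every density evaluation is floored at 1e-12 (configurable). Reporting
rates of exactly 0 or 1, possible on small references, are likewise clamped
to [1e-9, 1 − 1e-9] before logs are taken.

**Numerics.** The six-factor likelihood products can underflow doubles, so
all products are sums of logs and the posterior is formed with a
log-sum-exp guard; the unit tests verify equality with a direct-probability
Bayes computation to 1e-10 relative error across random models.

## Training

`mirfuse()` estimates everything from one labeled score table: the twelve
conditionals on class-stratified non-missing scores, the reporting rates by
class-wise counting, and the prior as the labeled positive fraction. The
prior is overridable because a curated training set is far more
positive-rich than the genome: for genome-wide prediction the bundled
reference value 0.0133 (from a miR-124 Ago2-IP benchmark of 278 targets vs
19780 non-targets) is the appropriate scale. The same benchmark supplies
the bundled per-tool reporting rates (`reference_rates()`); pinning rates
and prior to one reference miRNA is exactly the "performance is consistent
across miRNAs" assumption made explicit and optional.

Minimum data requirements are enforced per family (10 scores, 20 for the
mixture, non-degenerate variance); a failing tool × class fit aborts
training with an error naming the tool and class, rather than silently
producing a crippled model.

For negative-set construction from over-expression experiments the package
provides the filter predicate: a gene qualifies as a high-confidence
negative if it is **up**-regulated with differential-expression p-value
strictly below 0.001 and linear fold change strictly above 1.5 (both
thresholds configurable; boundary values excluded). Retrieval of the
expression data themselves is out of scope.

## Evaluation

**ROC under partial coverage.** Unscored records are "never called": they
stay in the denominators at every threshold, so a tool's realized curve
stops at its maximum reachable FPR (the fraction of negatives it scores at
all). A straight extrapolation segment to (1,1) — drawn dashed — completes
the curve; it equals the expected concordance of random tie-breaking among
the unscored records, so the trapezoid AUC over the completed curve equals
the Mann–Whitney pairwise-concordance statistic with unscored records tied
at the bottom (verified exactly in the tests). Ties enter and leave the
called set together. Per-tool curves use each tool's native orientation
(`default_directions()`; TargetScan and PITA rank more-negative first); the
fused posterior always ranks descending.

**Cross-validation.** `cv_fuse()` performs seeded, label-stratified k-fold
(default 5) splits — stratification guarantees both classes in every
training fold — trains on k−1 folds, predicts the held-out fold, and pools
the out-of-fold posteriors into one ROC.

**Cumulative down-fold.** For proteomics validation, predictions ranked by
posterior are scored by c(t), the running sum of the top-t proteins' fold
changes, and A(n) = Σ_{t≤n} c(t); more negative means stronger early
repression. Genes without proteomic measurements are skipped without
consuming rank positions (coverage differs between predictors and
proteomics). The cross-miRNA summary F(n) averages A_i(n) over the M miRNA
tests; `average_downfold(..., table6 = TRUE)` divides by 2M instead, an
alternative convention that appears in some published summary tables —
both are exposed because the two conventions differ by an overall factor
of 2 and only relative comparisons between methods are meaningful.

## The synthetic generator

A `mirfuse` model doubles as a generator (`simulate()` /
`generate_score_table()`): y ~ Bernoulli(prior), s_i ~ Bernoulli(tpr or fpr
by class) independently per tool, and present scores are drawn from the
class conditional. This is the model's own data-generating process, which
is precisely what makes it the right test harness: training must recover
the generating parameters, and the fused posterior is Bayes-optimal on such
data, so its cross-validated AUC must dominate every single tool's. The
generator emulates per-tool score distributions, reporting rates, the class
prior, and informative missingness; it does **not** emulate inter-tool
correlation within a class, heteroscedastic batch effects, or per-miRNA
performance differences, so passing these checks demonstrates correctness
of the machinery, not genome-scale accuracy of any particular trained
model.

Default study conditions (chosen once): training and cross-validation
experiments use the class composition of a realistic curated corpus, prior
= 929/24248 ≈ 0.0383 (929 positive pairs against 23319 negatives), which at
n = 20000 reproduces per-tool positive fit sizes (≈140–580) close to those
available in practice; prediction-parity checks use the genome-wide
reference prior 0.0133. The reference model's density parameters are
package defaults shaped after each tool's characteristic histogram
(e.g. TargetScan positives as a reflected Gamma pushed toward stronger
negative scores); they are labeled as defaults, not as estimates from any
external dataset. Experiment sizes (20000 records for recovery, 5000 for
cross-validation, 10000 draws per density-recovery check) keep the full
suite under a minute while leaving comfortable statistical margins.

## Known limitations

* Conditional independence given y ignores feature sharing between tools;
  posteriors rank well but are overconfident as probabilities.
* The reflected-Gamma support ends at the training maximum plus ε; stronger
  unseen scores rely on the density floor rather than an extrapolated tail.
* The NB discretization of continuous scores is a modeling convenience; the
  `scale` parameter exposes it but no automatic choice is attempted.
* No goodness-of-fit or automatic family selection: the family map is the
  user's scientific statement.
* Identifiers are opaque case-sensitive strings; no gene-symbol mapping is
  attempted, and one row per (miRNA, gene) pair is the input contract.
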