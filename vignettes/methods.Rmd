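---
title: "Adaptive severity measurement and diagnostic screening: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive severity measurement and diagnostic screening: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`catcad` implements two complementary adaptive assessment engines for
ordinal symptom inventories — a severity CAT built on bifactor
graded-response IRT, and a diagnostic CAD built on shallow extremely
randomized tree ensembles — together with the calibration, tuning,
validation and simulation machinery needed to study them without access to
any proprietary item bank. This vignette records the models, the tunable
parameters and their defaults, the numerical choices, and what the synthetic
data can and cannot establish.

## The measurement model

Responses are ordinal codes `0 .. K-1`. Item *j* follows the logistic
graded-response model with a bifactor restriction: the cumulative
probability of responding in category *k* or above is

$$P(Y_j \ge k \mid \theta_0, \theta_{g(j)}) =
  \mathrm{logit}^{-1}\!\big(a_{0j}\,\theta_0 + a_{gj}\,\theta_{g(j)} - c_{jk}\big),$$

with strictly ordered thresholds $c_{j1} < \dots < c_{j,K-1}$. Each item
loads on the primary severity dimension and on exactly one group (subdomain)
factor; all factors are mutually independent standard normal. This is a
confirmatory structure: no rotation is involved, and the loadings are
identified up to sign, which we fix by reflecting dimensions whose summed
slopes come out negative.

Two conventions deserve explicit statement because the 0.3 discrimination
filter depends on them:

* **Link.** Pure logistic, no 1.7 scaling constant. Slopes are on the
  logistic metric.
* **Standardization.** Loadings are reported as
  $\lambda = a / \sqrt{1 + a_0^2 + a_g^2}$, the normal-ogive-equivalent
  convention; its inverse is used by the synthetic generator. The historical
  software lineage for polytomous bifactor models reports standardized
  loadings in this way, and whether the original filter was applied to
  bifactor or preliminary unidimensional loadings is not documented — we
  default to the bifactor primary loading; both the conversion and the cut
  are plain functions, so the alternative is one line of user code.

### Estimation

Marginal maximum likelihood via EM. The bifactor structure reduces each
person's likelihood to a product over subdomains of two-dimensional
integrals (primary x one group factor), evaluated by Gauss–Hermite
quadrature — cost grows with the square of the per-dimension node count,
never with the number of subdomains. Defaults: 21 nodes per dimension,
relative log-likelihood change `1e-5` or 500 EM cycles. The M-step is
*generalized*: each item takes a few BFGS steps (analytic gradients,
thresholds kept ordered through a log-difference reparameterization) on its
expected complete-data log-likelihood rather than iterating to an inner
optimum. Because BFGS never returns a worse point than its start, the
monotone-EM contract survives, and the test suite asserts a nondecreasing
trace on every fit it runs.

Edge policies: categories never observed in the data are collapsed into the
adjacent observed category (with a warning naming the items); an item with
fewer than two observed categories is rejected by name; a bank with a single
subdomain pins all group slopes at zero, since one group factor shared by
every item is indistinguishable from the primary dimension.

### Scoring and information

Severity is the EAP (posterior mean) of $\theta_0$ with the group factors
integrated out over their priors — the same marginalization used in
fitting — and "uncertainty" is the posterior SD. With no responses the prior
itself is returned. Item information for adaptive selection is, by default,
the Fisher information of the *prior-averaged* category response curves
(marginal information): the CAT scores only the primary dimension, so the
group factor is nuisance variation and items with large group slopes are
correctly down-weighted. Conditioning on group factors at zero is available
by configuration; for an item with no group slope the two coincide, and for
a binary item both reduce to the classical $a_0^2 P (1-P)$.

## The adaptive test

A session starts at the prior (score 50) with the item most informative
there, then alternates: record response, re-score, check stopping rules,
select the next item. Scores are reported as `50 + 15 * theta` clipped to
[0, 100]; the transform is configurable, and every threshold below is
interpreted on this scale.

Stopping rules in order of precedence, with defaults:

| rule | default | meaning |
|---|---|---|
| `se_stop` | 5 | stop once uncertainty (posterior SD x 15) is at or below 5 points — fixed-precision measurement |
| `remaining_info_stop` | 0.1 | stop when no remaining item offers this much information at the current estimate (the bank is exhausted *locally*) |
| `max_items` | unbounded | hard budget |
| `min_items` | 4 | precision rule not consulted before this many items |

The precision threshold of 5 points comes from the published design; the
remaining-information cutoff and `min_items` have no published values — 0.1
is roughly the information of a weakly related item at a distant trait
value, and 4 matches the bottom of the published 4–17 length range.
Selection is argmax information with ties broken by item id; an optional
`top2_prob` administers the runner-up instead, driven by a session-local
MINSTD stream so sessions are bit-reproducible and never touch the global
RNG.

Posterior SD is *not* guaranteed to fall at every step — a surprising
response can widen the posterior — so trajectory monotonicity is asserted
only on a packaged fixture chosen to exhibit it, not claimed as a theorem.

### Tuning

`tune()` evaluates a configuration grid by simulated CAT (replaying complete
stored response patterns through the adaptive engine) and picks, among
configurations whose full-bank correlation is within 0.005 of the grid
maximum, the one with the fewest mean items. The factory grid crosses
`se_stop` (6 levels) x `remaining_info_stop` (5) x `top2_prob` (5) x
`max_items` (8) = 1200 configurations; the published work states the number
of simulations and the kinds of parameters but not the axes' levels, so the
factory levels are ours.

## The diagnostic screener

`train_cad()` grows extremely randomized trees against a binary criterion:
at each node, `ceiling(sqrt(p))` candidate items are drawn, each receives
one uniform-random cutpoint within the node's observed code range, and the
split with the largest Gini impurity decrease is kept; depth is capped at 3
and nodes smaller than 10 are not split. Two trees are combined by logistic
regression of the label on their leaf probabilities — the published design
says "combined linearly" without defining the combination; logistic
regression is our default (simple averaging by config) and adds the intended
extra degree of freedom over a single deeper tree. Ten alternative forms are
trained from distinct seeds ("a number of possible tests"; no count is
published), and `select_form()` picks one uniformly per patient.

Administration traverses the trees in order, asking each item at most once
per session; a repeated item reuses the earlier answer, so a session needs
at most `trees x depth = 6` distinct items and sometimes fewer. Batch
prediction on a complete stored row and interactive administration agree
exactly, which the tests assert identically (not approximately).

Ordinal codes are treated as numeric for cutpoints: the category codes *are*
the measurement scale.

## Validation statistics

AUC uses the rank (Mann–Whitney) formulation with midrank ties;
cross-validation is stratified by label and seeded, pooling out-of-fold
predictions. For severity scores a logistic calibration of the label on the
score is fitted per training fold; for screener probabilities the CAD is
retrained per fold (`cv_auc_cad`). Confidence intervals are DeLong (the
published work reports 95% CIs without naming a method).

Severity-category thresholds are selected against the criterion by a
constrained search: the none/mild cut is the largest cut keeping sensitivity
at or above 0.95 (high sensitivity, specificity as good as that allows), the
mild/moderate cut maximizes Youden's J, and the moderate/severe cut is the
smallest cut reaching specificity 0.93. These numeric targets
reverse-engineer the published sensitivity/specificity pairs (95%/51%,
79%/78%, 50%/93%) and are configurable; they are not claimed to be the
original authors' rule. Unsatisfiable constraints return the achievable
frontier rather than an error.

## The synthetic world

No item bank or response data are released, so every empirical claim in this
package rests on `gen_bank` / `gen_responses` / `gen_diagnosis`:

* 211 items over subdomains of 5/58/79/18/51; 4- or 5-category items in
  equal proportion; true primary loadings U(0.45, 0.90) (planted poor items:
  U(0, 0.15)); group loadings U(0.2, 0.5), capped so no item's communality
  exceeds 0.95; thresholds ordered around item locations U(-1.2, 1.8) with a
  minimum category gap, scaled by the item's slope magnitude.
* 713 simulees with independent standard-normal traits; diagnoses are
  Bernoulli with logit-linear liability in the primary trait, intercept
  solved so expected prevalence is 0.284 (the published cohort's rate) and
  slope 2.5 by default.

The loading and threshold ranges were frozen after a single calibration
pass: at the default precision stop the simulated CAT administers ~8 items
on average with full-bank correlation 0.97, the regime of the published
instrument (mean 10, r = 0.95). They were not adjusted after seeing any
test outcome.

What a green test establishes: that the algorithms recover a world that
exactly satisfies their assumptions — parameter recovery, filter behavior,
CAT fidelity, screener discrimination are all *internal* validity checks.
What it does not: real response data violate the model (local dependence
beyond one group factor, non-normal traits, careless responding,
differential item functioning), and the published real-data numbers (CAD
AUC 0.91, CAT AUC 0.85, convergent r = 0.88, the exact threshold
sensitivities) depend on the unpublished bank and cohort; none of them are
asserted as targets here.

## Numerical choices

* Gauss–Hermite nodes by Golub–Welsch eigendecomposition; weights sum to 1.
* Log-space accumulation with per-person shifts everywhere a product over
  items appears; probabilities floored at `1e-300` before logging.
* EAP uses 49 primary x 21 group nodes by default; the acceptance-scale
  calibrations reduce to 11 x 11 (explicitly permitted by the acceptance
  budget; recovery at Q = 11 reproduces truth with loading RMSE ~0.04).
* Ties in item selection break by item id, making sessions reproducible
  across platforms.
* CAD model JSON is written at 17 significant digits so probabilities
  round-trip bit-exactly.
* Thresholds are kept strictly ordered through a log-difference
  reparameterization inside the optimizer, never by post-hoc sorting.

## Known limitations

* The EM is a quadrature-discretized MML: with very long banks the absolute
  log-likelihood depends slightly on node count, so likelihood-ratio tests
  should compare fits computed at the same quadrature (enforced by the data
  fingerprint check only across *data*, not across options).
* `run_simulated_cat` treats stored responses as ground truth; skipping
  missing items changes the administered sequence relative to a complete
  row.
* The screener handles only binary criteria; no cost-sensitive splitting,
  boosting, or alternative learners (out of scope by design).
* Subdomain scores are computed nowhere: the engines score the primary
  dimension only.
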