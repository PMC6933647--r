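---
title: "Patient-centered composite endpoint weighting: models and methods"
author: "bwsweight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-centered composite endpoint weighting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bwsweight)
```

This vignette is the package's account of its own science: the models it
fits, the assumptions they lean on, the tunable parameters and their
defaults, what the built-in simulators do and do not emulate, and the
design choices made where the methodology was genuinely open.

## 1. The choice experiment and its design

Object-case (Case 1) Best-Worst Scaling presents a respondent with a small
set of items — here, clinical outcomes after surgical fracture treatment —
and asks for the best and the worst item in the set. Repeating this over
many sets, and many respondents, identifies the relative attractiveness of
every item far more efficiently than ranking or rating scales.

`generate_design()` builds the questionnaire: `n_versions` blocks (default
4) of `tasks_per_version` choice sets (default 10), each showing
`items_per_task` outcomes (default 3) from a ten-outcome catalog. The
default geometry therefore matches a survey in which each respondent
answers 10 triples and four questionnaire versions jointly cover the
catalog. A randomized greedy swap optimizer equalizes how often each item
appears — globally and within each version (the blocked-balance criterion)
— and breaks remaining ties by the D-efficiency `det(X'X)^(1/p) / n` of
the column-centered task-by-item incidence matrix, over `n_restarts`
(default 50) random restarts. `diagnose_design()` reports appearance
counts, pairwise co-occurrence, the frequency-balance score and a relative
D-efficiency normalized against the best design found over fresh restarts.

**The reference level is part of the item pool by default.** Respondents
can be shown "perfect health" alongside two complications. This is not
cosmetic: the best-worst likelihood below is invariant to adding a
constant to the utilities of the items in a set, so the gap between the
reference and the adverse outcomes is identified *only* by sets in which
the reference actually appears. A design over adverse outcomes only
(`include_reference = FALSE`) yields utilities identified up to a common
shift — the fit then warns, and only differences between outcomes are
interpretable.

## 2. The sequential best-worst logit

For a set \(S\) and part-worth vector \(\beta\), the probability of
picking best \(b\) and then worst \(w\) is

\[
P(b, w \mid S) \;=\;
\frac{e^{\beta_b}}{\sum_{j \in S} e^{\beta_j}} \cdot
\frac{e^{-\beta_w}}{\sum_{j \in S \setminus b} e^{-\beta_j}},
\]

the standard "exploded" MaxDiff model: a multinomial logit draw for the
best, then a logit draw with negated utilities for the worst among the
remainder. `bw_task_likelihood()` evaluates this directly; the six legal
(best, worst) pairs of a triple always sum to probability one. The same
likelihood drives the simulator (`simulate_choices()`), the pooled MLE and
the hierarchical model — generation and estimation agree by construction.

## 3. The hierarchical Bayesian multinomial logit

`fit_hb_mnl()` fits the mixed-logit hierarchy

\[
\beta_r \sim N(\mu, \Sigma), \qquad
\text{picks}_r \mid \beta_r \sim \text{sequential BW logit},
\]

with weakly informative priors \(\mu \sim N(0, 100 I)\) and
\(\Sigma \sim \mathrm{InvWishart}(d + 2, I)\). Each sweep draws

1. \(\mu \mid \beta, \Sigma\) from its conjugate normal full conditional;
2. \(\Sigma \mid \beta, \mu\) from its conjugate inverse-Wishart full
   conditional;
3. every \(\beta_r\) by random-walk Metropolis-Hastings with proposal
   \(\beta_r' = \beta_r + \rho L z\), \(L\) the Cholesky factor of the
   current \(\Sigma\); \(\rho\) is multiplied by 1.1 or 0.9 as the rolling
   acceptance sits above or below 30% during burn-in, then frozen at the
   geometric mean of its recent trajectory (the multiplicative rule makes
   \(\log\rho\) a random walk, so freezing at the final value would
   capture an arbitrary excursion);
4. a joint **location move**: one proposed constant added to every
   \(\beta_r\) and to \(\mu\). Only sets containing the reference inform
   the location, so respondent-wise random walks traverse it extremely
   slowly; the joint move restores mixing of that direction at practical
   chain lengths;
5. a joint **scale move**: all \(\beta_r\) contracted or expanded around
   \(\mu\) jointly with \(\Sigma \to g^2 \Sigma\). The hierarchical
   density change cancels against the Jacobian, leaving the likelihood,
   the inverse-Wishart prior, and the \(\Sigma\)-Jacobian; this is a
   parameter-expansion-flavored remedy for the geometrically slow mixing
   of the overall heterogeneity scale.

Respondents are initialized at the pooled MLE plus unit-scale normal
dispersion: starting all respondents at one point collapses the first
\(\Sigma\) draw toward zero, and the hierarchy re-inflates only slowly.
Defaults are 10,000 iterations with 5,000 burn-in; at the package's
desk-test scale, 2,000/1,000 recovers a 396-respondent survey's utilities
with maximum absolute error well under 0.5.

**Anchoring.** With `anchor = "fixed"` (default) the reference's utility
is pinned to zero for the population *and every respondent*: the anchor is
a common fixed point and heterogeneity attaches to the adverse outcomes.
With `anchor = "shifted"` the model is effects-coded and reported
utilities are shifted by a constant so the reference's posterior mean is
zero; the reference then keeps a non-degenerate interval (the presentation
style of elicited utility tables in which "perfect health" carries its own
interval). The shifted coding also grants the anchor its own
between-respondent variance, which best-worst data barely constrain; on
simulations this widens the anchor gap by several tenths of a utility
unit. Use `shifted` for presentation, `fixed` for recovery benchmarks.

**Respondent exclusions.** Respondents lacking a best or worst pick on any
task are dropped entirely, with a warning — mirroring how incomplete
questionnaires are excluded in practice.

**A documented limit of the homogeneity oracle.** With zero simulated
heterogeneity one would like the HB posterior mean to match the pooled
MLE. At the study's scale (396 respondents, 10 near-deterministic triples
each, utilities spanning 0 to −9) the data cannot distinguish
between-respondent variance of about 0.2 from zero; the heavy-tailed
inverse-Wishart prior keeps that mass, and residual heterogeneity inflates
the posterior utilities by roughly 0.3 relative to the MLE. Cold- and
hot-started chains agree, so this is a property of the posterior, not of
the sampler; the gap shrinks with more respondents (about 0.24 at 2,000).
The package's acceptance suite records this as a known red check rather
than papering over it.

## 4. From utilities to component weights

For a composite with components \(j = 1,\dots,k\) and mean utilities
\(u_j\), `compute_weights()` returns

\[
W_a = \frac{\sum_{j \neq a} e^{u_j}}{\sum_j e^{u_j}} = 1 - \mathrm{softmax}_a(u),
\]

a conditional-logit share complement: at \(k = 3\) this is
\((e^{u_b} + e^{u_i}) / (e^{u_a} + e^{u_b} + e^{u_i})\), and the
\(1 - \mathrm{softmax}\) form is its unique natural extension to other
\(k\). Identities: \(\sum_a W_a = k - 1\) exactly; \(u_a < u_b \iff
W_a > W_b\); invariance under \(u \to u + c\); equal utilities give
\((k-1)/k\) each. The denominator runs over the composite's components
only — the reference never enters unless explicitly included. Computation
is log-sum-exp stabilized and unrounded; the canonical three-component
example (−5.69, −5.20, −3.29) gives 0.9268, 0.8804, 0.1928, i.e. 0.93 /
0.88 / 0.19 at two decimals. (Published tables sometimes print 0.20 for
the lightest component; the formula applied to the printed utilities
rounds to 0.19 — the difference is consistent with the published value
having been computed from unrounded utilities.)

`subgroup_adjusted_weights()` substitutes subgroup-specific utilities
(e.g. the above-knee-amputation utility of respondents aged 65+) before
applying the same formula. `weight_sensitivity()` propagates utility
uncertainty by sampling each component's utility independently from a
normal matched to its mean and 95% interval; posterior correlations
between utilities are not published and are therefore not modelled — the
intervals are approximate and documented as such.

## 5. Heterogeneity testing cascade

Respondent-level utilities (posterior means from `respondent_utilities()`,
matching the mean-(SD) presentation of stratified tables) feed a
three-step cascade mirroring common practice:

1. `screen_interactions()`: each covariate is tested for a joint shift of
   the whole utility vector via a multivariate linear model (Pillai/Wilks
   F). The threshold is Bonferroni-adjusted, `alpha / n_covariates`
   (0.05/10 = 0.005 for a ten-covariate screen); screened-in covariates
   are re-tested jointly (type-II tests) at the same threshold. Testing
   posterior means outside the hierarchical model is an approximation of
   in-model interaction testing, chosen for tractability and exact null
   calibration under normality.
2. `stratified_anova()`: classical one-way ANOVA per outcome and
   covariate, with stratum means and SDs.
3. `tukey_kramer()`: studentized-range pairwise comparisons honoring
   unequal group sizes; with two strata this collapses exactly to the
   pooled t-test. `experienced_vs_not()` compares experiencers of an
   outcome with non-experiencers by an equal-variance Student t-test.

## 6. Trial simulation and the analysis battery

`simulate_trial()` draws, per patient and component, an independent
Bernoulli event with arm-specific probability, and an event time uniform
on the follow-up window (365 days by default; a truncated-exponential
option exists). Defaults reproduce a hypothetical 1,000-patient pilon
fracture trial: arm A (n = 498) has fewer deep infections and bone-healing
complications but more superficial infections than arm B (n = 502). There
is no competing-risk structure and components are independent within
patient — adequate for studying how weighting changes verdicts, not for
modeling real event correlation.

`analyze_all()` runs seven analyses; the effect direction is always A
versus B:

- **Fisher's exact test** on "any component event" per patient (the only
  reading of a composite that an exact 2×2 test supports).
- **Time to first event**: Cox model after censoring each patient at
  their earliest event — the analysis whose event-discarding the
  weighting is designed to fix.
- **Weighted recurrent-event Cox model**
  (`weighted_recurrent_tte()`), with each event record carrying its
  component weight in the partial likelihood and cluster-robust variance
  by patient. Two risk-set layouts are provided because the methodology
  is genuinely open here. In the default `"cohort"` layout every patient
  remains at risk for the whole follow-up (weight-1 baseline record) and
  events enter as instantaneous weighted records — the weighted composite
  endpoint convention, under which an arm that trades severe events for
  mild ones shows a hazard ratio well below 1. In the `"exit"` layout
  each event carries its own at-risk record from randomization and
  patients leave with their events; with unit weights and single events
  this reduces *exactly* to the time-to-first-event model, which makes it
  the layout of choice for reduction-identity checks.
- **Global-rank Wilcoxon test** (`global_rank_test()`): each patient's
  severity score is the *sum* of their events' weights (a patient with
  repeat events is worse off than one with a single event; `score =
  "max"` gives the worst-single-event alternative), compared across arms
  by the rank-sum test with midranks. The **Probability Index**
  \(P(S_A < S_B) + \tfrac12 P(S_A = S_B)\) is reported with a
  placement-variance confidence interval; values above 0.5 favor arm A
  (lower burden).
- **Random-effects logistic models** (`random_effects_composite()`),
  unweighted and weighted: patient × component binary outcomes, arm fixed
  effect, patient random intercept (fit with `glmmTMB`). Component
  weights enter as observation weights normalized to mean 1, so constant
  weights reproduce the unweighted fit exactly.

On the default trial profile the unweighted first-event hazard ratio sits
near 1 while the weighted recurrent-event hazard ratio is well below 1
with a confidence interval excluding 1 — weighting reverses the null
verdict because arm A's excess events are precisely the low-weight ones.

## 7. Numerical choices and degenerate inputs

- Log-sum-exp stabilization everywhere a softmax appears.
- The pooled MLE flags separation (a pick pattern whose likelihood is
  unbounded) by the magnitude of the fitted coefficients and names the
  runaway outcome.
- One-way ANOVA refuses zero within-stratum variance (undefined F).
- Weights must cover every component with events; missing labels are
  named in the error.
- All generators and samplers are pure functions of their inputs and a
  seed; the pipeline derives per-stage seeds from one master seed by a
  fixed affine rule, so artifacts are independently reproducible.

## 8. Problem sizes used by the test suite

The suite exercises the full questionnaire geometry (4 × 10 × 3 over ten
outcomes) with 396 simulated respondents and 2,000/1,000 MCMC iterations
for recovery checks; calibration checks use 500 null trials of 100
patients per arm and 1,000 null screens. These sizes were chosen so the
whole suite documents the methods at realistic scale while remaining
comfortable to run on a laptop.

## 9. Known limitations

- Item-position effects, respondent inattention and partial
  questionnaires are not modelled (incomplete respondents are dropped).
- The weight-sensitivity analysis ignores posterior correlations between
  utilities.
- The trial simulator's components are independent within patient; no
  competing risks, no event-time dependence on severity.
- Utilities from a no-reference design are identified only up to a
  common shift; the package warns rather than guessing an anchor.
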