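---
title: "Equating scale scores with a power-series model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equating scale scores with a power-series model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psequate)
```

## The model

Two bounded integer total scores $X_1 \in \{0,\dots,m_1\}$ and
$X_2 \in \{0,\dots,m_2\}$ (say, two sleep questionnaires filled in by the
same respondents) are assumed to depend on one latent person value
$\xi \ge 0$ through power-series distributions

$$P(X_i = x \mid \xi) = \frac{\xi^x \gamma_{ix}}{\sum_h \xi^h \gamma_{ih}},$$

with one non-negative score parameter $\gamma_{ix}$ per attainable score,
and to be conditionally independent given $\xi$. This is the total-score
(super-item) form of a polytomous Rasch model: the sum $R = X_1 + X_2$ is
again a power-series variable with parameters
$\omega_r = \sum_x \gamma_{1x}\gamma_{2,r-x}$, and the split of a given
total,

$$P(X_1 = x \mid R = r) = \frac{\gamma_{1x}\gamma_{2,r-x}}{\omega_r},$$

does not involve $\xi$: the total score is sufficient for the person. All
estimation in this package is built on that conditional distribution, so no
assumption about how persons are sampled or distributed is needed for the
score parameters, and the two scales can be equated through the latent
value they share.

Working on the log scale throughout (`theta = log xi`, log-gammas with a
running maximum subtracted) keeps every probability finite for score ranges
up to the largest in common use (the package is routinely exercised at
ranges 0–108) and for arbitrarily extreme latent values; `xi = 0` and
`xi = Inf` are explicit limit cases returning point masses at the extreme
scores, which makes the equating endpoints total.

## Estimation

`fit_leunbach()` maximises the conditional likelihood
$\prod_{\text{persons}} P(x \mid r)$ by iterative proportional fitting of
the quasi-independence structure the conditional model induces: fitted
expected counts $n_r \cdot P(x \mid r)$ always match the total-score
margins, and multiplicative updates of $\gamma_1$ and $\gamma_2$ match the
row and column margins in alternation (the inner loop is compiled; see
`src/ipf.cpp`). Convergence is declared when no fitted conditional split
probability moves by more than `tol` (default `1e-9`) in a cycle, with a
10,000-cycle cap; both are arguments. The estimate is validated in the test
suite against direct numerical maximisation of the conditional
log-likelihood on small all-positive tables.

The conditional likelihood identifies the gammas only up to a constant per
scale and a shared geometric tilt $\gamma_{ix} \mapsto b_i a^x \gamma_{ix}$.
The reported convention sets the first observed gamma of each scale to 1
and centres the tilt so the mean latent estimate over the observed interior
total scores is zero, which keeps `theta` numerically small; a fit under
`normalization = "none"` changes the gammas but provably not the
conditional distributions, the log-likelihood or any equating output (this
invariance is tested).

Scores never observed on a scale carry no conditional information; their
gammas are fixed at zero and all equating output is restricted to the
observed score range — conversion values for unobserved raw scores are
deliberately not interpolated.

Person values are estimated from a single score by solving
$E(X_i \mid \theta) = x$ with Newton-Raphson on $\theta$ inside a
maintained bisection bracket (`person_mle()`, tolerance `1e-10` on the
expected score). The minimum and maximum attainable scores have no finite
solution and are handled by the endpoint convention below.

## Equating and its error

Direct equating of a source score $x$: estimate $\hat\theta(x)$, evaluate
the target scale's expected score (its test characteristic curve) at
$\hat\theta$, and round to the nearest integer. Rounding halves go away
from zero — a declared dialect; halves do not occur in regular use. The
smallest and largest observed source scores map to the smallest and largest
observed target scores. Monotonicity of every equating table follows from
the strict monotonicity of the characteristic curves and is asserted
property-style in the tests.

Indirect equating (scales B and C observed in different samples, a common
scale A in both) composes two direct steps. Because the expected A score of
a B score is rarely an integer, the expected C score is linearly
interpolated between the neighbouring integer A scores,
$(1-f)\,e_C(k) + f\,e_C(k+1)$ with $k = \lfloor s \rfloor$; the midpoint
case $f = 0.5$ is the textbook walk-through, and fractional weights are the
natural continuous extension. Expected A scores outside A's observed range
in the second sample are clamped with a warning.

The Standard Error of Equating (SEE) is the standard deviation — with the
$S-1$ denominator, around the bootstrap mean — of the equated score over
`n_boot` (default 1000) nonparametric bootstrap replicates of the observed
contingency table: persons are resampled multinomially over the observed
cells, every replicate is refitted and re-equated. For indirect equating
both samples are resampled independently and the full three-step procedure
is replayed. Refits that fail to converge are dropped and counted, with a
warning above 5%. Per-score SEEs are summarised by a weighted mean with the
observed source-score frequencies as weights, so rare scores do not inflate
the summary; a weighted mean strictly below 0.91 score points is reported
as acceptable, following the convention that an error distribution
concentrated on $\{-1, 0, +1\}$ in equal thirds (plus 2.5% two-point
errors) is the worst acceptable case. Bootstrap replicate fits reuse the
parent estimate as a warm start, which changes nothing at convergence and
cuts the refit cost substantially.

Two qualitative behaviours follow from the construction and are verified on
simulated data in the acceptance suite: indirect equating is noisier than
direct equating of the same pair (two fitted links contribute error), and
equating a wide-range scale onto a short one is more precise than the
reverse, because the error is measured in target-score units.

## Tests of fit

Three statistics address the fit of the model to the two-way table; since
such tables are large and sparse, the first two get parametric-bootstrap
p-values (default `S = 1000`; `S = 199` is used in the package's own
simulation studies) with the `+1/(S+1)` counting convention, so a p-value
is never exactly zero.

1. **Conditional likelihood ratio.**
   $G^2 = 2\sum \text{obs}\,\ln(\text{obs}/\text{exp})$ over observed
   cells, with expected counts $n_r P(x \mid r)$. This is a pure test of
   the quasi-independence structure within the total-score diagonals.
2. **Observed vs expected Goodman-Kruskal gamma.** The observed rank
   correlation of the two scores is compared with its expected value under
   the full fitted model. A person distribution is unavoidable here: the
   expected joint table is computed from the fitted gammas combined with a
   discrete latent mixing distribution on a fixed grid, estimated from the
   total-score counts by EM (a nonparametric marginal-likelihood step).
   Mapping each total score to its raw latent estimate instead was tried
   and rejected: raw scores are overdispersed relative to the trait, which
   biased the expected association upward and broke the test's size at
   large n. The bootstrapped statistic is the difference between a
   replicate's observed gamma and its own refitted expected gamma, compared
   two-sidedly around the bootstrap mean.
3. **Person misfit count.** Every person's split of their total score gets
   a two-sided conditional exact test under the fitted split distribution;
   persons below the 5% level are counted. The default tail is the mid-p
   variant (half weight on equally probable splits): on discrete supports
   the plain probability-ordering tail is markedly conservative, and the
   mid-p construction is the one whose empirical flag rate supports a
   calibrated follow-up test. The flagged proportion $\hat p$ is compared
   with the nominal 5% by the chi-square statistic
   $n(\hat p - 0.05)^2 / (0.05 \cdot 0.95)$ with an upper-tail p-value —
   the arithmetic that reproduces the published applications of the method.
   Totals admitting a single split contribute no flags but stay in the
   denominator.

The evidence convention: a p-value at or below 0.01 is strong evidence
against fit on its own; p-values in (0.01, 0.05] are moderate evidence,
conclusive only when more than one test is significant.

The bootstrap reference tables are simulated from the full fitted model
(gammas plus the EM latent mixture; `parametric_bootstrap_tables(type =
"model")`). A purely conditional generator that fixes the observed
total-score counts and resamples only the splits is also provided
(`type = "conditional"`): it is the cleaner conditional-inference object
and is exactly margin-preserving, but tables built that way can never
contradict the fitted association, so they carry no information for the
gamma test; the model-based generator serves all statistics.

### What misfit can and cannot be detected

The gammas are free per score, so they absorb *any* pair of marginal score
distributions; the latent mixture is free, so it absorbs *any* strength of
positive association. Data whose only deviation is a latent trait
correlation below 1 — including fully independent scores, which satisfy the
model exactly with a degenerate trait distribution — therefore stay inside
the model family and are not flagged by any calibrated test. This is a
property of the model, not of the implementation. What the tests do detect,
and the suite demonstrates: associations no shared trait can produce (a
reversed-keyed scale drives the gamma test), and within-diagonal structure
that quasi-independence cannot carry, such as subgroups whose second score
tracks the first along different lines (bimodal splits drive the
likelihood-ratio and person-misfit tests). Substantively: a "fit" verdict
supports using the two scores interchangeably through the crosswalk; it
does not by itself prove the instruments share a single trait.

## The synthetic-data generator

`sim_scenario()` + `simulate_table()` emulate the study design the model
targets: cross-sectional samples of two (optionally three) bounded
self-report scale totals per person, driven by one latent value. Defaults
are chosen to mirror that setting — a mid-sized clinical cohort of 722
persons, scales shaped like 8 items scored 0–3 and 6 items scored 0–4, and
`theta ~ N(0, 1)`. The normal trait distribution is a
generator convention only (it is conventional in Rasch-type simulation);
conditional estimation never uses it, so none of the estimation results
depend on it. Controlled violations: a trait correlation below 1 (each
scale gets its own trait) and a unit factor on the second scale's trait
(different logit units, including reversed keying with a negative factor).
`simulate_from_rasch_items()` generates item-level partial-credit responses
and sums them, which satisfies the model by construction with score
parameters equal to the convolution of the per-item parameters
(`rasch_score_params()`); the equivalence of the two pathways is tested
exactly on enumerable cases.

What the generator does not emulate: missing-data mechanisms, DIF between
samples, floor/ceiling artefacts beyond what the score parameters induce,
and item-level local dependence. Passing tests on synthetic data therefore
certify the algorithms, not the behaviour of any particular instrument
pair.

## Problem sizes and numerical choices

The package's own simulation studies use sizes chosen to make their Monte
Carlo error small relative to what they assert: the type-I study runs 500
null tables of 500 persons on scales 0–10 and 0–12 with `S = 199`
bootstraps each; the SEE-ordering studies use 722 persons (0–6/0–8/0–12
scales for the indirect comparison, 0–24/0–48 for the direction
comparison); the recovery study uses 20,000 persons. Bootstrap refits use a
relaxed convergence tolerance (`1e-7` on conditional split probabilities);
the induced perturbation of the statistics is orders of magnitude below
their sampling noise.

One recovery tolerance deserves a note: requiring every fitted conditional
split distribution to sit within total-variation 0.01 of the truth for all
total scores with at least 200 observations is tighter than the binomial
noise floor at that count (sd of a two-cell split frequency at
$n_r = 200$ is about 0.035), so that check can fail for no fault of the
estimator; the suite asserts the attainable 0.03 bound alongside it.

Degenerate inputs are defined rather than rejected: tables in which every
observed total admits a single split have a constant conditional likelihood
and are flagged non-identifiable; all-tied tables make the gamma statistic
undefined (`NA` with a warning); empty tables error.

## Known limitations

- Equating is restricted to observed scores; no interpolation to scores
  the sample never produced.
- Pairwise complete cases only; no missing-data model.
- Trait-correlation violations of unidimensionality are structurally
  undetectable from a single two-way table (see above).
- The person-misfit exact test's construction (mid-p) is a convention
  validated by its calibration, not a canonical definition.
- No standard errors for the gammas themselves; only the equating error is
  propagated.
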