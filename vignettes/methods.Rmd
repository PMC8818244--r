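---
title: "Estimating diagnostic accuracy with suspect results and verification bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating diagnostic accuracy with suspect results and verification bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dxverify)
```

## The problem

Fine needle aspiration cytology (FNAC) of breast tumors, like many
diagnostic tests, violates two assumptions of the textbook 2x2 accuracy
analysis.

First, the test is not binary. Besides *positive* and *negative* readings it
produces *suspect* results (malignancy can be neither affirmed nor refuted)
and *insufficient* results (too little material to read). These are
different beasts: a suspect reading is informative — suspicion itself
carries a likelihood ratio — whereas an insufficient sample is a technical
failure unrelated to disease, which we treat as missing completely at
random and exclude.

Second, disease verification is neither complete nor uniform. Histology,
the reference standard, is performed only when the "triple test" (clinical
examination, imaging, cytology) raises suspicion; the remaining patients
are followed by imaging for 18 months, and some are lost altogether.
Because the verified subset is selected by the test result, naive
("complete-case") estimates of sensitivity and specificity are biased —
*partial verification bias*. Because follow-up itself misclassifies
disease, pooling it with histology creates *differential verification
bias*.

`dxverify` implements, in one coherent toolkit, the estimators and
corrections appropriate to this structure: conditional (3x2) accuracy
measures and test yields; the Begg–Greenes redistribution and an extension
of it that preserves the suspect category; multiple imputation by chained
equations (MICE) with Rubin pooling; and a Bayesian model that
accommodates an imperfect reference standard. A synthetic cohort generator
with the same structure provides ground truth for validating the
corrections.

The package ships the motivating study's verification table
(`builtin_study_table()`): 1820 breast tumor samples (tumor samples, not
patients, are the unit of analysis throughout; independence between tumors
of the same woman is assumed and the package never deduplicates).

## Conditional measures on the 3x2 table

With counts `a, b` (positive test, diseased / non-diseased), `e, f`
(suspect), `c, d` (negative), the conditional measures are

* positive test yield: Y+ = (a+c)/(a+e+c), the probability a diseased
  subject gets a definitive (positive or negative) result;
* negative test yield: Y- = (b+d)/(b+f+d);
* conditional sensitivity a/(a+c) and specificity d/(b+d), i.e. accuracy
  among definitive results — numerically identical to simply excluding
  suspects (the "conventional" strategy), which the test suite asserts on
  random tables;
* the likelihood ratio of a suspect result, (1-Y+)/(1-Y-).

The two extreme reassignment strategies bracket the conventional one:
"worst case" counts suspects as failures everywhere (negative in the
diseased, positive in the non-diseased), "best case" the reverse. Their
sensitivities/specificities enclose the conventional estimates — a
property the suite checks on random tables.

Intervals: Clopper–Pearson (exact beta-quantile) for every proportion, and
the log-method interval
exp(log(p1/p2) ± z·sqrt((1-p1)/(n1·p1) + (1-p2)/(n2·p2))) for all three
likelihood ratios. The package applies no continuity correction by default
(a zero cell yields an infinite, flagged LR); an optional Haldane +0.5
correction is available but off, since the study data's finite LR+ comes
from a real single false positive, not from a correction.

## Begg–Greenes redistribution, and its 3x2 extension

When histology is the only acceptable reference, every sample verified by
follow-up or lost is *non-verified*. If verification depends only on
observed quantities (test result, imaging class) and not directly on
disease — the missing-at-random condition — then among samples with the
same test result, the verified disease proportion applies to the
non-verified. Begg and Greenes' closed form redistributes the non-verified
totals T0+ and T0- accordingly: a' = a/(a+b)·T0+, and so on. The package
extends the same rule to the suspect row (e' = e/(e+f)·T0±), so
bias-adjusted yields and the suspect likelihood ratio remain available.
Adjusted conditional sensitivity and specificity from the 3x2 extension
coincide exactly with the plain 2x2 correction on the conventional matrix
— asserted in the suite in both rounding modes.

**Rounding.** By default redistributed cells are rounded half-up to
integers before being combined with the verified counts
(`round_cells = TRUE`). Rounding is what reproduces the study's published
corrected counts (38, 0, 109, 523) and its LR+ of 552; the unrounded mode
(LR+ ≈ 527 on the same data) conserves the non-verified totals exactly and
is the methodologically cleaner choice for new analyses. Both modes are
exposed and tested, and every serialized report embeds the flag so the two
are always distinguishable.

On the study data the extension redistributes only 3 non-verified suspect
samples (e' = 2, f' = 1), so the adjusted yields barely move; the
adjusted suspect likelihood ratio computed from those counts is ≈ 2.33.

## MICE correction

`mice_accuracy_correct()` treats the unverified disease statuses (or, in
`mode = "suspect"`, the suspect readings) as missing data and multiply
imputes them. The engine is a small chained-equations implementation of
the package's own:

* binary targets: logistic regression on the covariates and test result,
  with parameter uncertainty by the bootstrap variant — the model is refit
  on a resample of the observed rows before each imputation draw. The
  bootstrap draw was chosen over the asymptotic-normal coefficient draw
  deliberately: verified positives are almost purely diseased, and
  near-separation inflates the asymptotic covariance so badly that drawn
  coefficients materially distort the small imputed probabilities.
* continuous targets: linear fit plus predictive mean matching (5 donors,
  bootstrap-drawn coefficients), so imputed values are always observed
  values.
* design matrices are built over all rows at once, so a factor level
  confined to the rows being imputed cannot break prediction.

Per completed dataset the 2x2 (or 3x2) estimates are recomputed; point
estimates are pooled by Rubin's rules — total variance = mean
within-imputation variance + (1 + 1/M)·between-imputation variance, with a
t interval on Barnard–Rubin degrees of freedom. Proportions are pooled on
the probability scale by default, the simplest reading of the rules; a
logit-scale option exists (`logit_scale = TRUE`) for estimates near the
boundary. Likelihood ratios are not pooled directly: they are derived from
the pooled sensitivity and specificity, and carry no interval of their
own.

Defaults: M = 38 imputations for verification correction (matching the
share of missing disease status in the study data, the convention of
choosing M near the missingness percentage), M = 10 is appropriate for
suspect imputation; 10 cycles per imputation, far more than needed when a
single variable is incomplete (the chain then converges in one cycle), but
harmless.

## Bayesian model for an imperfect reference

For each reference standard, the verified data contribute two binomial
arms: among verified test-positives, the number reference-positive out of
n, and likewise among verified test-negatives. The success probabilities
link the parameters of interest:

P(R+|T+) = sD·PPV + (1-cD)·(1-PPV),  P(R+|T-) = sD·(1-NPV) + (1-cD)·NPV,

with PPV = prev·sT/(prev·sT + (1-prev)(1-cT)) and
1-NPV = prev·(1-sT)/(prev·(1-sT) + (1-prev)·cT); sT, cT are the index
test's sensitivity and specificity, prev the prevalence, and sD, cD the
reference's own accuracy. The test suite checks both formulas against a
brute-force enumeration of the joint distribution of (disease, test,
reference).

Priors: flat Beta(1,1) on sT, cT, prev; histology treated as perfect
(sD = cD = 1); follow-up given Beta(172.55, 30.45) on both sD and cD — a
density centered at 0.85 with spread matching a plausible 0.80–0.90 range.
Two sensitivity configurations are provided: flat reference priors
(`sensitivity2`) and informative index-test priors Beta(525, 55.1) /
Beta(465, 56) (`sensitivity3`).

By default one model is fitted per reference standard (histology-verified
arms only, or follow-up arms only); a joint two-stratum model sharing sT,
cT, prev is available since the two-reference data admit it. Samples lost
to follow-up are excluded (mode E); mode I first imputes their disease
status with the MICE machinery and counts them as follow-up-verified.

**Sampler.** A self-contained adaptive Metropolis sampler on
logit-transformed parameters: per-coordinate random-walk updates with
scales adapted toward 0.44 acceptance during burn-in, then Haario-style
joint proposals whose covariance (scaled by 2.38²/d) is learned from the
second half of burn-in, with a periodic per-coordinate sweep as a mixing
fallback. Four chains from jittered prior-mean starts; split-chain
scale-reduction (threshold 1.01) per parameter; identical seed and
settings reproduce the output exactly. Defaults are 20000 iterations with
2000 burn-in. The joint proposal matters here: with purely per-coordinate
updates the histology model mixes poorly (split-R̂ ≈ 1.02) because its
posterior is a ridge, and a short single chain can easily sit several
Monte-Carlo standard errors from the converged mean.

**Identifiability, and a caveat on the histology model.** The
perfect-reference model has three free parameters informed by two
proportions: it is partially identified, the posterior is ridge-shaped,
and marginal posterior means are prior-dependent by construction. On the
study's histology arms (803/804 and 24/139) well-mixed chains (split-R̂ <
1.01, confirmed at 4x100000 iterations, seed-to-seed spread ~0.002) put
the posterior mean of sT at ≈ 0.835 with a wide 95% interval, visibly
below single-short-chain estimates of the same posterior, which tend to
land higher (≈ 0.84–0.86) because the low-sT ridge tail is explored
slowly. Reported sensitivities for such a model should always be read
together with the convergence diagnostic and the interval, not as a point
value.

## The synthetic cohort generator

`generate_cohort()` draws records along the chain disease → FNAC category
→ covariates → verification route → observed disease status. Defaults are
calibrated once to the study's margins: prevalence 0.6;
P(positive | diseased) = 0.85, P(suspect | diseased) = 0.125;
P(negative | non-diseased) = 0.946; per-category age means 61/57/50 years,
tumor sizes from gamma distributions with the study's means and SDs (sizes
are positive and right-skewed), imaging risk classes concentrated at ACR
4–5 for positive/suspect cytology; histology nearly certain (0.96) for
positive/suspect cytology, 0.5/0.08 for high/low-risk imaging otherwise;
marginal loss to follow-up 21% (negative) and 3% (positive); follow-up
sensitivity = specificity = 0.85; 3% insufficient results independent of
everything (MCAR).

Verification depends only on the FNAC category and the ACR class — never
on true disease — so verification is missing-at-random **by
construction**. That is precisely the assumption Begg–Greenes and MICE
need, and it is what passing recovery tests demonstrate: that the
corrections remove MAR selection bias. They do *not* show robustness to
not-at-random verification, to within-patient correlation (the generator
draws independent tumors), or to covariate-disease dependence beyond the
test category (covariates are drawn given the category), all of which real
data may exhibit. A user can inject an MNAR rule only by editing the
generated data deliberately.

Test problem sizes were chosen to keep the recovery signal comfortably
above Monte-Carlo noise: cohorts of n = 2500 with 20 replicate seeds for
the mean-absolute-error comparisons (naive vs Begg–Greenes vs MICE), and
n = 100000 single cohorts for frequency calibration checks (3-standard-
error bands). Because a single cohort's verified-negative arm contains few
diseased samples, single-replicate error comparisons are noisy; all
bias-reduction claims are therefore asserted on means over replicates.

## Numerical choices and degenerate inputs

* Clopper–Pearson bounds come from beta quantiles and accept fractional
  "counts", so intervals remain computable on unrounded corrected cells.
* A zero false-positive cell makes LR+ infinite: flagged, never an error.
  A suspect-free table makes the suspect likelihood ratio 0/0: flagged
  indeterminate.
* Redistribution into an empty verified row (no verified samples with that
  test result, but a positive non-verified total) is an error naming the
  row — there is no proportion to apply.
* In the sampler, parameter values at 0 or 1 get log-posterior -Inf and
  are simply rejected.
* Rounding of redistributed cells is half-up (`floor(x + 0.5)`), matching
  the published corrected counts.
* Display rounding in reports is three decimals; all arithmetic is double
  precision throughout.

## Command-line interface

The installed script `cli/dxverify` (a thin wrapper over `cli_main()`)
exposes four subcommands — `estimate`, `simulate`, `bayes`, `mice` — with
JSON reports that embed the full resolved configuration (strategy set,
rounding flag, gold policy, priors, seeds, exclusion counts), so every
number in a report can be recomputed from the report alone. Exit codes: 0
success, 2 usage/validation error, 3 data error.

## Worked example

```{r example}
tab <- builtin_study_table()
m3 <- pool_to_3x2(tab)
estimate_conditional_3x2(m3)

# histology-only gold standard, Begg-Greenes corrected
m3h <- pool_to_3x2(tab, gold_policy(include_followup_as_gold = FALSE))
t0 <- unverified_totals(tab)
corr <- begg_greenes_3x2(m3h, t0[["t0_pos"]], t0[["t0_sus"]], t0[["t0_neg"]])
corr
estimate_conditional_3x2(corr$combined)
```

## Known limitations

* Only missing-at-random corrections: no Kosinski–Barnhart EM or other
  not-at-random estimators, and no inverse-probability weighting beyond
  the Begg–Greenes closed form.
* No more than three informative test categories; five-class cytology
  reporting systems are out of scope.
* Likelihood ratios from MICE-pooled estimates carry no confidence
  interval.
* The Bayesian model covers binary index tests; a conditional (3x2)
  Bayesian analysis with priors on the test yields would be a natural
  extension but is not implemented.
* Aggregated-table input cannot drive mode I of the Bayesian analysis or
  any MICE analysis; those need individual-level records.
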