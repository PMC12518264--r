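---
title: "MOHi: model, scoring rules and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MOHi: model, scoring rules and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mohi)
```

## The composite and its ingredients

Oral health has a clinical face (caries experience), a quality-of-life face
(how much oral problems interfere with daily living) and an attitudinal face
(how much a person values oral health in the first place). The
Multidimensional Oral Health indicator (MOHi) combines one validated measure
of each into a single continuous score:

* **OHVS** — Oral Health Value Scale, 12 items on a 1–5 Likert scale
  (total 12–60, higher = values oral health more). Four 3-item subdomains:
  professional dental care (items 4, 8, 11), appearance and health
  (3, 7, 12), flossing (2, 5, 10), retaining natural teeth (1, 6, 9).
* **OHIP-14** — Oral Health Impact Profile short form, 14 frequency items
  coded 0–4 (total 0–56, higher = worse oral-health-related quality of
  life).
* **DMFT** — count of Decayed, Missing and Filled Teeth on a 32-tooth
  chart (0–32).

Each score is normalized to $[0,1]$ by its theoretical bounds — never by
sample minima/maxima, so the scale is population-independent:

$$\mathrm{MOHi} = \underbrace{1 - \frac{\mathrm{OHVS}-12}{48}}_{A}
 + \underbrace{\frac{\mathrm{OHIP\text{-}14}}{56}}_{B}
 + \underbrace{\frac{\mathrm{DMFT}}{32}}_{C} \in [0, 3].$$

The OHVS component is reversed so that all three components point the same
way: higher MOHi means a more degraded oral health condition. The equal
weighting means each instrument contributes exactly one unit of the 0–3
range; no data-driven weighting is attempted. MOHi reaches 0 only for
OHVS 60 / OHIP 0 / DMFT 0 and 3 only for OHVS 12 / OHIP 56 / DMFT 32.

Two clinical classifications hang off the scores, both with inclusive
cutoffs: a **degraded oral health condition** is MOHi $\ge 1.5$ (the
midpoint of the scale) and **high caries experience** is DMFT $\ge 14$.
Components are kept at full double precision throughout; rounding (2
decimals for scores, 1 for percentages) happens only when tables are
serialized.

Item-level missingness is rejected, not imputed: a record with any missing
or out-of-range response is excluded at ingestion and counted in the
inclusion ledger, mirroring how consecutive-sampling clinical studies
filter incomplete questionnaires. Tooth position carries no weight in any
score, so charts are positional and no FDI/universal numbering map is
needed.

## The analysis stack

`analyze_cohort()` reproduces the standard epidemiological workflow around
the score:

* **Descriptives** (`describe()`): mean, sample SD, median, min–max,
  adjusted Fisher–Pearson skewness and bias-corrected excess kurtosis —
  the bias-corrected (type 2) estimators, matching the conventions of the
  major commercial statistics packages. Moments undefined at small n or
  for constant input are returned as `NA` with a note rather than
  silently.
* **Group contrasts**: pooled-variance t tests for binary factors
  (Welch optional), one-way ANOVA for $k \ge 3$ groups. Post-hoc pairwise
  comparisons (Tukey HSD by default, Bonferroni optional, $\alpha = 0.05$)
  are converted to homogeneous-subset letters: each maximal set of
  mutually non-significant groups receives a letter, and a group bridging
  two subsets shows both ("a,b"). Letters are assigned in factor-level
  order, so relabelling groups permutes letters consistently. P-values
  across the comparison table are deliberately unadjusted (each variable
  is a separate question); the report notes this.
* **Risk model** (`stepwise_logistic()`): binary logistic regression of
  the degraded outcome on age (continuous, per-year odds ratio), sex
  (reference male), education (reference higher), smoking status
  (reference never), self-reported periodontitis, employment and marital
  status. "Stepwise" is implemented as backward elimination on
  likelihood-ratio tests — remove the worst term while its LR p ≥ 0.10,
  then allow re-entry of a dropped term at p < 0.05 — because among the
  common stepwise variants the LR-based backward pass is the least
  path-dependent; the thresholds are arguments and every removal is
  logged in the fit's trace. Categorical terms enter and leave whole.
  Reported per term: odds ratios with Wald 95% intervals, plus the
  likelihood-ratio model $\chi^2$, Nagelkerke $R^2$
  ($R^2_{CS}$ rescaled by its attainable maximum) and classification
  accuracy at the conventional 0.5 probability cutoff.
* **Discrimination** (`roc_auc()`): AUC as the Mann–Whitney concordance
  probability (ties half-weighted), with a Hanley–McNeil normal
  confidence interval by default; DeLong (via pROC) is available when a
  variance estimate robust to the score distribution is preferred. The
  full sensitivity/specificity sweep is returned for plotting.
* **Alternative outcome**: the same machinery with high caries
  (DMFT ≥ 14) as outcome, for comparing which predictors a purely
  clinical index retains versus the multidimensional one.
* **Normality inspection**: the package reports moments
  (skewness/kurtosis near 0 indicating adequacy) and leaves formal
  normality testing to the user; no specific test is imposed.

Self-reported periodontitis is consumed as a given binary flag; the
underlying screening questionnaire is out of scope.

## What the synthetic cohort emulates

`simulate_cohort()` exists so every stage above is testable without
patient data. It generates, per participant:

1. **Covariates.** Age from a normal distribution with mean 46.8 and SD
   18.6 years truncated to 18–95 (the clinic population it emulates;
   truncation lifts the realized mean to about 48). Sex is female with
   probability 0.581. Education, employment and marital status carry the
   age structure a dental clinic actually sees: education odds tilt with
   age (elderly toward elementary schooling, the young toward higher
   education) with baseline weights solved by quadrature so the marginals
   stay at roughly equal thirds; employment and marital status follow
   life-stage tables (students young, retirees old, widowhood late).
   Smoking uses the two NHANES items (≥100 lifetime cigarettes 46.8%,
   currently smoking 49.36% of those), yielding never/former/active at
   53.2/23.7/23.1%. Self-reported periodontitis is logit-linear in age
   and smoking with the intercept solved numerically so the marginal
   prevalence is exactly 0.42.
2. **Latent severity.** A single unobserved oral-health severity
   $u = \eta + \varepsilon$, where $\eta$ is the centered linear
   predictor with log-odds effects of published-risk-model magnitude
   (per-year age OR 1.05; periodontitis 1.94; female 1.80;
   middle/elementary education 2.27/2.94; former/active smoking
   1.62/3.12) and $\varepsilon$ is logistic noise. Severity is the shared
   factor that induces the inter-instrument correlations the composite
   assumes.
3. **Items.** Ordinal OHVS and OHIP-14 responses come from equal-interval
   thresholds on a logistic latent whose mean moves linearly with
   severity (down for OHVS, up for OHIP-14). Teeth are independently
   affected with probability increasing in severity; an affected tooth is
   missing with probability increasing in severity *and age* (so tooth
   loss concentrates in the elderly), otherwise decayed or filled.

Determinism is strict: one global seed feeds a fixed-width per-participant
uniform stream, so participant $i$'s record is identical whatever the
cohort size — convenient for debugging single rows of large simulations.

### Why the severity noise SD is 1.719

If the degraded outcome (MOHi ≥ 1.5) is to follow a logistic regression
whose true odds ratios are the configured effects, the total
non-systematic variation at the outcome margin must have the standard
logistic scale ($\pi/\sqrt{3} \approx 1.814$). That variation has two
parts: the severity noise itself, and the item-level measurement noise
that propagates through the MOHi mapping (empirically ≈ 0.58 severity
units). The default severity noise SD is therefore set to
$\sqrt{\pi^2/3 - 0.58^2} \approx 1.719$, making the configured odds
ratios the (near-)exact truth of the generated outcome rather than
attenuated targets. Parameter-recovery simulations in the test suite
confirm the fitted Wald intervals cover the configured values at their
nominal rate.

### Calibration of the item mapping

The item centers, per-severity slopes and tooth-state logits were fixed
once, by simulation at $n = 2\times10^5$, so that the default cohort
reproduces the emulated population's score structure: OHVS mean ≈ 31,
OHIP-14 mean ≈ 12 with its characteristic right skew (a floor effect —
most respondents report little impact), DMFT mean ≈ 12.8 with roughly
half the affected teeth missing, MOHi ≈ 1.22 with SD ≈ 0.41, a degraded
prevalence of ≈ 25%, and a fitted-model AUC of ≈ 0.80 with Nagelkerke
$R^2$ ≈ 0.31. They are configuration values, not magic numbers: every one
can be overridden through `mohi_sim_config()`.

### What the generator does *not* reproduce

* A single latent factor makes the three instruments more strongly
  correlated with each other than in real cohorts, where each has
  substantial unique variance; consequently the simulated per-instrument
  SDs (especially OHIP-14 and DMFT) are somewhat smaller than real ones.
* Severe tooth loss (<10 remaining teeth) occurs in only ≈ 2–3% of
  simulated participants versus ≈ 9% in the emulated clinic population.
  Reproducing the real edentulism tail would need either a
  participant-level tooth frailty (extra noise that attenuates the
  planted odds ratios) or a direct age effect on tooth *count* (which
  would inflate the age odds ratio above its configured value); fidelity
  of the risk-model margin was judged more important for a testing
  generator. The age dependence acts instead on the missing-vs-restored
  split, which leaves the DMFT total — and hence MOHi — untouched.
* Item-level response styles (acquiescence, central tendency) and any
  real covariance beyond the age-linked structure described above.

Passing tests on simulated cohorts therefore demonstrate correctness of
the scoring and inference machinery under a known generative model — not
that any particular real population will show the same group differences.

## Numerical and design notes

* Thresholds (MOHi ≥ 1.5, DMFT ≥ 14) are inclusive; `1.4999` is not
  degraded.
* Stepwise fits detect separation (non-convergence or runaway
  coefficients) and stop with an explicit error instead of reporting
  meaningless Wald intervals; constant candidate predictors are set aside
  before elimination starts.
* `p_enter` may not exceed `p_remove`, which rules out remove/re-enter
  cycling; an iteration cap guards pathological multi-term cycles.
* Homogeneous-subset letters are computed from the exact maximal cliques
  of the pairwise non-significance graph (feasible because comparison
  factors have few levels); with heavily non-monotone group means a group
  can legitimately carry several letters.
* The AUC is computed via midranks, which is exactly the tie-aware
  pairwise concordance count at any sample size.
* Degenerate inputs (constant vectors, single-class outcomes, empty
  groups, an empty cohort after filtering) produce early, named errors or
  flagged `NA`s; nothing is silently dropped except invalid rows at
  ingestion, which are always counted in the ledger.

## Problem sizes used in the shipped checks

The test suite exercises parameter recovery with 200 replicates of
$n = 5000$ cohorts, null-calibration of the stepwise procedure with 500
replicates at $n = 1000$, AUC consistency with 200 replicates at
$n = 1000$, and type-I calibration of the group contrasts with 1000
replicates at $n = 200$ — sizes at which the Monte-Carlo error of the
checked rates is a few percent, chosen to keep the whole suite re-runnable
on a laptop in minutes.

## A worked run

```{r example, eval = FALSE}
cohort <- simulate_cohort(1034, seed = 1)
scored <- score_cohort(cohort)
describe(scored, mohi)

analysis <- analyze_cohort(scored)
tidy(analysis$model)        # odds-ratio table of the reduced model
glance(analysis$model)      # chi-square, Nagelkerke R2, accuracy, AUC
tidy(analysis$comparisons$education) # group means with subset letters
autoplot(analysis$roc)
```

`run_pipeline()` performs the same steps end to end and writes the tables,
the inclusion ledger and a plain-text report that records every setting in
effect (stepwise variant and thresholds, post-hoc method, cutoffs, seed),
so a result bundle is always self-describing.
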