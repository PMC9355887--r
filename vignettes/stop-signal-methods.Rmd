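---
title: "Measuring emotional modulation of response inhibition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring emotional modulation of response inhibition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the task protocol it
generates, the race model behind the simulator, the SSRT estimator, the
statistical battery, and the judgment calls made where the design was
genuinely open. Everything quantitative claimed here is computed by the
test suite or by `scripts/acceptance.R`; nothing is asserted from memory.

## The stop-signal task and the independent race model

In a stop-signal task (SST) the participant performs a speeded choice
(here: left/right arrow, one key per direction) and must cancel the
response outright when a stop signal appears after a stop-signal delay
(SSD). The canonical analysis treats each stop trial as a race between a
go process with finish time $G$ and a stop process that finishes at
$\mathrm{SSD} + \mathrm{SSRT}$, the two racing independently. A response
is emitted iff $G < \mathrm{SSD} + \mathrm{SSRT}$; otherwise the action is
inhibited. The stop-signal reaction time (SSRT) is latent — it is never
observed on any single trial and must be estimated from the joint
behavior of go RTs, SSDs, and stop outcomes.

`simulate_subject()` implements exactly this generative story:

* go finish times are ex-Gaussian, $G \sim \mu + \sigma Z + \tau E$
  (defaults $\mu = 430$, $\sigma = 60$, $\tau = 115$ ms, giving a mean go
  RT near 545 ms with the right-skew universally seen in RT data);
* the stop finish time is $\mathrm{SSD} + \mathrm{SSRT}_c + \eta$, with
  condition-specific true SSRT and trial-level jitter
  $\eta \sim N(0, 20\,\mathrm{ms})$ — some trial-level stop variability is
  needed for a realistic (smooth, increasing) inhibition function;
* go trials omit the response with probability 0.005 and press the wrong
  key with probability 0.015, so simulated go accuracy sits near the
  98.5% regime typical of healthy adults;
* a `p_trigger_failure` hook exists (stop process failing to launch) but
  defaults to 0; the protocol modeled here never invokes it.

## Task protocol and staircase

`session_config()` encodes the session: 4 experimental blocks of 128
trials (96 go, 32 stop; 16 stop trials per stimulus condition per block),
preceded by a 32-trial practice block, two stop-stimulus conditions
(emotional, neutral) in equal proportion, and a per-condition 1-up/1-down
staircase: SSD starts at 150 ms, moves +50 ms after a successful stop and
−50 ms after a failed one, clamped to [50, 650] ms. The two condition
tracks are fully independent — permuting one condition's outcomes never
moves the other's SSDs (this is a tested invariant).

Choices the protocol description leaves open, fixed here once:

* **Trial order** within a block is a uniform seeded shuffle constrained
  to at most 4 consecutive stop trials, to avoid degenerate runs the
  tracking rule would turn into long SSD excursions. No claim is made
  that the original task used this constraint.
* **Arrow direction** is balanced 50/50 within trial type (and within
  stop condition) per block.
* **The staircase runs during practice too** ("adjusted throughout the
  experiment"): practice rows are flagged `phase = "practice"` and
  excluded from every estimate, but they warm the SSD tracks up from the
  150-ms start toward their equilibria before block 1.
* Display durations (800 ms fixation, 70 ms stop signal, 1600 ms ITI,
  100 ms go arrow) are stored as metadata and never used in computation.

A 1-up/1-down rule equilibrates where the response probability is 0.5, so
long-run inhibition converges to ~50% per condition; the test suite
checks 0.5 ± 0.02 over ~1280 stop trials per subject and the acceptance
script reports the 30-subject grand mean.

## Cohort generation

`cohort_spec()` draws three 30-subject groups. Per subject $i$:

* neutral-condition true SSRT $\sim N(240, 38)$ ms (floored at 80 ms),
  matching the scale of published group SSRT means and SDs for this task
  family;
* the emotional-condition SSRT is built from a generative *SSRT index*
  (emotional − neutral):
  $\mathrm{index}_i = -8.3 + 1.192\,(\mathrm{BISnp}_i -
  \overline{\mathrm{BISnp}}) + \varepsilon_i$, with
  $\varepsilon_i \sim N(0, 10)$ ms. The −8.3 ms mean is the emotional
  stopping advantage the design is powered for; the 1.192 ms/point slope
  ties the advantage to BIS-11 non-planning impulsivity so the
  regression stage has a true signal to recover;
* go $\mu_i \sim N(430, 120)$ ms (floored at 200), reproducing
  between-subject go RT spread of ~130 ms;
* questionnaire scores (STAI-Y2, HADS anxiety/depression, three BIS-11
  subscales) are integer-rounded truncated normals with group-specific
  means/SDs on the instruments' ranges; BIS total is the subscale sum.

Seeding is hierarchical: one master seed draws per-subject streams, so a
cohort is reproducible subject-by-subject and unaffected by how many
subjects are simulated after any given one.

What the generator does **not** emulate: fear-conditioning acquisition,
sequential effects (post-stop slowing), go RT drift over blocks, trigger
failures, or item-level questionnaire structure. Passing recovery tests
therefore show the estimator and inference machinery are correct under
the race model's own assumptions — not that real data satisfy them.

## SSRT estimation: the integration method with omission replacement

`estimate_ssrt_integration()` implements the consensus estimator, per
condition over the whole session (blocks pooled, since the staircase runs
continuously):

1. collect all go trials **with a response**, including choice errors and
   premature responses;
2. append one copy of the subject's **maximum** observed go RT per go
   omission (scope: the whole session's maximum);
3. compute $p(\mathrm{respond}\mid\mathrm{signal})$ as the fraction of
   the condition's stop trials with a response — premature responses
   count as failures to stop;
4. take the $\lceil N p \rceil$-th smallest of the augmented go RT list
   (rank clamped to $[1, N]$);
5. subtract the mean SSD over **all** of the condition's stop trials
   (premature trials' SSDs included).

The ceiling rank convention is the conservative reading of "the
$n$-th RT where $n = N \times p$"; `rank_fun` switches to `round` or
`floor` for comparison. The estimator refuses to produce a number when
$p(\mathrm{respond}\mid\mathrm{signal}) \in \{0, 1\}$ (the race is never,
or always, lost — the quantile construction is undefined), raising a
typed error that `summarize_subject()` converts to `NA`.

Two properties worth stating plainly, both measured by the suite:

* On fixed-SSD data from the generator (staircase disabled, no stop
  jitter) the estimator recovers the generative SSRT to within 3 ms at
  10 000 go / 5 000 stop trials — the construction itself is essentially
  unbiased when the SSD is constant.
* Under the moving 50-ms staircase the pooled
  $p(\mathrm{respond}\mid\mathrm{signal})$ and mean SSD interact with the
  curvature of the skewed go RT distribution (the SSD track wanders with
  a standard deviation near 90 ms), and the estimate sits a few
  milliseconds **below** the generative value — the group-level recovery
  check at n = 30 lands around 3–9 ms low depending on the seed. This is
  a property of the consensus method under tracking staircases, shared
  by any faithful implementation; analyses based on condition
  *differences* (the SSRT index) are essentially unaffected because the
  shift is common to both conditions.

`verify_race_assumption()` performs the standard sanity check that mean
unsuccessful-stop RT is strictly below mean go RT (a consequence of the
race model's censoring); in simulated cohorts it holds for ~100% of
subjects.

## The statistical battery

Frequentist tests go through base R's fitting machinery (`aov` with
`Error` strata, `lm`, `t.test`, `chisq.test` without continuity
correction); the package adds the design bookkeeping, partial eta squared
($\eta_p^2 = SS_\mathrm{effect}/(SS_\mathrm{effect}+SS_\mathrm{error})$
within each effect's stratum), Bonferroni post hocs (adjusted
$p = \min(1, m\,p_\mathrm{raw})$), and typed result objects. Sums of
squares are sequential per stratum; for the balanced designs this
workflow produces they coincide with Type II/III, and for unbalanced
groups the within-factor main effect tests the grand-mean contrast of the
condition difference (documented rather than hidden). Every test is
checked against raw sums-of-squares oracles written independently in the
test helpers. Degenerate strata (zero effect and error SS at data scale,
e.g. a correct/incorrect share analysis whose subject means are
identically 0.5) report $F = 0$, $p = 1$ rather than machine-noise
ratios.

Bayes factors use the default-prior family:

* `jzs_bf_ttest()` — zero-centered Cauchy prior (scale 0.707) on the
  standardized effect, computed by adaptive quadrature of the g-mixture
  integral; cross-checked in the tests against the independent
  noncentral-t mixture representation.
* `default_bf_anova()` — default g-prior on standardized effects with an
  inverse-gamma(1/2, r²/2) mixing prior (fixed-effect scale 0.5). Every
  supported design reduces to a one-dimensional integral over g, so the
  package uses deterministic adaptive quadrature rather than Monte Carlo
  and reports the quadrature error estimate. Scope is deliberate: the
  one-way between design used for group comparisons, and the 2-level
  within design, which reduces to the paired JZS BF exactly when scales
  match (a tested identity). This is a documented default-g-prior
  implementation, not a re-implementation of any particular GUI's
  sampler.
* `bf_correlation()` — the exact sampling density of Pearson's r
  (Hotelling's ₂F₁ form) integrated against a stretched beta prior
  (width 1 = uniform on (−1,1)); integration is performed in Fisher-z
  space so near-perfect correlations stay numerically stable, and the
  suite compares against a Riemann-grid oracle built on the Euler
  integral representation of ₂F₁. At $|r| = 1$ the Bayes factor is
  unbounded and the function says so instead of returning a number.

`power_rm_within()` computes repeated-measures power from the noncentral
F distribution, $\lambda = n\,m\,f^2 \cdot m/(1-\rho)$ with
$df_1 = m-1$, $df_2 = (n-1)(m-1)$. The $m/(1-\rho)$ effect-size scaling
is the G*Power within-factors convention; it is what makes $f = 0.4$,
$\alpha = 0.01$, $m = 2$, $\rho = 0.5$ reach power ≥ 0.99 at $n = 30$
(the unscaled $\lambda = n\,m\,f^2/(1-\rho)$, which matches the paired-t
equivalent at $m = 2$ and gives 0.94 for those inputs, is available
behind `convention = "unscaled"` with a warning). The inverse search is
monotone bisection.

`regress_ssrt_index()` fits the SSRT index on STAI-Y2 and the three
BIS-11 subscales by full-entry OLS, then performs a one-shot outlier
pass: observations with $|e_i| > 2\hat\sigma$ (residual over the
*initial* fit's residual SD — standardized without leverage adjustment,
the plainest reading of "residual > 2 sigma") are dropped and the model
refit; both fits and the removed indices are reported. Full entry is the
default because a four-predictor model with outlier pruning is what the
reported degrees of freedom describe; a classic p-enter/p-remove
(.05/.10) stepwise mode exists but is off by default.

## Problem sizes and numerical choices

The suite and acceptance script use sizes chosen to make every stochastic
check statistically decisive at fixed seeds while keeping the default run light:
30-subject recovery runs, 90-subject cohorts, 100-replicate CI-coverage
loops, 1000-replicate type-I calibration of the mixed ANOVA (rejection
rate required within 5% ± 1.5%), and exhaustive 4096-sequence staircase
enumeration. Quadratures run at relative tolerance 1e-9 or tighter; BF
reciprocity (BF₁₀·BF₀₁ = 1) is asserted to 1e-9.

## Known limitations

* The generator's trial-level variance decomposition is calibrated only
  to reproduce group-level summary SDs approximately; it is not fit to
  any subject-level dataset.
* The SSRT point estimator inherits the integration method's small
  downward bias under tracking staircases (see above); absolute SSRT
  levels should be read with that in mind, condition differences are
  safe.
* `default_bf_anova()` covers the two designs this workflow needs, not
  general factorial Bayesian ANOVA.
* The mixed ANOVA assumes one observation per subject × condition cell
  and refuses anything else; it does not model heterogeneous variances
  (with two within levels, sphericity is not at issue).
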