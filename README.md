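# stopsignal

Simulation and measurement machinery for **stop-signal task (SST)**
studies of emotional response inhibition — built for researchers who want
to test, power, or stress their SST analysis pipeline against data with
known ground truth before (or instead of) touching human data.

The package covers the full chain:

1. **Task protocol** — sessions of 128-trial blocks (96 go / 32 stop),
   two stop-stimulus conditions (emotional / neutral) in equal
   proportion, and independent per-condition 1-up/1-down staircases on
   the stop-signal delay (start 150 ms, ±50 ms steps, clamped to
   [50, 650] ms).
2. **Race-model simulator** — cohorts of subjects under the independent
   horse-race model: ex-Gaussian go finish times race a stop process at
   `SSD + SSRT + jitter`; whichever finishes first decides the trial.
   Group structure, a built-in emotional stopping advantage, and
   questionnaire covariates (STAI-Y2, HADS, BIS-11) with a non-planning
   impulsivity moderation of that advantage give the downstream
   statistics a known truth to recover.
3. **SSRT estimation** — the consensus *integration method with
   go-omission replacement*: the go RT distribution (errors and
   premature responses included, omissions replaced by the maximum RT)
   is integrated to the quantile `p(respond|signal)`, and

   ```
   SSRT = Q_go( p(respond|signal) ) − mean SSD
   ```

   with premature stop responses counted as failed stops in both `p`
   and the SSD pool. Per-subject summaries mirror the standard
   descriptive table (inhibition rate, SSD, SSRT, unsuccessful-stop RT,
   go RT, accuracy), plus the race-model sanity check (unsuccessful-stop
   RT < go RT).
4. **Inferential battery** — mixed 2×3 ANOVAs with partial eta squared
   and Bonferroni post hocs, repeated-measures ANOVA, paired t, Pearson
   chi-squared; JZS Bayes factors (Cauchy 0.707), default g-prior ANOVA
   Bayes factors (fixed-effect scale 0.5), stretched-beta correlation
   Bayes factors; repeated-measures power analysis; and the SSRT-index
   (emotional − neutral) regression on trait predictors with a 2-sigma
   residual outlier pass.

## Worked example

The `analysis/` scripts run the whole workflow on a simulated 90-subject
cohort (three 30-subject groups) and write their tables under
`results/`:

```sh
Rscript analysis/01_simulate.R --seed 1
Rscript analysis/02_estimate.R
Rscript analysis/03_analyze.R
Rscript analysis/04_power.R
```

which prints, stage by stage:

```
simulate | seed 1 | 90 subjects, 46080 experimental trials (11520 stop) | 1.0s
estimate | 90 subjects | race assumption met 90/90 | mean inhibition 50.4% | mean SSRT (emotional/neutral) 220.0/227.1 ms | 0.4s
analyze | SSRT stimulus effect F(1,87) = 6.074, p = 0.01569, eta_p^2 = 0.065 | group BF01 = 8.06 | regression: 4 outliers removed, non-planning b = 0.774 | 0.1s
power | f = 0.4, alpha = 0.01, m = 2, rho = 0.5, n = 30 -> power 0.9994 | smallest n for 0.99: 23
```

Reading those numbers: the staircase held stop performance at ~50%
(its design target) for every subject; the race-model assumption check
passed for all 90; the emotional condition shortened SSRT (here by ~7 ms
at the group level, a significant Stimulus main effect with
η²ₚ = 0.065) while the three groups were indistinguishable (Bayes factor
8.1 **for** group equivalence); and the regression recovered a positive
BIS non-planning coefficient for this seed (generative slope 1.192,
single-cohort estimates are noisy by design — the acceptance script
averages replicates). The same objects are available interactively:

```r
library(stopsignal)
coh <- simulate_cohort(cohort_spec(rng_seed = 1))
sm  <- summarize_cohort(coh$trials)
run_full_analysis(sm)$ssrt_anova
jzs_bf_ttest(2.41, n = 30)           # BF10 = 2.2840
chi2_independence(rbind(F = c(19, 16, 20), M = c(11, 14, 10)))  # chi2(2) = 1.2156
power_rm_within(f = 0.4, n = 30, m = 2, rho = 0.5, alpha = 0.01)
```

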