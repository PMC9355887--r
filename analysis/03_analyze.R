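#!/usr/bin/env Rscript

# Stage 3: inferential battery on the subject summaries.
# Mixed 2x3 ANOVAs (inhibition rate, go accuracy, SSD, SSRT with
# Bonferroni post hocs), one-way go-RT ANOVA, per-group paired t-tests
# with JZS Bayes factors, a between-group g-prior Bayes factor, and the
# SSRT-index regression on STAI-Y2 + BIS subscales with the 2-sigma
# outlier pass.
#
# Usage: Rscript analysis/03_analyze.R

library(stopsignal)

t0 <- proc.time()[["elapsed"]]
sm <- read.csv("results/subject_summaries.csv", stringsAsFactors = FALSE)
params <- read.csv("results/generative_params.csv",
                   stringsAsFactors = FALSE)
covs <- params[, c("subject", "STAI_Y2", "BIS_motor", "BIS_attentional",
                   "BIS_nonplanning")]

res <- run_full_analysis(sm, covs)
write_report(res, "results/report.txt")

# flat CSV of every ANOVA effect for downstream use
eff <- do.call(rbind, lapply(
  c("inhibition_anova", "accuracy_anova", "go_rt_anova", "ssd_anova",
    "ssrt_anova"),
  function(k) cbind(analysis = k, res[[k]]$effects)))
write.csv(eff, "results/anova_effects.csv", row.names = FALSE)

ssrt_eff <- res$ssrt_anova$effects
message(sprintf(
  "analyze | SSRT stimulus effect F(%g,%g) = %.3f, p = %.4g, eta_p^2 = %.3f | group BF01 = %.2f | regression: %d outliers removed, non-planning b = %.3f | %.1fs",
  ssrt_eff$df1[1], ssrt_eff$df2[1], ssrt_eff$F[1], ssrt_eff$p[1],
  ssrt_eff$pes[1], res$ssrt_group_bf$bf01,
  length(res$index_regression$removed),
  res$index_regression$final$coefficients["BIS_nonplanning", "b"],
  proc.time()[["elapsed"]] - t0))
message("wrote results/report.txt and results/anova_effects.csv")
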