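#!/usr/bin/env Rscript

# Stage 1: simulate the study cohort.
# Three 30-subject groups play the full stop-signal session (practice +
# 4 blocks of 96 go / 32 stop trials) under the independent race model
# with per-stimulus 1-up/1-down staircases. Writes the trial log and the
# generative-truth table that later stages treat as unknown.
#
# Usage: Rscript analysis/01_simulate.R [--seed <int>]

library(stopsignal)

args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if ("--seed" %in% args)
  args[match("--seed", args) + 1] else "1")
dir.create("results", showWarnings = FALSE)

t0 <- proc.time()[["elapsed"]]
coh <- simulate_cohort(cohort_spec(rng_seed = seed))
write_trial_log(coh$trials, "results/trial_log.csv")
write.csv(coh$params, "results/generative_params.csv", row.names = FALSE)

n_sub <- length(unique(coh$trials$subject))
n_exp <- sum(coh$trials$phase == "experimental")
message(sprintf(
  "simulate | seed %d | %d subjects, %d experimental trials (%d stop) | %.1fs",
  seed, n_sub, n_exp,
  sum(coh$trials$phase == "experimental" & coh$trials$trial_type == "stop"),
  proc.time()[["elapsed"]] - t0))
message("wrote results/trial_log.csv and results/generative_params.csv")
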