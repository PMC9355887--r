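# Trial-log CSV schema: comma-separated, UTF-8, header mandatory, missing
# values as empty fields, durations in milliseconds.

trial_log_columns <- c("subject", "group", "block", "trial", "phase",
                       "trial_type", "condition", "arrow", "ssd",
                       "response", "rt", "premature", "correct")

stop_schema <- function(...) {
  stop(errorCondition(paste0(...), class = c("sst_schema_error", "error")))
}

#' Write a trial log to CSV
#'
#' @param trials Trial records ([simulate_subject()]/[simulate_cohort()]
#'   layout).
#' @param path Output file.
#' @export
write_trial_log <- function(trials, path) {
  write.csv(trials[, trial_log_columns], path, row.names = FALSE,
            na = "")
  invisible(path)
}

#' Read and validate a trial log
#'
#' Reads a trial-log CSV and enforces the record invariants: go trials
#' carry no SSD, inhibited stop trials carry no response/RT, premature
#' responses fall before stop-signal onset. Violations raise a schema
#' error naming the offending row.
#'
#' @param path CSV file written by [write_trial_log()] (or matching its
#'   schema).
#' @return A validated trial-record data.frame.
#' @export
read_trial_log <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  missing_cols <- setdiff(trial_log_columns, names(d))
  if (length(missing_cols))
    stop_schema("missing column(s): ", paste(missing_cols, collapse = ", "))
  d$response[is.na(d$response)] <- "none"
  d$premature <- as.logical(d$premature)
  d$correct <- as.logical(d$correct)
  validate_trial_records(d)
  d
}

validate_trial_records <- function(d) {
  bad_row <- function(mask, msg) {
    if (any(mask, na.rm = TRUE))
      stop_schema(msg, " (first offending row: ",
                  which(mask)[1], ")")
  }
  bad_row(!d$trial_type %in% c("go", "stop"),
          "trial_type must be 'go' or 'stop'")
  go <- d$trial_type == "go"
  bad_row(go & !is.na(d$ssd), "go trials must not carry an SSD")
  bad_row(!go & is.na(d$ssd), "stop trials must carry an SSD")
  bad_row(go & d$condition != "none",
          "go trials must have condition 'none'")
  inhibited <- !go & d$response == "none"
  bad_row(inhibited & !is.na(d$rt),
          "inhibited stop trials must not carry an RT")
  bad_row(d$response != "none" & is.na(d$rt),
          "responded trials must carry an RT")
  bad_row(d$premature & (go | d$response == "none"),
          "premature flag is only valid on responded stop trials")
  prem <- !go & d$response != "none" & d$premature
  bad_row(prem & !(d$rt < d$ssd),
          "premature responses must have rt < ssd")
  chk <- !go & d$response != "none" & !d$premature
  bad_row(chk & d$rt < d$ssd,
          "non-premature stop responses must have rt >= ssd")
  invisible(d)
}

#' Run the full inferential battery on a summarized cohort
#'
#' Reproduces the analysis sequence of an emotional stop-signal study on a
#' per-subject summary table: race-model check tally, mixed 2 x k ANOVAs on
#' inhibition rate, go accuracy (correct vs incorrect), mean SSD and SSRT
#' (the SSRT ANOVA with Bonferroni post hocs), per-group paired t-tests on
#' SSRT with JZS Bayes factors, a one-way ANOVA on go RT, a between-group
#' g-prior Bayes factor on SSRT, and the SSRT-index regression on trait
#' covariates.
#'
#' @param summaries [summarize_cohort()] output.
#' @param covariates Optional data.frame with `subject` plus predictor
#'   columns `STAI_Y2`, `BIS_motor`, `BIS_attentional`, `BIS_nonplanning`
#'   for the regression step (skipped when absent).
#' @param emotional,neutral Condition labels.
#' @return A named list of stat/bayes/regression results (class
#'   `"sst_analysis"`), in reporting order.
#' @export
run_full_analysis <- function(summaries, covariates = NULL,
                              emotional = "emotional",
                              neutral = "neutral") {
  # subjects whose SSRT is undefined in either condition (stop performance
  # at 0% or 100%) cannot enter the condition-wise analyses; exclude them
  # up front and record the exclusion, as a performance-screening step
  defined <- !is.na(summaries[[paste0("ssrt_", emotional)]]) &
    !is.na(summaries[[paste0("ssrt_", neutral)]])
  excluded <- summaries$subject[!defined]
  summaries <- summaries[defined, , drop = FALSE]
  if (nrow(summaries) < 2L)
    stop("fewer than two subjects with defined SSRT in both conditions")
  long <- function(col) {
    do.call(rbind, lapply(c(emotional, neutral), function(cc)
      data.frame(subject = summaries$subject, group = summaries$group,
                 stimulus = cc,
                 value = summaries[[paste0(col, "_", cc)]],
                 stringsAsFactors = FALSE)))
  }
  res <- list()
  res$excluded_subjects <- excluded
  res$race_check <- list(
    n = nrow(summaries),
    n_met = sum(summaries$race_assumption_met, na.rm = TRUE),
    prop_met = mean(summaries$race_assumption_met, na.rm = TRUE))
  res$inhibition_anova <- mixed_anova_2x3(long("inhibition_rate"))
  acc <- rbind(data.frame(subject = summaries$subject,
                          group = summaries$group, stimulus = "correct",
                          value = summaries$correct_go),
               data.frame(subject = summaries$subject,
                          group = summaries$group, stimulus = "incorrect",
                          value = 1 - summaries$correct_go))
  res$accuracy_anova <- mixed_anova_2x3(acc)
  res$go_rt_anova <- one_way_anova(summaries$go_rt, summaries$group)
  res$ssd_anova <- mixed_anova_2x3(long("mean_ssd"), posthoc = TRUE)
  res$ssrt_anova <- mixed_anova_2x3(long("ssrt"), posthoc = TRUE)
  res$ssrt_group_bf <- default_bf_anova(
    rowMeans(cbind(summaries[[paste0("ssrt_", emotional)]],
                   summaries[[paste0("ssrt_", neutral)]])),
    summaries$group, design = "between")
  res$ssrt_paired <- lapply(split(summaries, summaries$group), function(s) {
    tt <- paired_t(s[[paste0("ssrt_", emotional)]],
                   s[[paste0("ssrt_", neutral)]])
    list(t = tt, bf = jzs_bf_ttest(tt$t, tt$n))
  })
  if (!is.null(covariates)) {
    idx <- ssrt_index(summaries, emotional, neutral)
    cv <- covariates[match(summaries$subject, covariates$subject), ,
                     drop = FALSE]
    preds <- cv[, c("STAI_Y2", "BIS_motor", "BIS_attentional",
                    "BIS_nonplanning"), drop = FALSE]
    res$index_regression <- regress_ssrt_index(idx, preds)
  }
  structure(res, class = "sst_analysis")
}

fmt_anova <- function(x, con) {
  eff <- x$effects
  for (i in seq_len(nrow(eff)))
    writeLines(sprintf("  %s: F(%g,%g) = %.3f, p = %.4g, eta_p^2 = %.3f",
                       eff$effect[i], eff$df1[i], eff$df2[i], eff$F[i],
                       eff$p[i], eff$pes[i]), con)
  if (!is.null(x$posthoc))
    for (i in seq_len(nrow(x$posthoc)))
      writeLines(sprintf("  post hoc %s: diff = %.3f, p_bonf = %.4g",
                         x$posthoc$comparison[i], x$posthoc$estimate[i],
                         x$posthoc$p_bonferroni[i]), con)
}

#' Write a plain-text analysis report
#'
#' Deterministic, ordered rendering of a [run_full_analysis()] bundle;
#' writing the same bundle twice yields byte-identical files.
#'
#' @param results An `"sst_analysis"` bundle (may be partial or empty).
#' @param path Output text file.
#' @export
write_report <- function(results, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("Stop-signal task analysis report", con)
  writeLines("================================", con)
  sections <- c(
    race_check = "Race-model assumption check",
    inhibition_anova = "Inhibition rate (mixed ANOVA)",
    accuracy_anova = "Go accuracy (mixed ANOVA)",
    go_rt_anova = "Go RT (one-way ANOVA)",
    ssd_anova = "SSD (mixed ANOVA)",
    ssrt_anova = "SSRT (mixed ANOVA)",
    ssrt_group_bf = "SSRT group Bayes factor",
    ssrt_paired = "SSRT paired contrasts per group",
    index_regression = "SSRT-index regression")
  for (key in names(sections)) {
    if (is.null(results[[key]])) next
    writeLines(c("", sections[[key]]), con)
    x <- results[[key]]
    if (key == "race_check") {
      writeLines(sprintf(
        "  unsuccessful-stop RT < go RT in %d/%d subjects (%.1f%%)",
        x$n_met, x$n, 100 * x$prop_met), con)
    } else if (inherits(x, "stat_result")) {
      fmt_anova(x, con)
    } else if (inherits(x, "bayes_result")) {
      writeLines(sprintf("  BF10 = %.4g, BF01 = %.4g [%s]",
                         x$bf10, x$bf01, x$prior), con)
    } else if (key == "ssrt_paired") {
      for (g in names(x))
        writeLines(sprintf(
          "  %s: t(%g) = %.3f, p = %.4g, BF10 = %.4g",
          g, x[[g]]$t$df, x[[g]]$t$t, x[[g]]$t$p, x[[g]]$bf$bf10), con)
    } else if (inherits(x, "ssrt_regression")) {
      writeLines(sprintf(
        "  initial: R^2 = %.3f, F(%g,%g) = %.3f, p = %.4g",
        x$initial$r_squared, x$initial$df1, x$initial$df2, x$initial$F,
        x$initial$p), con)
      writeLines(sprintf("  outliers removed (>%g sigma): %d",
                         x$sd_threshold, length(x$removed)), con)
      writeLines(sprintf(
        "  final: R^2 = %.3f, F(%g,%g) = %.3f, p = %.4g",
        x$final$r_squared, x$final$df1, x$final$df2, x$final$F,
        x$final$p), con)
      ct <- x$final$coefficients
      for (i in seq_len(nrow(ct)))
        writeLines(sprintf("    %s: b = %.4f, t = %.3f, p = %.4g",
                           rownames(ct)[i], ct$b[i], ct$t[i], ct$p[i]),
                   con)
    }
  }
  invisible(path)
}
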