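#' Integration-method SSRT with go-omission replacement
#'
#' Consensus integration estimator of the stop-signal reaction time for one
#' stop-stimulus condition. The go RT distribution is built from ALL go
#' trials with a response (choice errors and premature responses included);
#' each go omission is appended as a copy of the subject's maximum observed
#' go RT. `p(respond|signal)` is the fraction of the condition's stop trials
#' with a response (premature responses count as failures to stop). The nth
#' RT is the `ceiling(N * p)`-th smallest of the omission-augmented go RT
#' list (rank clamped to `[1, N]`), and
#' `SSRT = nth RT - mean SSD` over all of the condition's stop trials
#' (premature trials' SSDs included).
#'
#' @param records Trial records for one subject ([simulate_subject()]
#'   columns); practice-phase rows are dropped if a `phase` column is
#'   present.
#' @param condition Stop-stimulus condition label to estimate.
#' @param rank_fun Rank convention applied to `N * p(respond|signal)`;
#'   `ceiling` (default) is the conservative consensus choice, `round` and
#'   `floor` are accepted alternatives.
#' @return An object of class `"ssrt_estimate"`: list with `ssrt`, `nth_rt`,
#'   `rank`, `n_go` (augmented count), `n_go_omissions`, `n_stop`,
#'   `p_respond_signal`, `mean_ssd`, `condition`.
#' @examples
#' trials <- simulate_subject(subject_params(), seed = 1)
#' estimate_ssrt_integration(trials, "neutral")$ssrt
#' @export
estimate_ssrt_integration <- function(records, condition,
                                      rank_fun = ceiling) {
  records <- drop_practice(records)
  go <- records[records$trial_type == "go", , drop = FALSE]
  st <- records[records$trial_type == "stop" &
                  records$condition == condition, , drop = FALSE]
  if (!nrow(st))
    stop("no stop trials for condition '", condition, "'")
  go_rts <- go$rt[go$response != "none"]
  if (!length(go_rts))
    stop("no go trials with a response; SSRT undefined")
  n_omit <- sum(go$response == "none")
  aug <- c(go_rts, rep(max(go_rts), n_omit))

  responded <- st$response != "none"
  p_respond <- mean(responded)
  if (p_respond <= 0 || p_respond >= 1)
    stop(errorCondition(
      paste0("p(respond|signal) = ", p_respond, " for condition '",
             condition, "'; the integration method is undefined"),
      class = c("ssrt_undefined_error", "error")))
  n_aug <- length(aug)
  rank <- min(n_aug, max(1L, as.integer(rank_fun(n_aug * p_respond))))
  nth_rt <- sort(aug)[rank]
  mean_ssd <- mean(st$ssd)
  structure(list(ssrt = nth_rt - mean_ssd, nth_rt = nth_rt, rank = rank,
                 n_go = n_aug, n_go_omissions = n_omit, n_stop = nrow(st),
                 p_respond_signal = p_respond, mean_ssd = mean_ssd,
                 condition = condition),
            class = "ssrt_estimate")
}

drop_practice <- function(records) {
  if ("phase" %in% names(records))
    records <- records[records$phase != "practice", , drop = FALSE]
  records
}

#' Race-model assumption check
#'
#' The independent race model implies that responses surviving the stop
#' process are fast ones, so the mean RT of unsuccessful stop trials
#' (premature responses included) must be shorter than the mean go RT.
#'
#' @param records Trial records for one subject.
#' @return List of class `"race_check"`: `subject`, `mean_unsuccessful_rt`,
#'   `mean_go_rt`, `n_unsuccessful`, `assumption_met` (strict inequality;
#'   `NA` when there are no unsuccessful stop trials).
#' @export
verify_race_assumption <- function(records) {
  records <- drop_practice(records)
  go_rts <- records$rt[records$trial_type == "go" &
                         records$response != "none"]
  if (!length(go_rts)) stop("no go trials with a response")
  us_rts <- records$rt[records$trial_type == "stop" &
                         records$response != "none"]
  m_us <- if (length(us_rts)) mean(us_rts) else NA_real_
  structure(list(subject = records$subject[1],
                 mean_unsuccessful_rt = m_us,
                 mean_go_rt = mean(go_rts),
                 n_unsuccessful = length(us_rts),
                 assumption_met = if (length(us_rts)) m_us < mean(go_rts)
                                  else NA),
            class = "race_check")
}

#' Per-subject SST performance summary
#'
#' Computes the descriptive performance row for one subject: per condition
#' the inhibition rate, mean SSD, `p(respond|signal)`, integration-method
#' SSRT (NA when undefined, i.e. `p(respond|signal)` is 0 or 1) and mean
#' unsuccessful-stop RT; overall the mean go RT, the proportion of correct
#' go responses among go trials with a response, and the go-omission count.
#'
#' @param records Trial records for one subject.
#' @param conditions Stop-stimulus labels; defaults to those present.
#' @return A one-row data.frame with columns `subject`, `group`,
#'   `inhibition_rate_<cond>`, `mean_ssd_<cond>`, `p_respond_<cond>`,
#'   `ssrt_<cond>`, `unsuccessful_rt_<cond>` for each condition, plus
#'   `go_rt`, `correct_go`, `go_omissions`, `race_assumption_met`.
#' @export
summarize_subject <- function(records, conditions = NULL) {
  records <- drop_practice(records)
  if (is.null(conditions))
    conditions <- sort(unique(records$condition[records$trial_type == "stop"]))
  go <- records[records$trial_type == "go", , drop = FALSE]
  go_resp <- go[go$response != "none", , drop = FALSE]
  out <- data.frame(subject = records$subject[1], group = records$group[1],
                    stringsAsFactors = FALSE)
  for (cc in conditions) {
    st <- records[records$trial_type == "stop" & records$condition == cc, ,
                  drop = FALSE]
    inhibited <- st$response == "none"
    est <- tryCatch(estimate_ssrt_integration(records, cc),
                    error = function(e) NULL)
    us <- st$rt[!inhibited]
    out[[paste0("inhibition_rate_", cc)]] <- mean(inhibited)
    out[[paste0("mean_ssd_", cc)]] <- mean(st$ssd)
    out[[paste0("p_respond_", cc)]] <- mean(!inhibited)
    out[[paste0("ssrt_", cc)]] <- if (is.null(est)) NA_real_ else est$ssrt
    out[[paste0("unsuccessful_rt_", cc)]] <-
      if (length(us)) mean(us) else NA_real_
  }
  out$go_rt <- mean(go_resp$rt)
  out$correct_go <- mean(go_resp$correct)
  out$go_omissions <- sum(go$response == "none")
  out$race_assumption_met <- verify_race_assumption(records)$assumption_met
  out
}

#' Summarize every subject in a trial log
#'
#' @param trials A multi-subject trial log (e.g. `simulate_cohort()$trials`).
#' @param conditions Stop-stimulus labels; defaults to those present.
#' @return A data.frame with one [summarize_subject()] row per subject.
#' @export
summarize_cohort <- function(trials, conditions = NULL) {
  out <- do.call(rbind, lapply(split(trials, trials$subject),
                               summarize_subject, conditions = conditions))
  rownames(out) <- NULL
  out[order(out$subject), , drop = FALSE]
}

#' SSRT index: emotional minus neutral
#'
#' The per-subject inhibition-for-negative-stimuli index: SSRT in the
#' emotional stop condition minus SSRT in the neutral one. Negative values
#' mean faster stopping for emotional stimuli.
#'
#' @param summary A [summarize_subject()] row (or data.frame of rows).
#' @param emotional,neutral Condition labels used in the summary columns.
#' @return Numeric vector of indices (ms).
#' @export
ssrt_index <- function(summary, emotional = "emotional",
                       neutral = "neutral") {
  e <- summary[[paste0("ssrt_", emotional)]]
  n <- summary[[paste0("ssrt_", neutral)]]
  if (is.null(e) || is.null(n))
    stop("summary lacks ssrt columns for '", emotional, "'/'", neutral, "'")
  if (anyNA(e) || anyNA(n))
    stop("SSRT undefined for at least one condition; index unavailable")
  e - n
}
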