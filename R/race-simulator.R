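#' Generative race-model parameters for one subject
#'
#' The independent horse-race model: on every trial a go process and (on
#' stop trials) a stop process race; the faster finisher determines the
#' outcome. Go finish times are ex-Gaussian (Gaussian mean `go_mu`, sd
#' `go_sigma`, exponential tail `go_tau`); the stop process finishes at
#' `SSD + ssrt_true[condition] + Normal(0, ssrt_noise_sd)`.
#'
#' @param go_mu,go_sigma,go_tau Ex-Gaussian go finish-time parameters (ms).
#'   Defaults give a mean go RT of about 545 ms.
#' @param ssrt_true Named numeric: true stop-process latency (ms) per stop
#'   condition; must cover every condition in the session config.
#' @param ssrt_noise_sd Trial-level Gaussian jitter of the stop latency (ms).
#' @param p_go_omission Probability of omitting the response on a go trial.
#' @param p_choice_error Probability of pressing the wrong key when
#'   responding.
#' @param p_trigger_failure Probability that the stop process fails to start
#'   on a stop trial (default 0; the response is then governed by the go
#'   process alone).
#' @param covariates Named numeric vector of questionnaire scores (may be
#'   empty).
#' @param group Group label.
#' @param id Subject identifier.
#' @return An object of class `"subject_params"`.
#' @export
subject_params <- function(go_mu = 430, go_sigma = 60, go_tau = 115,
                           ssrt_true = c(emotional = 231.7, neutral = 240),
                           ssrt_noise_sd = 20,
                           p_go_omission = 0.005,
                           p_choice_error = 0.015,
                           p_trigger_failure = 0,
                           covariates = numeric(),
                           group = "SARS-CoV-2",
                           id = "s01") {
  stopifnot(go_mu > 0, go_sigma > 0, go_tau > 0, all(ssrt_true > 0),
            ssrt_noise_sd >= 0,
            p_go_omission >= 0, p_go_omission <= 1,
            p_choice_error >= 0, p_choice_error <= 1,
            p_trigger_failure >= 0, p_trigger_failure <= 1)
  structure(list(go_mu = go_mu, go_sigma = go_sigma, go_tau = go_tau,
                 ssrt_true = ssrt_true, ssrt_noise_sd = ssrt_noise_sd,
                 p_go_omission = p_go_omission,
                 p_choice_error = p_choice_error,
                 p_trigger_failure = p_trigger_failure,
                 covariates = covariates, group = group, id = id),
            class = "subject_params")
}

rexgauss <- function(n, mu, sigma, tau) {
  rnorm(n, mu, sigma) + rexp(n, rate = 1 / tau)
}

other_key <- c(left = "right", right = "left")

#' Simulate one subject playing a full session
#'
#' Runs the staircase task protocol under the independent race model. Go
#' trials: a response is emitted with probability `1 - p_go_omission`, the
#' wrong key with probability `p_choice_error`, RT drawn ex-Gaussian. Stop
#' trials: SSD comes from the condition's staircase track; a response is
#' emitted iff the go finish time beats the stop finish time, in which case
#' the go RT is recorded and the trial counts as an unsuccessful stop
#' (premature if the response fell before stop-signal onset).
#'
#' @param params A [subject_params()] object.
#' @param config An [session_config()] object.
#' @param seed Integer seed for this subject's stream.
#' @return A data.frame of trial records with columns `subject`, `group`,
#'   `block`, `trial`, `phase`, `trial_type`, `condition`, `arrow`, `ssd`
#'   (NA on go trials), `response` (`"left"`/`"right"`/`"none"`), `rt` (ms
#'   from go-stimulus onset, NA when no response), `premature`, `correct`.
#' @export
simulate_subject <- function(params, config = session_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cond_missing <- setdiff(config$stop_stimuli, names(params$ssrt_true))
  if (length(cond_missing))
    stop("ssrt_true missing condition(s): ",
         paste(cond_missing, collapse = ", "))
  sched <- build_session(config, seed = NULL)
  n <- nrow(sched)
  rec <- sched
  rec$ssd <- NA_real_
  rec$response <- "none"
  rec$rt <- NA_real_
  rec$premature <- FALSE
  rec$correct <- NA

  is_go <- sched$trial_type == "go"
  n_go <- sum(is_go)
  ssd_col <- rep(NA_real_, n)
  resp_col <- rep("none", n)
  rt_col <- rep(NA_real_, n)
  prem_col <- rep(FALSE, n)
  corr_col <- rep(NA, n)
  if (n_go) {
    respond <- runif(n_go) >= params$p_go_omission
    wrong <- runif(n_go) < params$p_choice_error
    rts <- rexgauss(n_go, params$go_mu, params$go_sigma, params$go_tau)
    key <- ifelse(wrong, other_key[sched$arrow[is_go]], sched$arrow[is_go])
    resp_col[is_go] <- ifelse(respond, key, "none")
    rt_col[is_go] <- ifelse(respond, rts, NA_real_)
    corr_col[is_go] <- respond & !wrong
  }

  # stop trials run sequentially: each SSD depends on the staircase
  # history; the track is maintained inline (same rule as
  # staircase_update) to keep long simulations cheap
  stop_idx <- which(!is_go)
  n_stop <- length(stop_idx)
  if (n_stop) {
    track <- setNames(rep(config$ssd_initial, length(config$stop_stimuli)),
                      config$stop_stimuli)
    g_draw <- rexgauss(n_stop, params$go_mu, params$go_sigma, params$go_tau)
    jit <- rnorm(n_stop, 0, params$ssrt_noise_sd)
    trig <- if (params$p_trigger_failure > 0)
      runif(n_stop) < params$p_trigger_failure else rep(FALSE, n_stop)
    wrongs <- runif(n_stop) < params$p_choice_error
    conds <- sched$condition[stop_idx]
    arrows <- sched$arrow[stop_idx]
    for (k in seq_len(n_stop)) {
      cond <- conds[k]
      ssd <- track[[cond]]
      s <- if (trig[k]) Inf else ssd + params$ssrt_true[[cond]] + jit[k]
      i <- stop_idx[k]
      ssd_col[i] <- ssd
      responded <- g_draw[k] < s
      if (responded) {
        resp_col[i] <- if (wrongs[k]) other_key[[arrows[k]]] else arrows[k]
        rt_col[i] <- g_draw[k]
        prem_col[i] <- g_draw[k] < ssd
        corr_col[i] <- FALSE
      } else {
        corr_col[i] <- TRUE
      }
      delta <- if (responded) -config$ssd_step else config$ssd_step
      track[[cond]] <- min(config$ssd_max,
                           max(config$ssd_min, ssd + delta))
    }
  }

  rec$ssd <- ssd_col
  rec$response <- resp_col
  rec$rt <- rt_col
  rec$premature <- prem_col
  rec$correct <- corr_col
  rec <- cbind(subject = params$id, group = params$group, rec,
               stringsAsFactors = FALSE)
  rec
}

#' Cohort specification
#'
#' Defines the group structure and between-subject distributions for a
#' simulated cohort. Per subject, the neutral-condition true SSRT is drawn
#' `Normal(ssrt_neutral_mean, ssrt_between_sd)` (floored at 80 ms) and the
#' emotional-condition SSRT is
#' `neutral - emotional_advantage_ms + nonplanning_slope * (BISnp_i - mean(BISnp)) + Normal(0, index_noise_sd)`,
#' so the generative SSRT index (emotional minus neutral) has mean
#' `-emotional_advantage_ms` and is linearly moderated by non-planning
#' impulsivity. Questionnaire covariates are integer-rounded truncated
#' normals within instrument ranges.
#'
#' @param n_per_group Subjects per group.
#' @param groups Group labels.
#' @param emotional_advantage_ms True mean SSRT reduction (ms) for the
#'   emotional vs neutral stop stimulus.
#' @param nonplanning_slope ms of SSRT index per BIS-11 non-planning point.
#' @param ssrt_neutral_mean,ssrt_between_sd Between-subject distribution of
#'   the neutral true SSRT (ms).
#' @param index_noise_sd Residual sd (ms) of the generative SSRT index
#'   around its linear rule.
#' @param go_mu_mean,go_mu_sd Between-subject distribution of the
#'   ex-Gaussian go mean (ms); `go_sigma`, `go_tau` are shared.
#' @param go_sigma,go_tau,ssrt_noise_sd,p_go_omission,p_choice_error Trial
#'   level parameters passed to every subject.
#' @param rng_seed Master seed; per-subject streams are derived from it so
#'   cohorts are reproducible subject-by-subject.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_per_group = 30,
                        groups = c("SARS-CoV-2", "Fear-Face", "Fear-Body"),
                        emotional_advantage_ms = 8.3,
                        nonplanning_slope = 1.192,
                        ssrt_neutral_mean = 240,
                        ssrt_between_sd = 38,
                        index_noise_sd = 10,
                        go_mu_mean = 430, go_mu_sd = 120,
                        go_sigma = 60, go_tau = 115,
                        ssrt_noise_sd = 20,
                        p_go_omission = 0.005,
                        p_choice_error = 0.015,
                        rng_seed = 1L) {
  stopifnot(n_per_group > 0, !anyDuplicated(groups))
  structure(as.list(environment()), class = "cohort_spec")
}

# Table-4-style questionnaire score generator: truncated normal, integer
covariate_table <- function(group) {
  # mean, sd, min, max per instrument and group
  tab <- list(
    "SARS-CoV-2" = list(STAI_Y2 = c(45.17, 9.11), HADS_anxiety = c(8.00, 4.13),
                        HADS_depression = c(4.70, 3.72), BIS_motor = c(16.67, 3.24),
                        BIS_attentional = c(21.23, 3.96), BIS_nonplanning = c(26.47, 4.17)),
    "Fear-Face" = list(STAI_Y2 = c(46.77, 8.15), HADS_anxiety = c(7.00, 3.27),
                       HADS_depression = c(5.97, 3.20), BIS_motor = c(16.60, 3.09),
                       BIS_attentional = c(19.57, 3.44), BIS_nonplanning = c(26.50, 3.66)),
    "Fear-Body" = list(STAI_Y2 = c(47.43, 9.55), HADS_anxiety = c(6.97, 2.95),
                       HADS_depression = c(5.00, 3.13), BIS_motor = c(18.10, 2.72),
                       BIS_attentional = c(20.90, 4.38), BIS_nonplanning = c(25.70, 3.62)))
  tab[[group]] %||% tab[[1L]]
}

covariate_range <- c(STAI_Y2.lo = 20, STAI_Y2.hi = 80,
                     HADS_anxiety.lo = 0, HADS_anxiety.hi = 21,
                     HADS_depression.lo = 0, HADS_depression.hi = 21,
                     BIS_motor.lo = 11, BIS_motor.hi = 44,
                     BIS_attentional.lo = 8, BIS_attentional.hi = 32,
                     BIS_nonplanning.lo = 11, BIS_nonplanning.hi = 44)

`%||%` <- function(a, b) if (is.null(a)) b else a

draw_covariates <- function(group) {
  tab <- covariate_table(group)
  out <- vapply(names(tab), function(nm) {
    m <- tab[[nm]][1]; s <- tab[[nm]][2]
    lo <- covariate_range[[paste0(nm, ".lo")]]
    hi <- covariate_range[[paste0(nm, ".hi")]]
    x <- rnorm(1, m, s)
    while (x < lo || x > hi) x <- rnorm(1, m, s)
    round(x)
  }, numeric(1))
  out["BIS_total"] <- out["BIS_motor"] + out["BIS_attentional"] +
    out["BIS_nonplanning"]
  out
}

#' Simulate a full cohort
#'
#' Draws per-subject generative parameters from a [cohort_spec()], simulates
#' every subject's full session, and returns both the trial log and the
#' generative-truth table for parameter-recovery testing.
#'
#' @param spec A [cohort_spec()].
#' @param config An [session_config()].
#' @return A list with `trials` (row-bound [simulate_subject()] output for
#'   all subjects) and `params` (one row per subject: group, covariates,
#'   true go/stop parameters and the generative SSRT index).
#' @export
simulate_cohort <- function(spec = cohort_spec(), config = session_config()) {
  gen <- gen_cohort_params(spec, config)
  params <- gen$params
  n_tot <- nrow(params)
  trials <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    pars <- subject_params(
      go_mu = params$go_mu[i], go_sigma = spec$go_sigma,
      go_tau = spec$go_tau,
      ssrt_true = setNames(c(params$ssrt_true_emotional[i],
                             params$ssrt_true_neutral[i]),
                           config$stop_stimuli),
      ssrt_noise_sd = spec$ssrt_noise_sd,
      p_go_omission = spec$p_go_omission,
      p_choice_error = spec$p_choice_error,
      group = params$group[i], id = params$subject[i])
    trials[[i]] <- simulate_subject(pars, config, seed = gen$seeds[i])
  }
  list(trials = do.call(rbind, trials), params = params)
}

gen_cohort_params <- function(spec, config = session_config()) {
  set.seed(spec$rng_seed)
  n_tot <- spec$n_per_group * length(spec$groups)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n_tot)
  ids <- sprintf("s%03d", seq_len(n_tot))
  groups <- rep(spec$groups, each = spec$n_per_group)

  cov_mat <- t(vapply(groups, draw_covariates, numeric(7)))
  rownames(cov_mat) <- NULL
  bis_np_c <- cov_mat[, "BIS_nonplanning"] -
    mean(cov_mat[, "BIS_nonplanning"])

  ssrt_neutral <- pmax(80, rnorm(n_tot, spec$ssrt_neutral_mean,
                                 spec$ssrt_between_sd))
  index_true <- -spec$emotional_advantage_ms +
    spec$nonplanning_slope * bis_np_c + rnorm(n_tot, 0, spec$index_noise_sd)
  ssrt_emotional <- pmax(80, ssrt_neutral + index_true)
  go_mu <- pmax(200, rnorm(n_tot, spec$go_mu_mean, spec$go_mu_sd))

  params <- data.frame(subject = ids, group = groups,
                       go_mu = go_mu, go_sigma = spec$go_sigma,
                       go_tau = spec$go_tau,
                       ssrt_true_emotional = ssrt_emotional,
                       ssrt_true_neutral = ssrt_neutral,
                       ssrt_index_true = ssrt_emotional - ssrt_neutral,
                       stringsAsFactors = FALSE)
  params <- cbind(params, as.data.frame(cov_mat))
  list(params = params, seeds = subject_seeds)
}

#' Draw a cohort's generative parameters without simulating trials
#'
#' Same subject-by-subject draws as [simulate_cohort()] (identical under
#' the same `rng_seed`), returning only the generative-truth table. Useful
#' for recovery tests that need the generator's linear structure at large
#' n without paying for trial simulation.
#'
#' @param spec A [cohort_spec()].
#' @param config An [session_config()] (condition labels only).
#' @return The `params` data.frame of [simulate_cohort()].
#' @export
cohort_params_only <- function(spec = cohort_spec(),
                               config = session_config()) {
  gen_cohort_params(spec, config)$params
}
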