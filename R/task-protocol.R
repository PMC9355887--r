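#' Session configuration for the stop-signal task
#'
#' Defines the block composition, staircase parameters and timing of a
#' stop-signal task (SST) session. Defaults mirror a four-block design of
#' 128 trials per block (96 go, 32 stop), two stop-stimulus conditions in
#' equal proportion, and a one-up/one-down staircase starting at 150 ms
#' stepping by 50 ms within [50, 650] ms.
#'
#' @param n_blocks Number of experimental blocks.
#' @param trials_per_block Trials per block.
#' @param go_fraction Fraction of go trials per block; `trials_per_block *
#'   go_fraction` must be an integer and the stop trials must divide evenly
#'   between the stop conditions.
#' @param stop_stimuli Character vector of the two stop-stimulus condition
#'   labels (first label is the emotional condition by convention).
#' @param ssd_initial,ssd_step,ssd_min,ssd_max Staircase start, step and
#'   clamp bounds for the stop-signal delay (SSD), in ms.
#' @param fixation_ms,stop_signal_ms,iti_ms,go_stimulus_ms Display timing
#'   metadata in ms (stored, never used in computation).
#' @param practice_trials Number of practice trials (same go/stop mix);
#'   practice trials are flagged and excluded from analysis by default.
#' @param rng_seed Optional integer seed used by [build_session()] for trial
#'   ordering; `NULL` uses the current RNG state.
#' @return An object of class `"sst_config"` (a list of the above fields).
#' @examples
#' cfg <- session_config()
#' sched <- build_session(cfg)
#' table(sched$trial_type[sched$phase == "experimental"])
#' @export
session_config <- function(n_blocks = 4,
                           trials_per_block = 128,
                           go_fraction = 0.75,
                           stop_stimuli = c("emotional", "neutral"),
                           ssd_initial = 150,
                           ssd_step = 50,
                           ssd_min = 50,
                           ssd_max = 650,
                           fixation_ms = 800,
                           stop_signal_ms = 70,
                           iti_ms = 1600,
                           go_stimulus_ms = 100,
                           practice_trials = 32,
                           rng_seed = NULL) {
  cfg <- list(n_blocks = n_blocks, trials_per_block = trials_per_block,
              go_fraction = go_fraction, stop_stimuli = stop_stimuli,
              ssd_initial = ssd_initial, ssd_step = ssd_step,
              ssd_min = ssd_min, ssd_max = ssd_max,
              fixation_ms = fixation_ms, stop_signal_ms = stop_signal_ms,
              iti_ms = iti_ms, go_stimulus_ms = go_stimulus_ms,
              practice_trials = practice_trials, rng_seed = rng_seed)
  class(cfg) <- "sst_config"
  validate_session_config(cfg)
  cfg
}

validate_session_config <- function(cfg) {
  n_go <- cfg$trials_per_block * cfg$go_fraction
  n_stop <- cfg$trials_per_block - n_go
  if (abs(n_go - round(n_go)) > 1e-9)
    stop_config("trials_per_block * go_fraction must be an integer (got ",
                n_go, ")")
  if (length(cfg$stop_stimuli) != 2L || anyDuplicated(cfg$stop_stimuli))
    stop_config("stop_stimuli must be two distinct condition labels")
  if (n_stop %% length(cfg$stop_stimuli) != 0)
    stop_config("stop trials per block (", n_stop,
                ") must divide evenly between the stop conditions")
  if (!(cfg$ssd_min <= cfg$ssd_initial && cfg$ssd_initial <= cfg$ssd_max))
    stop_config("need ssd_min <= ssd_initial <= ssd_max")
  if (cfg$ssd_step <= 0) stop_config("ssd_step must be > 0")
  if (cfg$n_blocks < 0 || cfg$trials_per_block <= 0)
    stop_config("n_blocks must be >= 0 and trials_per_block > 0")
  if (cfg$practice_trials > 0) {
    p_go <- cfg$practice_trials * cfg$go_fraction
    if (abs(p_go - round(p_go)) > 1e-9 ||
        (cfg$practice_trials - round(p_go)) %% length(cfg$stop_stimuli) != 0)
      stop_config("practice trials must split into whole go/stop counts ",
                  "with stop trials even across conditions")
  }
  invisible(cfg)
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("sst_config_error", "error")))
}

# one balanced, shuffled block; block 0 = practice
build_block <- function(cfg, block, n_trials) {
  n_go <- round(n_trials * cfg$go_fraction)
  n_stop <- n_trials - n_go
  per_cond <- n_stop / length(cfg$stop_stimuli)
  # arrows balanced 50/50 within trial type (and within stop condition)
  half <- function(n) rep(c("left", "right"), length.out = n)
  go <- data.frame(trial_type = "go", condition = "none",
                   arrow = half(n_go), stringsAsFactors = FALSE)
  stop_df <- do.call(rbind, lapply(cfg$stop_stimuli, function(cc)
    data.frame(trial_type = "stop", condition = cc,
               arrow = half(per_cond), stringsAsFactors = FALSE)))
  blk <- rbind(go, stop_df)
  # uniform shuffle, rejecting orderings with > 4 consecutive stop trials
  for (i in 1:1000) {
    ord <- sample.int(nrow(blk))
    runs <- rle(blk$trial_type[ord] == "stop")
    if (!any(runs$values & runs$lengths > 4L)) break
  }
  blk <- blk[ord, , drop = FALSE]
  blk$block <- block
  blk$trial <- seq_len(nrow(blk))
  blk$phase <- if (block == 0L) "practice" else "experimental"
  rownames(blk) <- NULL
  blk[, c("block", "trial", "phase", "trial_type", "condition", "arrow")]
}

#' Build a full session schedule
#'
#' Generates the ordered trial plan for one session: an optional practice
#' block (block 0, flagged `phase = "practice"`) followed by the
#' experimental blocks. Go/stop counts are exact per block, stop trials are
#' split equally between the two stop conditions, arrow directions are
#' balanced within trial type, and ordering is a seeded uniform shuffle
#' constrained to at most 4 consecutive stop trials.
#'
#' @param config An [session_config()] object.
#' @param seed Optional integer seed overriding `config$rng_seed`.
#' @return A data.frame with columns `block`, `trial`, `phase`,
#'   `trial_type` (`"go"`/`"stop"`), `condition` (a stop-stimulus label or
#'   `"none"`), `arrow` (`"left"`/`"right"`).
#' @export
build_session <- function(config, seed = NULL) {
  validate_session_config(config)
  seed <- if (!is.null(seed)) seed else config$rng_seed
  if (!is.null(seed)) set.seed(seed)
  blocks <- list()
  if (config$practice_trials > 0)
    blocks[[1]] <- build_block(config, 0L, config$practice_trials)
  if (config$n_blocks > 0)
    for (b in seq_len(config$n_blocks))
      blocks[[length(blocks) + 1L]] <-
        build_block(config, b, config$trials_per_block)
  if (!length(blocks)) {
    return(data.frame(block = integer(), trial = integer(),
                      phase = character(), trial_type = character(),
                      condition = character(), arrow = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Create a staircase state
#'
#' One independent one-up/one-down SSD track per stop-stimulus condition.
#' After a successful inhibition the condition's SSD increases by one step;
#' after a failed stop it decreases by one step; values are clamped to
#' `[ssd_min, ssd_max]`.
#'
#' @param config An [session_config()] object.
#' @return An object of class `"staircase"` with fields `ssd` (named vector
#'   of current SSDs), `step`, `min`, `max`, and `history` (data.frame of
#'   `condition`, `ssd`, `inhibited` in update order).
#' @export
staircase_new <- function(config) {
  ssd <- setNames(rep(config$ssd_initial, length(config$stop_stimuli)),
                  config$stop_stimuli)
  structure(list(ssd = ssd, step = config$ssd_step,
                 min = config$ssd_min, max = config$ssd_max,
                 history = data.frame(condition = character(),
                                      ssd = numeric(),
                                      inhibited = logical(),
                                      stringsAsFactors = FALSE)),
            class = "staircase")
}

#' Update one condition's staircase track
#'
#' @param state A [staircase_new()] object.
#' @param condition A known stop-stimulus condition label.
#' @param inhibited Logical: was the response successfully inhibited at the
#'   current SSD?
#' @return The updated staircase; the other condition's track is untouched.
#' @examples
#' sc <- staircase_new(session_config())
#' sc <- staircase_update(sc, "emotional", inhibited = TRUE)
#' sc$ssd[["emotional"]]  # 200
#' @export
staircase_update <- function(state, condition, inhibited) {
  if (!condition %in% names(state$ssd))
    stop("unknown stop condition: ", condition)
  used <- state$ssd[[condition]]
  state$history <- rbind(state$history,
                         data.frame(condition = condition, ssd = used,
                                    inhibited = inhibited,
                                    stringsAsFactors = FALSE))
  delta <- if (inhibited) state$step else -state$step
  state$ssd[[condition]] <- min(state$max, max(state$min, used + delta))
  state
}
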