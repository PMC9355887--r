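ten_go <- seq(300, 750, by = 50)  # 10 evenly spread go RTs

test_that("integration estimator matches the worked rank selection", {
  # 10 go RTs, half the stop trials responded, mean SSD 200
  rec <- make_records(go_rts = ten_go,
                      stop_ssd = rep(200, 10),
                      stop_rt = rep(400, 5))
  est <- estimate_ssrt_integration(rec, "emotional")
  expect_equal(est$p_respond_signal, 0.5)
  expect_equal(est$rank, 5)
  expect_equal(est$nth_rt, 500)
  expect_equal(est$ssrt, 300)
  expect_equal(est$ssrt,
               oracle_ssrt(ten_go, 0, 0.5, rep(200, 10)))
})

test_that("go omissions are replaced by the maximum go RT before ranking", {
  rec <- make_records(go_rts = ten_go, go_omissions = 2,
                      stop_ssd = rep(200, 10), stop_rt = rep(400, 5))
  est <- estimate_ssrt_integration(rec, "emotional")
  expect_equal(est$n_go, 12)
  expect_equal(est$n_go_omissions, 2)
  expect_equal(est$rank, 6)
  # 6th smallest of {300..750, 750, 750} is 550
  expect_equal(est$nth_rt, 550)
  expect_equal(est$ssrt, 350)
  expect_equal(est$ssrt, oracle_ssrt(ten_go, 2, 0.5, rep(200, 10)))
})

test_that("degenerate stop performance is an estimation error", {
  all_resp <- make_records(go_rts = ten_go, stop_ssd = rep(200, 10),
                           stop_rt = rep(400, 10))
  expect_error(estimate_ssrt_integration(all_resp, "emotional"),
               class = "ssrt_undefined_error")
  none_resp <- make_records(go_rts = ten_go, stop_ssd = rep(200, 10))
  expect_error(estimate_ssrt_integration(none_resp, "emotional"),
               class = "ssrt_undefined_error")
  no_go <- make_records(go_omissions = 5, stop_ssd = rep(200, 10),
                        stop_rt = rep(400, 5))
  expect_error(estimate_ssrt_integration(no_go, "emotional"),
               "no go trials with a response")
})

test_that("rank selection agrees with the brute-force oracle on random sessions", {
  set.seed(31)
  for (rep in 1:60) {
    n_go <- sample(3:20, 1)
    n_omit <- sample(0:3, 1)
    n_stop <- sample(2:10, 1)
    n_resp <- sample(seq_len(n_stop - 1), 1)
    go_rts <- round(runif(n_go, 250, 900), 1)
    ssds <- sample(seq(50, 650, 50), n_stop, replace = TRUE)
    rec <- make_records(go_rts = go_rts, go_omissions = n_omit,
                        stop_ssd = ssds,
                        stop_rt = runif(n_resp, 300, 700))
    est <- estimate_ssrt_integration(rec, "emotional")
    expect_equal(est$ssrt,
                 oracle_ssrt(go_rts, n_omit, n_resp / n_stop, ssds))
  }
})

test_that("adding go omissions never decreases the nth RT", {
  set.seed(32)
  go_rts <- round(runif(30, 300, 800))
  base <- estimate_ssrt_integration(
    make_records(go_rts = go_rts, stop_ssd = rep(250, 8),
                 stop_rt = rep(400, 3)), "emotional")
  prev <- base$nth_rt
  for (k in 1:5) {
    est <- estimate_ssrt_integration(
      make_records(go_rts = go_rts, go_omissions = k,
                   stop_ssd = rep(250, 8), stop_rt = rep(400, 3)),
      "emotional")
    expect_gte(est$nth_rt, prev)
    prev <- est$nth_rt
  }
})

test_that("premature responses raise p(respond|signal) by exactly k/n", {
  rec <- make_records(go_rts = ten_go, stop_ssd = rep(300, 10),
                      stop_rt = rep(400, 4))
  base <- estimate_ssrt_integration(rec, "emotional")
  # convert k inhibited stops into premature responses (rt < ssd)
  inhibited_rows <- which(rec$trial_type == "stop" & rec$response == "none")
  for (k in 1:3) {
    rec2 <- rec
    rows <- inhibited_rows[seq_len(k)]
    rec2$response[rows] <- "left"
    rec2$rt[rows] <- 150
    rec2$premature[rows] <- TRUE
    rec2$correct[rows] <- FALSE
    est <- estimate_ssrt_integration(rec2, "emotional")
    expect_equal(est$p_respond_signal - base$p_respond_signal, k / 10)
    # premature SSDs stay in the mean-SSD pool
    expect_equal(est$mean_ssd, base$mean_ssd)
  }
})

test_that("race-model check compares unsuccessful-stop and go RT means", {
  r1 <- make_records(go_rts = 500, stop_ssd = 200, stop_rt = 400)
  expect_true(verify_race_assumption(r1)$assumption_met)
  r2 <- make_records(go_rts = c(400, 500), stop_ssd = c(200, 200),
                     stop_rt = c(400, 500))
  expect_false(verify_race_assumption(r2)$assumption_met)  # equal means
  r3 <- make_records(go_rts = ten_go, stop_ssd = rep(200, 4))
  chk <- verify_race_assumption(r3)
  expect_true(is.na(chk$assumption_met))
  expect_equal(chk$n_unsuccessful, 0)
})

test_that("subject summaries follow the record arithmetic", {
  # 64 stop trials, 33 inhibited -> inhibition rate 51.6%
  rec <- make_records(go_rts = ten_go, stop_ssd = rep(250, 64),
                      stop_rt = rep(400, 31))
  s <- summarize_subject(rec, conditions = "emotional")
  expect_equal(s$inhibition_rate_emotional, 33 / 64)
  expect_equal(round(100 * s$inhibition_rate_emotional, 1), 51.6)
  expect_equal(s$p_respond_emotional, 1 - s$inhibition_rate_emotional)
  # fully inhibited condition: rate 1, SSRT undefined
  rec_all <- make_records(go_rts = ten_go, stop_ssd = rep(250, 8))
  s_all <- summarize_subject(rec_all, conditions = "emotional")
  expect_equal(s_all$inhibition_rate_emotional, 1)
  expect_true(is.na(s_all$ssrt_emotional))
})

test_that("the SSRT index is the emotional-minus-neutral difference", {
  s <- data.frame(ssrt_emotional = 233.45, ssrt_neutral = 242.46)
  expect_equal(ssrt_index(s), -9.01)
  expect_equal(ssrt_index(data.frame(ssrt_emotional = 200,
                                     ssrt_neutral = 200)), 0)
  expect_error(ssrt_index(data.frame(ssrt_emotional = NA_real_,
                                     ssrt_neutral = 200)), "undefined")
})

test_that("the estimator recovers a known SSRT on fixed-SSD data", {
  # staircase disabled (degenerate bounds), no stop-latency jitter:
  # 10000 go and 5000 stop trials identify the quantile construction
  cfg <- session_config(n_blocks = 1, trials_per_block = 15000,
                        go_fraction = 2 / 3, ssd_initial = 250,
                        ssd_min = 250, ssd_max = 250,
                        practice_trials = 0)
  p <- subject_params(ssrt_true = c(emotional = 230, neutral = 230),
                      ssrt_noise_sd = 0, p_go_omission = 0,
                      p_choice_error = 0)
  tr <- simulate_subject(p, cfg, seed = 41)
  est_e <- estimate_ssrt_integration(tr, "emotional")
  est_n <- estimate_ssrt_integration(tr, "neutral")
  expect_lt(abs(est_e$ssrt - 230), 3)
  expect_lt(abs(est_n$ssrt - 230), 3)
})
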