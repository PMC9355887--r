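test_that("default session has the exact block composition", {
  sched <- build_session(session_config(), seed = 7)
  exp_rows <- sched[sched$phase == "experimental", ]
  expect_equal(sum(exp_rows$trial_type == "go"), 384)
  expect_equal(sum(exp_rows$trial_type == "stop"), 128)
  for (b in 1:4) {
    blk <- exp_rows[exp_rows$block == b, ]
    expect_equal(nrow(blk), 128)
    expect_equal(sum(blk$trial_type == "go"), 96)
    expect_equal(sum(blk$trial_type == "stop"), 32)
    expect_equal(as.integer(table(blk$condition[blk$trial_type == "stop"])),
                 c(16L, 16L))
    # arrows balanced within trial type
    expect_equal(sum(blk$arrow[blk$trial_type == "go"] == "left"), 48)
    expect_equal(sum(blk$arrow[blk$trial_type == "stop"] == "left"), 16)
  }
  # go trials carry no stop condition
  expect_true(all(exp_rows$condition[exp_rows$trial_type == "go"] == "none"))
  # practice block present and flagged
  expect_equal(sum(sched$phase == "practice"), 32)
})

test_that("schedule composition is exact for random valid configs", {
  set.seed(42)
  for (rep in 1:8) {
    tpb <- sample(c(40, 80, 120, 160), 1)
    gf <- sample(c(0.5, 0.75, 0.8), 1)
    if ((tpb * (1 - gf)) %% 2 != 0 ||
        abs(tpb * gf - round(tpb * gf)) > 1e-9) next
    nb <- sample(1:5, 1)
    cfg <- session_config(n_blocks = nb, trials_per_block = tpb,
                          go_fraction = gf, practice_trials = 0)
    sched <- build_session(cfg)
    expect_equal(nrow(sched), nb * tpb)
    for (b in seq_len(nb)) {
      blk <- sched[sched$block == b, ]
      expect_equal(sum(blk$trial_type == "go"), round(tpb * gf))
      tab <- table(blk$condition[blk$trial_type == "stop"])
      expect_true(all(tab == tab[1]))
    }
  }
})

test_that("stop-trial run lengths never exceed four", {
  for (s in 1:5) {
    sched <- build_session(session_config(), seed = s)
    runs <- rle(sched$trial_type == "stop")
    expect_true(all(runs$lengths[runs$values] <= 4))
  }
})

test_that("zero blocks give an empty schedule and bad configs error", {
  sched <- build_session(session_config(n_blocks = 0, practice_trials = 0))
  expect_equal(nrow(sched), 0)
  expect_error(session_config(trials_per_block = 100, go_fraction = 0.333),
               class = "sst_config_error")
  expect_error(session_config(ssd_initial = 40), class = "sst_config_error")
  expect_error(session_config(ssd_step = 0), class = "sst_config_error")
  expect_error(session_config(stop_stimuli = c("a", "a")),
               class = "sst_config_error")
})

test_that("same seed reproduces the schedule exactly", {
  expect_identical(build_session(session_config(), seed = 123),
                   build_session(session_config(), seed = 123))
})

test_that("staircase steps up, down, and clamps at the bounds", {
  cfg <- session_config()
  sc <- staircase_new(cfg)
  sc <- staircase_update(sc, "emotional", TRUE)
  expect_equal(sc$ssd[["emotional"]], 200)
  expect_equal(sc$ssd[["neutral"]], 150)
  # walk to the floor: 150 -> 100 -> 50 -> clamp
  sc2 <- staircase_new(cfg)
  for (i in 1:5) sc2 <- staircase_update(sc2, "neutral", FALSE)
  expect_equal(sc2$ssd[["neutral"]], 50)
  # walk to the ceiling: 150 + 10*50 = 650, then clamp
  sc3 <- staircase_new(cfg)
  for (i in 1:12) sc3 <- staircase_update(sc3, "emotional", TRUE)
  expect_equal(sc3$ssd[["emotional"]], 650)
  expect_error(staircase_update(sc, "unknown"), "unknown stop condition")
})

test_that("staircase matches a brute-force track over all 12-step outcome sequences", {
  cfg <- session_config()
  for (bits in 0:4095) {
    outcomes <- as.logical(bitwAnd(bits, 2^(0:11)) > 0)
    sc <- staircase_new(cfg)
    for (o in outcomes) sc <- staircase_update(sc, "emotional", o)
    ref <- oracle_staircase_track(outcomes)
    expect_identical(sc$ssd[["emotional"]], ref$final)
    expect_identical(sc$history$ssd, ref$path)
    # invariants: in bounds and on the step lattice
    expect_true(all(sc$history$ssd >= 50 & sc$history$ssd <= 650))
    expect_true(all(sc$history$ssd %% 50 == 0))
  }
})

test_that("the two condition tracks are independent", {
  cfg <- session_config()
  set.seed(5)
  a_out <- sample(c(TRUE, FALSE), 20, replace = TRUE)
  b_out <- sample(c(TRUE, FALSE), 20, replace = TRUE)
  run <- function(a_seq) {
    sc <- staircase_new(cfg)
    for (i in 1:20) {
      sc <- staircase_update(sc, "emotional", a_seq[i])
      sc <- staircase_update(sc, "neutral", b_out[i])
    }
    sc$ssd[["neutral"]]
  }
  expect_identical(run(a_out), run(sample(a_out)))
  expect_identical(run(a_out), run(rev(a_out)))
})
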