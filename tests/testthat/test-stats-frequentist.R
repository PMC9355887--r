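test_that("gender-count table gives the printed chi-squared", {
  gender <- rbind(F = c(19, 16, 20), M = c(11, 14, 10))
  res <- chi2_independence(gender)
  expect_equal(round(res$chi2, 3), 1.216)
  expect_equal(res$df, 2)
  expect_equal(res$n, 90)
})

test_that("chi-squared boundary cases behave", {
  prop <- rbind(c(10, 20, 30), c(5, 10, 15))  # proportional margins
  expect_equal(chi2_independence(prop)$chi2, 0)
  diag2 <- rbind(c(10, 0), c(0, 10))
  expect_equal(chi2_independence(diag2)$chi2, 20)  # equals N
  expect_error(chi2_independence(rbind(c(1, 0), c(2, 0))), "margin")
  expect_error(chi2_independence(rbind(c(-1, 2), c(2, 1))), "nonnegative")
})

test_that("paired t matches the closed form and rejects zero variance", {
  x <- c(300, 305, 310); y <- c(310, 315, 323)
  tt <- paired_t(x, y)
  expect_equal(tt$t, -11)  # mean diff -11, SE 1
  expect_equal(tt$df, 2)
  expect_error(paired_t(x, x), "zero variance")
  expect_error(paired_t(x, y[1:2]), "equal length")
})

test_that("one-way ANOVA agrees with the raw sums-of-squares oracle", {
  set.seed(51)
  for (rep in 1:10) {
    k <- sample(2:4, 1)
    n_g <- sample(2:5, k, replace = TRUE)
    g <- rep(letters[1:k], n_g)
    v <- round(rnorm(length(g), 10, 3), 2)
    res <- one_way_anova(v, g)$effects
    ref <- oracle_one_way(v, g)
    expect_equal(res$F, ref$F, tolerance = 1e-10)
    expect_equal(res$p, ref$p, tolerance = 1e-10)
    expect_equal(res$pes, ref$pes, tolerance = 1e-10)
    expect_equal(res$df1, ref$df1)
    expect_equal(res$df2, ref$df2)
  }
  expect_error(one_way_anova(1:5, rep("a", 5)), "two groups")
})

test_that("mixed ANOVA agrees with the cell-means decomposition oracle", {
  set.seed(52)
  for (rep in 1:12) {
    k <- sample(2:3, 1)
    n_per <- sample(3:6, 1)
    d <- expand.grid(subject = sprintf("s%02d", 1:(k * n_per)),
                     stimulus = c("emotional", "neutral"),
                     stringsAsFactors = FALSE)
    d$group <- rep(rep(LETTERS[1:k], each = n_per), 2)
    d$value <- round(rnorm(nrow(d), 240, 40), 1)
    res <- mixed_anova_2x3(d)$effects
    ref <- oracle_mixed_2xk(d)
    expect_equal(res$F, c(ref$stimulus$F, ref$group$F, ref$interaction$F),
                 tolerance = 1e-8)
    expect_equal(res$p, c(ref$stimulus$p, ref$group$p, ref$interaction$p),
                 tolerance = 1e-8)
    expect_equal(res$pes,
                 c(ref$stimulus$pes, ref$group$pes, ref$interaction$pes),
                 tolerance = 1e-8)
    expect_equal(res$df1, c(ref$stimulus$df1, ref$group$df1,
                            ref$interaction$df1))
    expect_equal(res$df2, c(ref$stimulus$df2, ref$group$df2,
                            ref$interaction$df2))
  }
})

test_that("a condition-invariant dataset has a zero stimulus effect", {
  d <- expand.grid(subject = sprintf("s%02d", 1:12),
                   stimulus = c("a", "b"), stringsAsFactors = FALSE)
  d$group <- rep(rep(c("g1", "g2", "g3"), each = 4), 2)
  base <- rnorm(12, 240, 30)
  d$value <- base[match(d$subject, sprintf("s%02d", 1:12))]
  res <- mixed_anova_2x3(d)$effects
  expect_equal(res$F[res$effect == "stimulus"], 0)
  expect_equal(res$p[res$effect == "stimulus"], 1)
})

test_that("mixed ANOVA rejects incomplete subjects", {
  d <- data.frame(subject = c("s1", "s1", "s2"),
                  stimulus = c("a", "b", "a"),
                  group = "g1", value = 1:3)
  expect_error(mixed_anova_2x3(d), "exactly one value")
})

test_that("Bonferroni post hocs never undercut the raw p", {
  set.seed(53)
  d <- expand.grid(subject = sprintf("s%02d", 1:15),
                   stimulus = c("emotional", "neutral"),
                   stringsAsFactors = FALSE)
  d$group <- rep(rep(c("A", "B", "C"), each = 5), 2)
  d$value <- rnorm(30, 240, 40) + (d$stimulus == "emotional") * -8
  res <- mixed_anova_2x3(d, posthoc = TRUE)
  expect_true(all(res$posthoc$p_bonferroni >= res$posthoc$p_raw))
  expect_true(all(res$posthoc$p_bonferroni <= 1))
})

test_that("within-subject two-way ANOVA matches its oracle", {
  set.seed(54)
  for (rep in 1:8) {
    n <- sample(3:6, 1)
    d <- expand.grid(subject = sprintf("s%02d", 1:n),
                     emotion = c("negative", "neutral"),
                     stimulus = c("virus", "face", "body"),
                     stringsAsFactors = FALSE)
    d$value <- round(runif(nrow(d), 1, 10), 1)
    res <- rm_anova_2x3_within(d)$effects
    ref <- oracle_within_2xk(d)
    expect_equal(res$F, c(ref$A$F, ref$B$F, ref$AB$F), tolerance = 1e-8)
    expect_equal(res$p, c(ref$A$p, ref$B$p, ref$AB$p), tolerance = 1e-8)
    expect_equal(res$pes, c(ref$A$pes, ref$B$pes, ref$AB$pes),
                 tolerance = 1e-8)
    expect_equal(res$df2, c(ref$A$df2, ref$B$df2, ref$AB$df2))
  }
})

test_that("constant ratings give all-zero within-subject F values", {
  d <- expand.grid(subject = sprintf("s%02d", 1:5),
                   emotion = c("neg", "neu"),
                   stimulus = c("a", "b", "c"),
                   stringsAsFactors = FALSE)
  d$value <- 5
  res <- rm_anova_2x3_within(d)$effects
  expect_equal(res$F, c(0, 0, 0))
  d2 <- d[-1, ]
  expect_error(rm_anova_2x3_within(d2), "complete")
})

test_that("a pure emotion shift leaves stimulus and interaction near null", {
  # simulate many small rating studies with only an emotion main effect and
  # check the other two effects reject at about the nominal rate
  set.seed(55)
  rej_b <- 0; rej_ab <- 0; n_rep <- 200
  for (rep in 1:n_rep) {
    d <- expand.grid(subject = sprintf("s%02d", 1:8),
                     emotion = c("neg", "neu"),
                     stimulus = c("a", "b", "c"),
                     stringsAsFactors = FALSE)
    d$value <- rnorm(nrow(d), 5, 1.5) + (d$emotion == "neg") * 3
    res <- rm_anova_2x3_within(d)$effects
    rej_b <- rej_b + (res$p[2] < 0.05)
    rej_ab <- rej_ab + (res$p[3] < 0.05)
  }
  expect_lt(rej_b / n_rep, 0.11)
  expect_lt(rej_ab / n_rep, 0.11)
})
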