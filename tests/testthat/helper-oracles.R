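# Independent reference implementations used to freeze expected values.
# They deliberately avoid the package's code paths: explicit loops,
# selection by repeated minimum removal, raw sums-of-squares arithmetic,
# Riemann-sum quadrature.

# integration-method SSRT by brute force: augment, select the k-th
# smallest by removing minima, subtract the mean SSD
oracle_ssrt <- function(go_rts, n_omissions, p_respond, ssds,
                        rank_fun = ceiling) {
  aug <- go_rts
  if (n_omissions > 0) {
    mx <- go_rts[1]
    for (v in go_rts) if (v > mx) mx <- v
    for (i in seq_len(n_omissions)) aug <- c(aug, mx)
  }
  n <- length(aug)
  k <- rank_fun(n * p_respond)
  if (k < 1) k <- 1
  if (k > n) k <- n
  pool <- aug
  nth <- NA_real_
  for (i in seq_len(k)) {
    j <- which.min(pool)
    nth <- pool[j]
    pool <- pool[-j]
  }
  ssd_sum <- 0
  for (s in ssds) ssd_sum <- ssd_sum + s
  nth - ssd_sum / length(ssds)
}

# brute-force staircase track for one condition
oracle_staircase_track <- function(outcomes, init = 150, step = 50,
                                   lo = 50, hi = 650) {
  ssd <- init
  path <- numeric(length(outcomes))
  for (i in seq_along(outcomes)) {
    path[i] <- ssd
    ssd <- ssd + if (outcomes[i]) step else -step
    if (ssd < lo) ssd <- lo
    if (ssd > hi) ssd <- hi
  }
  list(path = path, final = ssd)
}

# one-way between-subjects ANOVA from raw sums of squares
oracle_one_way <- function(values, groups) {
  gm <- mean(values)
  ss_b <- 0; ss_w <- 0
  for (g in unique(groups)) {
    v <- values[groups == g]
    ss_b <- ss_b + length(v) * (mean(v) - gm)^2
    ss_w <- ss_w + sum((v - mean(v))^2)
  }
  df1 <- length(unique(groups)) - 1
  df2 <- length(values) - length(unique(groups))
  f <- (ss_b / df1) / (ss_w / df2)
  list(F = f, df1 = df1, df2 = df2,
       p = pf(f, df1, df2, lower.tail = FALSE),
       pes = ss_b / (ss_b + ss_w))
}

# balanced mixed design (one between factor, one 2-level within factor):
# cell-means sums-of-squares decomposition
oracle_mixed_2xk <- function(d) {
  # d: subject, group, stimulus, value; balanced groups
  W <- length(unique(d$stimulus))
  subj <- unique(d$subject)
  gm <- mean(d$value)
  smean <- sapply(subj, function(s) mean(d$value[d$subject == s]))
  sgroup <- sapply(subj, function(s) d$group[d$subject == s][1])
  groups <- unique(d$group)
  stims <- unique(d$stimulus)
  ss_between_subj <- W * sum((smean - gm)^2)
  ss_group <- 0
  for (g in groups) {
    n_g <- sum(sgroup == g)
    ss_group <- ss_group + W * n_g * (mean(smean[sgroup == g]) - gm)^2
  }
  ss_subj_err <- ss_between_subj - ss_group
  ss_total <- sum((d$value - gm)^2)
  ss_within <- ss_total - ss_between_subj
  n_subj <- length(subj)
  ss_w <- 0
  for (w in stims)
    ss_w <- ss_w + n_subj * (mean(d$value[d$stimulus == w]) - gm)^2
  ss_cells <- 0
  for (g in groups) for (w in stims) {
    v <- d$value[d$group == g & d$stimulus == w]
    ss_cells <- ss_cells + length(v) * (mean(v) - gm)^2
  }
  ss_int <- ss_cells - ss_group - ss_w
  ss_w_err <- ss_within - ss_w - ss_int
  k <- length(groups)
  out <- list()
  mk <- function(ss, df1, ss_err, df2) {
    f <- (ss / df1) / (ss_err / df2)
    list(F = f, df1 = df1, df2 = df2,
         p = pf(f, df1, df2, lower.tail = FALSE),
         pes = ss / (ss + ss_err))
  }
  out$stimulus <- mk(ss_w, W - 1, ss_w_err, (n_subj - k) * (W - 1))
  out$group <- mk(ss_group, k - 1, ss_subj_err, n_subj - k)
  out$interaction <- mk(ss_int, (k - 1) * (W - 1), ss_w_err,
                        (n_subj - k) * (W - 1))
  out
}

# fully within two-factor design, one observation per cell
oracle_within_2xk <- function(d) {
  subj <- unique(d$subject); A <- unique(d$emotion); B <- unique(d$stimulus)
  n <- length(subj); a <- length(A); b <- length(B)
  gm <- mean(d$value)
  cell <- function(s = NULL, aa = NULL, bb = NULL) {
    idx <- rep(TRUE, nrow(d))
    if (!is.null(s)) idx <- idx & d$subject == s
    if (!is.null(aa)) idx <- idx & d$emotion == aa
    if (!is.null(bb)) idx <- idx & d$stimulus == bb
    mean(d$value[idx])
  }
  ss_A <- n * b * sum(sapply(A, function(x) (cell(aa = x) - gm)^2))
  ss_B <- n * a * sum(sapply(B, function(x) (cell(bb = x) - gm)^2))
  ss_sA <- 0
  for (s in subj) for (aa in A)
    ss_sA <- ss_sA + b * (cell(s, aa) - cell(s) - cell(aa = aa) + gm)^2
  ss_sB <- 0
  for (s in subj) for (bb in B)
    ss_sB <- ss_sB + a * (cell(s, bb = bb) - cell(s) - cell(bb = bb) + gm)^2
  ss_AB <- 0
  for (aa in A) for (bb in B)
    ss_AB <- ss_AB + n * (cell(aa = aa, bb = bb) - cell(aa = aa) -
                            cell(bb = bb) + gm)^2
  ss_sAB <- 0
  for (s in subj) for (aa in A) for (bb in B) {
    y <- d$value[d$subject == s & d$emotion == aa & d$stimulus == bb]
    pred <- cell(s, aa) + cell(s, bb = bb) + cell(aa = aa, bb = bb) -
      cell(s) - cell(aa = aa) - cell(bb = bb) + gm
    ss_sAB <- ss_sAB + (y - pred)^2
  }
  mk <- function(ss, df1, ss_err, df2) {
    f <- (ss / df1) / (ss_err / df2)
    list(F = f, df1 = df1, df2 = df2,
         p = pf(f, df1, df2, lower.tail = FALSE),
         pes = ss / (ss + ss_err))
  }
  list(A = mk(ss_A, a - 1, ss_sA, (n - 1) * (a - 1)),
       B = mk(ss_B, b - 1, ss_sB, (n - 1) * (b - 1)),
       AB = mk(ss_AB, (a - 1) * (b - 1), ss_sAB, (n - 1) * (a - 1) * (b - 1)))
}

# Gauss 2F1 via the Euler integral (b > 0, c > b), Riemann midpoint rule
# with the substitution t = u^2 to tame the endpoint singularity
oracle_hyp2f1 <- function(a, b, cc, z, n_grid = 40000L) {
  u <- (seq_len(n_grid) - 0.5) / n_grid
  h <- 1 / n_grid
  integrand <- 2 * u^(2 * b - 1) * (1 - u^2)^(cc - b - 1) *
    (1 - z * u^2)^(-a)
  gamma(cc) / (gamma(b) * gamma(cc - b)) * sum(integrand) * h
}

# correlation Bayes factor by midpoint Riemann integration of the exact
# r-likelihood ratio against the stretched beta prior
oracle_bf_corr <- function(r, n, width = 1, n_grid = 4000L) {
  shape <- 1 / width
  rho <- -1 + (2 * seq_len(n_grid) - 1) / n_grid
  h <- 2 / n_grid
  lik_ratio <- sapply(rho, function(p) {
    (1 - p^2)^((n - 1) / 2) * (1 - p * r)^(-(n - 1.5)) *
      oracle_hyp2f1(0.5, 0.5, n - 0.5, (1 + p * r) / 2, 2000L) /
      oracle_hyp2f1(0.5, 0.5, n - 0.5, 0.5, 2000L)
  })
  prior <- dbeta((rho + 1) / 2, shape, shape) / 2
  sum(lik_ratio * prior) * h
}

# build a minimal trial-record data.frame for estimator tests
make_records <- function(go_rts = numeric(), go_omissions = 0,
                         stop_ssd = numeric(), stop_rt = numeric(),
                         condition = "emotional", subject = "s01",
                         group = "G") {
  n_stop <- length(stop_ssd)
  stopifnot(length(stop_rt) <= n_stop)
  go_n <- length(go_rts) + go_omissions
  go <- if (go_n) data.frame(
    subject = subject, group = group, block = 1L,
    trial = seq_len(go_n), phase = "experimental", trial_type = "go",
    condition = "none", arrow = "left",
    ssd = NA_real_,
    response = c(rep("left", length(go_rts)), rep("none", go_omissions)),
    rt = c(go_rts, rep(NA_real_, go_omissions)),
    premature = FALSE,
    correct = c(rep(TRUE, length(go_rts)), rep(NA, go_omissions)),
    stringsAsFactors = FALSE) else NULL
  st <- if (n_stop) {
    responded <- c(rep(TRUE, length(stop_rt)),
                   rep(FALSE, n_stop - length(stop_rt)))
    rts <- c(stop_rt, rep(NA_real_, n_stop - length(stop_rt)))
    data.frame(
      subject = subject, group = group, block = 1L,
      trial = go_n + seq_len(n_stop), phase = "experimental",
      trial_type = "stop", condition = condition, arrow = "left",
      ssd = stop_ssd,
      response = ifelse(responded, "left", "none"),
      rt = rts,
      premature = responded & !is.na(rts) & rts < stop_ssd,
      correct = !responded,
      stringsAsFactors = FALSE)
  } else NULL
  rbind(go, st)
}
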