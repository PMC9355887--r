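# Frequentist battery: mixed and within-subject ANOVAs with partial eta
# squared, one-way ANOVA, paired t, Pearson chi-squared, Bonferroni post
# hocs. Model fitting goes through base stats (aov/lm/t.test/chisq.test);
# this layer adds the design bookkeeping, effect sizes and result objects.

new_stat_result <- function(test, effects, posthoc = NULL, extra = list()) {
  structure(c(list(test = test, effects = effects, posthoc = posthoc),
              extra),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(x$test, "\n")
  eff <- x$effects
  for (i in seq_len(nrow(eff))) {
    cat(sprintf("  %s: F(%g,%g) = %.3f, p = %.4g", eff$effect[i],
                eff$df1[i], eff$df2[i], eff$F[i], eff$p[i]))
    if (!is.na(eff$pes[i])) cat(sprintf(", eta_p^2 = %.3f", eff$pes[i]))
    cat("\n")
  }
  if (!is.null(x$posthoc)) {
    cat("  Bonferroni post hocs:\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

# pull F, dfs, p, partial eta^2 for one term out of a summary.aov stratum
extract_effect <- function(stratum_tab, term, ss_tol = 0) {
  tab <- as.data.frame(stratum_tab)
  rn <- trimws(rownames(tab))
  i <- match(term, rn)
  ir <- match("Residuals", rn)
  if (is.na(i) || is.na(ir)) stop("term '", term, "' not found in stratum")
  ss_e <- tab$`Sum Sq`[i]
  ss_r <- tab$`Sum Sq`[ir]
  fv <- tab$`F value`[i]
  pv <- tab$`Pr(>F)`[i]
  if (ss_e <= ss_tol) ss_e <- 0
  if (ss_r <= ss_tol) ss_r <- 0
  if (ss_e <= 0 || !is.finite(fv) || ss_r <= 0) {
    # degenerate stratum: zero effect and/or zero error SS at data scale
    fv <- if (ss_e <= 0) 0 else Inf
    pv <- if (ss_e <= 0) 1 else 0
  }
  data.frame(effect = term, df1 = tab$Df[i], df2 = tab$Df[ir],
             F = fv, p = pv,
             pes = if (ss_e + ss_r > 0) ss_e / (ss_e + ss_r) else 0,
             stringsAsFactors = FALSE)
}

check_complete_within <- function(data, subject, within) {
  tab <- table(data[[subject]], data[[within]])
  if (any(tab != 1L))
    stop("each subject needs exactly one value per '", within, "' level")
}

#' Mixed-design 2 (within) x k (between) ANOVA
#'
#' One within-subject factor with two levels (the stop-stimulus condition)
#' crossed with a between-subject grouping factor. Fit via `aov` with an
#' `Error(subject)` stratum; partial eta squared is
#' `SS_effect / (SS_effect + SS_error)` within each effect's stratum. With
#' balanced groups the sequential sums of squares coincide with Type II;
#' with unbalanced groups the within-factor main effect tests the
#' grand-mean contrast of the condition difference.
#'
#' @param data Long data.frame.
#' @param value,stimulus,group,subject Column names.
#' @param posthoc If `TRUE`, add Bonferroni-adjusted pairwise comparisons:
#'   paired t across the within levels, pooled-SD pairwise t on subject
#'   means across groups.
#' @return A `"stat_result"` with one row per effect (`stimulus`, `group`,
#'   `stimulus:group`).
#' @export
mixed_anova_2x3 <- function(data, value = "value", stimulus = "stimulus",
                            group = "group", subject = "subject",
                            posthoc = FALSE) {
  d <- data.frame(y = data[[value]],
                  w = factor(data[[stimulus]]),
                  g = factor(data[[group]]),
                  s = factor(data[[subject]]))
  if (anyNA(d)) stop("missing values in the design columns")
  if (nlevels(d$w) != 2L) stop("the within factor must have 2 levels")
  check_complete_within(d, "s", "w")
  fit <- aov(y ~ w * g + Error(s), data = d)
  sm <- summary(fit)
  between <- sm[["Error: s"]][[1]]
  within <- sm[["Error: Within"]][[1]]
  ss_tol <- 1e-10 * (sum(d$y^2) + 1)
  eff <- rbind(extract_effect(within, "w", ss_tol),
               extract_effect(between, "g", ss_tol),
               extract_effect(within, "w:g", ss_tol))
  eff$effect <- c(stimulus, group, paste0(stimulus, ":", group))
  ph <- NULL
  if (posthoc) {
    wide <- reshape_wide(d)
    lv <- levels(d$w)
    t_w <- t.test(wide[[lv[1]]], wide[[lv[2]]], paired = TRUE)
    ph_w <- data.frame(comparison = paste(lv[1], "vs", lv[2]),
                       estimate = unname(t_w$estimate),
                       p_raw = t_w$p.value, stringsAsFactors = FALSE)
    m <- rowMeans(wide[, lv, drop = FALSE])
    pt <- pairwise.t.test(m, wide$g, p.adjust.method = "none",
                          pool.sd = TRUE)$p.value
    cmp <- which(!is.na(pt), arr.ind = TRUE)
    ph_g <- data.frame(
      comparison = paste(rownames(pt)[cmp[, 1]], "vs",
                         colnames(pt)[cmp[, 2]]),
      estimate = tapply(m, wide$g, mean)[rownames(pt)[cmp[, 1]]] -
        tapply(m, wide$g, mean)[colnames(pt)[cmp[, 2]]],
      p_raw = pt[cmp], stringsAsFactors = FALSE)
    ph <- rbind(ph_w, ph_g)
    ph$p_bonferroni <- pmin(1, ph$p_raw * nrow(ph))
    rownames(ph) <- NULL
  }
  new_stat_result("mixed-design ANOVA", eff, ph)
}

reshape_wide <- function(d) {
  wide <- reshape(d[, c("s", "g", "w", "y")], idvar = c("s", "g"),
                  timevar = "w", direction = "wide")
  names(wide) <- sub("^y\\.", "", names(wide))
  wide
}

#' Two-way fully within-subject ANOVA (2 x k)
#'
#' Both factors vary within subject (e.g. rating studies with
#' Emotion x Stimulus designs). Fit via `aov` with
#' `Error(subject/(A*B))`; each effect is tested against its own
#' subject-by-effect interaction stratum.
#'
#' @param data Long data.frame with one value per subject x A x B cell.
#' @param value,a,b,subject Column names (`a`, `b` the within factors).
#' @return A `"stat_result"` with rows for `a`, `b`, `a:b`.
#' @export
rm_anova_2x3_within <- function(data, value = "value", a = "emotion",
                                b = "stimulus", subject = "subject") {
  d <- data.frame(y = data[[value]], A = factor(data[[a]]),
                  B = factor(data[[b]]), s = factor(data[[subject]]))
  if (anyNA(d)) stop("missing values in the design columns")
  tab <- table(d$s, d$A, d$B)
  if (any(tab != 1L)) stop("design must be complete: one value per cell")
  fit <- aov(y ~ A * B + Error(s / (A * B)), data = d)
  sm <- summary(fit)
  ss_tol <- 1e-10 * (sum(d$y^2) + 1)
  eff <- rbind(extract_effect(sm[["Error: s:A"]][[1]], "A", ss_tol),
               extract_effect(sm[["Error: s:B"]][[1]], "B", ss_tol),
               extract_effect(sm[["Error: s:A:B"]][[1]], "A:B", ss_tol))
  eff$effect <- c(a, b, paste0(a, ":", b))
  new_stat_result("repeated-measures ANOVA", eff)
}

#' One-way between-subject ANOVA
#'
#' @param values Numeric vector.
#' @param groups Grouping vector (>= 2 groups, each with >= 2 members).
#' @return A `"stat_result"` with the group effect and partial eta squared.
#' @export
one_way_anova <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least two groups")
  if (any(table(g) < 2L)) stop("each group needs at least two members")
  tab <- anova(lm(values ~ g))
  eff <- data.frame(effect = "group", df1 = tab$Df[1], df2 = tab$Df[2],
                    F = tab$`F value`[1], p = tab$`Pr(>F)`[1],
                    pes = tab$`Sum Sq`[1] / sum(tab$`Sum Sq`),
                    stringsAsFactors = FALSE)
  new_stat_result("one-way ANOVA", eff)
}

#' Paired t-test
#'
#' @param x,y Paired numeric vectors (length >= 2, non-degenerate
#'   differences).
#' @return List of class `"paired_t"`: `t`, `df`, `p` (two-sided),
#'   `mean_diff`, `n`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least two pairs")
  d <- x - y
  if (sd(d) == 0)
    stop("zero variance of the paired differences; t undefined")
  tt <- t.test(x, y, paired = TRUE)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, mean_diff = unname(tt$estimate),
                 n = length(x)),
            class = "paired_t")
}

#' Pearson chi-squared test of independence
#'
#' Uncorrected Pearson chi-squared on an r x c contingency table.
#'
#' @param counts Matrix of nonnegative counts with positive margins.
#' @return List of class `"chi2_result"`: `chi2`, `df`, `p`, `n`.
#' @examples
#' gender <- rbind(F = c(19, 16, 20), M = c(11, 14, 10))
#' chi2_independence(gender)$chi2  # 1.216
#' @export
chi2_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero row or column margin")
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  structure(list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value, n = sum(counts)),
            class = "chi2_result")
}
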