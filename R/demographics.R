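#' Summary statistic triple (mean, SD, n)
#' @param mean group mean.
#' @param sd group standard deviation (>= 0).
#' @param n group size (>= 2).
#' @return list of class `summary_stat`.
#' @export
summary_stat <- function(mean, sd, n) {
  if (n < 2) stop("n must be >= 2")
  if (sd < 0) stop("sd must be nonnegative")
  structure(list(mean = mean, sd = sd, n = n), class = "summary_stat")
}

#' Pooled two-sample t from summary statistics
#'
#' Student's pooled-variance t:
#' `sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`,
#' `t = (m1 - m2) / (sp * sqrt(1/n1 + 1/n2))`, `df = n1 + n2 - 2`.
#' This reproduces the demographics-table statistics computable from
#' published mean +/- SD rows without raw data.
#'
#' @param a,b `summary_stat` objects (or lists with mean, sd, n).
#' @return list with `t` and `df`.
#' @export
t_from_summary <- function(a, b) {
  df <- a$n + b$n - 2L
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  if (sp2 == 0) {
    if (a$mean == b$mean) return(list(t = 0, df = df))
    stop("zero pooled variance with unequal means")
  }
  list(t = (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n)), df = df)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Plain `sum((O - E)^2 / E)` without continuity correction, df = 1, with
#' the upper-tail chi-square p-value. Invariant to transposition.
#'
#' @param counts 2x2 nonnegative integer matrix.
#' @return list with `chi2`, `df`, `p`.
#' @export
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == 2)) stop("counts must be 2x2")
  if (any(counts < 0)) stop("counts must be nonnegative")
  rs <- rowSums(counts); cs <- colSums(counts); n <- sum(counts)
  if (any(rs == 0) || any(cs == 0)) stop("zero marginal")
  E <- outer(rs, cs) / n
  chi2 <- sum((counts - E)^2 / E)
  list(chi2 = chi2, df = 1L, p = pchisq(chi2, 1, lower.tail = FALSE))
}

#' Frequency as a percentage
#' @param k count (0 <= k <= n).
#' @param n total (> 0).
#' @return list with `percent` (exact) and `display` (2-dp rounded).
#' @export
frequency_percent <- function(k, n) {
  if (n <= 0) stop("n must be positive")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  pct <- 100 * k / n
  list(percent = pct, display = round(pct, 2))
}

#' Demographics table for a cohort
#'
#' Renders a demographics/clinical summary in the conventional two-column
#' (MDD, HC) layout: male frequency with chi-square, then mean +/- SD rows
#' with pooled t-tests, reporting per-variable n after listwise deletion
#' when a score is missing for some subjects.
#'
#' @param cohort a `limb_cohort`.
#' @param variables numeric metadata columns to summarize (besides sex).
#' @return data.frame, one row per variable.
#' @export
demographics_table <- function(cohort,
                               variables = intersect(
                                 c("age", "madrs", "qids"),
                                 names(cohort$subjects))) {
  s <- cohort$subjects
  mdd <- s[s$group == "MDD", ]; hc <- s[s$group == "HC", ]
  cs <- chi_square_2x2(rbind(c(sum(mdd$sex == "male"), sum(mdd$sex != "male")),
                             c(sum(hc$sex == "male"), sum(hc$sex != "male"))))
  rows <- list(data.frame(
    variable = "male_frequency",
    mdd = sprintf("%d, %.2f%%", sum(mdd$sex == "male"),
                  frequency_percent(sum(mdd$sex == "male"), nrow(mdd))$display),
    hc = sprintf("%d, %.2f%%", sum(hc$sex == "male"),
                 frequency_percent(sum(hc$sex == "male"), nrow(hc))$display),
    statistic = cs$chi2, df = cs$df, p = cs$p, stringsAsFactors = FALSE))
  for (v in variables) {
    a <- mdd[[v]][!is.na(mdd[[v]])]; b <- hc[[v]][!is.na(hc[[v]])]
    ts <- t_from_summary(summary_stat(mean(a), sd(a), length(a)),
                         summary_stat(mean(b), sd(b), length(b)))
    fmt <- function(x, tot) sprintf("%.2f ± %.2f%s", mean(x), sd(x),
                                    if (length(x) < tot)
                                      sprintf(" (%d)", length(x)) else "")
    rows[[v]] <- data.frame(
      variable = v, mdd = fmt(a, nrow(mdd)), hc = fmt(b, nrow(hc)),
      statistic = ts$t, df = ts$df, p = 2 * pt(-abs(ts$t), ts$df),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
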