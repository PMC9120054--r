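#' Partial Spearman correlation
#'
#' Rank-transforms `x` and `y` (average ranks for ties), residualizes both
#' rank vectors on an intercept plus the covariates by least squares, and
#' correlates the residuals. The p-value uses the t approximation with
#' `df = n - n_covariates - 2`. Listwise deletion is applied to incomplete
#' rows first. With no covariates this is plain Spearman's rho, and the
#' statistic is invariant under strictly monotone transforms of `x` or `y`.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix or `NULL`.
#' @return list with `rho`, `p`, `n_used`, `df`.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  keep <- !is.na(x) & !is.na(y) &
    (if (is.null(covariates)) TRUE else rowSums(is.na(covariates)) == 0)
  x <- x[keep]; y <- y[keep]
  cov <- if (is.null(covariates)) NULL else covariates[keep, , drop = FALSE]
  n <- length(x)
  if (n < 5) stop("fewer than 5 complete cases")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0) stop("constant x after ranking")
  if (sd(ry) == 0) stop("constant y after ranking")
  nq <- nuisance_q(cov, n)
  ex <- project_off(nq$Q, rx)
  ey <- project_off(nq$Q, ry)
  rho <- sum(ex * ey) / sqrt(sum(ex^2) * sum(ey^2))
  rho <- max(min(rho, 1), -1)
  df <- n - nq$p_nuis - 2L
  tval <- if (abs(rho) == 1) Inf else abs(rho) * sqrt(df / (1 - rho^2))
  list(rho = rho, p = 2 * pt(tval, df, lower.tail = FALSE), n_used = n,
       df = df)
}

#' Symptom associations of limbic subregion features
#'
#' Within the MDD group only, correlates each hippocampal (8) and amygdala
#' (12) subregion's AUC feature with a symptom score by partial Spearman
#' correlation, controlling by default for age, sex, the subregion's own
#' volume and previous antidepressant medication history. BH-FDR is applied
#' separately within the 8-test hippocampus family and the 12-test amygdala
#' family, per metric. Episode-duration associations are conventionally
#' reported uncorrected (`fdr = FALSE` leaves `q` as `NA` and labels rows).
#'
#' @param features feature table from [compute_nodal_features()].
#' @param cohort the `limb_cohort`.
#' @param score metadata column holding the score (`"madrs"`, `"qids"`,
#'   `"episode_duration"`).
#' @param covariates covariate names as in [compare_groups()].
#' @param metrics metrics to test.
#' @param q FDR level.
#' @param fdr apply family-wise BH correction (default `FALSE` for episode
#'   duration, `TRUE` otherwise).
#' @return data.frame with `region_index`, `region`, `metric`, `score`,
#'   `rho`, `p`, `q_fdr`, `n_used`, `family`, `uncorrected`.
#' @export
associate_limbic <- function(features, cohort, score = "madrs",
                             covariates = c("age", "sex", "volume",
                                            "medication_history"),
                             metrics = unique(features$metric), q = 0.05,
                             fdr = !identical(score, "episode_duration")) {
  if (!score %in% names(cohort$subjects))
    stop("score column not found in metadata: ", score)
  rt <- cohort$region_table
  limbic <- rt[rt$family != "none", , drop = FALSE]
  if (nrow(limbic) == 0)
    stop("region table has no limbic subregions; need the full parcellation")
  pat <- which(cohort$subjects$group == "MDD")
  y_all <- cohort$subjects[[score]][pat]
  out <- list()
  for (m in metrics) {
    fm <- feature_matrix(features, m, cohort)
    for (fam in unique(limbic$family)) {
      fr <- limbic[limbic$family == fam, , drop = FALSE]
      rows <- lapply(seq_len(nrow(fr)), function(i) {
        cov <- build_covariates(cohort, covariates,
                                region_name = fr$name[i], rows = pat)
        ps <- partial_spearman(fm[pat, fr$region_index[i] + 1L], y_all, cov)
        data.frame(region_index = fr$region_index[i], region = fr$name[i],
                   metric = m, score = toupper(score), rho = ps$rho,
                   p = ps$p, n_used = ps$n_used, family = fam,
                   stringsAsFactors = FALSE)
      })
      tab <- do.call(rbind, rows)
      tab$q_fdr <- if (fdr) fdr_bh(tab$p, q)$q_values else NA_real_
      tab$uncorrected <- !fdr
      out[[paste(m, fam)]] <- tab
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("region_index", "region", "metric", "score", "rho", "p", "q_fdr",
          "n_used", "family", "uncorrected")]
}
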