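# Residual-maker helpers for covariate-adjusted contrasts.
# X is the nuisance design (intercept + covariates); projecting both the
# feature and the group indicator off X (Frisch-Waugh-Lovell) reproduces
# the group coefficient t of the full linear model exactly, and lets the
# permutation loop run as a single matrix product.
nuisance_q <- function(covariates, n) {
  X <- cbind(rep(1, n), covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient covariate design")
  list(Q = qr.Q(qx), p_nuis = ncol(X) - 1L)  # covariate count excl. intercept
}

project_off <- function(Q, v) v - Q %*% crossprod(Q, v)

# squared norm, snapped to zero when it is numerical dust relative to the
# unprojected vector (a constant feature projects to ~1e-15 residuals)
sq_norm <- function(e, raw) {
  s <- sum(e^2)
  if (s <= 1e-20 * max(1, sum(raw^2))) 0 else s
}

t_from_residuals <- function(eg, ey, df) {
  seg <- sum(eg^2); sey <- sum(ey^2)
  if (seg <= 0 || sey <= 0) return(0)
  r <- sum(eg * ey) / sqrt(seg * sey)
  r <- max(min(r, 1), -1)
  if (abs(r) == 1) return(sign(r) * Inf)
  r * sqrt(df / (1 - r^2))
}

#' Covariate-adjusted two-sample contrast (ANCOVA-style)
#'
#' Fits `feature ~ intercept + group + covariates` by least squares. The
#' test statistic is the group-coefficient estimate divided by its standard
#' error, with `df = n - n_covariates - 2`; Cohen's d is the adjusted
#' group-mean difference divided by the residual standard deviation. With no
#' covariates this reduces exactly to the classic pooled-variance two-sample
#' t-test. The group indicator is 1 for MDD, so a negative t means MDD < HC
#' on the adjusted means.
#'
#' @param feature numeric vector, one value per subject.
#' @param group character/factor with levels `MDD` and `HC`.
#' @param covariates numeric matrix (subjects x covariates) or `NULL`.
#' @return list with `t`, `df`, `cohen_d`.
#' @export
adjusted_group_t <- function(feature, group, covariates = NULL) {
  g <- as.integer(group == "MDD")
  if (sum(g) < 3 || sum(1 - g) < 3) stop("need at least 3 subjects per group")
  n <- length(feature)
  nq <- nuisance_q(covariates, n)
  ey <- project_off(nq$Q, feature)
  if (sq_norm(ey, feature) == 0) ey <- ey * 0
  eg <- project_off(nq$Q, g)
  df <- n - nq$p_nuis - 2L
  tval <- t_from_residuals(eg, ey, df)
  seg <- sum(eg^2)
  beta <- if (seg > 0) sum(eg * ey) / seg else 0
  rss <- sum((ey - beta * eg)^2)
  sigma <- sqrt(rss / df)
  d <- if (sigma > 0) beta / sigma else 0
  list(t = tval, df = df, cohen_d = d)
}

#' Permutation p-value for the adjusted group contrast
#'
#' Builds the null distribution by shuffling group labels while covariates
#' stay bound to their subjects, recomputing the adjusted t each repetition.
#' The default reported p is two-sided with the add-one correction,
#' `(1 + #\{|t_perm| >= |t_obs|\}) / (1 + n_perm)`, so `p >= 1/(n_perm+1)`.
#' The literal one-sided fraction of permuted t values smaller than the
#' observed t is additionally returned as `frac_smaller` for completeness;
#' read literally that quantity grows with the effect size and is not a
#' significance measure.
#'
#' @inheritParams adjusted_group_t
#' @param n_perm number of label shuffles (>= 1).
#' @param seed integer seed for the shuffle stream.
#' @return list with `p` (two-sided add-one), `frac_smaller`, `t_obs`, `df`.
#' @export
permutation_p <- function(feature, group, covariates = NULL, n_perm = 1000,
                          seed = 1) {
  if (!is.numeric(n_perm) || n_perm < 1) stop("n_perm must be >= 1")
  g <- as.integer(group == "MDD")
  if (sum(g) < 3 || sum(1 - g) < 3) stop("need at least 3 subjects per group")
  n <- length(feature)
  nq <- nuisance_q(covariates, n)
  ey <- project_off(nq$Q, feature)
  if (sq_norm(ey, feature) == 0) ey <- ey * 0
  df <- n - nq$p_nuis - 2L
  t_obs <- t_from_residuals(project_off(nq$Q, g), ey, df)
  G <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) g[sample.int(n)], numeric(n))
  })
  EG <- G - nq$Q %*% crossprod(nq$Q, G)
  seg <- colSums(EG^2); sey <- sum(ey^2)
  num <- as.numeric(crossprod(EG, ey))
  r <- ifelse(seg > 0 & sey > 0, num / sqrt(seg * sey), 0)
  r <- pmax(pmin(r, 1), -1)
  t_perm <- ifelse(abs(r) == 1, sign(r) * Inf, r * sqrt(df / (1 - r^2)))
  list(p = (1 + sum(abs(t_perm) >= abs(t_obs))) / (1 + n_perm),
       frac_smaller = mean(t_perm < t_obs),
       t_obs = t_obs, df = df)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure: adjusted value for the p ranked `i` of `m` is
#' `min_{j >= i} p_(j) * m / j`, clamped at 1 (monotone enforcement).
#' Discoveries are tests with adjusted value at most `q`.
#'
#' @param p_values vector of p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return list with `q_values` (adjusted p, original order) and
#'   `discoveries` (logical).
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p_values)
  ord <- order(p_values)
  adj <- p_values[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  qv <- numeric(m)
  qv[ord] <- adj
  list(q_values = qv, discoveries = qv <= q)
}

# Assemble the covariate matrix for one region from the cohort metadata.
# `covariates` names a subset of {age, sex, volume, medication_history};
# "volume" resolves to the region's own volume column.
build_covariates <- function(cohort, covariates, region_name = NULL,
                             rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(cohort$subjects))
  s <- cohort$subjects[rows, , drop = FALSE]
  cols <- list()
  for (cv in covariates) {
    cols[[cv]] <- switch(cv,
      age = s$age,
      sex = as.numeric(s$sex == "male"),
      medication_history = s$medication_history,
      volume = {
        v <- region_volumes(cohort, region_name)[rows]
        if (all(is.na(v)))
          stop(sprintf("covariate 'volume' requested but no volume column for region '%s'",
                       region_name))
        v
      },
      stop("unknown covariate: ", cv))
  }
  if (!length(cols)) return(NULL)
  do.call(cbind, cols)
}

#' Group comparison of nodal features across all regions
#'
#' For each metric and each region, runs the covariate-adjusted contrast
#' ([adjusted_group_t()]) and its permutation test ([permutation_p()]), then
#' applies BH-FDR within that metric's family of `N` region tests (families
#' are never pooled across metrics). The `volume` covariate resolves to each
#' region's own volume. Subjects with a missing covariate value are dropped
#' listwise per region, with the count logged. Per-region random streams are
#' derived deterministically from `(seed, region_index, metric)` so results
#' do not depend on execution order.
#'
#' @param features feature table from [compute_nodal_features()].
#' @param cohort the `limb_cohort`.
#' @param covariates covariate names; default `c("age","sex","volume")`.
#' @param n_perm permutations per region (default 1000).
#' @param seed master seed.
#' @param q FDR level.
#' @param metrics metrics to test (defaults to those present in `features`).
#' @param p_source which p-value feeds the FDR step: the permutation p
#'   (default) or the parametric t p-value. Note the permutation p is
#'   floored at `1/(n_perm + 1)`, so a lone strong effect cannot reach
#'   `q <= 0.05` over 98 tests unless `n_perm` is large or several regions
#'   hit the floor together; the parametric source has no such floor.
#' @return data.frame with columns `region_index`, `region`, `metric`, `t`,
#'   `df`, `cohen_d`, `p_perm`, `q_fdr`, `direction`.
#' @export
compare_groups <- function(features, cohort,
                           covariates = c("age", "sex", "volume"),
                           n_perm = 1000, seed = 1, q = 0.05,
                           metrics = unique(features$metric),
                           p_source = c("perm", "param")) {
  p_source <- match.arg(p_source)
  rt <- cohort$region_table
  out <- list()
  for (m in metrics) {
    fm <- feature_matrix(features, m, cohort)
    rows <- lapply(seq_len(nrow(rt)), function(ri) {
      rname <- rt$name[ri]
      y <- fm[, ri]
      cov <- build_covariates(cohort, covariates, region_name = rname)
      keep <- !is.na(y) & (if (is.null(cov)) TRUE else rowSums(is.na(cov)) == 0)
      if (sum(!keep) > 0)
        log_msg("%s/%s: dropped %d subjects with missing data", m, rname,
                sum(!keep))
      gt <- adjusted_group_t(y[keep], cohort$subjects$group[keep],
                             if (is.null(cov)) NULL else cov[keep, , drop = FALSE])
      pp <- permutation_p(y[keep], cohort$subjects$group[keep],
                          if (is.null(cov)) NULL else cov[keep, , drop = FALSE],
                          n_perm = n_perm,
                          seed = derive_seed(seed, rt$region_index[ri], m))
      data.frame(region_index = rt$region_index[ri], region = rname,
                 metric = m, t = gt$t, df = gt$df, cohen_d = gt$cohen_d,
                 p_perm = pp$p,
                 p_param = 2 * pt(-abs(gt$t), gt$df),
                 direction = if (gt$t < 0) "MDD<HC" else "MDD>HC",
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    fdr <- fdr_bh(if (p_source == "perm") tab$p_perm
                  else pmax(tab$p_param, .Machine$double.xmin), q)
    tab$q_fdr <- fdr$q_values
    out[[m]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("region_index", "region", "metric", "t", "df", "cohen_d",
          "p_perm", "p_param", "q_fdr", "direction")]
}

#' Plain two-sample t-tests of limbic subregion volumes
#'
#' Pooled-variance t-test per limbic subregion volume, MDD versus HC,
#' without covariates — a check that connectivity differences are not driven
#' by volume differences. Subjects missing a region's volume are dropped
#' listwise (df reflects the reduced n, which is logged).
#'
#' @param cohort the `limb_cohort` (volume columns required).
#' @return data.frame with `region_index`, `region`, `t`, `df`, `p`, `n_used`.
#' @export
compare_volumes <- function(cohort) {
  rt <- cohort$region_table
  limbic <- rt[rt$family != "none", , drop = FALSE]
  if (nrow(limbic) == 0) stop("region table has no limbic subregions")
  g <- cohort$subjects$group
  rows <- lapply(seq_len(nrow(limbic)), function(i) {
    v <- region_volumes(cohort, limbic$name[i])
    keep <- !is.na(v)
    if (all(!keep)) stop("volumes missing for region ", limbic$name[i])
    if (sum(!keep) > 0)
      log_msg("volumes/%s: dropped %d subjects", limbic$name[i], sum(!keep))
    a <- v[keep & g == "MDD"]; b <- v[keep & g == "HC"]
    ts <- t_from_summary(summary_stat(mean(a), sd(a), length(a)),
                         summary_stat(mean(b), sd(b), length(b)))
    data.frame(region_index = limbic$region_index[i], region = limbic$name[i],
               t = ts$t, df = ts$df,
               p = 2 * pt(-abs(ts$t), ts$df), n_used = length(a) + length(b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exploratory one-sided edge t-tests around a node
#'
#' For one region, compares the raw streamline count of each of its edges
#' between groups with a one-sided pooled t-test and flags `p < 0.05`
#' uncorrected. Explicitly exploratory: the output carries an
#' `uncorrected = TRUE` column and no FDR adjustment.
#'
#' @param node region index (0-based) of the seed node.
#' @param cohort the `limb_cohort`.
#' @param side `"less"` tests MDD < HC, `"greater"` tests MDD > HC.
#' @param alpha flag threshold (default 0.05).
#' @return data.frame with `neighbor_index`, `neighbor`, `t`, `df`,
#'   `p_uncorrected`, `flagged`, `uncorrected`.
#' @export
edge_ttests <- function(node, cohort, side = c("less", "greater"),
                        alpha = 0.05) {
  side <- match.arg(side)
  rt <- cohort$region_table
  if (!node %in% rt$region_index) stop("invalid node index: ", node)
  i <- node + 1L
  g <- cohort$subjects$group
  E <- vapply(cohort$matrices, function(W) W[i, ], numeric(nrow(rt)))
  rows <- lapply(setdiff(seq_len(nrow(rt)), i), function(j) {
    a <- E[j, g == "MDD"]; b <- E[j, g == "HC"]
    ts <- t_from_summary(summary_stat(mean(a), sd(a), length(a)),
                         summary_stat(mean(b), sd(b), length(b)))
    p <- if (side == "less") pt(ts$t, ts$df) else pt(ts$t, ts$df,
                                                     lower.tail = FALSE)
    data.frame(neighbor_index = rt$region_index[j], neighbor = rt$name[j],
               t = ts$t, df = ts$df, p_uncorrected = p, flagged = p < alpha,
               uncorrected = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
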