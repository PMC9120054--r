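test_that("adjusted contrast reduces to the pooled two-sample t", {
  set.seed(21)
  y <- c(rnorm(10, 1), rnorm(12, 0))
  g <- rep(c("MDD", "HC"), c(10, 12))
  res <- adjusted_group_t(y, g)
  tt <- stats::t.test(y[g == "MDD"], y[g == "HC"], var.equal = TRUE)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$df, 20)
  # classic Cohen's d = mean difference / pooled SD
  sp <- sqrt(((10 - 1) * var(y[g == "MDD"]) + (12 - 1) * var(y[g == "HC"])) / 20)
  expect_equal(res$cohen_d, (mean(y[g == "MDD"]) - mean(y[g == "HC"])) / sp,
               tolerance = 1e-12)
})

test_that("adjusted contrast matches the normal-equations oracle", {
  set.seed(22)
  n <- 80
  g <- rep(c("MDD", "HC"), each = 40)
  covs <- cbind(age = rnorm(n, 40, 10), sex = rbinom(n, 1, 0.5))
  # confounded feature: depends on age and weakly on group
  y <- 0.05 * covs[, "age"] + 0.3 * (g == "MDD") + rnorm(n)
  res <- adjusted_group_t(y, g, covs)
  bf <- bf_ancova_t(y, as.integer(g == "MDD"), covs)
  expect_equal(res$t, bf$t, tolerance = 1e-10)
  expect_equal(res$df, bf$df)
  expect_equal(res$cohen_d, bf$d, tolerance = 1e-10)
  # and the lm route agrees too
  fit <- summary(lm(y ~ g2 + covs, data = list(g2 = as.integer(g == "MDD"))))
  expect_equal(res$t, fit$coefficients["g2", "t value"], tolerance = 1e-10)
})

test_that("degenerate contrasts behave as specified", {
  g <- rep(c("MDD", "HC"), each = 5)
  res <- adjusted_group_t(rep(1, 10), g)
  expect_equal(res$t, 0)
  expect_equal(res$cohen_d, 0)
  expect_error(adjusted_group_t(rnorm(4), rep(c("MDD", "HC"), c(2, 2))),
               "3 subjects")
  covs <- cbind(a = 1:10, b = 2 * (1:10))   # collinear
  expect_error(adjusted_group_t(rnorm(10), g, covs), "rank-deficient")
})

test_that("permutation t matches the full-model t and is reproducible", {
  set.seed(30)
  n <- 40
  g <- rep(c("MDD", "HC"), each = 20)
  covs <- cbind(rnorm(n), rbinom(n, 1, 0.5))
  y <- rnorm(n) + 0.5 * (g == "MDD")
  pp <- permutation_p(y, g, covs, n_perm = 100, seed = 4)
  expect_equal(pp$t_obs, adjusted_group_t(y, g, covs)$t, tolerance = 1e-10)
  pp2 <- permutation_p(y, g, covs, n_perm = 100, seed = 4)
  expect_identical(pp, pp2)
  expect_gte(pp$p, 1 / 101)
  # two-sided default is invariant to which group is labeled MDD
  gswap <- ifelse(g == "MDD", "HC", "MDD")
  pp3 <- permutation_p(y, gswap, covs, n_perm = 100, seed = 4)
  expect_equal(pp3$p, pp$p)
  # constant feature: p = 1 under the add-one definition
  expect_equal(permutation_p(rep(2, n), g, covs, n_perm = 50, seed = 1)$p, 1)
})

test_that("Monte-Carlo permutation p approaches the exhaustive p at n=3+3", {
  set.seed(31)
  y <- c(5.1, 4.2, 6.3, 1.0, 2.2, 0.8)
  g <- rep(c("MDD", "HC"), each = 3)
  p_exh <- bf_exhaustive_perm_p(y, g)        # over all 20 assignments
  pp <- permutation_p(y, g, n_perm = 4000, seed = 7)
  # add-one MC estimate within 3 binomial SEs of the exhaustive value
  se <- sqrt(p_exh * (1 - p_exh) / 4000)
  expect_lt(abs(pp$p - p_exh), 3 * se + 1 / 4001)
})

test_that("BH-FDR matches the step-up definition and p.adjust", {
  r <- fdr_bh(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(r$discoveries))
  expect_equal(fdr_bh(0.03)$q_values, 0.03)
  expect_error(fdr_bh(c(0.1, 0)), "in \\(0, 1\\]")
  expect_error(fdr_bh(c(0.1, 1.2)), "in \\(0, 1\\]")
  set.seed(40)
  for (i in 1:20) {
    p <- runif(sample(3:60, 1))
    r <- fdr_bh(p)
    expect_equal(r$q_values, bf_bh(p), tolerance = 1e-12)
    expect_equal(r$q_values, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    # discoveries grow with q
    expect_true(all(fdr_bh(p, 0.05)$discoveries <= fdr_bh(p, 0.2)$discoveries))
  }
})

test_that("compare_groups recovers a planted strength deficit", {
  co <- make_test_cohort(n_nodes = 24, n_mdd = 12, n_hc = 12, seed = 55,
                         deficit_nodes = 7L, delta = 0.25)
  feats <- compute_nodal_features(co, short_grid(), "strength")
  res <- compare_groups(feats, co, n_perm = 200, seed = 3)
  top <- res[which.max(abs(res$t)), ]
  expect_equal(top$region_index, 7)
  expect_equal(top$direction, "MDD<HC")
  expect_true(all(res$p_perm >= 1 / 201))
  # parametric p source lets a lone strong effect pass the BH floor
  res_param <- compare_groups(feats, co, n_perm = 200, seed = 3,
                              p_source = "param")
  expect_true(res_param$q_fdr[res_param$region_index == 7] < 0.05)
})

test_that("identical groups give null statistics everywhere", {
  co <- make_test_cohort(n_nodes = 10, n_mdd = 4, n_hc = 4, seed = 8)
  # copy MDD matrices onto HC subjects: zero group signal by construction
  for (i in 1:4) co$matrices[[4 + i]] <- co$matrices[[i]]
  s <- co$subjects
  s$age[5:8] <- s$age[1:4]; s$sex[5:8] <- s$sex[1:4]
  co$subjects <- s
  feats <- compute_nodal_features(co, short_grid(), "strength")
  res <- compare_groups(feats, co, covariates = c("age", "sex"),
                        n_perm = 100, seed = 2)
  expect_true(all(abs(res$t) < 1e-8))
  expect_true(all(abs(res$cohen_d) < 1e-8))
})

test_that("volume comparisons are plain pooled t-tests with listwise n", {
  co <- make_test_cohort(n_nodes = 98, n_mdd = 5, n_hc = 5, seed = 77)
  # equalize volumes across groups for one region
  vcol <- paste0("vol_", co$region_table$name[co$region_table$family != "none"][1])
  co$subjects[[vcol]] <- 1000
  res <- compare_volumes(co)
  expect_equal(nrow(res), 20)            # 8 hippocampal + 12 amygdala
  expect_equal(res$t[1], 0)
  expect_equal(res$df, res$n_used - 2)

  # a planted volume reduction at right CA3/4 (index 89) is the top |t|
  co2 <- make_test_cohort(n_nodes = 98, n_mdd = 20, n_hc = 20, seed = 78,
                          deficit_nodes = 89L, delta = 0.2,
                          vol_strength_coupling = 1)
  res2 <- compare_volumes(co2)
  expect_equal(res2$region_index[which.max(abs(res2$t))], 89)

  # a missing volume reduces df
  co$subjects[[paste0("vol_", res$region[2])]][1] <- NA
  res3 <- compare_volumes(co)
  expect_equal(res3$df[2], 7)
})

test_that("edge t-tests flag planted deficits only in the stated direction", {
  reps <- 0
  for (seed in 1:5) {
    co <- make_test_cohort(n_nodes = 20, n_mdd = 30, n_hc = 30, seed = seed)
    # plant a 30% reduction on 5 designated edges of node 4 in patients
    planted <- c(1, 7, 10, 15, 19)
    for (i in which(co$subjects$group == "MDD")) {
      co$matrices[[i]][5, planted] <- co$matrices[[i]][5, planted] * 0.7
      co$matrices[[i]][planted, 5] <- co$matrices[[i]][5, planted]
    }
    res <- edge_ttests(4L, co, side = "less")
    hit <- res$neighbor_index[res$flagged]
    reps <- reps + (sum((planted - 1) %in% hit) >= 3)
    # opposite side must not flag the planted deficit
    res_g <- edge_ttests(4L, co, side = "greater")
    expect_false(any((planted - 1) %in% res_g$neighbor_index[res_g$flagged]))
    expect_true(all(res$uncorrected))
  }
  expect_gte(reps, 4)   # majority of planted edges recovered in most runs
  co <- make_test_cohort(n_nodes = 10, n_mdd = 3, n_hc = 3, seed = 1)
  expect_error(edge_ttests(99L, co), "invalid node")
})
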