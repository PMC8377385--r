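test_that("Harrell's C matches pair enumeration, perfect ordering, and antisymmetry", {
  # risk reproducing the event order exactly, no censoring
  time <- c(5, 3, 9, 1, 7)
  risk <- -time
  expect_equal(harrell_cindex(risk, time, rep(1, 5)), 1)

  # 6-sample cohort with one censored record: brute-force oracle
  time2 <- c(2, 4, 3, 8, 6, 5)
  event2 <- c(1, 1, 0, 1, 1, 1)
  risk2 <- c(0.9, 0.1, 0.5, 0.2, 0.2, 0.8)
  expect_equal(harrell_cindex(risk2, time2, event2),
               oracle_cindex_pairs(risk2, time2, event2),
               tolerance = 1e-12)

  # negating the risk maps C -> 1 - C when no risk ties exist
  risk3 <- c(0.9, 0.1, 0.5, 0.25, 0.2, 0.8)
  expect_equal(harrell_cindex(-risk3, time2, event2),
               1 - harrell_cindex(risk3, time2, event2), tolerance = 1e-12)
  expect_error(harrell_cindex(risk2, time2, rep(0, 6)), "no events")
})

test_that("variant comparison reproduces exact rank-sum p-values", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  p <- compare_variants(m)
  expect_equal(p["a", "b"], 0.1, tolerance = 1e-12)  # 2 * 1/C(6,3)... = 2/20
  # identical distributions sit at the null center
  m2 <- cbind(a = 1:10 / 10, b = 1:10 / 10)
  expect_equal(compare_variants(m2)["a", "b"], 1)
  expect_error(compare_variants(m[0, , drop = FALSE]), "empty")
})

test_that("Cox fits match a grid-search partial-likelihood oracle and behave under rescaling", {
  time <- c(1.1, 2.3, 3.7, 4.1, 5.9, 6.2, 7.8, 9.4)
  event <- c(1, 1, 1, 0, 1, 1, 0, 1)
  x <- c(1, 0, 1, 1, 0, 1, 0, 0)
  fit <- cox_fit(x, time, event)
  grid <- seq(-4, 4, by = 1e-4)
  ll <- vapply(grid, oracle_cox_loglik, 0, x = x, time = time,
               event = event)
  expect_equal(fit$beta, grid[which.max(ll)], tolerance = 1e-4)
  expect_equal(fit$hr, exp(fit$beta), tolerance = 1e-12)
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)

  # covariate rescaled by c: beta scales by 1/c, Wald p unchanged
  fit10 <- cox_fit(x * 10, time, event)
  expect_equal(fit10$beta, fit$beta / 10, tolerance = 1e-8)
  expect_equal(fit10$p, fit$p, tolerance = 1e-8)

  # null covariate: HR near 1, p near 1
  withr::with_seed(2, {
    t0 <- rexp(200); e0 <- rbinom(200, 1, 0.8); g <- rep(0:1, 100)
  })
  fit0 <- cox_fit(g, t0, e0)
  expect_lt(abs(fit0$beta), 0.3)
  expect_gt(fit0$p, 0.05)

  expect_error(cox_fit(rep(1, 8), time, event), "constant")

  # multivariate fit returns one row per term with factor reference coding
  df <- data.frame(x = x, grp = rep(c("big", "big", "small", "big"), 2))
  mv <- cox_fit(df, time, event, multivariate = TRUE)
  expect_equal(mv$model, rep("multivariate", 2))
  expect_true(any(grepl("small", mv$term)))  # "big" (modal) is reference
})

test_that("monotone-likelihood Cox fits are flagged rather than silent", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- rep(1, 6)
  x <- c(1, 1, 1, 0, 0, 0)  # perfect separation of early vs late deaths
  fit <- suppressWarnings(cox_fit(x, time, event))
  expect_false(fit$converged)
})

test_that("median-split KM uses the <=-median rule and the log-rank oracle", {
  # tie rule on [1, 2, 3, 4]: interpolated median 2.5, low = {1, 2}
  vals <- c(1, 2, 3, 4)
  km <- km_median_split(vals, c(5, 6, 7, 8), c(1, 1, 1, 1))
  expect_equal(km$median, 2.5)
  expect_equal(as.character(km$groups), c("low", "low", "high", "high"))

  # identical event patterns in the groups: statistic 0, p = 1
  km0 <- km_median_split(c(1, 1, 1, 2, 2, 2), rep(c(3, 5, 8), 2),
                         rep(1, 6))
  expect_equal(km0$chisq, 0, tolerance = 1e-12)
  expect_equal(km0$p, 1)

  # 10-sample staggered toy matches the observed-vs-expected formula
  time <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 1)
  vals2 <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  km2 <- km_median_split(vals2, time, event)
  expect_equal(km2$chisq,
               oracle_logrank_chisq(km2$groups, time, event),
               tolerance = 1e-9)

  # curves start at 1, never increase, and end at the empirical fraction
  # when no censoring occurs
  km3 <- km_median_split(vals2, time, rep(1, 10))
  for (g in c("low", "high")) {
    s <- km3$curves$surv[km3$curves$group == g]
    expect_true(all(diff(s) <= 1e-12))
    expect_lte(s[1], 1)
    expect_equal(s[length(s)], 0)
  }
  expect_error(km_median_split(rep(1, 4), 1:4, rep(1, 4)), "identical")
})

test_that("chi-squared contingency test matches the direct formula", {
  flat <- matrix(10, 2, 2)
  r <- chisq_table(flat)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)

  diag40 <- rbind(c(20, 0), c(0, 20))
  r2 <- chisq_table(diag40)
  expect_equal(r2$statistic, 40, tolerance = 1e-12)  # sum (O-E)^2/E, E = 10
  expect_lt(r2$p, 1e-9)

  # invariant under row/column permutation
  tab <- rbind(c(12, 5, 9), c(3, 14, 7))
  expect_equal(chisq_table(tab[, c(3, 1, 2)])$statistic,
               chisq_table(tab)$statistic, tolerance = 1e-12)
  expect_equal(chisq_table(tab[2:1, ])$statistic,
               chisq_table(tab)$statistic, tolerance = 1e-12)

  expect_error(chisq_table(rbind(c(0, 0), c(1, 2))), "marginal")
  expect_error(chisq_table(rbind(c(-1, 2), c(1, 2))), "non-negative")
})

test_that("repeated-split survival forests separate informative from null variants", {
  spec <- demo_cohort_spec(seed = 17, n_per_class = 60, n_pairs = 8,
                           n_effect_pairs = 2, beta = 1.2)
  co <- simulate_cohort(spec)
  f <- edge_transform(log2_zscore(co$expression, log2 = FALSE), co$network)
  variants <- list(
    Clinical = list(features = character(), covariates = "stage"),
    Edges = list(features = edge_ids(co$network), covariates = character()))
  ci <- mc_cv_cindex(co$clinical, variants, features = f, n_iter = 8,
                     seed = 3, num_trees = 300)
  expect_equal(dim(ci), c(8L, 2L))
  expect_true(all(ci >= 0 & ci <= 1))
  expect_gt(mean(ci[, "Edges"]), mean(ci[, "Clinical"]))

  # identical seed reproduces the identical C-index table
  ci2 <- mc_cv_cindex(co$clinical, variants, features = f, n_iter = 8,
                      seed = 3, num_trees = 300)
  expect_identical(ci, ci2)

  # cv-safe mode recomputes features per split and stays in range
  ci3 <- mc_cv_cindex(co$clinical, variants,
                      expression = log2_zscore(co$expression, log2 = FALSE),
                      network = co$network, mode = "cv-safe", n_iter = 3,
                      seed = 3, num_trees = 200)
  expect_true(all(ci3 >= 0 & ci3 <= 1))
  expect_error(mc_cv_cindex(co$clinical, variants, features = f,
                            n_iter = 2, train_fraction = 1.2),
               "train_fraction")
})
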