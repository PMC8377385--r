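test_that("cohort specifications are validated", {
  net <- toy_network(3)
  expect_error(cohort_spec(net, 2, 10), ">= 3 samples")
  expect_error(cohort_spec(net, 10, 10, censor_fraction = 1), "censor_fraction")
  expect_error(cohort_spec(net, 10, 10,
                           edge_effects = data.frame(kinase = "K01",
                                                     substrate = "S01",
                                                     rho1 = 1, rho2 = 0)),
               "\\(-1, 1\\)")
  expect_error(cohort_spec(net, 10, 10,
                           edge_effects = data.frame(kinase = "K09",
                                                     substrate = "S09",
                                                     rho1 = 0, rho2 = 0)),
               "not in network")
  # overlapping planted pairs are rejected, not silently overwritten
  expect_error(cohort_spec(
    ks_network(c("K01", "K01"), c("S01", "S02")), 10, 10,
    edge_effects = data.frame(kinase = c("K01", "K01"),
                              substrate = c("S01", "S02"),
                              rho1 = c(0.5, 0.5), rho2 = c(0.5, 0.5))),
    "share gene")
  expect_error(cohort_spec(net, 10, 10,
                           survival_betas = data.frame(feature = "NOPE",
                                                       beta = 1)),
               "unknown")
})

test_that("expression generation is deterministic and recovers planted structure", {
  spec <- demo_cohort_spec(seed = 101, n_per_class = 500, n_pairs = 6,
                           n_effect_pairs = 1, rho = 0.8, delta = 0.5)
  e1 <- generate_expression(spec)
  e2 <- generate_expression(spec)
  expect_identical(e1$values, e2$values)

  # planted correlations: +0.8 in class 1, -0.8 in class 2, within 0.08
  k1 <- e1$class == "C1"
  r1 <- cor(e1$values["KIN001", k1], e1$values["SUB001", k1])
  r2 <- cor(e1$values["KIN001", !k1], e1$values["SUB001", !k1])
  expect_lt(abs(r1 - 0.8), 0.08)
  expect_lt(abs(r2 + 0.8), 0.08)

  # planted mean shift on the flagged node gene
  g <- spec$node_effects$gene
  expect_lt(abs(mean(e1$values[g, !k1]) - mean(e1$values[g, k1]) - 0.5),
            0.2)
})

test_that("a null cohort yields the nominal t-test rejection rate", {
  # 200 genes, no planted effects: the alpha = 0.05 prefilter should keep
  # roughly 5% of genes (binomial error band)
  net <- ks_network(sprintf("K%03d", 1:100), sprintf("S%03d", 1:100))
  spec <- cohort_spec(net, 100, 100, seed = 73)
  e <- generate_expression(spec)
  kept <- ttest_prefilter(e$values, e$class, alpha = 0.05)
  rate <- length(kept) / nrow(e$values)
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / 200))
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("null hazards give all-events cohorts with chance-level concordance", {
  net <- toy_network(4)
  spec <- cohort_spec(net, 500, 500, censor_fraction = 0, seed = 5)
  co <- simulate_cohort(spec)
  expect_true(all(co$clinical$event == 1))
  expect_true(all(co$clinical$time > 0))
  ci <- harrell_cindex(co$expression$values["K01", co$clinical$sample_id],
                       co$clinical$time, co$clinical$event)
  expect_lt(abs(ci - 0.5), 0.05)
})

test_that("censoring calibration hits the requested fraction", {
  for (target in c(0.1, 0.3, 0.5)) {
    spec <- demo_cohort_spec(seed = 19, n_per_class = 300,
                             censor_fraction = target)
    co <- simulate_cohort(spec)
    expect_lt(abs(mean(co$clinical$event == 0) - target), 0.03)
  }
})

test_that("univariate Cox recovers a planted node hazard", {
  net <- toy_network(5)
  spec <- cohort_spec(net, 500, 500,
                      survival_betas = data.frame(feature = "K01", beta = 1),
                      censor_fraction = 0.2, seed = 47)
  co <- simulate_cohort(spec)
  z <- log2_zscore(co$expression, log2 = FALSE)
  fit <- cox_fit(z$values["K01", co$clinical$sample_id],
                 co$clinical$time, co$clinical$event)
  expect_lt(abs(fit$beta - 1), 0.15)
})

test_that("written cohorts round-trip losslessly and record the truth", {
  spec <- demo_cohort_spec(seed = 3, n_per_class = 20, n_pairs = 4,
                           n_effect_pairs = 1)
  co <- simulate_cohort(spec)
  dir <- tempfile("cohort")
  paths <- write_cohort(co, dir)
  expect_equal(read_expression(paths[["expression"]]),
               co$expression$values)
  clin <- read_clinical(paths[["clinical"]])
  expect_equal(clin$sample_id, co$clinical$sample_id)
  expect_equal(clin$time, co$clinical$time, tolerance = 1e-12)
  expect_equal(clin$event, co$clinical$event)
  net <- read_network(paths[["network"]])
  expect_equal(as.data.frame(net), as.data.frame(co$network))

  truth <- yaml::read_yaml(paths[["truth"]])
  expect_equal(truth$edge_effects[[1]]$kinase, "KIN001")
  expect_equal(truth$survival_betas[[1]]$feature, "KIN001-SUB001")
  expect_equal(truth$seed, 3)

  expect_error(write_cohort(co, ""), "directory")
})
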