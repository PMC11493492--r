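lambda_statistic <- function(genotype, environment, topology = "truncate") {
  function(cohort, trials) {
    growth_rate(build_matrix(
      estimate_vital_rates(cohort, trials, genotype, environment),
      topology = topology))
  }
}

test_that("bias-corrected interval follows the BC formula", {
  # symmetric case: z0 = 0 and BC reduces to the plain percentile interval
  bc <- bc_interval(1:100, 50.5)
  expect_equal(bc$z0, 0)
  expect_equal(c(bc$ci_low, bc$ci_high),
               unname(stats::quantile(1:100, c(0.025, 0.975))))

  # shifted case: z0 = qnorm(0.6), frozen adjusted levels
  bc2 <- bc_interval(1:100, 60.5)
  expect_equal(bc2$z0, stats::qnorm(0.6))
  expect_equal(bc2$levels, c(0.0730744, 0.9931810), tolerance = 1e-5)

  # all replicates below the point estimate: degenerate, not fatal
  bc3 <- bc_interval(1:100, 200)
  expect_true(bc3$degenerate)
  expect_true(is.infinite(bc3$z0))
  expect_lte(bc3$ci_low, bc3$ci_high)

  # zero acceleration reproduces BC; nonzero shifts the levels
  bc4 <- bc_interval(1:100, 60.5, acceleration = 0)
  expect_equal(bc4$levels, bc2$levels)
  bc5 <- bc_interval(1:100, 60.5, acceleration = 0.05)
  expect_false(isTRUE(all.equal(bc5$levels, bc2$levels)))
})

test_that("a cohort of identical individuals gives a width-zero interval", {
  cohort <- tiny_cohort()
  # make all individuals identical: everyone survives, flowers, 10 seeds
  for (cl in grep("^(alive_|flowered_)", names(cohort), value = TRUE)) {
    cohort[[cl]] <- 1L
  }
  cohort$seeds_y1 <- 10L
  cohort$seeds_y2 <- 10L
  attr(cohort, "seasons") <- c("S1", "W1", "S2")
  trials <- tiny_trials()
  trials$established <- 1L  # identical pots too
  res <- stratified_bootstrap(cohort, trials,
                              lambda_statistic("low", "low"),
                              B = 50, seed = 1)
  expect_equal(res$ci_low, res$ci_high)
  expect_true(all(res$replicates == res$point_estimate))
  expect_equal(res$n_degenerate, 0)
})

test_that("bootstrap is deterministic given the seed", {
  cfg <- uniform_config(n_per_site = 120, pots_per_site = 24)
  cohort <- generate_cohort(cfg, seed = 5)
  trials <- generate_establishment(cfg, seed = 6)
  r1 <- stratified_bootstrap(cohort, trials, lambda_statistic("low", "low"),
                             B = 40, seed = 9)
  r2 <- stratified_bootstrap(cohort, trials, lambda_statistic("low", "low"),
                             B = 40, seed = 9)
  expect_identical(r1$replicates, r2$replicates)
  r3 <- stratified_bootstrap(cohort, trials, lambda_statistic("low", "low"),
                             B = 40, seed = 10)
  expect_false(identical(r1$replicates, r3$replicates))

  f1 <- bootstrap_growth_rate(cohort, trials, "low", "low", B = 40, seed = 9)
  f2 <- bootstrap_growth_rate(cohort, trials, "low", "low", B = 40, seed = 9)
  expect_identical(f1$replicates, f2$replicates)
})

test_that("every replicate preserves the population sample sizes", {
  cfg <- uniform_config(n_per_site = 90, pots_per_site = 24)
  cohort <- generate_cohort(cfg, seed = 15)
  n_low1 <- sum(cohort$population == "low1")
  count_stat <- function(c, t) sum(c$population == "low1")
  res <- stratified_bootstrap(cohort, NULL, count_stat, B = 30, seed = 2)
  expect_true(all(res$replicates == n_low1))
})

test_that("degenerate replicates are excluded and counted", {
  cohort <- tiny_cohort()
  flaky <- local({
    k <- 0
    function(c, t) {
      k <<- k + 1
      if (k %% 3 == 0) NA_real_ else 1.0
    }
  })
  expect_warning(
    res <- stratified_bootstrap(cohort, NULL, flaky, B = 30, seed = 1),
    "degenerate")
  expect_equal(res$n_degenerate, 10)
  expect_equal(length(res$replicates), 20)
  expect_equal(length(res$replicates_full), 30)
})

test_that("weighted and generic bootstrap agree on the same pipeline", {
  cfg <- uniform_config(surv = 0.8, flow = 0.5, n_per_site = 150,
                        pots_per_site = 36)
  cohort <- generate_cohort(cfg, seed = 25)
  trials <- generate_establishment(cfg, seed = 26)
  fast <- bootstrap_growth_rate(cohort, trials, "low", "low",
                                B = 300, seed = 3)
  slow <- stratified_bootstrap(
    subset(cohort, genotype == "low" & elevation == "low"),
    subset(trials, genotype == "low" & elevation == "low"),
    lambda_statistic("low", "low"), B = 300, seed = 3)
  expect_equal(fast$point_estimate, slow$point_estimate)
  # same resampling scheme, different streams: distributions must agree
  expect_lt(abs(mean(fast$replicates) - mean(slow$replicates)), 0.02)
  expect_lt(abs(stats::sd(fast$replicates) / stats::sd(slow$replicates) - 1),
            0.3)
})

test_that("growth-rate comparison reports advantage and difference interval", {
  cfg <- uniform_config(n_per_site = 150, pots_per_site = 36)
  cohort <- generate_cohort(cfg, seed = 35)
  trials <- generate_establishment(cfg, seed = 36)
  res <- bootstrap_growth_rate(cohort, trials, "low", "low", B = 60, seed = 1)

  cmp_same <- compare_growth_rates(res, res)
  expect_equal(cmp_same$advantage_pct, 0)
  expect_equal(cmp_same$difference, 0)
  expect_false(cmp_same$excludes_zero)

  other <- bootstrap_growth_rate(cohort, trials, "high", "low",
                                 B = 50, seed = 1)
  expect_error(compare_growth_rates(res, other),
               class = "mpmfit_structure_error")

  # percent advantage is a pure ratio statement
  inflate <- res
  inflate$point_estimate <- 1.39 * res$point_estimate
  inflate$replicates_full <- 1.39 * res$replicates_full
  cmp <- compare_growth_rates(inflate, res)
  expect_equal(cmp$advantage_pct, 39)
})

test_that("subsampling a cohort where no plant flowers marks replicates degenerate", {
  cohort <- tiny_cohort()
  cohort$flowered_y1 <- 0L; cohort$seeds_y1 <- 0L
  cohort$flowered_y2 <- 0L; cohort$seeds_y2 <- 0L
  attr(cohort, "seasons") <- c("S1", "W1", "S2")
  expect_warning(
    res <- bootstrap_growth_rate(cohort, tiny_trials(), "low", "low",
                                 B = 10, seed = 1),
    "degenerate")
  expect_equal(res$n_degenerate, 10)
})

test_that("BCa jackknife acceleration runs and reduces to BC when symmetric", {
  cfg <- uniform_config(n_per_site = 60, pots_per_site = 12)
  cohort <- generate_cohort(cfg, seed = 45)
  trials <- generate_establishment(cfg, seed = 46)
  res <- stratified_bootstrap(cohort, trials, lambda_statistic("low", "low"),
                              B = 60, seed = 4, ci = "bca")
  expect_s3_class(res, "bootstrap_result")
  expect_true(is.finite(res$ci_low) && is.finite(res$ci_high))
})
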