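test_that("two-stage Leslie build places survival and reproduction correctly", {
  pm <- build_matrix(list(T = 0.5, R = c(0, 2)))
  expect_equal(unname(pm$A), matrix(c(0, 0.5, 2, 0), 2, 2))
  expect_equal(unname(pm$vital_rate_map[2, 1]), "T1")
  expect_equal(unname(pm$vital_rate_map[1, 2]), "R2")
})

test_that("five-stage seasonal build has the Leslie structure", {
  T <- c(0.5, 0.8, 0.6, 0.7)
  R <- c(0, 1.5, 2.5)  # reproduction per summer year; none in year 1
  pm <- build_matrix(list(T = T, R = R,
                          seasons = c("S1", "W1", "S2", "W2", "S3")))
  A <- pm$A
  expect_equal(sum(A != 0), 4 + sum(R != 0))
  expect_equal(unname(A[cbind(2:5, 1:4)]), T)
  expect_equal(unname(A[1, c(1, 3, 5)]), R)
  expect_equal(unname(pm$vital_rate_map[1, c(1, 3, 5)]),
               c("R1", "R2", "R3"))
  # truncation: nothing leaves the terminal stage
  expect_equal(unname(A[, 5]), c(R[3], 0, 0, 0, 0))

  pm2 <- build_matrix(list(T = T, R = R,
                           seasons = c("S1", "W1", "S2", "W2", "S3")),
                      topology = "selfloop")
  expect_equal(unname(pm2$A[5, 5]), T[4])
  expect_equal(unname(pm2$vital_rate_map[5, 5]), "T4")
})

test_that("structural errors are raised for inconsistent inputs", {
  expect_error(build_matrix(list(T = c(0.5, 1.2), R = c(1, 1, 1))),
               class = "mpmfit_structure_error")
  expect_error(build_matrix(list(T = 0.5, R = c(-1, 2))),
               class = "mpmfit_structure_error")
  expect_error(build_matrix(list(T = c(0.5, 0.6), R = c(1, 1),
                                 seasons = c("S1", "W1"))),
               class = "mpmfit_structure_error")
  # R length matching neither stages nor reproductive years
  expect_error(build_matrix(list(T = c(0.5, 0.6, 0.7, 0.8), R = c(1, 1),
                                 seasons = c("S1", "W1", "S2", "W2", "S3"))),
               class = "mpmfit_structure_error")
})

test_that("eigenanalysis matches the closed forms of the 2-stage chain", {
  ea <- eigen_analysis(matrix(c(0, 0.5, 2, 0), 2, 2))
  expect_equal(ea$lambda, 1)
  expect_equal(unname(ea$w), c(2 / 3, 1 / 3))
  expect_equal(unname(ea$elasticity),
               matrix(c(0, 0.5, 0.5, 0), 2, 2))

  ea2 <- eigen_analysis(matrix(c(0.3, 0.5, 2, 0), 2, 2))
  expect_equal(ea2$lambda, (0.3 + sqrt(4.09)) / 2)
})

test_that("elasticities sum to one and sensitivities match perturbation", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(3:6, 1)
    pm <- random_leslie(n)
    ea <- eigen_analysis(pm)
    expect_true(ea$primitive)
    expect_lt(abs(sum(ea$elasticity) - 1), 1e-10)
    expect_true(all(ea$elasticity[pm$A == 0] == 0))
    # central-difference perturbation oracle on every nonzero entry
    delta <- 1e-6
    nz <- which(pm$A != 0, arr.ind = TRUE)
    for (k in seq_len(nrow(nz))) {
      Ap <- pm$A; Am <- pm$A
      Ap[nz[k, 1], nz[k, 2]] <- Ap[nz[k, 1], nz[k, 2]] + delta
      Am[nz[k, 1], nz[k, 2]] <- Am[nz[k, 1], nz[k, 2]] - delta
      s_num <- (growth_rate(Ap) - growth_rate(Am)) / (2 * delta)
      expect_lt(abs(ea$sensitivity[nz[k, 1], nz[k, 2]] - s_num), 1e-4)
    }
  }
})

test_that("projection of any positive start converges to lambda and w", {
  set.seed(7)
  pm <- random_leslie(5)
  ea <- eigen_analysis(pm)
  po <- power_iteration(pm$A)
  expect_equal(ea$lambda, po$lambda, tolerance = 1e-9)
  expect_equal(unname(ea$w), po$w, tolerance = 1e-6)
})

test_that("pure semelparous chains scale as lambda = sqrt(R * T)", {
  for (R2 in c(0.5, 1, 2, 4)) {
    pm <- build_matrix(list(T = 0.5, R = c(0, R2)))
    expect_equal(eigen_analysis(pm)$lambda, sqrt(0.5 * R2))
  }
})

test_that("matrices without a reproductive loop are flagged, not fatal", {
  pm <- build_matrix(list(T = c(0.5, 0.8), R = c(0, 0),
                          seasons = c("S1", "W1", "S2")))
  ea <- eigen_analysis(pm)
  expect_equal(ea$lambda, 0)
  expect_false(ea$primitive)
  expect_true(ea$degenerate)
  expect_true(all(is.na(ea$w)))
  expect_error(eigen_analysis(matrix(0, 2, 2)),
               class = "mpmfit_structure_error")
})

test_that("stable age summary regroups w by season and conserves mass", {
  ea <- eigen_analysis(build_matrix(list(T = 0.5, R = c(0, 2),
                                         seasons = c("S1", "W1"))))
  sas <- stable_age_summary(ea)
  expect_equal(sas$proportion, c(2 / 3, 1 / 3))
  expect_equal(sas$season, c("summer", "winter"))
  expect_equal(sum(sas$proportion), 1)

  cfg <- uniform_config(n_per_site = 200, pots_per_site = 24)
  cohort <- generate_cohort(cfg, seed = 3)
  trials <- generate_establishment(cfg, seed = 4)
  vr <- estimate_vital_rates(cohort, trials, "low", "low")
  sas2 <- stable_age_summary(eigen_analysis(build_matrix(vr)))
  expect_equal(sas2$stage, cfg$seasons)
  expect_equal(sum(sas2$proportion), 1, tolerance = 1e-12)
})
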