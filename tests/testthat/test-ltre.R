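test_that("identical matrices decompose to zero everywhere", {
  pm <- build_matrix(list(T = 0.5, R = c(0, 2)))
  lt <- ltre_fixed_design(pm, pm)
  expect_equal(lt$delta_lambda, 0)
  expect_true(all(lt$contributions == 0))
  expect_equal(lt$approx_error, 0)
  lt_ref <- ltre_fixed_design(pm, pm, sensitivity = "reference")
  expect_true(all(lt_ref$contributions == 0))
})

test_that("the 2-stage worked example matches closed-form sensitivities", {
  loc <- build_matrix(list(T = 0.5, R = c(0, 2)))
  fgn <- build_matrix(list(T = 0.4, R = c(0, 1.8)))
  lt <- ltre_fixed_design(loc, fgn)

  expect_equal(lt$delta_lambda, sqrt(0.72) - 1)  # ~ -0.15147
  # closed forms at the midpoint matrix [[0, 1.9], [0.45, 0]]
  lam_mid <- sqrt(1.9 * 0.45)
  expect_equal(unname(lt$contributions["R2"]), -0.2 * lam_mid / (2 * 1.9))
  expect_equal(unname(lt$contributions["T1"]), -0.1 * lam_mid / (2 * 0.45))
  expect_equal(sum(lt$contributions), -0.15141, tolerance = 1e-4)
  expect_lt(abs(lt$approx_error), 7e-4)

  # halving every perturbation: the reference-sensitivity residual is
  # second-order (shrinks ~4x); the midpoint rule cancels the quadratic
  # term, so its residual is third-order (shrinks ~8x)
  half <- build_matrix(list(T = 0.45, R = c(0, 1.9)))
  lt_ref <- ltre_fixed_design(loc, fgn, sensitivity = "reference")
  lt_ref_half <- ltre_fixed_design(loc, half, sensitivity = "reference")
  ratio_ref <- abs(lt_ref$approx_error) / abs(lt_ref_half$approx_error)
  expect_gt(ratio_ref, 3.5)
  expect_lt(ratio_ref, 4.5)

  lt_half <- ltre_fixed_design(loc, half)
  ratio_mid <- abs(lt$approx_error) / abs(lt_half$approx_error)
  expect_gt(ratio_mid, 6)
  expect_lt(ratio_mid, 12)
})

test_that("swapping focal and reference negates the decomposition", {
  loc <- build_matrix(list(T = c(0.6, 0.7), R = c(1, 0.5),
                           seasons = c("S1", "W1", "S2")))
  fgn <- build_matrix(list(T = c(0.5, 0.6), R = c(0.8, 0.4),
                           seasons = c("S1", "W1", "S2")))
  ab <- ltre_fixed_design(loc, fgn)
  ba <- ltre_fixed_design(fgn, loc)
  expect_equal(ba$delta_lambda, -ab$delta_lambda)
  # midpoint matrix is shared, so contributions negate exactly
  expect_equal(ba$contributions, -ab$contributions)
})

test_that("single-entry contributions converge to the sensitivity", {
  base <- build_matrix(list(T = c(0.6, 0.7), R = c(1, 0.5),
                            seasons = c("S1", "W1", "S2")))
  s <- eigen_analysis(base)$sensitivity
  delta <- 1e-5
  pert <- base
  pert$A[2, 1] <- pert$A[2, 1] + delta
  lt <- ltre_fixed_design(base, pert)
  expect_equal(unname(lt$contributions["T1"]) / delta, s[2, 1],
               tolerance = 1e-4)
})

test_that("vital-rate aggregation conserves the entry-level contributions", {
  loc <- build_matrix(list(T = c(0.6, 0.7, 0.5, 0.8), R = c(0.2, 1, 2),
                           seasons = c("S1", "W1", "S2", "W2", "S3")))
  fgn <- build_matrix(list(T = c(0.5, 0.75, 0.45, 0.7), R = c(0.1, 0.8, 1.6),
                           seasons = c("S1", "W1", "S2", "W2", "S3")))
  lt <- ltre_fixed_design(loc, fgn)
  expect_equal(sum(lt$contributions), sum(lt$contributions_matrix))
  expect_setequal(names(lt$contributions),
                  c("T1", "T2", "T3", "T4", "R1", "R2", "R3"))
})

test_that("topology mismatch is a structural error", {
  a <- build_matrix(list(T = 0.5, R = c(0, 2)))
  b <- build_matrix(list(T = c(0.5, 0.6), R = c(1, 1, 1)))
  expect_error(ltre_fixed_design(a, b), class = "mpmfit_structure_error")
})

fake_ea <- function(e_R, e_T) {
  # 2-stage elasticity structure: R on (1,2), T on (2,1)
  e <- matrix(c(0, e_T, e_R, 0), 2, 2)
  map <- matrix(c("", "T1", "R1", ""), 2, 2)
  structure(list(elasticity = e, vital_rate_map = map,
                 stage_labels = c("S1", "W1")),
            class = "eigen_analysis")
}

test_that("elasticity shift and distance behave as defined", {
  # home = away: all shifts zero
  same <- list(p1 = fake_ea(0.6, 0.4))
  other <- list(q1 = fake_ea(0.5, 0.5))
  cmp <- elasticity_shift_distance(same, same, other, other)
  expect_true(all(cmp$table$shift == 0))

  # identical home elasticities of the two genotypes: all distances zero
  cmp2 <- elasticity_shift_distance(
    list(p1 = fake_ea(0.6, 0.4)), list(p1 = fake_ea(0.5, 0.5)),
    list(q1 = fake_ea(0.6, 0.4)), list(q1 = fake_ea(0.5, 0.5)))
  expect_true(all(cmp2$table$distance == 0))

  # mirrored 2-vital-rate case: collinear shift/distance pairs
  hl <- list(p1 = fake_ea(0.6, 0.4)); al <- list(p1 = fake_ea(0.5, 0.5))
  hh <- list(q1 = fake_ea(0.4, 0.6)); ah <- list(q1 = fake_ea(0.5, 0.5))
  cmp3 <- elasticity_shift_distance(hl, al, hh, ah)
  expect_equal(sort(cmp3$table$shift), c(-0.1, -0.1, 0.1, 0.1))
  expect_equal(sort(cmp3$table$distance), c(-0.2, -0.2, 0.2, 0.2))
  expect_equal(cmp3$correlation, 1)
})
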