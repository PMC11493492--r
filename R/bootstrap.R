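#' Bias-corrected percentile confidence interval
#'
#' Bias-corrected (BC) bootstrap interval without acceleration: the
#' correction constant is \eqn{z_0 = \Phi^{-1}} of the fraction of
#' replicates strictly below the point estimate, and the interval endpoints
#' are the empirical quantiles of the replicates at the adjusted levels
#' \eqn{\Phi(2 z_0 \pm z_{1-\alpha/2})}. When exactly half the replicates lie
#' below the point estimate (\eqn{z_0 = 0}), the BC interval coincides with
#' the plain percentile interval.
#'
#' If every replicate falls on one side of the point estimate, \eqn{z_0} is
#' infinite; a degenerate interval (collapsed to the extreme quantile) is
#' returned with `degenerate = TRUE` rather than failing.
#'
#' @param replicates Numeric vector of bootstrap replicates (non-finite
#'   values are dropped).
#' @param point_estimate Statistic computed on the original data.
#' @param alpha Two-sided error rate (default 0.05 for a 95% interval).
#' @param acceleration BCa acceleration constant \eqn{a}; the default 0
#'   gives the plain bias-corrected interval. With nonzero \eqn{a} each
#'   adjusted level becomes \eqn{\Phi(z_0 + (z_0 + z)/(1 - a(z_0 + z)))}
#'   with \eqn{z = \pm z_{1-\alpha/2}}.
#' @return List with `ci_low`, `ci_high`, `z0`, `levels` (the adjusted
#'   quantile levels) and `degenerate`.
#' @examples
#' bc_interval(1:100, 60.5)  # z0 = qnorm(0.6), shifted quantile levels
#' @export
bc_interval <- function(replicates, point_estimate, alpha = 0.05,
                        acceleration = 0) {
  reps <- replicates[is.finite(replicates)]
  if (length(reps) < 2 || !is.finite(point_estimate)) {
    one <- if (length(reps) > 0) reps[1] else NA_real_
    return(list(ci_low = one, ci_high = one, z0 = NA_real_,
                levels = c(NA_real_, NA_real_), degenerate = TRUE))
  }
  if (max(reps) == min(reps)) {
    return(list(ci_low = reps[1], ci_high = reps[1], z0 = 0,
                levels = c(0, 1), degenerate = FALSE))
  }
  z0 <- stats::qnorm(mean(reps < point_estimate))
  zq <- stats::qnorm(1 - alpha / 2)
  zz <- z0 + c(-zq, zq)
  adj <- if (acceleration == 0) z0 + zz else z0 + zz / (1 - acceleration * zz)
  levels <- stats::pnorm(adj)
  qs <- stats::quantile(reps, levels, names = FALSE, type = 7)
  list(ci_low = qs[1], ci_high = qs[2], z0 = z0, levels = levels,
       degenerate = !is.finite(z0))
}

# Jackknife acceleration constant for BCa: leave-one-individual-out
# statistic values, skewness-based formula.
jackknife_acceleration <- function(cohort, trials, statistic) {
  n <- nrow(cohort)
  seasons <- attr(cohort, "seasons")
  theta <- vapply(seq_len(n), function(i) {
    rc <- cohort[-i, , drop = FALSE]
    attr(rc, "seasons") <- seasons
    tryCatch(as.numeric(statistic(rc, trials)),
             mpmfit_estimation_error = function(e) NA_real_,
             mpmfit_structure_error = function(e) NA_real_)
  }, numeric(1))
  theta <- theta[is.finite(theta)]
  d <- mean(theta) - theta
  denom <- 6 * sum(d^2)^1.5
  if (denom == 0) 0 else sum(d^3) / denom
}

new_bootstrap_result <- function(statistic_name, point_estimate,
                                 replicates_full, B, alpha, seed,
                                 acceleration = 0) {
  ok <- is.finite(replicates_full)
  replicates <- replicates_full[ok]
  n_degenerate <- B - length(replicates)
  if (n_degenerate > 0.01 * B) {
    warning(sprintf("%d of %d bootstrap replicates were degenerate",
                    n_degenerate, B))
  }
  bc <- bc_interval(replicates, point_estimate, alpha, acceleration)
  structure(list(statistic_name = statistic_name,
                 point_estimate = point_estimate,
                 replicates = replicates,
                 replicates_full = replicates_full,
                 n_degenerate = n_degenerate,
                 B = B, alpha = alpha, seed = seed,
                 z0 = bc$z0, ci_low = bc$ci_low, ci_high = bc$ci_high,
                 ci_levels = bc$levels,
                 degenerate_interval = bc$degenerate),
            class = "bootstrap_result")
}

resample_within <- function(idx_by_stratum) {
  unlist(lapply(idx_by_stratum, function(ii) {
    ii[sample.int(length(ii), length(ii), replace = TRUE)]
  }), use.names = FALSE)
}

#' Population-stratified bootstrap of an arbitrary pipeline statistic
#'
#' Resamples individuals with replacement within each source-population
#' stratum (and establishment pots within population), re-runs the supplied
#' statistic on every resampled data set, and summarises the replicate
#' distribution with a bias-corrected percentile interval. Every replicate
#' preserves each population's sample size exactly. Replicates on which the
#' statistic raises an estimation/structural error or returns a non-finite
#' value are counted as degenerate and excluded (with a warning when they
#' exceed 1% of `B`).
#'
#' @param cohort Cohort table with a `population` column.
#' @param trials Establishment table (or `NULL` if the statistic ignores it).
#' @param statistic Function `(cohort, trials) -> scalar`.
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed; the whole replicate schedule is deterministic
#'   given `(data, B, seed)`.
#' @param alpha Two-sided error rate for the confidence interval.
#' @param ci Interval type: `"bc"` (bias-corrected, default) or `"bca"`
#'   (additionally estimates the acceleration constant by a
#'   leave-one-individual-out jackknife of the statistic).
#' @param statistic_name Label stored in the result.
#' @return Object of class `bootstrap_result`.
#' @seealso [bootstrap_growth_rate()] for the fast growth-rate path,
#'   [bc_interval()] for the interval construction.
#' @export
stratified_bootstrap <- function(cohort, trials = NULL, statistic,
                                 B = 20000, seed = 1, alpha = 0.05,
                                 ci = c("bc", "bca"),
                                 statistic_name = "statistic") {
  ci <- match.arg(ci)
  if (nrow(cohort) == 0) stop_estimation("cohort is empty")
  pop <- cohort$population
  if (is.factor(pop) && any(table(pop) == 0)) {
    stop_estimation("empty population stratum: %s",
                    paste(names(which(table(pop) == 0)), collapse = ", "))
  }
  idx_by_pop <- split(seq_len(nrow(cohort)), as.character(pop))
  tidx_by_pop <- if (!is.null(trials)) {
    split(seq_len(nrow(trials)), as.character(trials$population))
  }
  seasons <- attr(cohort, "seasons")
  point <- statistic(cohort, trials)
  if (!is.numeric(point) || length(point) != 1 || !is.finite(point)) {
    stop_estimation("statistic is not computable on the original data")
  }
  reps <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      rc <- cohort[resample_within(idx_by_pop), , drop = FALSE]
      attr(rc, "seasons") <- seasons
      rt <- if (!is.null(trials)) {
        trials[resample_within(tidx_by_pop), , drop = FALSE]
      }
      tryCatch(as.numeric(statistic(rc, rt)),
               mpmfit_estimation_error = function(e) NA_real_,
               mpmfit_structure_error = function(e) NA_real_)
    }, numeric(1))
  })
  accel <- if (ci == "bca") {
    jackknife_acceleration(cohort, trials, statistic)
  } else {
    0
  }
  new_bootstrap_result(statistic_name, point, reps, B, alpha, seed, accel)
}

# Internal: pooled count arrays for one stratum, used by the weighted
# bootstrap. Resampling n individuals with replacement within a population is
# equivalent to drawing a multinomial weight vector over the individuals, so
# all pooled-ratio vital rates can be computed from weighted column sums.
stratum_arrays <- function(cohort, trials, genotype, environment) {
  dat <- subset_stratum(cohort, genotype, environment)
  if (nrow(dat) == 0) {
    stop_estimation("no individuals for genotype=%s environment=%s",
                    genotype, environment)
  }
  seasons <- cohort_seasons(cohort)
  acols <- paste0("alive_", seasons)
  fcols <- year_columns(cohort, "flowered")
  scols <- year_columns(cohort, "seeds")
  pots <- trials[trials$genotype == genotype &
                 trials$elevation == environment, , drop = FALSE]
  if (nrow(pots) == 0) {
    stop_estimation("no establishment pots for genotype=%s environment=%s",
                    genotype, environment)
  }
  list(alive = as.matrix(dat[acols]),
       flowered = as.matrix(dat[fcols]),
       seeds = as.matrix(dat[scols]),
       pop = as.character(dat$population),
       sown = pots$sown, established = pots$established,
       pot_pop = as.character(pots$population),
       seasons = seasons,
       summer_idx = which(substr(seasons, 1, 1) == "S"))
}

#' Fast stratified bootstrap of the population growth rate
#'
#' Specialised bootstrap for the full vital-rate \eqn{\to} matrix \eqn{\to}
#' \eqn{\lambda} pipeline of one genotype \eqn{\times} environment stratum.
#' Because every estimator in the pipeline is a pooled ratio, resampling
#' individuals (and pots) with replacement within populations is carried out
#' as multinomial weight draws, and all replicate vital rates are obtained
#' from weighted column sums; only the eigenvalue extraction loops over
#' replicates. This reproduces the generic [stratified_bootstrap()] scheme
#' orders of magnitude faster, which makes the 20,000-replicate default
#' practical.
#'
#' Replicates in which some census has no survivors (a survival rate becomes
#' 0/0) or in which no plant flowers in any year (a nilpotent matrix with
#' \eqn{\lambda = 0}) are degenerate: they are excluded from the interval and
#' counted in `n_degenerate`.
#'
#' @inheritParams stratified_bootstrap
#' @param genotype,environment Stratum labels.
#' @param topology Terminal-stage rule passed to [build_matrix()].
#' @return Object of class `bootstrap_result` with `statistic_name`
#'   `"lambda"`.
#' @export
bootstrap_growth_rate <- function(cohort, trials, genotype, environment,
                                  B = 20000, seed = 1, alpha = 0.05,
                                  topology = "truncate") {
  arr <- stratum_arrays(cohort, trials, genotype, environment)
  n_seasons <- length(arr$seasons)
  n_years <- length(arr$summer_idx)

  point_rates <- estimate_vital_rates(cohort, trials, genotype, environment)
  point <- growth_rate(build_matrix(point_rates, topology = topology))

  pops <- sort(unique(arr$pop))
  pot_pops <- sort(unique(arr$pot_pop))
  aliveB <- matrix(0, B, n_seasons)
  flowB <- matrix(0, B, n_years)
  seedB <- matrix(0, B, n_years)
  estNum <- numeric(B)
  estDen <- numeric(B)
  with_seed(seed, {
    for (p in pops) {
      ii <- which(arr$pop == p)
      W <- stats::rmultinom(B, length(ii), rep(1, length(ii)))
      aliveB <- aliveB + crossprod(W, arr$alive[ii, , drop = FALSE])
      flowB <- flowB + crossprod(W, arr$flowered[ii, , drop = FALSE])
      seedB <- seedB + crossprod(W, arr$seeds[ii, , drop = FALSE])
    }
    for (p in pot_pops) {
      ii <- which(arr$pot_pop == p)
      W <- stats::rmultinom(B, length(ii), rep(1, length(ii)))
      estNum <- estNum + as.numeric(crossprod(W, arr$established[ii]))
      estDen <- estDen + as.numeric(crossprod(W, arr$sown[ii]))
    }
  })

  Tb <- aliveB[, -1, drop = FALSE] / aliveB[, -n_seasons, drop = FALSE]
  Fb <- flowB / aliveB[, arr$summer_idx, drop = FALSE]
  Nb <- seedB / flowB           # NaN where nothing flowered (then Fb = 0)
  Eb <- estNum / estDen
  Rb <- ifelse(Fb == 0, 0, Fb * Nb * Eb)

  ok <- rowSums(!is.finite(Tb)) == 0 & rowSums(!is.finite(Fb)) == 0 &
    rowSums(Rb > 0) > 0
  lam <- rep(NA_real_, B)
  # template matrix; only the varying entries are overwritten per replicate
  A <- matrix(0, n_seasons, n_seasons)
  sub_idx <- cbind(seq_len(n_seasons - 1L) + 1L, seq_len(n_seasons - 1L))
  rep_idx <- cbind(1L, arr$summer_idx)
  if (topology == "selfloop") {
    loop_idx <- cbind(n_seasons, n_seasons)
  }
  for (b in which(ok)) {
    A[sub_idx] <- Tb[b, ]
    A[rep_idx] <- Rb[b, ]
    if (topology == "selfloop") A[loop_idx] <- Tb[b, n_seasons - 1L]
    lam[b] <- max(Mod(eigen(A, only.values = TRUE)$values))
  }
  new_bootstrap_result("lambda", point, lam, B, alpha, seed)
}

#' Compare bootstrap growth-rate distributions of two genotypes
#'
#' Summarises the local-versus-foreign growth-rate contrast within one
#' environment: the two point estimates, the percent advantage of the local
#' genotype \eqn{100(\lambda_{local}/\lambda_{foreign} - 1)}, and the
#' replicate-wise difference distribution
#' \eqn{\lambda_{local} - \lambda_{foreign}} with its bias-corrected
#' interval. The two bootstrap runs are independent; replicates are aligned
#' by index to form the difference distribution, so both results must carry
#' the same number of replicates.
#'
#' @param result_local,result_foreign `bootstrap_result` objects for the
#'   local and foreign genotype in the same environment, with equal `B` and
#'   `alpha`.
#' @return Object of class `growth_comparison`: list with `lambda_local`,
#'   `lambda_foreign`, `advantage_pct`, `difference` (point difference), the
#'   BC interval of the difference (`ci_low`, `ci_high`, `z0`),
#'   `excludes_zero`, `n_degenerate`, `B` and `alpha`.
#' @export
compare_growth_rates <- function(result_local, result_foreign) {
  if (!inherits(result_local, "bootstrap_result") ||
      !inherits(result_foreign, "bootstrap_result")) {
    stop_structure("expected two bootstrap_result objects")
  }
  if (result_local$B != result_foreign$B) {
    stop_structure("mismatched replicate counts: %d vs %d",
                   result_local$B, result_foreign$B)
  }
  alpha <- result_local$alpha
  d_full <- result_local$replicates_full - result_foreign$replicates_full
  point_d <- result_local$point_estimate - result_foreign$point_estimate
  bc <- bc_interval(d_full, point_d, alpha)
  structure(list(
    lambda_local = result_local$point_estimate,
    lambda_foreign = result_foreign$point_estimate,
    advantage_pct = 100 * (result_local$point_estimate /
                             result_foreign$point_estimate - 1),
    difference = point_d,
    difference_replicates = d_full[is.finite(d_full)],
    ci_low = bc$ci_low, ci_high = bc$ci_high, z0 = bc$z0,
    degenerate_interval = bc$degenerate,
    excludes_zero = is.finite(bc$ci_low) && is.finite(bc$ci_high) &&
      (bc$ci_low > 0 || bc$ci_high < 0),
    n_degenerate = sum(!is.finite(d_full)),
    B = result_local$B, alpha = alpha),
    class = "growth_comparison")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap of %s: point = %.5f, %d%% BC CI [%.5f, %.5f]\n",
              x$statistic_name, x$point_estimate,
              round(100 * (1 - x$alpha)), x$ci_low, x$ci_high))
  cat(sprintf("  B = %d, degenerate = %d, z0 = %.4f\n",
              x$B, x$n_degenerate, x$z0))
  invisible(x)
}

#' @export
print.growth_comparison <- function(x, ...) {
  cat(sprintf("lambda local = %.4f, foreign = %.4f (advantage %.1f%%)\n",
              x$lambda_local, x$lambda_foreign, x$advantage_pct))
  cat(sprintf("difference BC CI [%.4f, %.4f]%s\n", x$ci_low, x$ci_high,
              if (x$excludes_zero) " (excludes 0)" else ""))
  invisible(x)
}
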