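# Column helpers shared by the estimators and the validators.
alive_columns <- function(cohort) {
  cols <- grep("^alive_", names(cohort), value = TRUE)
  if (length(cols) == 0) stop_estimation("cohort has no alive_<season> columns")
  cols
}

cohort_seasons <- function(cohort) {
  attr(cohort, "seasons") %||% sub("^alive_", "", alive_columns(cohort))
}

year_columns <- function(cohort, prefix) {
  cols <- grep(paste0("^", prefix, "_y[0-9]+$"), names(cohort), value = TRUE)
  cols[order(as.integer(sub(paste0("^", prefix, "_y"), "", cols)))]
}

subset_stratum <- function(cohort, genotype, environment, population = NULL) {
  keep <- cohort$genotype == genotype & cohort$elevation == environment
  if (!is.null(population)) keep <- keep & cohort$population %in% population
  cohort[keep, , drop = FALSE]
}

#' Estimate seasonal survival vital rates
#'
#' Computes the survival vital rate for each season-to-season transition as
#' the proportion of individuals alive at the earlier census that are still
#' alive at the later one, pooled over all populations of the genotype within
#' the environment (optionally restricted to given populations). Individuals
#' never observed alive contribute to no transition.
#'
#' @param cohort A cohort table (see [generate_cohort()] for the layout).
#' @param genotype Genotype label to estimate for.
#' @param environment Environment (elevation) label.
#' @param population Optional character vector restricting the stratum to
#'   particular source populations.
#' @return Named numeric vector of transition probabilities `T1`, `T2`, ...,
#'   with the at-risk counts per census attached as attribute `at_risk`.
#' @export
estimate_survival <- function(cohort, genotype, environment,
                              population = NULL) {
  dat <- subset_stratum(cohort, genotype, environment, population)
  cols <- alive_columns(cohort)
  seasons <- cohort_seasons(cohort)
  if (nrow(dat) == 0) {
    stop_estimation("no individuals for genotype=%s environment=%s",
                    genotype, environment)
  }
  at_risk <- vapply(cols, function(cl) sum(dat[[cl]]), numeric(1))
  names(at_risk) <- seasons
  n_trans <- length(cols) - 1L
  if (n_trans < 1) stop_estimation("need at least two censuses to estimate survival")
  zero <- which(at_risk[seq_len(n_trans)] == 0)
  if (length(zero) > 0) {
    stop_estimation("zero individuals at risk at transition %s -> %s",
                    seasons[zero[1]], seasons[zero[1] + 1L])
  }
  T <- unname(at_risk[-1] / at_risk[-length(at_risk)])
  names(T) <- paste0("T", seq_len(n_trans))
  attr(T, "at_risk") <- at_risk
  T
}

#' Estimate yearly flowering probabilities
#'
#' For each reproductive year (summer census), the proportion of individuals
#' alive at that summer census that flowered.
#'
#' @inheritParams estimate_survival
#' @return Named numeric vector `F1`, `F2`, ... with attribute `at_risk`
#'   (alive counts at each summer census).
#' @export
estimate_flowering <- function(cohort, genotype, environment,
                               population = NULL) {
  dat <- subset_stratum(cohort, genotype, environment, population)
  seasons <- cohort_seasons(cohort)
  summer_idx <- which(substr(seasons, 1, 1) == "S")
  fcols <- year_columns(cohort, "flowered")
  if (length(fcols) != length(summer_idx)) {
    stop_estimation("cohort has %d flowered-year columns but %d summer censuses",
                    length(fcols), length(summer_idx))
  }
  acols <- alive_columns(cohort)[summer_idx]
  alive <- vapply(acols, function(cl) sum(dat[[cl]]), numeric(1))
  if (any(alive == 0)) {
    y <- which(alive == 0)[1]
    stop_estimation("no individuals alive at summer census %s", seasons[summer_idx[y]])
  }
  F <- vapply(seq_along(fcols), function(y) sum(dat[[fcols[y]]]) / alive[y],
              numeric(1))
  names(F) <- paste0("F", seq_along(fcols))
  attr(F, "at_risk") <- stats::setNames(alive, seasons[summer_idx])
  F
}

#' Estimate mean seed number per flowering plant
#'
#' For each reproductive year, the arithmetic mean number of mature seeds over
#' the individuals that flowered that year. Years with no flowering plants
#' have no defined seed number and are returned as `NA`; downstream,
#' [compose_reproduction()] resolves such years to a zero reproductive rate
#' when the flowering probability is also zero and refuses to impute
#' otherwise.
#'
#' @inheritParams estimate_survival
#' @return Named numeric vector `N1`, `N2`, ... (possibly containing `NA`),
#'   with attribute `n_flowering` (flowering plant counts per year).
#' @export
estimate_seed_number <- function(cohort, genotype, environment,
                                 population = NULL) {
  dat <- subset_stratum(cohort, genotype, environment, population)
  fcols <- year_columns(cohort, "flowered")
  scols <- year_columns(cohort, "seeds")
  if (length(fcols) != length(scols)) {
    stop_estimation("flowered/seeds year columns do not match")
  }
  n_fl <- numeric(length(fcols))
  N <- vapply(seq_along(fcols), function(y) {
    fl <- dat[[fcols[y]]] == 1
    n_fl[y] <<- sum(fl)
    if (!any(fl)) return(NA_real_)
    mean(dat[[scols[y]]][fl])
  }, numeric(1))
  names(N) <- paste0("N", seq_along(scols))
  attr(N, "n_flowering") <- stats::setNames(n_fl, names(N))
  N
}

#' Estimate the establishment probability from pot trials
#'
#' Pooled binomial proportion: total seedlings established over total seeds
#' sown across all pots of the stratum. With equal sowing per pot this equals
#' the mean of per-pot proportions.
#'
#' @param trials An establishment table (see [generate_establishment()]).
#' @inheritParams estimate_survival
#' @return Establishment probability (scalar) with attributes `sown` and
#'   `established` (pooled totals).
#' @export
estimate_establishment <- function(trials, genotype, environment,
                                   population = NULL) {
  keep <- trials$genotype == genotype & trials$elevation == environment
  if (!is.null(population)) keep <- keep & trials$population %in% population
  dat <- trials[keep, , drop = FALSE]
  if (nrow(dat) == 0) {
    stop_estimation("no establishment pots for genotype=%s environment=%s",
                    genotype, environment)
  }
  sown <- sum(dat$sown)
  established <- sum(dat$established)
  E <- established / sown
  attr(E, "sown") <- sown
  attr(E, "established") <- established
  E
}

#' Compose yearly reproductive rates
#'
#' The composite reproductive rate of year \eqn{i} is the product of that
#' year's flowering probability, mean seed number per flowering plant, and
#' the establishment probability: \eqn{R_i = F_i \cdot N_i \cdot E}. A year
#' with undefined seed number (`NA`) is resolved to \eqn{R_i = 0} when
#' \eqn{F_i = 0} (nobody flowered, so no seeds enter the model); if
#' \eqn{F_i > 0} the missing seed count is a data defect and an error is
#' raised rather than imputing.
#'
#' @param F Vector of flowering probabilities per year.
#' @param N Vector of mean seed numbers per year (may contain `NA`).
#' @param E Establishment probability (scalar).
#' @return Named numeric vector `R1`, `R2`, ...
#' @export
compose_reproduction <- function(F, N, E) {
  if (length(F) != length(N)) {
    stop_estimation("flowering and seed-number vectors differ in length")
  }
  if (!is_probability(F)) stop_estimation("flowering probabilities outside [0,1]")
  if (!is_probability(E) || length(E) != 1) {
    stop_estimation("establishment probability must be a scalar in [0,1]")
  }
  bad <- is.na(N) & F > 0
  if (any(bad)) {
    stop_estimation("seed number undefined in year %d but flowering probability > 0",
                    which(bad)[1])
  }
  if (any(!is.na(N) & N < 0)) stop_estimation("seed numbers must be non-negative")
  R <- ifelse(F == 0, 0, F * N * E)
  names(R) <- paste0("R", seq_along(R))
  R
}

new_vital_rates <- function(genotype, environment, seasons, T, F, N, E,
                            at_risk = NULL) {
  R <- compose_reproduction(F, N, E)
  names(T) <- paste0("T", seq_along(T))
  names(F) <- paste0("F", seq_along(F))
  names(N) <- paste0("N", seq_along(N))
  structure(list(genotype = genotype, environment = environment,
                 seasons = seasons, T = T, F = F, N = N, E = unname(E),
                 R = R, at_risk = at_risk),
            class = "vital_rates")
}

#' Estimate the full vital-rate set of a stratum
#'
#' Convenience wrapper running [estimate_survival()], [estimate_flowering()],
#' [estimate_seed_number()] and [estimate_establishment()] on one genotype
#' \eqn{\times} environment stratum and composing the yearly reproductive
#' rates.
#'
#' @inheritParams estimate_survival
#' @param trials An establishment table.
#' @return An object of class `vital_rates`: a list with elements `genotype`,
#'   `environment`, `seasons`, `T` (seasonal survival), `F` (flowering), `N`
#'   (seed number), `E` (establishment), `R` (composite reproduction) and
#'   `at_risk` (underlying counts).
#' @examples
#' cfg <- simulation_config(n_individuals_per_site = 200)
#' cohort <- generate_cohort(cfg, seed = 7)
#' trials <- generate_establishment(cfg, seed = 8)
#' estimate_vital_rates(cohort, trials, "low", "low")
#' @export
estimate_vital_rates <- function(cohort, trials, genotype, environment,
                                 population = NULL) {
  T <- estimate_survival(cohort, genotype, environment, population)
  F <- estimate_flowering(cohort, genotype, environment, population)
  N <- estimate_seed_number(cohort, genotype, environment, population)
  E <- estimate_establishment(trials, genotype, environment, population)
  at_risk <- list(survival = attr(T, "at_risk"),
                  flowering = attr(F, "at_risk"),
                  n_flowering = attr(N, "n_flowering"),
                  sown = attr(E, "sown"), established = attr(E, "established"))
  new_vital_rates(genotype = genotype, environment = environment,
                  seasons = cohort_seasons(cohort),
                  T = as.numeric(T), F = as.numeric(F), N = as.numeric(N),
                  E = as.numeric(E), at_risk = at_risk)
}

#' @export
print.vital_rates <- function(x, ...) {
  cat(sprintf("Vital rates: genotype=%s, environment=%s\n",
              x$genotype, x$environment))
  cat("  T:", paste(sprintf("%s=%.4f", names(x$T), x$T), collapse = " "), "\n")
  cat("  F:", paste(sprintf("%s=%.4f", names(x$F), x$F), collapse = " "), "\n")
  cat("  N:", paste(sprintf("%s=%.2f", names(x$N), x$N), collapse = " "), "\n")
  cat(sprintf("  E: %.4f\n", x$E))
  cat("  R:", paste(sprintf("%s=%.4f", names(x$R), x$R), collapse = " "), "\n")
  invisible(x)
}
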