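# Hand-enumerable cohort: 10 individuals of one genotype/environment over
# seasons S1, W1, S2. Survival 10 -> 7 -> 5; year-1 flowering 4/10 with
# seeds {10, 20, 30, 0}; year-2 flowering 2/5 with seeds {7, 0}.
tiny_cohort <- function() {
  d <- data.frame(
    individual_id = sprintf("i%02d", 1:10),
    site = "low1", elevation = "low",
    block = rep(1:2, 5),
    genotype = "low",
    population = rep(c("low1", "low2"), each = 5),
    family = "f1",
    alive_S1 = rep(1L, 10),
    alive_W1 = c(1, 1, 1, 1, 1, 1, 1, 0, 0, 0),
    alive_S2 = c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
    flowered_y1 = c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
    seeds_y1 = c(10, 20, 30, 0, 0, 0, 0, 0, 0, 0),
    flowered_y2 = c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0),
    seeds_y2 = c(7, 0, 0, 0, 0, 0, 0, 0, 0, 0))
  attr(d, "seasons") <- c("S1", "W1", "S2")
  d
}

# Matching pot trials: pools to E = 3/30 = 0.1.
tiny_trials <- function() {
  data.frame(
    pot_id = c("p1", "p2", "p3"),
    site = "low1", elevation = "low",
    genotype = "low",
    population = c("low1", "low2", "low1"),
    family = "f1",
    sown = c(10L, 10L, 10L),
    established = c(1L, 2L, 0L))
}

# Uniform-rate configuration used by recovery and calibration checks: the
# same survival/flowering/seed/establishment parameters in every genotype x
# elevation stratum (so the two genotypes are exchangeable).
uniform_config <- function(surv = 0.8, flow = 0.4, seed_mean = 50,
                           seed_zero = 0.2, estab = 0.1,
                           seasons = c("S1", "W1", "S2", "W2", "S3"),
                           n_per_site = 500, sites = NULL,
                           pots_per_site = 120, seeds_per_pot = 10) {
  if (is.null(sites)) {
    sites <- data.frame(site = c("low1", "low2", "high1", "high2"),
                        elevation = c("low", "low", "high", "high"))
  }
  n_trans <- length(seasons) - 1L
  n_years <- sum(substr(seasons, 1, 1) == "S")
  grid <- expand.grid(genotype = c("low", "high"),
                      elevation = unique(sites$elevation),
                      stringsAsFactors = FALSE)
  survival <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    data.frame(genotype = grid$genotype[i], elevation = grid$elevation[i],
               transition = seq_len(n_trans), prob = surv)
  }))
  reproduction <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    data.frame(genotype = grid$genotype[i], elevation = grid$elevation[i],
               year = seq_len(n_years), flowering_prob = flow,
               seed_mean = seed_mean, seed_zero_infl = seed_zero)
  }))
  establishment <- data.frame(genotype = grid$genotype,
                              elevation = grid$elevation, prob = estab)
  simulation_config(n_individuals_per_site = n_per_site, sites = sites,
                    seasons = seasons, survival = survival,
                    reproduction = reproduction,
                    establishment = establishment,
                    pots_per_site = pots_per_site,
                    seeds_per_pot = seeds_per_pot)
}

# Random Leslie-type seasonal matrix with all reproductive entries positive
# (hence primitive), used by the eigenanalysis property checks.
random_leslie <- function(n_stages) {
  T <- stats::runif(n_stages - 1, 0.2, 0.95)
  R <- numeric(n_stages)
  summer_idx <- seq(1, n_stages, by = 2)
  R[summer_idx] <- stats::runif(length(summer_idx), 0.1, 3)
  build_matrix(list(T = T, R = R))
}

# Independent power-iteration oracle for the dominant eigenvalue and the
# stable stage distribution.
power_iteration <- function(A, tol = 1e-13, max_iter = 1e5) {
  x <- rep(1, nrow(A))
  lam <- NA_real_
  for (i in seq_len(max_iter)) {
    y <- A %*% x
    lam_new <- sum(y) / sum(x)
    x <- as.numeric(y) / sum(y)
    if (!is.na(lam) && abs(lam_new - lam) < tol * lam_new) {
      lam <- lam_new
      break
    }
    lam <- lam_new
  }
  list(lambda = lam, w = x)
}
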