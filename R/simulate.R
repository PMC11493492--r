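#' Default vital-rate parameters for the cohort simulator
#'
#' Returns the three parameter tables used by [simulation_config()]: seasonal
#' survival probabilities per genotype and elevation, yearly reproduction
#' parameters (flowering probability, Poisson seed mean, structural
#' zero-inflation), and establishment probability per sown seed.
#'
#' The default values emulate a strong elevational local-adaptation contrast
#' in a short-lived perennial: the low-elevation genotype invests in early
#' flowering and high seed output but suffers summer mortality at home, while
#' the high-elevation genotype delays reproduction and survives winters well
#' at home. Establishment probabilities follow pot-sowing trials where roughly
#' 10% of seeds establish at low elevation and 3%--5% at high elevation.
#' Under these defaults the local genotype's asymptotic growth rate exceeds
#' the foreign genotype's by roughly 30%--40% at both elevations.
#'
#' @return A list with data frames `survival` (columns `genotype`,
#'   `elevation`, `transition`, `prob`), `reproduction` (columns `genotype`,
#'   `elevation`, `year`, `flowering_prob`, `seed_mean`, `seed_zero_infl`)
#'   and `establishment` (columns `genotype`, `elevation`, `prob`).
#' @export
default_rates <- function() {
  grid <- expand.grid(genotype = c("low", "high"),
                      elevation = c("low", "high"),
                      stringsAsFactors = FALSE)
  surv <- list(
    low.low   = c(0.55, 0.85, 0.55, 0.85),
    high.low  = c(0.40, 0.82, 0.48, 0.82),
    low.high  = c(0.80, 0.44, 0.80, 0.44),
    high.high = c(0.85, 0.60, 0.85, 0.60))
  survival <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    key <- paste(grid$genotype[i], grid$elevation[i], sep = ".")
    data.frame(genotype = grid$genotype[i], elevation = grid$elevation[i],
               transition = seq_along(surv[[key]]), prob = surv[[key]])
  }))
  flow <- list(
    low.low   = c(0.15, 0.50, 0.70),
    high.low  = c(0.08, 0.40, 0.60),
    low.high  = c(0.05, 0.30, 0.45),
    high.high = c(0.02, 0.30, 0.50))
  smean <- list(
    low.low   = c(30, 45, 50),
    high.low  = c(22, 38, 42),
    low.high  = c(15, 30, 36),
    high.high = c(15, 30, 35))
  szero <- list(
    low.low = c(0.20, 0.20, 0.20), high.low = c(0.30, 0.30, 0.30),
    low.high = c(0.35, 0.35, 0.35), high.high = c(0.30, 0.30, 0.30))
  reproduction <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    key <- paste(grid$genotype[i], grid$elevation[i], sep = ".")
    data.frame(genotype = grid$genotype[i], elevation = grid$elevation[i],
               year = seq_along(flow[[key]]), flowering_prob = flow[[key]],
               seed_mean = smean[[key]], seed_zero_infl = szero[[key]])
  }))
  establishment <- data.frame(
    genotype = c("low", "high", "low", "high"),
    elevation = c("low", "low", "high", "high"),
    prob = c(0.112, 0.098, 0.033, 0.051))
  list(survival = survival, reproduction = reproduction,
       establishment = establishment)
}

#' Build a simulation configuration for synthetic transplant cohorts
#'
#' Assembles and validates the full parameterisation of the individual-based
#' cohort simulator: the transplant design (sites, blocks, populations,
#' maternal families, census seasons) and the stochastic vital rates
#' (per-season Bernoulli survival, per-year Bernoulli flowering, zero-inflated
#' seed counts, per-seed establishment).
#'
#' Seasons are ordered census labels alternating summer (`S`) and winter (`W`)
#' stages; survival parameters refer to the transitions between consecutive
#' seasons, so `survival` must provide `length(seasons) - 1` probabilities per
#' genotype \eqn{\times} elevation, and `reproduction` one row per summer
#' season (reproductive year).
#'
#' @param n_individuals_per_site Transplanted individuals per site.
#' @param sites Data frame with columns `site` and `elevation`
#'   (`"low"`/`"high"`).
#' @param genotypes Genotype (ecotype) labels; each is also an elevation
#'   class of origin.
#' @param populations_per_genotype Source populations per genotype.
#' @param families_per_population Maternal families per population.
#' @param blocks_per_site Randomised blocks per site.
#' @param seasons Ordered census labels, e.g. `c("S1","W1","S2","W2","S3")`.
#' @param survival,reproduction,establishment Parameter tables as returned by
#'   [default_rates()]; any of them may be replaced wholesale.
#' @param seed_dist Conditional seed-count law for flowering plants:
#'   zero-inflated Poisson (`"zip"`, default) or zero-inflated negative
#'   binomial (`"nbinom"`).
#' @param nbinom_size Dispersion parameter when `seed_dist = "nbinom"`.
#' @param family_sd,block_sd Standard deviations of optional Gaussian random
#'   intercepts (maternal family, block) applied on the logit scale for
#'   survival/flowering and the log scale for seed mean. Default 0 (off), so
#'   configured rates are exact marginal rates.
#' @param seeds_per_pot,pots_per_site Establishment-trial design: seeds sown
#'   per pot and pots per site.
#' @param rng_seed Default random seed used by the generators.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_cohort()], [generate_establishment()]
#' @export
simulation_config <- function(n_individuals_per_site = 500,
                              sites = data.frame(
                                site = c("low1", "low2", "high1", "high2"),
                                elevation = c("low", "low", "high", "high")),
                              genotypes = c("low", "high"),
                              populations_per_genotype = 3,
                              families_per_population = 20,
                              blocks_per_site = 8,
                              seasons = c("S1", "W1", "S2", "W2", "S3"),
                              survival = NULL,
                              reproduction = NULL,
                              establishment = NULL,
                              seed_dist = c("zip", "nbinom"),
                              nbinom_size = 5,
                              family_sd = 0,
                              block_sd = 0,
                              seeds_per_pot = 10,
                              pots_per_site = 120,
                              rng_seed = 1L) {
  rates <- default_rates()
  cfg <- list(
    n_individuals_per_site = n_individuals_per_site,
    sites = sites,
    genotypes = genotypes,
    populations_per_genotype = populations_per_genotype,
    families_per_population = families_per_population,
    blocks_per_site = blocks_per_site,
    seasons = seasons,
    survival = survival %||% rates$survival,
    reproduction = reproduction %||% rates$reproduction,
    establishment = establishment %||% rates$establishment,
    seed_dist = match.arg(seed_dist),
    nbinom_size = nbinom_size,
    family_sd = family_sd,
    block_sd = block_sd,
    seeds_per_pot = seeds_per_pot,
    pots_per_site = pots_per_site,
    rng_seed = rng_seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks all invariants of a [simulation_config()] object: probabilities in
#' \[0,1\], non-negative seed means, at least one individual per site, a
#' non-empty ordered season list alternating `S`/`W` stages, and complete
#' parameter coverage of every genotype \eqn{\times} elevation stratum.
#'
#' @param config A `sim_config` object.
#' @return `config`, invisibly, if valid; otherwise a configuration error.
#' @export
validate_sim_config <- function(config) {
  if (!inherits(config, "sim_config")) stop_config("not a sim_config object")
  if (length(config$seasons) < 1) stop_config("season list is empty")
  pref <- substr(config$seasons, 1, 1)
  if (!all(pref %in% c("S", "W"))) {
    stop_config("season labels must start with 'S' (summer) or 'W' (winter)")
  }
  if (any(pref[-1] == pref[-length(pref)])) {
    stop_config("seasons must alternate summer and winter stages")
  }
  if (config$n_individuals_per_site < 1) {
    stop_config("n_individuals_per_site must be >= 1")
  }
  if (!all(c("site", "elevation") %in% names(config$sites))) {
    stop_config("sites must have columns 'site' and 'elevation'")
  }
  n_trans <- length(config$seasons) - 1L
  n_years <- sum(pref == "S")
  for (g in config$genotypes) {
    for (e in unique(config$sites$elevation)) {
      sv <- config$survival[config$survival$genotype == g &
                            config$survival$elevation == e, ]
      if (n_trans > 0 && nrow(sv) != n_trans) {
        stop_config("survival needs %d transitions for genotype=%s elevation=%s",
                    n_trans, g, e)
      }
      if (!is_probability(sv$prob)) {
        stop_config("survival probabilities outside [0,1] for %s/%s", g, e)
      }
      rp <- config$reproduction[config$reproduction$genotype == g &
                                config$reproduction$elevation == e, ]
      if (nrow(rp) != n_years) {
        stop_config("reproduction needs %d years for genotype=%s elevation=%s",
                    n_years, g, e)
      }
      if (!is_probability(rp$flowering_prob)) {
        stop_config("flowering probabilities outside [0,1] for %s/%s", g, e)
      }
      if (!is_probability(rp$seed_zero_infl)) {
        stop_config("seed zero-inflation outside [0,1] for %s/%s", g, e)
      }
      if (any(rp$seed_mean < 0)) {
        stop_config("seed_mean must be non-negative for %s/%s", g, e)
      }
      es <- config$establishment[config$establishment$genotype == g &
                                 config$establishment$elevation == e, ]
      if (nrow(es) != 1 || !is_probability(es$prob)) {
        stop_config("establishment probability missing or outside [0,1] for %s/%s",
                    g, e)
      }
    }
  }
  if (config$seeds_per_pot < 1) stop_config("seeds_per_pot must be >= 1")
  if (config$pots_per_site < 1) stop_config("pots_per_site must be >= 1")
  if (config$family_sd < 0 || config$block_sd < 0) {
    stop_config("random-intercept standard deviations must be non-negative")
  }
  invisible(config)
}

# Population labels: one block of populations per genotype ("low1", ...).
population_labels <- function(config) {
  unlist(lapply(config$genotypes, function(g) {
    paste0(g, seq_len(config$populations_per_genotype))
  }))
}

rate_key <- function(genotype, elevation) paste(genotype, elevation, sep = ".")

# Lookup matrices keyed by genotype.elevation for fast vectorised indexing.
survival_matrix <- function(config) {
  n_trans <- length(config$seasons) - 1L
  keys <- unique(rate_key(config$survival$genotype, config$survival$elevation))
  m <- matrix(NA_real_, length(keys), n_trans, dimnames = list(keys, NULL))
  for (i in seq_len(nrow(config$survival))) {
    r <- config$survival[i, ]
    m[rate_key(r$genotype, r$elevation), r$transition] <- r$prob
  }
  m
}

reproduction_matrices <- function(config) {
  rp <- config$reproduction
  keys <- unique(rate_key(rp$genotype, rp$elevation))
  n_years <- max(rp$year)
  out <- list(flower = NULL, mean = NULL, zero = NULL)
  for (nm in names(out)) {
    out[[nm]] <- matrix(NA_real_, length(keys), n_years,
                        dimnames = list(keys, NULL))
  }
  col <- c(flower = "flowering_prob", mean = "seed_mean",
           zero = "seed_zero_infl")
  for (i in seq_len(nrow(rp))) {
    r <- rp[i, ]
    k <- rate_key(r$genotype, r$elevation)
    for (nm in names(out)) out[[nm]][k, r$year] <- r[[col[[nm]]]]
  }
  out
}

#' Simulate an individual-level transplant cohort
#'
#' Generates one census row per transplanted individual. Survival is a chain
#' of independent per-season Bernoulli draws conditional on being alive at the
#' previous census; flowering is Bernoulli conditional on being alive at that
#' year's summer census; seed counts are zero-inflated Poisson (or negative
#' binomial) draws conditional on flowering. Individuals are assigned in
#' balanced rotation to populations, maternal families and blocks, emulating
#' a randomised reciprocal transplant design in which every population is
#' planted at every site.
#'
#' The output is reproducible: the same configuration and seed give an
#' identical table, and generation never disturbs the caller's RNG state.
#'
#' @param config A [simulation_config()] object.
#' @param seed Integer seed; defaults to `config$rng_seed`.
#' @return A data frame (cohort table) with one row per individual and columns
#'   `individual_id`, `site`, `elevation`, `block`, `genotype`, `population`,
#'   `family`, `alive_<season>` (0/1 per census), `flowered_y<i>` and
#'   `seeds_y<i>` per reproductive year.
#' @examples
#' cfg <- simulation_config(n_individuals_per_site = 60)
#' cohort <- generate_cohort(cfg, seed = 42)
#' head(cohort)
#' @export
generate_cohort <- function(config, seed = config$rng_seed) {
  validate_sim_config(config)
  seasons <- config$seasons
  n_seasons <- length(seasons)
  summer_idx <- which(substr(seasons, 1, 1) == "S")
  n_years <- length(summer_idx)
  pops <- population_labels(config)
  n_pops <- length(pops)
  pop_geno <- sub("[0-9]+$", "", pops)

  per_site <- lapply(seq_len(nrow(config$sites)), function(si) {
    n <- config$n_individuals_per_site
    i <- seq_len(n)
    pop_i <- ((i - 1L) %% n_pops) + 1L
    fam_i <- (((i - 1L) %/% n_pops) %% config$families_per_population) + 1L
    data.frame(
      site = config$sites$site[si],
      elevation = config$sites$elevation[si],
      block = ((i - 1L) %% config$blocks_per_site) + 1L,
      genotype = pop_geno[pop_i],
      population = pops[pop_i],
      family = paste0(pops[pop_i], "_f", fam_i))
  })
  ind <- do.call(rbind, per_site)
  n_ind <- nrow(ind)
  ind <- cbind(individual_id = sprintf("ind%05d", seq_len(n_ind)), ind)
  key <- rate_key(ind$genotype, ind$elevation)

  sv <- survival_matrix(config)
  rp <- reproduction_matrices(config)

  with_seed(seed, {
    fam_eff <- blk_eff <- numeric(n_ind)
    if (config$family_sd > 0) {
      fams <- unique(ind$family)
      fe <- stats::rnorm(length(fams), 0, config$family_sd)
      fam_eff <- fe[match(ind$family, fams)]
    }
    if (config$block_sd > 0) {
      blks <- unique(paste(ind$site, ind$block))
      be <- stats::rnorm(length(blks), 0, config$block_sd)
      blk_eff <- be[match(paste(ind$site, ind$block), blks)]
    }
    shift_p <- function(p) stats::plogis(stats::qlogis(p) + fam_eff + blk_eff)

    alive <- matrix(1L, n_ind, n_seasons,
                    dimnames = list(NULL, paste0("alive_", seasons)))
    if (n_seasons > 1) {
      for (t in seq_len(n_seasons - 1L)) {
        p <- shift_p(sv[key, t])
        surv <- as.integer(stats::runif(n_ind) < p)
        alive[, t + 1L] <- alive[, t] * surv
      }
    }
    flowered <- matrix(0L, n_ind, n_years,
                       dimnames = list(NULL, paste0("flowered_y", seq_len(n_years))))
    seeds <- matrix(0L, n_ind, n_years,
                    dimnames = list(NULL, paste0("seeds_y", seq_len(n_years))))
    for (y in seq_len(n_years)) {
      pf <- shift_p(rp$flower[key, y])
      flowered[, y] <- alive[, summer_idx[y]] *
        as.integer(stats::runif(n_ind) < pf)
      fl <- flowered[, y] == 1L
      if (any(fl)) {
        mu <- exp(log(pmax(rp$mean[key, y], 1e-12)) + fam_eff + blk_eff)[fl]
        zero <- stats::runif(sum(fl)) < rp$zero[key, y][fl]
        cnt <- if (config$seed_dist == "zip") {
          stats::rpois(sum(fl), mu)
        } else {
          stats::rnbinom(sum(fl), mu = mu, size = config$nbinom_size)
        }
        seeds[fl, y] <- ifelse(zero, 0L, cnt)
      }
    }
    out <- cbind(ind, as.data.frame(alive), as.data.frame(flowered),
                 as.data.frame(seeds))
    rownames(out) <- NULL
    attr(out, "seasons") <- seasons
    out
  })
}

#' Simulate a seedling establishment trial
#'
#' Generates one row per sown pot. Pots are assigned in rotation to all
#' populations at every site; the number of established seedlings per pot is
#' a binomial draw with the configured per-seed establishment probability of
#' that genotype at that site's elevation.
#'
#' @inheritParams generate_cohort
#' @return A data frame (establishment table) with columns `pot_id`, `site`,
#'   `elevation`, `genotype`, `population`, `family`, `sown`, `established`.
#' @examples
#' cfg <- simulation_config(pots_per_site = 24)
#' trials <- generate_establishment(cfg, seed = 42)
#' head(trials)
#' @export
generate_establishment <- function(config, seed = config$rng_seed) {
  validate_sim_config(config)
  pops <- population_labels(config)
  n_pops <- length(pops)
  pop_geno <- sub("[0-9]+$", "", pops)
  est <- config$establishment
  per_site <- lapply(seq_len(nrow(config$sites)), function(si) {
    n <- config$pots_per_site
    i <- seq_len(n)
    pop_i <- ((i - 1L) %% n_pops) + 1L
    fam_i <- (((i - 1L) %/% n_pops) %% 5L) + 1L
    data.frame(
      site = config$sites$site[si],
      elevation = config$sites$elevation[si],
      genotype = pop_geno[pop_i],
      population = pops[pop_i],
      family = paste0(pops[pop_i], "_f", fam_i),
      sown = config$seeds_per_pot)
  })
  pots <- do.call(rbind, per_site)
  pots <- cbind(pot_id = sprintf("pot%04d", seq_len(nrow(pots))), pots)
  p <- est$prob[match(rate_key(pots$genotype, pots$elevation),
                      rate_key(est$genotype, est$elevation))]
  with_seed(seed, {
    pots$established <- stats::rbinom(nrow(pots), pots$sown, p)
    rownames(pots) <- NULL
    pots
  })
}

#' True vital rates implied by a simulation configuration
#'
#' Returns, for one genotype \eqn{\times} elevation stratum, the vital-rate
#' set the simulator was configured with: the seasonal survival probabilities,
#' flowering probabilities, expected seed count per flowering plant (the
#' zero-inflated mean \eqn{(1-\pi)\mu}), establishment probability, and the
#' composite reproductive rates. Useful as ground truth when checking
#' estimator recovery or bootstrap coverage on synthetic cohorts.
#'
#' @param config A [simulation_config()] object.
#' @param genotype,elevation Stratum labels.
#' @return A `vital_rates` object (see [estimate_vital_rates()]).
#' @export
true_vital_rates <- function(config, genotype, elevation) {
  validate_sim_config(config)
  key <- rate_key(genotype, elevation)
  sv <- survival_matrix(config)[key, ]
  rp <- reproduction_matrices(config)
  Fp <- rp$flower[key, ]
  N <- (1 - rp$zero[key, ]) * rp$mean[key, ]
  est <- config$establishment
  E <- est$prob[est$genotype == genotype & est$elevation == elevation]
  new_vital_rates(genotype = genotype, environment = elevation,
                  seasons = config$seasons,
                  T = as.numeric(sv), F = as.numeric(Fp), N = as.numeric(N),
                  E = E, at_risk = NULL)
}
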