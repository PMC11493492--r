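# CSV dialect: comma-separated, UTF-8, mandatory header, booleans as 0/1,
# missing values as empty fields.

#' Read and write cohort and establishment tables
#'
#' Plain-CSV serialisation of the two input tables. `read_cohort_csv`
#' restores the ordered season labels from the `alive_<season>` columns and
#' runs [validate_inputs()] unless `validate = FALSE`.
#'
#' @param path File path.
#' @param validate Check table invariants on read (default `TRUE`).
#' @return The table as a data frame.
#' @name table_io
#' @export
read_cohort_csv <- function(path, validate = TRUE) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(x, "seasons") <- sub("^alive_", "", grep("^alive_", names(x), value = TRUE))
  if (validate) {
    diag <- validate_inputs(x)
    if (nrow(diag) > 0) {
      stop_estimation("cohort table violates invariants (%d problems); run validate_inputs() for details",
                      nrow(diag))
    }
  }
  x
}

#' @rdname table_io
#' @param cohort Cohort table.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_establishment_csv <- function(path, validate = TRUE) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (validate) {
    diag <- validate_inputs(cohort = NULL, trials = x)
    if (nrow(diag) > 0) {
      stop_estimation("establishment table violates invariants (%d problems)",
                      nrow(diag))
    }
  }
  x
}

#' @rdname table_io
#' @param trials Establishment table.
#' @export
write_establishment_csv <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' Reads a flat YAML file whose keys mirror the arguments of
#' [simulation_config()]. The tables `sites`, `survival`, `reproduction` and
#' `establishment` may be given as lists of records; scalar fields are passed
#' through. Missing fields fall back to the defaults.
#'
#' @param path YAML file path.
#' @return A validated `sim_config` object.
#' @export
config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  scalars <- c("n_individuals_per_site", "populations_per_genotype",
               "families_per_population", "blocks_per_site", "seed_dist",
               "nbinom_size", "family_sd", "block_sd", "seeds_per_pot",
               "pots_per_site", "rng_seed")
  for (nm in scalars) if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  if (!is.null(y$genotypes)) args$genotypes <- unlist(y$genotypes)
  if (!is.null(y$seasons)) args$seasons <- unlist(y$seasons)
  for (nm in c("sites", "survival", "reproduction", "establishment")) {
    if (!is.null(y[[nm]])) {
      args[[nm]] <- do.call(rbind, lapply(y[[nm]], function(r) {
        as.data.frame(r, stringsAsFactors = FALSE)
      }))
    }
  }
  do.call(simulation_config, args)
}

#' Write a simulation configuration to YAML
#'
#' @param config A `sim_config` object.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
config_to_yaml <- function(config, path) {
  validate_sim_config(config)
  df_records <- function(d) lapply(seq_len(nrow(d)), function(i) as.list(d[i, ]))
  y <- list(
    n_individuals_per_site = config$n_individuals_per_site,
    genotypes = config$genotypes,
    populations_per_genotype = config$populations_per_genotype,
    families_per_population = config$families_per_population,
    blocks_per_site = config$blocks_per_site,
    seasons = config$seasons,
    seed_dist = config$seed_dist,
    nbinom_size = config$nbinom_size,
    family_sd = config$family_sd,
    block_sd = config$block_sd,
    seeds_per_pot = config$seeds_per_pot,
    pots_per_site = config$pots_per_site,
    rng_seed = config$rng_seed,
    sites = df_records(config$sites),
    survival = df_records(config$survival),
    reproduction = df_records(config$reproduction),
    establishment = df_records(config$establishment))
  yaml::write_yaml(y, path)
  invisible(path)
}

# Serialise a vital_rates object as a tidy data frame (for CSV export).
vital_rates_to_df <- function(vr) {
  rbind(
    data.frame(genotype = vr$genotype, environment = vr$environment,
               rate = names(vr$T), value = as.numeric(vr$T)),
    data.frame(genotype = vr$genotype, environment = vr$environment,
               rate = names(vr$F), value = as.numeric(vr$F)),
    data.frame(genotype = vr$genotype, environment = vr$environment,
               rate = names(vr$N), value = as.numeric(vr$N)),
    data.frame(genotype = vr$genotype, environment = vr$environment,
               rate = "E", value = vr$E),
    data.frame(genotype = vr$genotype, environment = vr$environment,
               rate = names(vr$R), value = as.numeric(vr$R)))
}
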