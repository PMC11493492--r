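#' Validate cohort and establishment tables
#'
#' Structural checks of the analysis inputs: census status must be monotone
#' non-increasing across the ordered seasons (no resurrection), flowering in
#' a year requires being alive at that year's summer census, a positive seed
#' count requires flowering, status flags must be 0/1, seed counts
#' non-negative, and establishment counts must satisfy
#' `0 <= established <= sown` with `sown >= 1`.
#'
#' @param cohort Cohort table, or `NULL` to check only `trials`.
#' @param trials Establishment table, or `NULL`.
#' @return Data frame of violations with columns `table`, `id`, `rule`,
#'   `message`; zero rows when all checks pass.
#' @export
validate_inputs <- function(cohort = NULL, trials = NULL) {
  probs <- list()
  note <- function(table, id, rule, message) {
    probs[[length(probs) + 1L]] <<- data.frame(
      table = table, id = id, rule = rule, message = message)
  }
  if (!is.null(cohort)) {
    need <- c("individual_id", "genotype", "population", "site", "elevation")
    miss <- setdiff(need, names(cohort))
    if (length(miss) > 0) {
      note("cohort", NA_character_, "columns",
           paste("missing columns:", paste(miss, collapse = ", ")))
    } else {
      acols <- grep("^alive_", names(cohort), value = TRUE)
      fcols <- year_columns(cohort, "flowered")
      scols <- year_columns(cohort, "seeds")
      seasons <- sub("^alive_", "", acols)
      summer_idx <- which(substr(seasons, 1, 1) == "S")
      ids <- as.character(cohort$individual_id)
      for (cl in c(acols, fcols)) {
        bad <- which(!cohort[[cl]] %in% c(0L, 1L))
        for (i in bad) note("cohort", ids[i], "binary",
                            sprintf("%s is not 0/1", cl))
      }
      if (length(acols) > 1) {
        for (t in seq_len(length(acols) - 1L)) {
          bad <- which(cohort[[acols[t + 1L]]] > cohort[[acols[t]]])
          for (i in bad) {
            note("cohort", ids[i], "monotone_survival",
                 sprintf("alive at %s but dead at %s",
                         seasons[t + 1L], seasons[t]))
          }
        }
      }
      for (y in seq_along(fcols)) {
        if (y <= length(summer_idx)) {
          bad <- which(cohort[[fcols[y]]] > cohort[[acols[summer_idx[y]]]])
          for (i in bad) {
            note("cohort", ids[i], "flowered_implies_alive",
                 sprintf("flowered in year %d but dead at %s",
                         y, seasons[summer_idx[y]]))
          }
        }
        bad <- which(cohort[[scols[y]]] > 0 & cohort[[fcols[y]]] == 0)
        for (i in bad) {
          note("cohort", ids[i], "seeds_imply_flowering",
               sprintf("seeds > 0 in year %d without flowering", y))
        }
        bad <- which(cohort[[scols[y]]] < 0)
        for (i in bad) note("cohort", ids[i], "seed_count",
                            sprintf("negative seed count in year %d", y))
      }
    }
  }
  if (!is.null(trials)) {
    ids <- as.character(trials$pot_id %||% seq_len(nrow(trials)))
    bad <- which(trials$sown < 1)
    for (i in bad) note("establishment", ids[i], "sown", "sown < 1")
    bad <- which(trials$established < 0 | trials$established > trials$sown)
    for (i in bad) {
      note("establishment", ids[i], "established_bounds",
           "established outside [0, sown]")
    }
  }
  if (length(probs) == 0) {
    data.frame(table = character(), id = character(), rule = character(),
               message = character())
  } else {
    do.call(rbind, probs)
  }
}

stratum_key <- function(genotype, environment) {
  paste(genotype, environment, sep = ".")
}

#' Run the full demographic analysis pipeline
#'
#' End-to-end orchestration: simulate (or ingest) the cohort and
#' establishment tables, validate them, estimate vital rates per genotype
#' \eqn{\times} environment, build the seasonal projection matrices, run the
#' eigenanalyses, bootstrap the growth rates with population stratification,
#' compare the local against the foreign genotype in each environment
#' (percent advantage and difference interval), decompose the
#' local-vs-foreign \eqn{\lambda} difference with a fixed-design LTRE, and
#' compute per-population elasticity shift/distance descriptors.
#'
#' One run seed deterministically spawns independent sub-seeds for the
#' cohort simulation, the establishment simulation and each bootstrap, so
#' e.g. changing `B` never changes the simulated data, and two runs with the
#' same inputs and seed produce identical reports.
#'
#' @param config A [simulation_config()] object, or `NULL` when `cohort` and
#'   `trials` are supplied directly (exactly one input mode must be used).
#' @param cohort,trials Observed tables (see [generate_cohort()] and
#'   [generate_establishment()] for the layout).
#' @param B Bootstrap replicates per stratum.
#' @param alpha Two-sided error rate for all intervals.
#' @param seed Run seed.
#' @param topology Terminal-stage rule for [build_matrix()].
#' @param ltre_sensitivity Sensitivity evaluation point for
#'   [ltre_fixed_design()].
#' @param out_dir Optional directory; when given, all artifacts (tables,
#'   matrices, JSON summaries, human-readable summary) are written there.
#' @param coerce Drop rows that violate input invariants (with a warning)
#'   instead of failing.
#' @return Object of class `run_report`.
#' @examples
#' cfg <- simulation_config(n_individuals_per_site = 120, pots_per_site = 60)
#' rep <- run_pipeline(config = cfg, B = 50, seed = 1)
#' rep$comparisons$low$advantage_pct
#' @export
run_pipeline <- function(config = NULL, cohort = NULL, trials = NULL,
                         B = 20000, alpha = 0.05, seed = 1,
                         topology = c("truncate", "selfloop"),
                         ltre_sensitivity = c("midpoint", "reference"),
                         out_dir = NULL, coerce = FALSE) {
  topology <- match.arg(topology)
  ltre_sensitivity <- match.arg(ltre_sensitivity)
  have_config <- !is.null(config)
  have_tables <- !is.null(cohort) || !is.null(trials)
  if (have_config == have_tables) {
    stop_config("provide exactly one of: a simulation config, or cohort+trials tables")
  }
  if (have_config) {
    validate_sim_config(config)
    cohort <- generate_cohort(config, seed = derive_seed(seed, 1L))
    trials <- generate_establishment(config, seed = derive_seed(seed, 2L))
  }
  if (is.null(cohort) || is.null(trials)) {
    stop_config("both cohort and trials tables are required")
  }
  diag <- validate_inputs(cohort, trials)
  if (nrow(diag) > 0) {
    if (!coerce) {
      stop_estimation("input tables violate invariants (%d problems; first: %s)",
                      nrow(diag), diag$message[1])
    }
    warning(sprintf("dropping %d invalid rows", nrow(diag)))
    bad_ind <- unique(diag$id[diag$table == "cohort"])
    bad_pot <- unique(diag$id[diag$table == "establishment"])
    seasons <- attr(cohort, "seasons")
    cohort <- cohort[!cohort$individual_id %in% bad_ind, , drop = FALSE]
    attr(cohort, "seasons") <- seasons
    trials <- trials[!as.character(trials$pot_id) %in% bad_pot, , drop = FALSE]
  }

  environments <- unique(cohort$elevation)
  genotypes <- unique(cohort$genotype)
  strata <- expand.grid(genotype = genotypes, environment = environments,
                        stringsAsFactors = FALSE)
  vital_rates <- list(); matrices <- list(); eigen <- list(); boot <- list()
  for (i in seq_len(nrow(strata))) {
    g <- strata$genotype[i]; e <- strata$environment[i]
    key <- stratum_key(g, e)
    vr <- tryCatch(
      estimate_vital_rates(cohort, trials, g, e),
      error = function(err) {
        stop_estimation("stratum genotype=%s environment=%s failed: %s",
                        g, e, conditionMessage(err))
      })
    vital_rates[[key]] <- vr
    matrices[[key]] <- build_matrix(vr, topology = topology)
    eigen[[key]] <- eigen_analysis(matrices[[key]])
    boot[[key]] <- bootstrap_growth_rate(
      cohort, trials, g, e, B = B, alpha = alpha,
      seed = derive_seed(seed, 10L + i), topology = topology)
  }

  comparisons <- list(); ltre <- list()
  for (e in environments) {
    local <- genotypes[genotypes == e]
    if (length(local) != 1) next  # no genotype is native to this environment
    foreign <- setdiff(genotypes, local)
    if (length(foreign) != 1) next
    kl <- stratum_key(local, e); kf <- stratum_key(foreign, e)
    comparisons[[e]] <- compare_growth_rates(boot[[kl]], boot[[kf]])
    ltre[[e]] <- ltre_fixed_design(matrices[[kl]], matrices[[kf]],
                                   sensitivity = ltre_sensitivity)
  }

  elasticity <- NULL
  if (setequal(genotypes, environments) && length(genotypes) == 2) {
    per_pop <- function(g, env) {
      pops <- sort(unique(cohort$population[cohort$genotype == g]))
      out <- list()
      for (p in pops) {
        ea <- tryCatch({
          vr <- estimate_vital_rates(cohort, trials, g, env, population = p)
          eigen_analysis(build_matrix(vr, topology = topology))
        }, error = function(err) NULL)
        if (!is.null(ea) && !any(is.na(ea$elasticity))) out[[p]] <- ea
      }
      out
    }
    gl <- genotypes[1]; gh <- genotypes[2]
    hl <- per_pop(gl, gl); al <- per_pop(gl, gh)
    hh <- per_pop(gh, gh); ah <- per_pop(gh, gl)
    common_l <- intersect(names(hl), names(al))
    common_h <- intersect(names(hh), names(ah))
    if (length(common_l) > 0 && length(common_h) > 0) {
      elasticity <- elasticity_shift_distance(hl[common_l], al[common_l],
                                              hh[common_h], ah[common_h])
    }
  }

  report <- structure(list(
    vital_rates = vital_rates, matrices = matrices, eigen = eigen,
    bootstrap = boot, comparisons = comparisons, ltre = ltre,
    elasticity = elasticity,
    cohort = cohort, trials = trials,
    provenance = list(seed = seed, B = B, alpha = alpha,
                      topology = topology,
                      ltre_sensitivity = ltre_sensitivity,
                      n_individuals = nrow(cohort), n_pots = nrow(trials),
                      simulated = have_config,
                      package_version = as.character(utils::packageVersion("mpmfit")))),
    class = "run_report")
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' Write all pipeline artifacts to a directory
#'
#' Persists the inputs (CSV), per-stratum vital rates and projection matrices
#' (CSV), eigenanalyses, LTRE decompositions, growth-rate comparisons and
#' provenance (JSON), and a human-readable `summary.txt`.
#'
#' @param report A `run_report` object.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort_csv(report$cohort, file.path(out_dir, "cohort.csv"))
  write_establishment_csv(report$trials, file.path(out_dir, "establishment.csv"))
  vr_df <- do.call(rbind, lapply(report$vital_rates, vital_rates_to_df))
  utils::write.csv(vr_df, file.path(out_dir, "vital_rates.csv"),
                   row.names = FALSE)
  for (key in names(report$matrices)) {
    utils::write.csv(report$matrices[[key]]$A,
                     file.path(out_dir, paste0("matrix_", key, ".csv")))
  }
  jw <- function(x, file) {
    jsonlite::write_json(x, file.path(out_dir, file), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  jw(lapply(report$eigen, function(ea) {
    list(lambda = ea$lambda, w = as.list(ea$w), v = as.list(ea$v),
         primitive = ea$primitive, degenerate = ea$degenerate)
  }), "eigen.json")
  jw(lapply(report$ltre, function(l) {
    list(delta_lambda = l$delta_lambda,
         contributions = as.list(l$contributions),
         approx_error = l$approx_error)
  }), "ltre.json")
  jw(lapply(report$comparisons, function(cm) {
    cm[c("lambda_local", "lambda_foreign", "advantage_pct", "difference",
         "ci_low", "ci_high", "excludes_zero", "n_degenerate", "B", "alpha")]
  }), "comparisons.json")
  jw(lapply(report$bootstrap, function(b) {
    b[c("statistic_name", "point_estimate", "ci_low", "ci_high", "z0",
        "n_degenerate", "B", "alpha")]
  }), "bootstrap.json")
  if (!is.null(report$elasticity)) {
    utils::write.csv(report$elasticity$table,
                     file.path(out_dir, "elasticity_shift_distance.csv"),
                     row.names = FALSE)
  }
  jw(report$provenance, "provenance.json")
  con <- file(file.path(out_dir, "summary.txt"), "w")
  sink(con); on.exit({ sink(); close(con) }, add = TRUE)
  print(report)
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Reciprocal-transplant demographic analysis\n")
  cat(sprintf("  individuals: %d, pots: %d, B = %d, seed = %d\n",
              x$provenance$n_individuals, x$provenance$n_pots,
              x$provenance$B, x$provenance$seed))
  for (key in names(x$bootstrap)) {
    b <- x$bootstrap[[key]]
    cat(sprintf("  lambda[%s] = %.4f  BC CI [%.4f, %.4f]\n",
                key, b$point_estimate, b$ci_low, b$ci_high))
  }
  for (e in names(x$comparisons)) {
    cm <- x$comparisons[[e]]
    cat(sprintf("  %s elevation: local advantage %.1f%%%s\n", e,
                cm$advantage_pct,
                if (cm$excludes_zero) " (difference CI excludes 0)" else ""))
  }
  for (e in names(x$ltre)) {
    l <- x$ltre[[e]]
    top <- names(l$contributions)[which.max(abs(l$contributions))]
    cat(sprintf("  LTRE %s: delta lambda = %.4f, largest contribution %s\n",
                e, l$delta_lambda, top))
  }
  if (!is.null(x$elasticity)) {
    cat(sprintf("  elasticity shift~distance correlation: %.3f\n",
                x$elasticity$correlation))
  }
  invisible(x)
}
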