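#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and tests) can distinguish configuration,
# estimation and structural failures without string matching.
stop_config <- function(msg, ...) {
  stop(structure(class = c("mpmfit_config_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

stop_estimation <- function(msg, ...) {
  stop(structure(class = c("mpmfit_estimation_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

stop_structure <- function(msg, ...) {
  stop(structure(class = c("mpmfit_structure_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All exported stochastic functions take an explicit seed and route through
# here, so package calls never perturb the user's random stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1)
    }
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a per-module substream seed from the run seed, kept within the
# 32-bit integer range. Offsets are fixed per module so e.g. changing the
# number of bootstrap replicates never alters the simulated cohort.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_probability <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)
}
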