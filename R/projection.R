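#' Build a seasonal age-structured projection matrix
#'
#' Assembles a Leslie-type projection matrix over ordered seasonal stages:
#' survival rates on the subdiagonal link consecutive stages, and composite
#' reproductive rates sit in the first row (recruits enter the first stage one
#' projection step after reproduction; establishment is already folded into
#' the reproductive rates).
#'
#' Reproduction can be supplied in two forms. A `vital_rates` object (or an
#' `R` vector with one entry per reproductive year) is placed at the summer
#' stage columns, which is the layout of the seasonal life cycle. A raw
#' per-stage `R` vector of length equal to the number of stages is placed in
#' the first row as given, which permits arbitrary Leslie topologies in tests
#' and perturbation studies.
#'
#' @param rates A `vital_rates` object, or a list with elements `T` (survival
#'   per transition), `R` (reproduction per year or per stage) and optionally
#'   `seasons` (stage labels).
#' @param topology Terminal-stage rule: `"truncate"` (default; no survival out
#'   of the last stage, adding no unobserved parameter) or `"selfloop"`
#'   (terminal self-loop reusing the last observed seasonal survival).
#' @return An object of class `projection_matrix`: list with the matrix `A`,
#'   `stage_labels`, and `vital_rate_map` (character matrix naming the vital
#'   rate behind each structural entry).
#' @examples
#' build_matrix(list(T = 0.5, R = c(0, 2)))$A  # two-stage Leslie
#' @export
build_matrix <- function(rates, topology = c("truncate", "selfloop")) {
  topology <- match.arg(topology)
  if (inherits(rates, "vital_rates")) {
    T <- unname(rates$T); R <- unname(rates$R); seasons <- rates$seasons
  } else {
    T <- unname(rates$T); R <- unname(rates$R)
    seasons <- rates$seasons %||% NULL
  }
  if (any(T < 0) || any(T > 1)) {
    stop_structure("survival entries must be probabilities in [0,1]")
  }
  if (any(R < 0)) stop_structure("reproductive rates must be non-negative")
  n_stages <- length(T) + 1L
  if (is.null(seasons)) {
    seasons <- paste0(rep(c("S", "W"), length.out = n_stages),
                      rep(seq_len(n_stages), each = 2)[seq_len(n_stages)])
  }
  if (length(seasons) != n_stages) {
    stop_structure("got %d survival transitions but %d stage labels",
                   length(T), length(seasons))
  }
  summer_idx <- which(substr(seasons, 1, 1) == "S")

  A <- matrix(0, n_stages, n_stages, dimnames = list(seasons, seasons))
  map <- matrix("", n_stages, n_stages, dimnames = list(seasons, seasons))
  for (k in seq_along(T)) {
    A[k + 1L, k] <- T[k]
    map[k + 1L, k] <- paste0("T", k)
  }
  if (length(R) == n_stages) {
    # per-stage first row, placed as given
    A[1, ] <- A[1, ] + R
    map[1, R > 0] <- ifelse(map[1, R > 0] == "",
                            paste0("R", which(R > 0)), map[1, R > 0])
  } else if (length(R) == length(summer_idx)) {
    for (y in seq_along(R)) {
      A[1, summer_idx[y]] <- A[1, summer_idx[y]] + R[y]
      map[1, summer_idx[y]] <- paste0("R", y)
    }
  } else {
    stop_structure(
      "R has length %d; expected %d (per stage) or %d (per reproductive year)",
      length(R), n_stages, length(summer_idx))
  }
  if (topology == "selfloop" && length(T) > 0) {
    A[n_stages, n_stages] <- T[length(T)]
    map[n_stages, n_stages] <- paste0("T", length(T))
  }
  structure(list(A = A, stage_labels = seasons, vital_rate_map = map,
                 topology = topology),
            class = "projection_matrix")
}

as_matrix_A <- function(x) {
  if (inherits(x, "projection_matrix")) x$A
  else if (is.matrix(x)) x
  else stop_structure("expected a projection_matrix or a numeric matrix")
}

#' Eigenanalysis of a projection matrix
#'
#' Computes the asymptotic demographic quantities of a non-negative
#' projection matrix \eqn{A}: the dominant eigenvalue \eqn{\lambda}
#' (population growth rate per projection step), the stable stage
#' distribution \eqn{w} (right eigenvector, normalised to sum to one),
#' reproductive values \eqn{v} (left eigenvector, scaled so
#' \eqn{\langle v, w \rangle = 1}), the sensitivity matrix
#' \eqn{s_{ij} = \partial\lambda/\partial a_{ij} = v_i w_j} and the
#' elasticity matrix \eqn{e_{ij} = (a_{ij}/\lambda) s_{ij}}. For a primitive
#' matrix the elasticities sum to one.
#'
#' Matrices whose dominant-modulus eigenvalues form an imprimitive cycle are
#' handled by preferring the real positive eigenvalue on the spectral circle
#' when one exists (the usual case for periodic Leslie chains); otherwise
#' \eqn{\lambda} is reported as the spectral radius with `primitive = FALSE`
#' and eigenvector-based quantities set to `NA`. A matrix with no
#' reproductive loop (all reproduction zero) is nilpotent with
#' \eqn{\lambda = 0}; it is flagged `degenerate` rather than raising, so
#' bootstrap replicates never abort.
#'
#' @param x A `projection_matrix` or a non-negative numeric matrix.
#' @return Object of class `eigen_analysis` with elements `lambda`, `w`, `v`,
#'   `sensitivity`, `elasticity`, `primitive`, `degenerate`, `stage_labels`,
#'   and `vital_rate_map` (when built from a `projection_matrix`).
#' @examples
#' ea <- eigen_analysis(matrix(c(0, 0.5, 2, 0), 2, 2))
#' ea$lambda        # 1
#' ea$w             # stable stage distribution (2/3, 1/3)
#' @export
eigen_analysis <- function(x) {
  A <- as_matrix_A(x)
  if (nrow(A) != ncol(A)) stop_structure("matrix is not square")
  if (any(!is.finite(A))) stop_structure("matrix has non-finite entries")
  if (any(A < 0)) stop_structure("matrix has negative entries")
  if (all(A == 0)) stop_structure("all-zero matrix has no growth rate")
  labels <- if (inherits(x, "projection_matrix")) x$stage_labels else rownames(A)
  map <- if (inherits(x, "projection_matrix")) x$vital_rate_map else NULL
  n <- nrow(A)

  ev <- eigen(A)
  mods <- Mod(ev$values)
  lam_mod <- max(mods)
  out <- list(lambda = lam_mod, w = rep(NA_real_, n), v = rep(NA_real_, n),
              sensitivity = matrix(NA_real_, n, n),
              elasticity = matrix(NA_real_, n, n),
              primitive = FALSE, degenerate = FALSE,
              stage_labels = labels, vital_rate_map = map)
  class(out) <- "eigen_analysis"

  if (lam_mod <= .Machine$double.eps^0.5) {
    # nilpotent (no reproductive loop): growth rate 0, structure undefined
    out$lambda <- 0
    out$degenerate <- TRUE
    return(out)
  }
  tol <- lam_mod * 1e-9
  on_circle <- which(mods > lam_mod - tol)
  # prefer the real positive eigenvalue on the spectral circle (Perron root)
  real_pos <- on_circle[abs(Im(ev$values[on_circle])) < tol &
                        Re(ev$values[on_circle]) > 0]
  out$primitive <- length(on_circle) == 1L
  if (length(real_pos) == 0) {
    warning("dominant eigenvalues form a complex pair; reporting the spectral radius")
    return(out)
  }
  j <- real_pos[1]
  lam <- Re(ev$values[j])
  out$lambda <- lam

  w <- Re(ev$vectors[, j])
  if (sum(w) < 0) w <- -w
  w[w < 0 & w > -1e-12 * max(abs(w))] <- 0
  w <- w / sum(w)
  lv <- eigen(t(A))
  jv <- which.min(abs(lv$values - lam))
  v <- Re(lv$vectors[, jv])
  if (sum(v) < 0) v <- -v
  v[v < 0 & v > -1e-12 * max(abs(v))] <- 0
  v <- v / sum(v * w)  # <v, w> = 1
  s <- outer(v, w)
  e <- (A / lam) * s
  names(w) <- names(v) <- labels
  dimnames(s) <- dimnames(e) <- dimnames(A)
  out$w <- w; out$v <- v; out$sensitivity <- s; out$elasticity <- e
  out
}

#' Dominant eigenvalue of a projection matrix
#'
#' Fast path returning only the population growth rate (spectral radius).
#'
#' @inheritParams eigen_analysis
#' @return Scalar \eqn{\lambda} (0 for a nilpotent matrix).
#' @export
growth_rate <- function(x) {
  A <- as_matrix_A(x)
  vals <- eigen(A, only.values = TRUE)$values
  max(Mod(vals))
}

#' Stable age distribution grouped by season
#'
#' Reports the stable stage distribution by stage label together with its
#' season type, so summer and winter stages can be tabulated separately.
#'
#' @param analysis An `eigen_analysis` object.
#' @return Data frame with columns `stage`, `season` (`"summer"`/`"winter"`)
#'   and `proportion` (sums to one).
#' @export
stable_age_summary <- function(analysis) {
  if (!inherits(analysis, "eigen_analysis")) {
    stop_structure("expected an eigen_analysis object")
  }
  w <- analysis$w
  if (any(is.na(w))) stop_structure("stable stage distribution is undefined")
  labels <- analysis$stage_labels %||% paste0("stage", seq_along(w))
  data.frame(stage = labels,
             season = ifelse(substr(labels, 1, 1) == "W", "winter", "summer"),
             proportion = as.numeric(w))
}

# Sum elasticities over entries sharing a vital-rate name.
elasticity_by_vital_rate <- function(analysis) {
  map <- analysis$vital_rate_map
  if (is.null(map)) stop_structure("eigen_analysis carries no vital_rate_map")
  e <- analysis$elasticity
  keep <- map != ""
  tapply(e[keep], map[keep], sum)
}

#' @export
print.projection_matrix <- function(x, ...) {
  cat(sprintf("Projection matrix (%d stages, topology=%s)\n",
              nrow(x$A), x$topology))
  print(round(x$A, 4))
  invisible(x)
}

#' @export
print.eigen_analysis <- function(x, ...) {
  cat(sprintf("lambda = %.5f (primitive: %s%s)\n", x$lambda, x$primitive,
              if (x$degenerate) ", degenerate" else ""))
  if (!any(is.na(x$w))) {
    cat("stable stage distribution:\n")
    print(round(x$w, 4))
  }
  invisible(x)
}
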