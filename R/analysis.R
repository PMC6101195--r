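# Degeneracy analytics on valid model populations: parameter and measurement
# correlation matrices, normalized Euclidean and Mahalanobis distances, and
# cross-set nonparametric comparisons.

as_param_matrix <- function(x) {
  if (inherits(x, "stellate_population")) {
    m <- x$params[x$valid, , drop = FALSE]
  } else {
    m <- as.matrix(x)
  }
  if (!nrow(m)) stop("no (valid) models in input")
  m
}

#' Pairwise Pearson correlations between model parameters
#'
#' Computes the p x p Pearson correlation matrix across the valid models of
#' a population (55 parameters give 1485 unique off-diagonal pairs). A
#' constant column has no defined correlation and is reported as missing.
#'
#' @param x A `stellate_population` (valid models are used) or a numeric
#'   matrix (models x parameters).
#' @return A `correlation_matrix`: list with `r` (matrix), `n_pairs`,
#'   `values` (the unique off-diagonal coefficients), `n_models`.
#' @export
parameter_correlations <- function(x) {
  m <- as_param_matrix(x)
  if (nrow(m) < 3L) stop("need at least 3 models")
  constant <- apply(m, 2, function(v) diff(range(v)) == 0)
  r <- suppressWarnings(cor(m))
  r[constant, ] <- NA
  r[, constant] <- NA
  diag(r) <- 1
  new_correlation_matrix(r, nrow(m))
}

#' Pairwise Pearson correlations between intrinsic measurements
#'
#' The measurement analogue of [parameter_correlations()]: across a valid
#' model population, correlations between the physiological measurements
#' (the standard set is the 8 protocol measurements V_RMP, Sag, R_in, Q_R,
#' f_R, f_osc, N_400, V_AP plus the 6 STA-derived ones, 14 in all, giving
#' 91 unique pairs).
#'
#' @param measurements Data frame (models x measurements), e.g. the
#'   measurement columns of a population joined with STA metrics.
#' @return A `correlation_matrix`.
#' @export
measurement_correlations <- function(measurements) {
  m <- as.matrix(measurements)
  if (!is.numeric(m)) stop("measurements must be numeric")
  keep <- complete.cases(m)
  if (sum(keep) < 3L) stop("need at least 3 complete models")
  parameter_correlations(m[keep, , drop = FALSE])
}

new_correlation_matrix <- function(r, n_models) {
  vals <- r[upper.tri(r)]
  structure(list(r = r, n_pairs = length(vals), values = vals,
                 n_models = n_models),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf(
    "Pearson correlation matrix: %d variables, %d unique pairs, %d models\n",
    ncol(x$r), x$n_pairs, x$n_models))
  ok <- !is.na(x$values)
  cat(sprintf("  |r| median %.3f, max %.3f%s\n",
              median(abs(x$values[ok])), max(abs(x$values[ok])),
              if (any(!ok)) sprintf(" (%d undefined)", sum(!ok)) else ""))
  invisible(x)
}

#' Normalized Euclidean distances between models
#'
#' Euclidean distance between parameter vectors after rescaling each
#' parameter's min-max range to 0-1, so every coordinate contributes
#' comparably; distances are bounded by `sqrt(55)`.
#'
#' @param x A `stellate_population` or matrix (models x parameters).
#' @param space The `parameter_space` providing the min-max ranges.
#' @return A `distance_matrix`: list with `D` (symmetric matrix), `metric`,
#'   `max_distance` (the attainable maximum, `sqrt(p)`), `values` (unique
#'   pairwise distances).
#' @export
normalized_euclidean <- function(x, space = parameter_space()) {
  m <- as_param_matrix(x)
  rng <- space$max - space$min
  mn <- sweep(sweep(m, 2, space$min[match(colnames(m), space$name)], "-"),
              2, rng[match(colnames(m), space$name)], "/")
  D <- as.matrix(dist(mn))
  new_distance_matrix(D, "normalized-euclidean", sqrt(ncol(m)))
}

#' Mahalanobis distances between models
#'
#' Pairwise distances `sqrt((x-y)' Sigma^-1 (x-y))` on the unnormalized
#' parameter vectors, with `Sigma` the parameter covariance estimated from
#' the same (valid) population. When the population has at most as many
#' models as parameters the covariance is singular; diagonal loading
#' `Sigma + eps I` with `eps = 1e-6 trace(Sigma)/p` is applied and recorded.
#' The normalization constant is the distance between the two synthetic
#' vectors `x_max` and `x_min` holding every parameter at its maximum /
#' minimum.
#'
#' @param x A `stellate_population` or matrix.
#' @param space The `parameter_space` (for `x_max`/`x_min`).
#' @param sigma Optional covariance matrix overriding the estimate.
#' @param regularize Apply diagonal loading when needed (default: only if
#'   `n <= p` or the covariance is computationally singular).
#' @return A `distance_matrix` with `max_distance = d_M(x_max, x_min)` and
#'   a `regularized` flag.
#' @export
mahalanobis_distances <- function(x, space = parameter_space(), sigma = NULL,
                                  regularize = NULL) {
  m <- as_param_matrix(x)
  S <- if (is.null(sigma)) cov(m) else sigma
  reg <- FALSE
  if (is.null(regularize)) regularize <- nrow(m) <= ncol(m)
  if (regularize || inherits(try(solve(S), silent = TRUE), "try-error")) {
    S <- S + diag(1e-6 * sum(diag(S)) / ncol(S), ncol(S))
    reg <- TRUE
  }
  Si <- solve(S)
  U <- chol(Si)
  D <- as.matrix(dist(m %*% t(U)))
  dmax <- sqrt(mahalanobis(space$max, center = space$min, cov = Si,
                           inverted = TRUE))
  out <- new_distance_matrix(D, "mahalanobis", dmax)
  out$regularized <- reg
  out
}

new_distance_matrix <- function(D, metric, max_distance) {
  structure(list(D = D, metric = metric, max_distance = max_distance,
                 values = D[upper.tri(D)]),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("%s distance matrix: %d models, max attainable %.3f\n",
              x$metric, nrow(x$D), x$max_distance))
  if (length(x$values)) {
    cat(sprintf("  pairwise distances: median %.3f, range [%.3f, %.3f]\n",
                median(x$values), min(x$values), max(x$values)))
  }
  invisible(x)
}

#' Nonparametric comparison of a measurement across independent populations
#'
#' Kruskal-Wallis test across the valid models of two or more populations,
#' followed by pairwise two-sided Mann-Whitney (Wilcoxon rank sum) tests.
#' Raw p values are reported without multiple-testing correction.
#'
#' @param populations List of `stellate_population`s (or list of numeric
#'   vectors of the measurement values).
#' @param measurement Measurement column name (ignored for numeric input).
#' @return List with `kruskal_p`, `pairwise_p` (matrix), `n` (per-set valid
#'   counts).
#' @export
compare_sets <- function(populations, measurement = "V_RMP") {
  groups <- lapply(populations, function(p) {
    if (inherits(p, "stellate_population")) {
      v <- p$measurements[p$valid, measurement]
    } else {
      v <- as.numeric(p)
    }
    v[!is.na(v)]
  })
  if (length(groups) < 2L) stop("need at least 2 populations")
  if (any(vapply(groups, length, 1L) < 2L)) {
    stop("each population needs at least 2 valid models")
  }
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  kw <- if (length(unique(x)) == 1L) 1 else kruskal.test(x, g)$p.value
  k <- length(groups)
  pw <- matrix(NA_real_, k, k)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      pw[i, j] <- pw[j, i] <- if (identical(groups[[i]], groups[[j]])) 1 else
        suppressWarnings(wilcox.test(groups[[i]], groups[[j]])$p.value)
    }
  }
  list(kruskal_p = kw, pairwise_p = pw,
       n = vapply(groups, length, integer(1)))
}
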