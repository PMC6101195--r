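# Multiparametric multiobjective stochastic search: uniform rejection
# sampling of 55-parameter vectors, measurement of each sampled model, and
# validation against the ten physiological bounds.

#' Validate a measurement set against the physiological bounds
#'
#' Inclusive comparison of each of the ten measurements against its bounds.
#' A missing measurement (including an absent perithreshold oscillation
#' frequency) fails its criterion. A model is valid iff all ten criteria
#' pass.
#'
#' @param m A `measurement_set` (or named list holding the ten
#'   measurements).
#' @param bounds A [validation_bounds()] table.
#' @return A `validity_report`: data frame with `name`, `value`, `lower`,
#'   `upper`, `pass`, plus attributes `valid` (logical) and `reasons`.
#' @export
validate_measurements <- function(m, bounds = validation_bounds()) {
  value <- vapply(bounds$name, function(nm) {
    v <- m[[nm]]
    if (is.null(v) || length(v) != 1L) NA_real_ else as.numeric(v)
  }, numeric(1))
  pass <- !is.na(value) &
    (is.na(bounds$lower) | value >= bounds$lower) &
    (is.na(bounds$upper) | value <= bounds$upper)
  rep <- data.frame(name = bounds$name, value = value,
                    lower = bounds$lower, upper = bounds$upper, pass = pass,
                    stringsAsFactors = FALSE)
  structure(rep, class = c("validity_report", "data.frame"),
            valid = all(pass), reasons = bounds$name[!pass])
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf("Model %s (%d/10 criteria pass)\n",
              if (attr(x, "valid")) "VALID" else "invalid", sum(x$pass)))
  print.data.frame(x, ...)
  invisible(x)
}

# Widen bounds for the coarse screening pass so that models near a bound are
# not rejected by discretization error before confirmation at the fine step.
widen_bounds <- function(bounds, margin = 0.2) {
  b <- bounds
  for (i in seq_len(nrow(b))) {
    if (b$name[i] %in% c("N_100", "N_400")) {
      if (!is.na(b$lower[i])) b$lower[i] <- b$lower[i] - 2
      if (!is.na(b$upper[i])) b$upper[i] <- b$upper[i] + 2
    } else if (!is.na(b$lower[i]) && !is.na(b$upper[i])) {
      w <- (b$upper[i] - b$lower[i]) * margin
      b$lower[i] <- b$lower[i] - w
      b$upper[i] <- b$upper[i] + w
    } else if (!is.na(b$upper[i])) {
      b$upper[i] <- b$upper[i] * (1 + margin)
    } else {
      b$lower[i] <- b$lower[i] * (1 - margin)
    }
  }
  b
}

measurement_row <- function(m) {
  v <- vapply(MEASUREMENT_NAMES, function(nm) {
    x <- m[[nm]]
    if (is.null(x)) NA_real_ else as.numeric(x)
  }, numeric(1))
  out <- as.data.frame(as.list(v))
  out$Phi_L <- if (is.null(m$Phi_L)) NA_real_ else m$Phi_L
  out$aborted_at <- if (is.na(m$aborted_at)) "" else m$aborted_at
  out$flags <- paste(m$flags, collapse = ";")
  out
}

#' Evaluate one parameter vector
#'
#' Builds the model, runs the measurement protocols (short-circuiting once a
#' criterion has failed, which cannot change the validity decision), and
#' validates against the bounds.
#'
#' @param params Parameter vector (55).
#' @param bounds Validation bounds.
#' @param dt Integration step, ms.
#' @param short_circuit Abort measurement after the first failed criterion.
#' @return List `measurements` (a `measurement_set`) and `validity` (a
#'   `validity_report`).
#' @export
evaluate_model <- function(params, bounds = validation_bounds(), dt = 0.025,
                           short_circuit = TRUE) {
  model <- stellate_model(params)
  m <- measure_all(model, dt = dt, bounds = bounds,
                   short_circuit = short_circuit)
  list(measurements = m, validity = validate_measurements(m, bounds))
}

#' Run the stochastic search
#'
#' Samples `n` parameter vectors independently and uniformly within their
#' ranges, measures each resulting model, and validates it against the ten
#' physiological bounds. Model `k` is derived from substream seed `k` (see
#' [model_seeds()]), so any subset of models is reproducible independent of
#' batch size, and an interrupted search resumed over the remaining indices
#' yields the same population.
#'
#' With `screen_dt` set, each model is first evaluated at the coarser
#' screening step against bounds widened by `screen_margin`; only models
#' passing the screen are confirmed at `dt` against the exact bounds (the
#' recorded measurements of screen-rejected models are their screening
#' values). The screening step is recorded in the population metadata.
#'
#' @param n Number of models to sample.
#' @param seed Global integer seed.
#' @param space Parameter space to sample from.
#' @param bounds Validation bounds.
#' @param dt Integration step for (confirmation) measurements, ms.
#' @param screen_dt Optional coarser screening step, ms.
#' @param screen_margin Relative widening of each bound range during
#'   screening.
#' @param indices Optional subset of model indices to evaluate (resume /
#'   parallel splits); default `1:n`.
#' @param verbose Print progress every 100 models.
#' @return A `stellate_population`: list with `params` (matrix), `seeds`,
#'   `measurements` (data frame), `validity` (logical matrix), `valid`
#'   (logical), `meta`.
#' @export
#' @examples
#' \donttest{
#' pop <- run_search(2, seed = 1, screen_dt = 0.1)
#' }
run_search <- function(n, seed, space = parameter_space(),
                       bounds = validation_bounds(), dt = 0.025,
                       screen_dt = NULL, screen_margin = 0.2,
                       indices = NULL, verbose = FALSE) {
  stopifnot(n >= 0)
  if (is.null(indices)) indices <- seq_len(n)
  if (n == 0 || length(indices) == 0) {
    return(empty_population(seed, dt, screen_dt))
  }
  seeds <- model_seeds(seed, max(indices))[indices]
  wide <- widen_bounds(bounds, screen_margin)
  params <- matrix(NA_real_, nrow = length(indices), ncol = 55,
                   dimnames = list(NULL, space$name))
  mrows <- vector("list", length(indices))
  vmat <- matrix(NA, nrow = length(indices), ncol = nrow(bounds),
                 dimnames = list(NULL, bounds$name))
  screened_only <- logical(length(indices))

  for (i in seq_along(indices)) {
    p <- sample_parameters(space, n = 1, seed = seeds[i])[1, ]
    params[i, ] <- p
    if (!is.null(screen_dt)) {
      scr <- evaluate_model(p, bounds = wide, dt = screen_dt)
      if (!attr(scr$validity, "valid")) {
        mrows[[i]] <- measurement_row(scr$measurements)
        vmat[i, ] <- validate_measurements(scr$measurements, bounds)$pass
        screened_only[i] <- TRUE
        if (verbose && i %% 100 == 0) message("model ", indices[i])
        next
      }
    }
    ev <- evaluate_model(p, bounds = bounds, dt = dt)
    mrows[[i]] <- measurement_row(ev$measurements)
    vmat[i, ] <- ev$validity$pass
    if (verbose && i %% 100 == 0) message("model ", indices[i])
  }

  meas <- do.call(rbind, mrows)
  meas <- cbind(data.frame(model = indices, seed = seeds,
                           screened_only = screened_only), meas)
  structure(list(params = params, seeds = seeds, measurements = meas,
                 validity = vmat, valid = apply(vmat, 1, all),
                 meta = list(n = n, seed = seed, dt = dt,
                             screen_dt = screen_dt,
                             screen_margin = screen_margin,
                             indices = indices,
                             package_version =
                               as.character(utils::packageVersion("stellate")))),
            class = "stellate_population")
}

empty_population <- function(seed, dt, screen_dt) {
  structure(list(params = matrix(numeric(0), 0, 55), seeds = integer(0),
                 measurements = data.frame(), validity = matrix(logical(0), 0, 10),
                 valid = logical(0),
                 meta = list(n = 0, seed = seed, dt = dt,
                             screen_dt = screen_dt)),
            class = "stellate_population")
}

#' Run several independent searches
#'
#' @param n_each Models per set.
#' @param seeds Distinct global seeds, one per set.
#' @param ... Passed to [run_search()].
#' @return List of `stellate_population`s.
#' @export
run_independent_sets <- function(n_each, seeds, ...) {
  if (anyDuplicated(seeds)) stop("seeds must be distinct")
  lapply(seeds, function(s) run_search(n_each, seed = s, ...))
}

#' @export
print.stellate_population <- function(x, ...) {
  cat(sprintf("Stellate model population: %d sampled, %d valid (%.2f%%)\n",
              nrow(x$params), sum(x$valid),
              if (nrow(x$params)) 100 * mean(x$valid) else 0))
  if (!is.null(x$meta$screen_dt)) {
    cat(sprintf("  screening dt = %g ms, confirmation dt = %g ms\n",
                x$meta$screen_dt, x$meta$dt))
  } else {
    cat(sprintf("  dt = %g ms\n", x$meta$dt))
  }
  invisible(x)
}

#' @export
summary.stellate_population <- function(object, ...) {
  print(object)
  if (any(object$valid)) {
    cat("\nMeasurement ranges over valid models:\n")
    mv <- object$measurements[object$valid, MEASUREMENT_NAMES]
    print(t(vapply(mv, range, numeric(2))))
  }
  cat("\nPer-criterion pass rates over all sampled models:\n")
  print(round(colMeans(object$validity), 4))
  invisible(object)
}

#' Extract the valid models of a population
#'
#' @param pop A `stellate_population`.
#' @return List with `params` (matrix of valid parameter vectors) and
#'   `measurements` (their measurement rows).
#' @export
valid_models <- function(pop) {
  stopifnot(inherits(pop, "stellate_population"))
  list(params = pop$params[pop$valid, , drop = FALSE],
       measurements = pop$measurements[pop$valid, , drop = FALSE])
}

#' Write a population to CSV files
#'
#' Writes `<prefix>_parameters.csv` (one row per model: id, seed, the 55
#' parameters), `<prefix>_measurements.csv` and `<prefix>_validity.csv`,
#' plus `<prefix>_meta.yaml` with the search configuration.
#'
#' @param pop A `stellate_population`.
#' @param prefix Output path prefix.
#' @return Invisibly, the written file paths.
#' @export
write_population <- function(pop, prefix) {
  stopifnot(inherits(pop, "stellate_population"))
  pfile <- paste0(prefix, "_parameters.csv")
  mfile <- paste0(prefix, "_measurements.csv")
  vfile <- paste0(prefix, "_validity.csv")
  yfile <- paste0(prefix, "_meta.yaml")
  write.csv(cbind(data.frame(model = pop$measurements$model,
                             seed = pop$seeds), pop$params),
            pfile, row.names = FALSE)
  write.csv(pop$measurements, mfile, row.names = FALSE)
  write.csv(cbind(data.frame(model = pop$measurements$model),
                  pop$validity, valid = pop$valid),
            vfile, row.names = FALSE)
  yaml::write_yaml(pop$meta, yfile)
  invisible(c(pfile, mfile, vfile, yfile))
}
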