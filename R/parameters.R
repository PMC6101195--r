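# Parameter space (the 55 model parameters), validation bounds, and the
# uniform sampler used for population generation.

#' The 55-parameter space of the stellate cell model
#'
#' Reads the packaged parameter table: per-parameter name, unit, description,
#' hand-tuned base value and the min/max range used for uniform sampling.
#' Conductance ranges span 0.5x-2x their base values, time-constant scale
#' factors 0.8x-1.2x, half-maximal voltages are shifted by 5 mV on either
#' side, and sigmoid slopes by 20%.
#'
#' @param file Path to a parameter YAML file; defaults to the packaged table.
#' @return A data frame of class `parameter_space` with columns `name`,
#'   `unit`, `description`, `base`, `min`, `max` (55 rows).
#' @export
#' @examples
#' space <- parameter_space()
#' nrow(space)
parameter_space <- function(file = system.file("extdata", "parameters.yaml",
                                               package = "stellate")) {
  raw <- yaml::read_yaml(file)$parameters
  space <- do.call(rbind, lapply(raw, function(p) {
    data.frame(name = p$name, unit = p$unit, description = p$description,
               base = as.numeric(p$base), min = as.numeric(p$min),
               max = as.numeric(p$max), stringsAsFactors = FALSE)
  }))
  if (nrow(space) != 55L) stop("parameter space must have exactly 55 entries")
  if (anyDuplicated(space$name)) stop("parameter names must be unique")
  bad <- space$min > space$base | space$base > space$max
  if (any(bad)) {
    stop("min <= base <= max violated for: ",
         paste(space$name[bad], collapse = ", "))
  }
  class(space) <- c("parameter_space", "data.frame")
  space
}

#' Base parameter vector of the hand-tuned stellate cell model
#'
#' @param space A `parameter_space`.
#' @return Named numeric vector of length 55 (canonical order).
#' @export
#' @examples
#' p <- base_parameters()
#' p["gbar_NaF"]
base_parameters <- function(space = parameter_space()) {
  setNames(space$base, space$name)
}

#' Physiological validation bounds for the ten measurements
#'
#' Reads the packaged table of electrophysiologically derived ranges used to
#' validate stochastically generated models. A missing bound (`NA`) means the
#' measurement is unconstrained on that side; all comparisons are inclusive.
#'
#' @param file Path to a bounds YAML file; defaults to the packaged table.
#' @return A data frame of class `validation_bounds` with columns `name`,
#'   `unit`, `description`, `lower`, `upper` (10 rows).
#' @export
validation_bounds <- function(file = system.file("extdata", "bounds.yaml",
                                                 package = "stellate")) {
  raw <- yaml::read_yaml(file)$bounds
  b <- do.call(rbind, lapply(raw, function(x) {
    data.frame(name = x$name, unit = x$unit, description = x$description,
               lower = ifelse(is.null(x$lower), NA_real_, as.numeric(x$lower)),
               upper = ifelse(is.null(x$upper), NA_real_, as.numeric(x$upper)),
               stringsAsFactors = FALSE)
  }))
  if (nrow(b) != 10L) stop("validation bounds must have exactly 10 entries")
  if (any(is.na(b$lower) & is.na(b$upper))) stop("each criterion needs a bound")
  class(b) <- c("validation_bounds", "data.frame")
  b
}

#' Per-model substream seeds
#'
#' Expands one global seed into per-model seeds so that model `k` of a search
#' is reproducible independent of the batch size: the first `n` seeds drawn
#' under a given global seed are always the same sequence.
#'
#' @param seed Global integer seed.
#' @param n Number of models.
#' @return Integer vector of `n` distinct seeds (each below 2^31).
#' @export
model_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

#' Sample parameter vectors uniformly within their ranges
#'
#' Each of the 55 parameters is drawn independently and uniformly within its
#' `[min, max]` range (closed interval; for a continuous uniform the endpoint
#' convention is immaterial).
#'
#' @param space A `parameter_space`.
#' @param n Number of vectors to draw.
#' @param seed Optional integer seed (applied locally; the caller's RNG state
#'   is restored).
#' @return An `n` x 55 matrix with parameter names as column names.
#' @export
#' @examples
#' x <- sample_parameters(n = 3, seed = 1)
#' dim(x)
sample_parameters <- function(space = parameter_space(), n = 1, seed = NULL) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
  }
  m <- matrix(runif(n * 55L), nrow = n)
  m <- sweep(m, 2L, space$max - space$min, "*")
  m <- sweep(m, 2L, space$min, "+")
  colnames(m) <- space$name
  m
}

#' @export
print.parameter_space <- function(x, ...) {
  cat("Stellate cell model parameter space: 55 parameters\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
print.validation_bounds <- function(x, ...) {
  cat("Validation bounds for the 10 intrinsic measurements\n")
  print.data.frame(x, ...)
  invisible(x)
}

# Canonical order check and coercion for a user-supplied parameter vector.
as_param_vector <- function(params, space = NULL) {
  nm <- if (is.null(space)) parameter_space()$name else space$name
  if (is.null(names(params))) {
    if (length(params) != 55L) stop("parameter vector must have length 55")
    return(setNames(as.numeric(params), nm))
  }
  missing <- setdiff(nm, names(params))
  if (length(missing)) {
    stop("missing parameters: ", paste(missing, collapse = ", "))
  }
  as.numeric(params[nm]) -> out
  setNames(out, nm)
}
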