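#' Load the model parameter registry
#'
#' Reads a YAML registry with one entry per model parameter (point estimate,
#' units, sampling distribution, source note). The default file shipped with
#' the package mirrors the published transition-probability and
#' utility/resource-use/cost tables row for row.
#'
#' Gamma-distributed rows may omit `dist_params`, in which case the
#' `(shape, scale)` pair is fitted at load time by [gamma_from_mean_se()]
#' from the row's `point` and `se`, guaranteeing that the analytic mean of
#' the sampling distribution equals the point estimate. Beta and log-normal
#' rows store their parameters explicitly.
#'
#' @param path Path to a registry YAML file; defaults to the bundled
#'   registry.
#'
#' @return An object of class `param_registry`: a named list of parameter
#'   specifications, each a list with elements `name`, `point`, `units`,
#'   `dist` (one of `"beta"`, `"gamma"`, `"lognormal"`, `"fixed"`),
#'   `dist_params` and `source`.
#'
#' @examples
#' reg <- default_registry()
#' reg[["bnp_test_cost"]]$point
#' @export
load_registry <- function(path = system.file("extdata", "parameters.yaml",
                                             package = "bnpcea")) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$parameters)) {
    stop("registry file has no top-level `parameters` list: ", path,
         call. = FALSE)
  }
  specs <- lapply(raw$parameters, as_param_spec)
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(names(specs))) {
    stop("duplicate parameter names in registry: ",
         paste(unique(names(specs)[duplicated(names(specs))]),
               collapse = ", "), call. = FALSE)
  }
  structure(specs, class = "param_registry", path = path)
}

#' @rdname load_registry
#' @export
default_registry <- function() {
  reg <- getOption("bnpcea.registry")
  if (is.null(reg)) reg <- load_registry()
  reg
}

# Validate one registry entry and fit missing gamma parameters.
as_param_spec <- function(x) {
  stopifnot(is.list(x), !is.null(x$name), !is.null(x$point), !is.null(x$dist))
  dist <- match.arg(x$dist, c("beta", "gamma", "lognormal", "fixed"))
  dp <- if (!is.null(x$dist_params)) as.numeric(x$dist_params)
  if (dist == "beta") {
    if (is.null(dp)) dp <- unname(beta_from_mean_se(x$point, x$se))
    if (length(dp) != 2L || any(dp <= 0)) {
      stop("parameter ", x$name, ": beta parameters must be two positive ",
           "numbers", call. = FALSE)
    }
    m <- dp[1] / (dp[1] + dp[2])
    if (m <= 0 || m >= 1) {
      stop("parameter ", x$name, ": implied beta mean outside (0,1)",
           call. = FALSE)
    }
  } else if (dist == "gamma") {
    if (is.null(dp)) {
      if (is.null(x$se)) {
        stop("parameter ", x$name, ": gamma row needs `dist_params` or `se`",
             call. = FALSE)
      }
      dp <- unname(gamma_from_mean_se(x$point, x$se))
    }
    if (length(dp) != 2L || any(dp <= 0)) {
      stop("parameter ", x$name, ": gamma parameters must be two positive ",
           "numbers", call. = FALSE)
    }
  } else if (dist == "lognormal") {
    if (length(dp) != 2L || dp[2] < 0) {
      stop("parameter ", x$name, ": lognormal needs [mu, sigma >= 0]",
           call. = FALSE)
    }
  } else {
    dp <- NULL
  }
  list(name = x$name, point = as.numeric(x$point),
       se = if (!is.null(x$se)) as.numeric(x$se),
       units = x$units %||% "", dist = dist, dist_params = dp,
       source = x$source %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.param_registry <- function(x, ...) {
  cat("<param_registry> ", length(x), " parameters\n", sep = "")
  df <- data.frame(
    name = names(x),
    point = vapply(x, `[[`, numeric(1), "point"),
    dist = vapply(x, `[[`, character(1), "dist"),
    units = vapply(x, `[[`, character(1), "units"),
    row.names = NULL, check.names = FALSE
  )
  print(df, right = FALSE)
  invisible(x)
}

#' Point-estimate parameter set
#'
#' Collapses every registry entry to its point estimate, as used by the
#' deterministic analyses.
#'
#' @param registry A [param_registry][load_registry] object.
#' @return A `parameter_set`: a named numeric vector with a `provenance`
#'   attribute.
#' @examples
#' ps <- point_estimate_set(default_registry())
#' ps[["mortality_rate_under75"]]
#' @export
point_estimate_set <- function(registry = default_registry()) {
  stopifnot(inherits(registry, "param_registry"))
  values <- vapply(registry, `[[`, numeric(1), "point")
  structure(values, class = "parameter_set",
            provenance = list(kind = "point_estimate"))
}

#' Draw one probabilistic parameter set
#'
#' Samples every registry parameter independently from its distribution
#' (fixed parameters stay at their point value). No correlation between
#' parameters is modelled. The draw is reproducible: the RNG stream is
#' derived deterministically from `(seed, iteration)`, so draws are
#' independent of execution order.
#'
#' @param registry A [param_registry][load_registry] object.
#' @param seed Integer base seed.
#' @param iteration Iteration index (>= 1); each index gets its own stream.
#' @return A `parameter_set` named numeric vector; `provenance` records the
#'   seed and iteration.
#' @examples
#' a <- sample_parameter_set(default_registry(), seed = 1, iteration = 3)
#' b <- sample_parameter_set(default_registry(), seed = 1, iteration = 3)
#' identical(a, b)
#' @export
sample_parameter_set <- function(registry = default_registry(), seed = 1L,
                                 iteration = 1L) {
  stopifnot(inherits(registry, "param_registry"),
            length(seed) == 1L, length(iteration) == 1L, iteration >= 1)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(iteration_seed(seed, iteration))
  values <- vapply(registry, sample_param, numeric(1))
  structure(values, class = "parameter_set",
            provenance = list(kind = "psa_draw", seed = seed,
                              iteration = iteration))
}

# Distinct, reproducible sub-seed per iteration, kept inside 32-bit range.
iteration_seed <- function(seed, iteration) {
  as.integer((as.double(seed) * 48271 + as.double(iteration) * 16807) %%
               2147483647)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

sample_param <- function(spec) {
  dp <- spec$dist_params
  switch(spec$dist,
         fixed = spec$point,
         beta = stats::rbeta(1L, dp[1], dp[2]),
         gamma = stats::rgamma(1L, shape = dp[1], scale = dp[2]),
         lognormal = stats::rlnorm(1L, meanlog = dp[1], sdlog = dp[2]))
}

#' @export
print.parameter_set <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("<parameter_set> ", length(x), " values (", prov$kind,
      if (identical(prov$kind, "psa_draw"))
        paste0(", seed ", prov$seed, ", iteration ", prov$iteration),
      ")\n", sep = "")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

# Apply named overrides (e.g. from a scenario) to a parameter set.
override_parameters <- function(params, overrides) {
  if (is.null(overrides) || length(overrides) == 0L) return(params)
  bad <- setdiff(names(overrides), names(params))
  if (length(bad)) {
    stop("override refers to unknown parameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  params[names(overrides)] <- as.numeric(overrides)
  params
}
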