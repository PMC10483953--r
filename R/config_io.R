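# YAML serialization of experiment configurations.
#
# Schema (all keys optional; defaults from experiment_config()):
#   scenarios, n_grid, n_replicates, master_seed, alpha,
#   timepoints_of_interest, methods, power_target, n_search_max,
#   n_search_step,
#   population: {timepoints, mu, sigma, corr_lower_triangle},
#   effect: {delta},
#   allocation: {kind, intercept, slope}
# Unknown keys are rejected so that typos fail loudly.

config_keys <- c("scenarios", "n_grid", "n_replicates", "master_seed",
                 "alpha", "timepoints_of_interest", "methods", "power_target",
                 "n_search_max", "n_search_step", "population", "effect",
                 "allocation")

#' Read an experiment configuration from YAML
#'
#' @param path Path to a YAML file following the schema documented in
#'   [write_config_yaml()]; unknown keys are an error.
#' @return An [experiment_config()] object.
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  args <- raw[intersect(names(raw),
                        setdiff(config_keys, c("population", "effect", "allocation")))]
  if (!is.null(raw$population)) {
    p <- raw$population
    unknown <- setdiff(names(p), c("timepoints", "mu", "sigma", "corr_lower_triangle"))
    if (length(unknown))
      stop("unknown population key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    tp <- if (is.null(p$timepoints)) c(0, 6, 12, 18, 24) else p$timepoints
    args$population <- laz_population(
      timepoints = tp, mu = p$mu, sigma = p$sigma,
      corr = correlation_from_lower(p$corr_lower_triangle, length(tp)))
  }
  if (!is.null(raw$effect)) {
    tp <- if (is.null(args$population)) c(0, 6, 12, 18, 24) else
      args$population$timepoints
    args$effect <- effect_profile(raw$effect$delta, timepoints = tp)
  }
  if (!is.null(raw$allocation)) {
    a <- raw$allocation
    unknown <- setdiff(names(a), c("kind", "intercept", "slope"))
    if (length(unknown))
      stop("unknown allocation key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    args$allocation <- allocation_rule(a$kind, intercept = a$intercept,
                                       slope = a$slope)
  }
  do.call(experiment_config, args)
}

# Plain-list form of a config, used for YAML/JSON serialization.
config_to_list <- function(config) {
  list(
    scenarios = config$scenarios,
    n_grid = config$n_grid,
    n_replicates = config$n_replicates,
    master_seed = config$master_seed,
    alpha = config$alpha,
    timepoints_of_interest = config$timepoints_of_interest,
    methods = config$methods,
    power_target = config$power_target,
    n_search_max = config$n_search_max,
    n_search_step = config$n_search_step,
    population = list(
      timepoints = config$population$timepoints,
      mu = config$population$mu,
      sigma = config$population$sigma,
      corr_lower_triangle = correlation_to_lower(config$population$corr)),
    effect = list(delta = config$effect$delta),
    allocation = list(kind = config$allocation$kind,
                      intercept = config$allocation$intercept,
                      slope = config$allocation$slope)
  )
}

#' Write an experiment configuration to YAML
#'
#' Inverse of [read_config_yaml()]: serializes the scalar settings plus
#' `population` (timepoints, mu, sigma, corr_lower_triangle in row-major
#' order), `effect` (delta) and `allocation` (kind, intercept, slope).
#'
#' @param config An [experiment_config()] object.
#' @param path Output path.
#' @export
write_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "laz_config"))
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}
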