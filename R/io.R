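# Configuration files (YAML), trace round-tripping (CSV) and a summary
# report (JSON).

#' Load a scenario configuration from a YAML file
#'
#' Reads a YAML file of configuration keys, validates it and returns a fully
#' explicit [scenario_config()]. Unknown keys are rejected by name; an empty
#' file yields the all-defaults configuration.
#'
#' @param path Path to a YAML file. Recognized keys are the arguments of
#'   [scenario_config()] plus `scenario`.
#' @return An `sc_config`.
#' @examples
#' cfg <- load_config(system.file("extdata", "scenarios", "s2.yaml",
#'                                package = "pharmsim"))
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  scenario <- raw$scenario %||% "custom"
  raw$scenario <- NULL
  raw <- raw[!vapply(raw, is.null, logical(1))] # null-valued keys mean "default"
  if (!is.null(raw$split_rules)) raw$split_rules <- unlist(raw$split_rules)
  do.call(scenario_config, c(list(scenario = scenario), raw))
}

#' Write a scenario configuration to a YAML file
#'
#' The written file round-trips: `load_config(write_config(cfg, path))`
#' reproduces `cfg`.
#'
#' @param config An `sc_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  out <- unclass(config)
  if (inherits(out$disruption, "disruption_profile")) {
    out$disruption <- if (out$disruption$type %in% c("short", "moderate", "long")) {
      out$disruption$type
    } else {
      list(severity = out$disruption$severity, breadth = out$disruption$breadth)
    }
  }
  out$split_rules <- as.list(out$split_rules)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write / read a run trace as CSV
#'
#' One row per time-step and agent (or per time-step and supply edge for the
#' `flows` and `trust` tables). Round-trips losslessly within floating-point
#' tolerance.
#'
#' @param trace A trace tibble (`trace`, `flows` or `trust` element of an
#'   `sc_run`).
#' @param path File path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns
#'   the tibble.
#' @export
write_trace <- function(trace, path) {
  readr::write_csv(trace, path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write a JSON summary report for a run
#'
#' Per-agent window costs, the accounting window, the disruption profile and
#' (for planning runs) the planner's action frequencies.
#'
#' @param run An `sc_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(run, path) {
  costs <- agent_cost(run)
  acts <- run$trace |>
    dplyr::filter(.data$agent == "Disrupted DS",
                  .data$t >= run$window[1], .data$t <= run$window[2]) |>
    dplyr::count(.data$action)
  out <- list(
    scenario = run$config$scenario,
    delta = run$config$delta,
    disruption = list(type = run$disruption$type,
                      severity = run$disruption$severity,
                      breadth = run$disruption$breadth,
                      start = run$disruption$start),
    window = as.list(run$window),
    costs = setNames(as.list(costs$cost), costs$agent),
    overall_cost = sum(costs$cost),
    allocation_actions = setNames(as.list(acts$n), acts$action)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
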