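# Capacity-reduction disruptions at a manufacturer: rectangular profiles
# defined by severity (fraction of capacity removed) and breadth (duration).

.disruption_table <- list(
  short    = list(severity = 0.84, breadth = 10L),
  moderate = list(severity = 0.42, breadth = 20L),
  long     = list(severity = 0.17, breadth = 50L)
)

#' Define a capacity-reduction disruption profile
#'
#' A disruption removes a fixed fraction (`severity`) of a manufacturer's
#' nominal production capacity for `breadth` consecutive time-steps. The
#' three named profiles remove (approximately) the same total capacity with
#' different temporal signatures: `"short"` (84% for 10 steps), `"moderate"`
#' (42% for 20 steps) and `"long"` (17% for 50 steps).
#'
#' @param type One of `"short"`, `"moderate"`, `"long"`, or `NULL` for a
#'   custom profile given by `severity` and `breadth`.
#' @param severity Fraction of capacity removed, in \[0, 1\].
#' @param breadth Duration in time-steps (\eqn{\ge 1}).
#' @param target Name of the disrupted manufacturer (default
#'   `"Disrupted MN"`).
#' @param start Time-step at which the disruption begins; usually set by the
#'   scenario runner after the warm-up stabilizes.
#' @return An object of class `disruption_profile`.
#' @examples
#' disruption_profile("short")
#' disruption_profile(severity = 0.3, breadth = 15)
#' @export
disruption_profile <- function(type = NULL, severity = NULL, breadth = NULL,
                               target = "Disrupted MN", start = NA_integer_) {
  if (!is.null(type)) {
    type <- match.arg(tolower(type), names(.disruption_table))
    severity <- .disruption_table[[type]]$severity
    breadth <- .disruption_table[[type]]$breadth
  } else {
    type <- "custom"
  }
  if (is.null(severity) || is.null(breadth)) {
    stop("configuration error: give `type` or both `severity` and `breadth`", call. = FALSE)
  }
  if (severity < 0 || severity > 1) {
    stop("configuration error: `severity` must lie in [0, 1]", call. = FALSE)
  }
  if (breadth < 1) stop("configuration error: `breadth` must be >= 1", call. = FALSE)
  structure(
    list(type = type, severity = severity, breadth = as.integer(breadth),
         target = target, start = as.integer(start)),
    class = "disruption_profile"
  )
}

#' Effective production capacity under a disruption
#'
#' @param nominal Nominal capacity in units per time-step.
#' @param profile A [disruption_profile()] with its `start` set (a profile
#'   with `start = NA`, or `NULL`, never binds).
#' @param t Current time-step.
#' @return `nominal * (1 - severity)` while `start <= t < start + breadth`,
#'   `nominal` otherwise.
#' @export
effective_capacity <- function(nominal, profile, t) {
  check_nonneg(nominal, "nominal")
  if (is.null(profile) || is.na(profile$start)) return(nominal)
  if (t >= profile$start && t < profile$start + profile$breadth) {
    nominal * (1 - profile$severity)
  } else {
    nominal
  }
}

#' Total capacity removed by a disruption profile
#'
#' @param profile A [disruption_profile()].
#' @param nominal Nominal capacity in units per time-step.
#' @return `nominal * severity * breadth`, the total production capacity lost
#'   over the whole disruption window.
#' @export
total_capacity_loss <- function(profile, nominal) {
  profile$severity * profile$breadth * nominal
}

#' @export
print.disruption_profile <- function(x, ...) {
  cat(sprintf(
    "<disruption_profile> %s: severity %.0f%%, breadth %d steps, target '%s', start %s\n",
    x$type, 100 * x$severity, x$breadth, x$target,
    if (is.na(x$start)) "unscheduled" else x$start
  ))
  invisible(x)
}
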