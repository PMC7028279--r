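# Trust bookkeeping: a buyer attributes a trustworthiness value to each of
# its suppliers, updated every step by exponential smoothing of the windowed
# on-time delivery rate.

# Per-step fulfillment ratio min(R/E, 1); steps with nothing expected count
# as fully met. Works elementwise on vectors/matrices/arrays.
on_time_ratio <- function(received, expected) {
  r <- pmin(received / expected, 1)
  r[expected == 0] <- 1
  r
}

# One smoothing step T <- (1 - delta) T + delta D, elementwise.
smooth_trust <- function(trust, rate, delta) {
  if (delta < 0 || delta > 1) {
    stop("configuration error: `delta` must lie in [0, 1]", call. = FALSE)
  }
  (1 - delta) * trust + delta * rate
}

#' Create a trust state for one buyer-supplier pair
#'
#' Tracks the attributed trustworthiness `T` and the rolling window of
#' (received, expected) delivery pairs that feeds the on-time delivery rate.
#' Pre-history is padded with fully met expectations, so `T` starts at its
#' initial value and stays there while every delivery arrives on schedule.
#'
#' @param delta Sensitivity factor in \[0, 1\]: the exponential smoothing
#'   weight on the most recent on-time delivery rate. Higher values react
#'   more strongly to recent performance.
#' @param window_length Number of most recent steps entering the delivery
#'   rate (default 3, i.e. lead time + 1 under the default lead time of 2).
#' @param trust Initial trustworthiness (default 1).
#' @return An object of class `trust_state`.
#' @seealso [record_expectation()], [record_delivery()],
#'   [on_time_delivery_rate()], [update_trust()]
#' @export
trust_state <- function(delta, window_length = 3L, trust = 1) {
  if (delta < 0 || delta > 1) {
    stop("configuration error: `delta` must lie in [0, 1]", call. = FALSE)
  }
  if (trust < 0 || trust > 1) stop("`trust` must lie in [0, 1]", call. = FALSE)
  window_length <- as.integer(window_length)
  if (window_length < 1L) stop("`window_length` must be >= 1", call. = FALSE)
  structure(
    list(
      trust = trust,
      delta = delta,
      window_length = window_length,
      received = numeric(window_length),
      expected = numeric(window_length),
      pending = numeric(0) # expectations keyed by promised arrival step
    ),
    class = "trust_state"
  )
}

#' Record the expectation created by placing an order
#'
#' When a buyer places an order it expects delivery after the promised lead
#' time; the expected quantity is accumulated at the promised arrival step.
#'
#' @param state A [trust_state()].
#' @param order Units ordered (\eqn{\ge 0}).
#' @param promised_arrival Integer time-step at which delivery is due.
#' @return The updated `trust_state`.
#' @export
record_expectation <- function(state, order, promised_arrival) {
  stopifnot(inherits(state, "trust_state"))
  check_nonneg(order, "order")
  if (order == 0) return(state)
  key <- as.character(as.integer(promised_arrival))
  state$pending[key] <- sum(state$pending[key], order, na.rm = TRUE)
  state
}

#' Record the delivery observed at a time-step
#'
#' Pushes the pair (units received at `t`, units that were due at `t`) into
#' the rolling window. Deliveries are credited to the step at which they
#' arrive; expectations to the step at which they were due.
#'
#' @param state A [trust_state()].
#' @param received Units actually received at step `t`.
#' @param t The current time-step.
#' @return The updated `trust_state`.
#' @export
record_delivery <- function(state, received, t) {
  stopifnot(inherits(state, "trust_state"))
  check_nonneg(received, "received")
  key <- as.character(as.integer(t))
  due <- if (key %in% names(state$pending)) state$pending[[key]] else 0
  state$pending <- state$pending[setdiff(names(state$pending), key)]
  state$received <- c(state$received[-1], received)
  state$expected <- c(state$expected[-1], due)
  state
}

#' Windowed on-time delivery rate
#'
#' The mean, over the rolling window, of the per-step fulfillment ratio
#' `min(received / expected, 1)`; steps with nothing expected count as fully
#' met. Always lies in \[0, 1\], and equals 1 for a supplier that has met
#' every expectation.
#'
#' @param state A [trust_state()].
#' @return The on-time delivery rate `D` in \[0, 1\].
#' @export
on_time_delivery_rate <- function(state) {
  stopifnot(inherits(state, "trust_state"))
  mean(on_time_ratio(state$received, state$expected))
}

#' Exponential-smoothing trust update
#'
#' Applies one update `T <- (1 - delta) T + delta D` where `D` is the current
#' windowed on-time delivery rate. With constant `D = d*`, `T` converges to
#' `d*` geometrically with ratio `1 - delta`.
#'
#' @param state A [trust_state()].
#' @return The updated `trust_state`.
#' @export
update_trust <- function(state) {
  stopifnot(inherits(state, "trust_state"))
  state$trust <- smooth_trust(state$trust, on_time_delivery_rate(state), state$delta)
  state
}

#' @export
print.trust_state <- function(x, ...) {
  cat(sprintf(
    "<trust_state> T = %.4f (delta = %g, window = %d, D = %.4f)\n",
    x$trust, x$delta, x$window_length, on_time_delivery_rate(x)
  ))
  invisible(x)
}
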