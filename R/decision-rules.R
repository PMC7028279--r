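# Fixed decision calculations available to the agents: base-stock order
# quantities, rationing rules for sellers, order-splitting rules for buyers.
# Quantities are non-negative reals (fluid model); no integer rounding.

#' Base-stock (order-up-to) quantity
#'
#' The classic order-up-to rule: order the gap between a target level and the
#' current inventory position, floored at zero. The inventory position is
#' on-hand stock plus the in-transit/on-order pipeline minus backlog owed
#' downstream.
#'
#' @param inventory_position Numeric, current inventory position (may be
#'   negative when backlog dominates).
#' @param up_to_level Numeric \eqn{\ge 0}, the order-up-to target, typically
#'   forecast demand per step \eqn{\times} (lead time + 1) plus safety stock.
#' @return The order (or production request) quantity, `pmax(0, up_to_level -
#'   inventory_position)`.
#' @examples
#' base_stock_quantity(50, 120)
#' base_stock_quantity(130, 120) # already above target
#' @export
base_stock_quantity <- function(inventory_position, up_to_level) {
  if (any(up_to_level < 0)) stop("`up_to_level` must be non-negative", call. = FALSE)
  pmax(0, up_to_level - inventory_position)
}

#' Order-up-to target level
#'
#' Target = forecast demand per step x (replenishment lead time + 1) plus a
#' safety stock expressed as a fraction of one step's forecast demand.
#'
#' @param forecast Forecast demand per time-step (most recent observed demand).
#' @param lead_time Replenishment lead time in steps.
#' @param safety_frac Safety stock as a fraction of `forecast` (default 0.5).
#' @return The up-to level `forecast * (lead_time + 1 + safety_frac)`.
#' @export
up_to_level <- function(forecast, lead_time, safety_frac = 0.5) {
  forecast * (lead_time + 1 + safety_frac)
}

#' Proportional allocation of scarce stock
#'
#' When on-hand stock covers all requests each buyer receives its request;
#' otherwise stock is rationed pro-rata to request sizes.
#'
#' @param on_hand Units available to ship.
#' @param requests Named numeric vector of outstanding requests per buyer.
#' @return Named numeric vector of shipped quantities; the total shipped is
#'   `min(on_hand, sum(requests))`.
#' @examples
#' allocate_proportional(60, c(A = 40, B = 80))
#' @export
allocate_proportional <- function(on_hand, requests) {
  check_nonneg(on_hand, "on_hand")
  check_nonneg(requests, "requests")
  total <- sum(requests)
  if (total <= on_hand || total == 0) return(requests + 0)
  requests * (on_hand / total)
}

#' Preferential allocation of scarce stock
#'
#' Serves the preferred buyer's request in full (up to stock), then the
#' remaining buyers in their listed order.
#'
#' @param on_hand Units available to ship.
#' @param requests Named numeric vector of outstanding requests per buyer.
#' @param preferred Name (or index) of the preferred buyer in `requests`.
#' @return Named numeric vector of shipped quantities.
#' @examples
#' allocate_preferential(60, c(A = 40, B = 80), preferred = "A")
#' @export
allocate_preferential <- function(on_hand, requests, preferred) {
  check_nonneg(on_hand, "on_hand")
  check_nonneg(requests, "requests")
  if (is.character(preferred)) {
    preferred <- match(preferred, names(requests))
    if (is.na(preferred)) stop("`preferred` is not a buyer in `requests`", call. = FALSE)
  }
  if (preferred < 1 || preferred > length(requests)) {
    stop("`preferred` is not a buyer in `requests`", call. = FALSE)
  }
  ord <- c(preferred, setdiff(seq_along(requests), preferred))
  out <- requests * 0
  rem <- on_hand
  for (i in ord) {
    out[i] <- min(rem, requests[i])
    rem <- rem - out[i]
  }
  out
}

#' Split an order equally across sellers
#'
#' @param total Total units to order.
#' @param sellers Character vector of seller names (non-empty).
#' @return Named numeric vector, `total / length(sellers)` each.
#' @export
split_equal <- function(total, sellers) {
  check_nonneg(total, "total")
  if (length(sellers) == 0) stop("configuration error: empty seller list", call. = FALSE)
  setNames(rep(total / length(sellers), length(sellers)), sellers)
}

#' Split an order across sellers in proportion to trustworthiness
#'
#' Seller `i` receives `total * T_i / sum(T)`. When all trust values are zero
#' the split falls back to equal shares so the rule stays total-preserving.
#'
#' @param total Total units to order.
#' @param trust Named numeric vector of trustworthiness values in \[0, 1\],
#'   one per seller.
#' @return Named numeric vector of per-seller order quantities summing to
#'   `total`.
#' @examples
#' split_by_trust(100, c(d1 = 0.8, d2 = 0.2))
#' split_by_trust(100, c(d1 = 0, d2 = 0)) # falls back to equal
#' @export
split_by_trust <- function(total, trust) {
  check_nonneg(total, "total")
  if (any(trust < 0 | trust > 1)) stop("trust values must lie in [0, 1]", call. = FALSE)
  s <- sum(trust)
  if (s <= 0) return(split_equal(total, names(trust)))
  total * trust / s
}

check_nonneg <- function(x, what) {
  if (any(x < 0)) stop(sprintf("`%s` must be non-negative", what), call. = FALSE)
  invisible(x)
}
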