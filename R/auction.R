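#' Minimum-cost assignment by the auction algorithm
#'
#' Solves the square linear assignment problem by a forward auction with
#' epsilon scaling: unassigned bidders bid for their best object at the
#' current prices, raising the price by the bid increment (best minus
#' second-best value plus epsilon). Each scaling phase keeps the learned
#' prices and rebuilds the assignment with a smaller epsilon; at the final
#' epsilon the assignment is within `n * eps_final` of the optimum, i.e.
#' exactly optimal for costs that differ by more than that.
#'
#' `Inf` entries are forbidden pairings; a feasible perfect matching must
#' exist.
#'
#' @param cost Square numeric cost matrix (rows = bidders, columns =
#'   objects); `Inf` forbids a pairing.
#' @param eps_final Final epsilon of the scaling schedule.
#' @return Integer vector: `result[i]` is the object assigned to bidder
#'   `i`.
#' @export
auction_assignment <- function(cost, eps_final = 1e-9) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, n >= 1)
  if (n == 1) return(1L)
  fin <- is.finite(cost)
  if (!any(fin)) stop("all pairings are forbidden")
  big <- max(cost[fin]) - min(cost[fin]) + 1
  benefit <- -cost
  benefit[!fin] <- -(n + 1) * big - 1
  price <- rep(0, n)
  eps <- max(big / 2, eps_final)
  assign <- rep(NA_integer_, n)
  repeat {
    assign[] <- NA_integer_
    owner <- rep(NA_integer_, n)
    un <- seq_len(n)
    while (length(un)) {
      i <- un[1]; un <- un[-1]
      vals <- benefit[i, ] - price
      j <- which.max(vals)
      v1 <- vals[j]
      vals[j] <- -Inf
      v2 <- max(vals)
      price[j] <- price[j] + (v1 - v2) + eps
      prev <- owner[j]
      owner[j] <- i
      assign[i] <- j
      if (!is.na(prev)) {
        assign[prev] <- NA_integer_
        un <- c(un, prev)
      }
    }
    if (eps <= eps_final) break
    eps <- max(eps / 6, eps_final)
  }
  assign
}
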