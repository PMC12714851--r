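#' End-to-end latency budget
#'
#' The latency model decomposes the device-to-alert path into six component
#' delay ranges (milliseconds). The defaults are the published budget for a
#' 5G edge deployment: sensing 5-10, edge transmission 1-5, edge processing
#' 5-8, model inference 8-12, game-theoretic decision 3-6, alert dispatch
#' 2-5, for a total of 24-46 ms. Latency here is a configured budget, not a
#' wall-clock measurement.
#'
#' @param sensing,edge_transmission,edge_processing,inference,game_decision,alert_dispatch
#'   Length-2 numeric `(min, max)` pairs in ms, `0 <= min <= max`.
#' @return A list of class `latency_budget`.
#' @export
latency_budget <- function(sensing = c(5, 10), edge_transmission = c(1, 5),
                           edge_processing = c(5, 8), inference = c(8, 12),
                           game_decision = c(3, 6), alert_dispatch = c(2, 5)) {
  comps <- list(sensing = sensing, edge_transmission = edge_transmission,
                edge_processing = edge_processing, inference = inference,
                game_decision = game_decision,
                alert_dispatch = alert_dispatch)
  for (nm in names(comps)) {
    v <- comps[[nm]]
    if (length(v) != 2L || !all(is.finite(v)) || v[1L] < 0 || v[1L] > v[2L]) {
      stop("invalid latency component ", nm, ": need 0 <= min <= max")
    }
  }
  structure(comps, class = "latency_budget")
}

#' Total end-to-end latency
#'
#' @param budget A [latency_budget()].
#' @param mode `"min"`/`"max"` sum the respective bounds; `"sample"` draws
#'   each component uniformly within its range and sums.
#' @param seed Optional seed for `"sample"` mode.
#' @return Total latency in ms.
#' @export
total_latency <- function(budget, mode = c("min", "max", "sample"),
                          seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(budget, "latency_budget"))
  lo <- vapply(budget, `[`, numeric(1), 1L)
  hi <- vapply(budget, `[`, numeric(1), 2L)
  switch(mode,
         min = sum(lo),
         max = sum(hi),
         sample = {
           if (!is.null(seed)) set.seed(seed)
           sum(stats::runif(length(lo), lo, hi))
         })
}

#' Edge topology
#'
#' @param node_positions `N x 2` matrix of edge-node coordinates.
#' @param capacities Max concurrent devices per node (recycled to `N`).
#' @param device_positions `M x 2` matrix of device coordinates.
#' @param device_ids Optional device identifiers.
#' @return A list of class `edge_topology`.
#' @export
edge_topology <- function(node_positions, capacities, device_positions,
                          device_ids = NULL) {
  node_positions <- as.matrix(node_positions)
  device_positions <- as.matrix(device_positions)
  stopifnot(ncol(node_positions) == 2L, ncol(device_positions) == 2L,
            nrow(node_positions) >= 1L)
  capacities <- rep_len(as.integer(capacities), nrow(node_positions))
  stopifnot(all(capacities >= 0L))
  if (is.null(device_ids)) {
    device_ids <- paste0("D", seq_len(nrow(device_positions)))
  }
  structure(list(node_positions = node_positions, capacities = capacities,
                 device_positions = device_positions,
                 device_ids = device_ids),
            class = "edge_topology")
}

device_node_distances <- function(topo) {
  dn <- topo$device_positions; np <- topo$node_positions
  outer(seq_len(nrow(dn)), seq_len(nrow(np)),
        Vectorize(function(i, j) sqrt(sum((dn[i, ] - np[j, ])^2))))
}

#' Assign devices to edge nodes
#'
#' `"nearest"` maps each device to its closest node (Euclidean distance,
#' capacities ignored). `"capacity_aware"` minimizes the total device-node
#' distance subject to node capacities, solved exactly by depth-first
#' branch-and-bound (intended for desk-scale instances, up to roughly a dozen
#' devices).
#'
#' @param topo An [edge_topology()].
#' @param policy `"nearest"` or `"capacity_aware"`.
#' @return A list: `assignment` (node index per device), `total_distance`.
#' @export
assign_offloading <- function(topo, policy = c("nearest", "capacity_aware")) {
  policy <- match.arg(policy)
  d <- device_node_distances(topo)
  m <- nrow(d)
  if (policy == "nearest") {
    asg <- apply(d, 1L, which.min)
    return(list(assignment = as.integer(asg),
                total_distance = sum(d[cbind(seq_len(m), asg)])))
  }
  if (sum(topo$capacities) < m) {
    stop(sprintf("infeasible: total capacity %d < %d devices",
                 sum(topo$capacities), m))
  }
  # branch and bound over devices in order; bound = optimistic per-device min
  min_rest <- rev(cumsum(rev(c(apply(d, 1L, min), 0))))[-1L]
  best <- list(cost = Inf, asg = integer(m))
  recurse <- function(i, cap, cost, asg) {
    if (cost + (if (i <= m) min_rest[i] else 0) >= best$cost) return()
    if (i > m) {
      best <<- list(cost = cost, asg = asg)
      return()
    }
    for (j in order(d[i, ])) {
      if (cap[j] > 0L) {
        cap[j] <- cap[j] - 1L
        asg[i] <- j
        recurse(i + 1L, cap, cost + d[i, j], asg)
        cap[j] <- cap[j] + 1L
      }
    }
  }
  recurse(1L, topo$capacities, 0, integer(m))
  list(assignment = best$asg, total_distance = best$cost)
}

#' Score streams and raise alerts
#'
#' Each device's risk score is compared with the alert threshold (strictly
#' greater than: a score exactly at threshold does not alert), and every
#' decision is stamped with a total end-to-end latency drawn from the budget.
#'
#' @param scores Named or unnamed numeric vector of per-device risk scores in
#'   `[0, 1]`.
#' @param threshold Alert threshold in `[0, 1]`.
#' @param budget A [latency_budget()].
#' @param mode Latency mode, see [total_latency()].
#' @param seed Optional seed for `"sample"` mode.
#' @return A data.frame with columns `device`, `score`, `threshold`, `alert`,
#'   `end_to_end_ms`.
#' @export
process_and_alert <- function(scores, threshold = 0.5,
                              budget = latency_budget(),
                              mode = c("sample", "min", "max"), seed = NULL) {
  mode <- match.arg(mode)
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  ids <- names(scores)
  if (is.null(ids)) ids <- paste0("D", seq_along(scores))
  lat <- vapply(seq_along(scores), function(i) total_latency(budget, mode),
                numeric(1))
  data.frame(device = ids, score = as.numeric(scores), threshold = threshold,
             alert = as.numeric(scores) > threshold, end_to_end_ms = lat,
             stringsAsFactors = FALSE)
}
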