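#' Policy-layer configuration for the integrated model
#'
#' The policy layer is a capacity-limited first-in-first-out service
#' process: agents whose internal adoption output exceeds
#' `output_threshold` emit a behavior-change request (at most one pending
#' request per agent); the policy serves up to `service_capacity` requests
#' per step, and each served request reverts the agent to susceptible with
#' probability `success_prob`.
#'
#' @param output_threshold Threshold on the agent's internal adoption
#'   output, in \[0, 1\] scale (may exceed 1 to disable requests).
#' @param service_capacity Requests processed per step (>= 0; `Inf`
#'   allowed).
#' @param success_prob Probability a processed request reverts the agent,
#'   in \[0, 1\].
#' @param smoothing Exponential smoothing constant of the agent's internal
#'   adoption output, in (0, 1\]; 1 makes the output the raw adoption
#'   state.
#' @return An object of class `policy_config`.
#' @export
policy_config <- function(output_threshold, service_capacity, success_prob,
                          smoothing = 1) {
  stopifnot_scalar(output_threshold, "output_threshold")
  if (!is.numeric(service_capacity) || length(service_capacity) != 1L ||
      is.na(service_capacity) || service_capacity < 0)
    stop("`service_capacity` must be >= 0", call. = FALSE)
  stopifnot_scalar(success_prob, "success_prob", 0, 1)
  stopifnot_scalar(smoothing, "smoothing", 1e-9, 1)
  structure(list(output_threshold = output_threshold,
                 service_capacity = service_capacity,
                 success_prob = success_prob, smoothing = smoothing),
            class = "policy_config")
}

#' Integrated network-contagion plus policy model
#'
#' Couples the agent-based contagion process with a discrete-event policy
#' layer.  Each step: (1) the network contagion update of
#' [simulate_network_contagion()] runs; (2) each agent's internal output
#' `o_i` is updated by exponential smoothing of its adoption state,
#' `o_i <- (1 - gamma) o_i + gamma * adopted_i`, and agents with
#' `o_i > output_threshold` and no pending request enqueue one; (3) the
#' policy serves up to `service_capacity` queued requests (first in, first
#' out); each served request reverts the agent to susceptible (and resets
#' its output) with probability `success_prob`.  Reverted agents can adopt
#' again later.
#'
#' @param graph An `igraph` graph.
#' @param transmit_prob,spontaneous_prob,immune,initial_adopters,behavioral_degree
#'   As in [simulate_network_contagion()].
#' @param policy A [policy_config()].
#' @param n_steps Number of steps.
#' @param seed Optional RNG seed.
#' @return A data frame with columns `step`, `adopted`, `queue_length`,
#'   `requests_emitted`, `requests_served`, `reversions`.
#' @export
run_integrated_model <- function(graph, transmit_prob,
                                 spontaneous_prob = 0,
                                 immune = integer(0),
                                 initial_adopters = integer(0),
                                 policy, n_steps, seed = NULL,
                                 behavioral_degree = 1) {
  stopifnot(igraph::is_igraph(graph), inherits(policy, "policy_config"))
  stopifnot_scalar(transmit_prob, "transmit_prob", 0, 1)
  stopifnot_scalar(spontaneous_prob, "spontaneous_prob", 0, 1)
  stopifnot_scalar(n_steps, "n_steps", lower = 1, integer = TRUE)
  n <- igraph::vcount(graph)
  if (length(intersect(immune, initial_adopters)) > 0L)
    stop("initial adopters must not be immune", call. = FALSE)
  bd <- rep_len(behavioral_degree, n)
  adj <- lapply(igraph::as_adj_list(graph), as.integer)
  adj_len <- lengths(adj)
  is_immune <- rep(FALSE, n); is_immune[immune] <- TRUE
  gamma <- policy$smoothing
  with_seed(seed, {
    adopted <- rep(FALSE, n); adopted[initial_adopters] <- TRUE
    output <- rep(0, n)
    queue <- integer(0)
    queued <- rep(FALSE, n)
    out <- vector("list", n_steps)
    for (t in seq_len(n_steps)) {
      # (1) contagion update (synchronous, no recovery within this phase)
      frontier <- which(adopted & bd > 0)
      newly <- integer(0)
      if (length(frontier) > 0L && transmit_prob > 0) {
        nb <- unlist(adj[frontier], use.names = FALSE)
        if (length(nb) > 0L) {
          w <- rep.int(bd[frontier], adj_len[frontier])
          keep <- !adopted[nb] & !is_immune[nb]
          nb <- nb[keep]; w <- w[keep]
          if (length(nb) > 0L) {
            lq <- rowsum(log1p(-transmit_prob * w), nb)
            uq <- as.integer(rownames(lq))
            newly <- uq[stats::runif(length(uq)) < -expm1(lq[, 1L])]
          }
        }
      }
      if (spontaneous_prob > 0) {
        cand <- setdiff(which(!adopted & !is_immune), newly)
        if (length(cand) > 0L)
          newly <- c(newly,
                     cand[stats::runif(length(cand)) < spontaneous_prob])
      }
      adopted[newly] <- TRUE
      # (2) internal output update and request emission
      output <- (1 - gamma) * output + gamma * as.numeric(adopted)
      emitters <- which(output > policy$output_threshold & !queued)
      queued[emitters] <- TRUE
      queue <- c(queue, emitters)
      # (3) FIFO service up to capacity
      n_serve <- as.integer(min(length(queue), policy$service_capacity))
      served <- queue[seq_len(n_serve)]
      if (n_serve > 0L) queue <- queue[-seq_len(n_serve)]
      queued[served] <- FALSE
      reverted <- served[stats::runif(length(served)) < policy$success_prob]
      adopted[reverted] <- FALSE
      output[reverted] <- 0
      out[[t]] <- c(step = t, adopted = sum(adopted),
                    queue_length = length(queue),
                    requests_emitted = length(emitters),
                    requests_served = length(served),
                    reversions = length(reverted))
    }
    as.data.frame(do.call(rbind, out))
  })
}
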