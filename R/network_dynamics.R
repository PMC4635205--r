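#' Generate a Poisson (Erdos-Renyi) random contact network
#'
#' Each unordered pair of the `n` individuals is linked independently with
#' probability `p`.
#'
#' @param n Number of nodes (>= 1).
#' @param p Link probability, in \[0, 1\].
#' @param seed Optional RNG seed for reproducibility.
#' @return An undirected `igraph` graph.
#' @examples
#' g <- generate_poisson_graph(100, 0.05, seed = 1)
#' @export
generate_poisson_graph <- function(n, p, seed = NULL) {
  stopifnot_scalar(n, "n", lower = 1, integer = TRUE)
  stopifnot_scalar(p, "p", 0, 1)
  with_seed(seed, igraph::sample_gnp(n, p, directed = FALSE))
}

#' Generate a preferential-attachment (Barabasi-Albert) network
#'
#' Grows a network from a single node; each arriving node attaches one edge
#' to an existing node chosen with probability proportional to its degree.
#' The result is a tree with `n - 1` edges and an approximately power-law
#' degree distribution `P(k) ~ k^-gamma` with `2 <= gamma <= 3`.
#'
#' @param n Number of nodes (>= 2).
#' @param seed Optional RNG seed.
#' @return An undirected `igraph` graph (a tree).
#' @export
generate_ba_graph <- function(n, seed = NULL) {
  stopifnot_scalar(n, "n", lower = 2, integer = TRUE)
  with_seed(seed, igraph::sample_pa(n, power = 1, m = 1, directed = FALSE))
}

#' Generate a configuration-model network from a degree sequence
#'
#' Stub-matching construction; self-loops and multi-edges are removed after
#' matching (the usual simplification; the degree distortion is O(1) edges
#' for the sizes used here).
#'
#' @param degree_sequence Non-negative integer degrees with an even sum.
#' @param seed Optional RNG seed.
#' @return An undirected simple `igraph` graph.
#' @export
generate_configuration_graph <- function(degree_sequence, seed = NULL) {
  if (any(degree_sequence < 0) || any(degree_sequence != round(degree_sequence)))
    stop("degrees must be non-negative integers", call. = FALSE)
  if (sum(degree_sequence) %% 2 != 0)
    stop("degree sum must be even", call. = FALSE)
  g <- with_seed(seed,
                 igraph::sample_degseq(degree_sequence,
                                       method = "configuration"))
  igraph::simplify(g)
}

#' Remove immune individuals from a contact network
#'
#' Each node is independently immune with probability `alpha_immune` and
#' removed; the induced subgraph on the surviving nodes is returned,
#' relabeled 1..m, with the original ids of survivors and immune nodes.
#'
#' @param graph An `igraph` graph.
#' @param alpha_immune Immunity probability, in \[0, 1\].
#' @param seed Optional RNG seed.
#' @return A list with elements `graph` (the induced subgraph), `kept`
#'   (original ids of surviving nodes, in relabeling order) and `immune`
#'   (original ids of removed nodes).
#' @export
remove_immune <- function(graph, alpha_immune, seed = NULL) {
  stopifnot(igraph::is_igraph(graph))
  stopifnot_scalar(alpha_immune, "alpha_immune", 0, 1)
  n <- igraph::vcount(graph)
  immune <- with_seed(seed, which(stats::runif(n) < alpha_immune))
  kept <- setdiff(seq_len(n), immune)
  list(graph = igraph::induced_subgraph(graph, kept),
       kept = kept, immune = immune)
}

#' Fraction of nodes in the largest connected component
#'
#' @param graph An `igraph` graph.
#' @return Size of the largest component divided by the node count; 0 for
#'   an empty graph.
#' @export
giant_component_fraction <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  n <- igraph::vcount(graph)
  if (n == 0L) return(0)
  max(igraph::components(graph)$csize) / n
}

#' Expected outbreak fraction on a Poisson network
#'
#' Solves the fixed point `r = 1 - exp(-c r)` for the expected size of a
#' behavior outbreak as a fraction of the susceptible nodes, where
#' `c = (1 - alpha) n p` is the mean degree among the non-immune.  For
#' `c <= 1` the only root in \[0, 1\] is 0 (no giant outbreak); above the
#' threshold the positive root is returned (bisection to ~1e-12).
#'
#' @param c Dimensionless mean degree `(1 - alpha) n p` (>= 0).
#' @return Outbreak fraction in \[0, 1\].
#' @examples
#' solve_outbreak_fraction(2) # ~0.7968
#' @export
solve_outbreak_fraction <- function(c) {
  stopifnot_scalar(c, "c", lower = 0)
  if (c <= 1) return(0)
  f <- function(r) 1 - exp(-c * r) - r
  stats::uniroot(f, lower = 1e-12, upper = 1, tol = 1e-14)$root
}

#' Mean degree consistent with an outbreak fraction
#'
#' Inverts the fixed point `r = 1 - exp(-c r)`:
#' `c = (1 - alpha) n p = -log(1 - r) / r`.
#'
#' @param r Outbreak fraction in (0, 1).
#' @return The dimensionless mean degree `c`.
#' @export
outbreak_mean_degree <- function(r) {
  stopifnot_scalar(r, "r", 1e-12, 1 - 1e-12)
  -log(1 - r) / r
}

#' Estimate the percolation threshold of an immunised Poisson network
#'
#' For each link probability on a grid, generates Poisson networks, removes
#' immune nodes, and averages the largest-component fraction over
#' replicates.  The critical `p` is the first grid point where the average
#' crosses `cutoff`; the dimensionless product `p (1 - alpha) n` at the
#' crossing is reported (the asymptotic threshold is at product 1).
#'
#' @param n Nodes per generated network.
#' @param alpha_immune Immunity probability.
#' @param p_grid Sorted grid of link probabilities; by default the grid
#'   spans products `(1 - alpha) n p` from 0.5 to 1.5 in steps of 0.05.
#' @param reps Replicates per grid point (>= 1).
#' @param seed Optional RNG seed for the whole sweep.
#' @param cutoff Emergence cutoff on the mean giant-component fraction
#'   (default 0.05).
#' @return A list with `p_critical`, `product` (`p (1-alpha) n` at the
#'   crossing), and `curve`, a data frame of `p`, `product` and
#'   `mean_gc_fraction`.  If the first grid point is already above the
#'   cutoff a warning is issued and that point reported; a grid that never
#'   crosses is an error.
#' @export
estimate_percolation_threshold <- function(n, alpha_immune = 0,
                                           p_grid = NULL, reps = 30,
                                           seed = NULL, cutoff = 0.05) {
  stopifnot_scalar(n, "n", lower = 2, integer = TRUE)
  stopifnot_scalar(alpha_immune, "alpha_immune", 0, 1 - 1e-9)
  stopifnot_scalar(reps, "reps", lower = 1, integer = TRUE)
  m <- (1 - alpha_immune) * n
  if (is.null(p_grid)) p_grid <- seq(0.5, 1.5, by = 0.05) / m
  if (is.unsorted(p_grid) || any(p_grid < 0) || any(p_grid > 1))
    stop("`p_grid` must be sorted probabilities", call. = FALSE)
  means <- with_seed(seed, vapply(p_grid, function(p) {
    mean(vapply(seq_len(reps), function(r) {
      g <- igraph::sample_gnp(n, p, directed = FALSE)
      giant_component_fraction(remove_immune(g, alpha_immune)$graph)
    }, numeric(1)))
  }, numeric(1)))
  curve <- data.frame(p = p_grid, product = p_grid * m,
                      mean_gc_fraction = means)
  hit <- which(means >= cutoff)
  if (length(hit) == 0L)
    stop("no threshold in range: the grid never crosses the cutoff",
         call. = FALSE)
  if (hit[1L] == 1L)
    warning("grid entirely above the emergence cutoff; reporting the first grid point")
  k <- hit[1L]
  list(p_critical = p_grid[k], product = p_grid[k] * m, curve = curve,
       alpha_immune = alpha_immune, n = n, cutoff = cutoff)
}

#' Classify the connectivity regime of an immunised Poisson network
#'
#' Compares `p` with the giant-component threshold `1 / ((1-alpha) n)` and
#' the connectivity bound `log((1-alpha) n) / ((1-alpha) n)`: below the
#' first only a vanishing share of susceptible individuals can be reached;
#' between them a giant component of susceptibles emerges; above the second
#' the susceptible network is (asymptotically) fully connected.
#'
#' @param n Number of nodes.
#' @param alpha_immune Immunity probability.
#' @param p Link probability.
#' @return One of `"subcritical"`, `"supercritical"`, `"connected"`.
#' @export
connectivity_regime <- function(n, alpha_immune, p) {
  stopifnot_scalar(n, "n", lower = 1, integer = TRUE)
  stopifnot_scalar(alpha_immune, "alpha_immune", 0, 1)
  stopifnot_scalar(p, "p", 0, 1)
  m <- (1 - alpha_immune) * n
  if (m < 2) stop("(1 - alpha) n must be at least 2", call. = FALSE)
  if (p < 1 / m) "subcritical"
  else if (p > log(m) / m) "connected"
  else "supercritical"
}

#' Degree moments of a graph or degree sequence
#'
#' @param x An `igraph` graph or a numeric degree sequence.
#' @return A list with `mean_deg` and `second_moment`.
#' @export
degree_moments <- function(x) {
  d <- if (igraph::is_igraph(x)) igraph::degree(x) else x
  if (length(d) == 0L) return(list(mean_deg = 0, second_moment = 0))
  list(mean_deg = mean(d), second_moment = mean(d^2))
}

#' Supercriticality margin in the configuration model
#'
#' The percolation threshold for an emerging giant component in the
#' configuration model sits at `<d^2> = 2 <d>`; this returns the signed
#' margin `<d^2> - 2 <d>` (positive: a giant component is expected; zero:
#' critical; negative: subcritical).  When immune nodes are removed the
#' moments are computed on the residual (post-removal) degree sequence.
#'
#' @param moments A list with `mean_deg` and `second_moment`, as from
#'   [degree_moments()].
#' @return The signed margin.
#' @export
config_supercritical_margin <- function(moments) {
  stopifnot(is.list(moments),
            all(c("mean_deg", "second_moment") %in% names(moments)))
  moments$second_moment - 2 * moments$mean_deg
}

#' Homogeneous mean-field spreading on a network
#'
#' In a network where every node has about `<k>` neighbors, the informed
#' density follows `di/dt = lambda i <k> (1 - i)`, whose solution is the
#' logistic `i(t) = i0 e^{lambda <k> t} / (1 - i0 + i0 e^{lambda <k> t})`.
#'
#' @param lam Diffusion probability per unit time (>= 0).
#' @param k_mean Mean degree (>= 0).
#' @param i0 Initial informed density, in \[0, 1\].
#' @param times Vector of evaluation times.
#' @return A data frame with columns `time` and `density`.
#' @export
meanfield_homogeneous <- function(lam, k_mean, i0, times) {
  stopifnot_scalar(lam, "lam", lower = 0)
  stopifnot_scalar(k_mean, "k_mean", lower = 0)
  stopifnot_scalar(i0, "i0", 0, 1)
  e <- exp(lam * k_mean * times)
  data.frame(time = times, density = i0 * e / (1 - i0 + i0 * e))
}

#' Degree-based mean-field parameters
#'
#' Holds the diffusion probability `lambda`, the initial informed density
#' `i0`, and a degree distribution `P(k)`; derives the moments and the
#' relaxation time `tau = <k^2> / (lambda (<k^2> - <k>))`, which requires
#' `<k^2> > <k>`.
#'
#' @param lam Diffusion probability, in (0, 1].
#' @param i0 Initial informed density, in (0, 1].
#' @param degree_dist A data frame with columns `k` (integer degrees) and
#'   `pk` (masses summing to 1), or a named numeric vector of masses with
#'   degrees as names.
#' @return An object of class `meanfield_sis_params` with elements `lam`,
#'   `i0`, `k`, `pk`, `k_mean`, `k2_mean`, `tau`.
#' @export
meanfield_sis_params <- function(lam, i0, degree_dist) {
  stopifnot_scalar(lam, "lam", 1e-12, 1)
  stopifnot_scalar(i0, "i0", 1e-12, 1)
  if (is.data.frame(degree_dist)) {
    k <- degree_dist$k; pk <- degree_dist$pk
  } else {
    k <- as.numeric(names(degree_dist)); pk <- as.numeric(degree_dist)
  }
  if (any(pk < 0) || abs(sum(pk) - 1) > 1e-9)
    stop("degree distribution masses must be >= 0 and sum to 1",
         call. = FALSE)
  k_mean <- sum(k * pk)
  k2_mean <- sum(k^2 * pk)
  if (k2_mean <= k_mean)
    stop("tau undefined: requires <k^2> > <k>", call. = FALSE)
  structure(list(lam = lam, i0 = i0, k = k, pk = pk, k_mean = k_mean,
                 k2_mean = k2_mean,
                 tau = k2_mean / (lam * (k2_mean - k_mean))),
            class = "meanfield_sis_params")
}

#' Degree-based mean-field spreading on a heterogeneous network
#'
#' Tracks the informed density per degree class.  Two routes are computed:
#' the early-time closed form
#' `i_k(t) = i0 (1 + k <k> / (<k^2> - <k>) (e^{t/tau} - 1))` with
#' `tau = <k^2> / (lambda (<k^2> - <k>))`, capped at 1; and a numerical
#' integration of `di_k/dt = lambda theta(t) k (1 - i_k)` with the
#' neighbor density `theta(t) = sum_k (k - 1) P(k) i_k(t) / <k^2>` (the
#' normalisation whose linearised growth rate equals `1/tau`).  The two
#' agree for early times (`t` up to about `0.1 tau`); the closed form is an
#' early-time approximation only.
#'
#' @param params A [meanfield_sis_params()] object.
#' @param times Vector of non-negative evaluation times.
#' @return A list with `times`, `k`, matrices `closed_form` and `ode`
#'   (times x degree classes), aggregate densities `aggregate_closed` and
#'   `aggregate_ode`, and `tau`.
#' @export
meanfield_degree_based <- function(params, times) {
  stopifnot(inherits(params, "meanfield_sis_params"))
  if (any(times < 0)) stop("`times` must be >= 0", call. = FALSE)
  k <- params$k; pk <- params$pk
  gap <- params$k2_mean - params$k_mean
  closed <- outer(exp(times / params$tau) - 1,
                  k * params$k_mean / gap) # times x k
  closed <- pmin(params$i0 * (1 + closed), 1)
  deriv <- function(t, y, p) {
    theta <- sum((k - 1) * pk * y) / params$k2_mean
    list(params$lam * theta * k * (1 - y))
  }
  tt <- sort(unique(c(0, times)))
  sol <- deSolve::ode(y = rep(params$i0, length(k)), times = tt,
                      func = deriv, parms = NULL, rtol = 1e-10, atol = 1e-12)
  ode <- sol[match(times, tt), -1L, drop = FALSE]
  dimnames(closed) <- dimnames(ode) <- list(NULL, paste0("k", k))
  list(times = times, k = k, closed_form = closed, ode = ode,
       aggregate_closed = as.numeric(closed %*% pk),
       aggregate_ode = as.numeric(ode %*% pk),
       tau = params$tau)
}

#' Agent-based behavior contagion on a network
#'
#' Synchronous discrete-time process: at every step each adopter with
#' positive `behavioral_degree` tries to transmit the behavior to each
#' susceptible, non-immune neighbor independently with probability
#' `transmit_prob * behavioral_degree`; susceptible non-immune nodes also
#' adopt spontaneously with probability `spontaneous_prob`.  There is no
#' recovery: adoption counts are non-decreasing and immune nodes never
#' adopt.
#'
#' @param graph An `igraph` graph.
#' @param transmit_prob Per-contact per-step transmission probability.
#' @param spontaneous_prob Per-step spontaneous adoption probability.
#' @param immune Integer vector of immune node ids (1-based).
#' @param initial_adopters Integer vector of seed adopters; must be
#'   disjoint from `immune`.
#' @param n_steps Number of steps (>= 1).
#' @param seed Optional RNG seed for the whole ensemble.
#' @param reps Number of independent replicates.
#' @param behavioral_degree Diffusion strength in \[0, 1\], a scalar or a
#'   per-node vector; an agent spreads only if its value is positive.
#' @return A data frame with columns `rep`, `step` (0..n_steps) and
#'   `adopted` (count).
#' @export
simulate_network_contagion <- function(graph, transmit_prob,
                                       spontaneous_prob = 0,
                                       immune = integer(0),
                                       initial_adopters = integer(0),
                                       n_steps, seed = NULL, reps = 1,
                                       behavioral_degree = 1) {
  stopifnot(igraph::is_igraph(graph))
  stopifnot_scalar(transmit_prob, "transmit_prob", 0, 1)
  stopifnot_scalar(spontaneous_prob, "spontaneous_prob", 0, 1)
  stopifnot_scalar(n_steps, "n_steps", lower = 1, integer = TRUE)
  stopifnot_scalar(reps, "reps", lower = 1, integer = TRUE)
  n <- igraph::vcount(graph)
  if (length(intersect(immune, initial_adopters)) > 0L)
    stop("initial adopters must not be immune", call. = FALSE)
  bd <- rep_len(behavioral_degree, n)
  if (any(bd < 0) || any(bd > 1))
    stop("`behavioral_degree` must be in [0, 1]", call. = FALSE)
  adj <- lapply(igraph::as_adj_list(graph), as.integer)
  adj_len <- lengths(adj)
  is_immune <- rep(FALSE, n); is_immune[immune] <- TRUE
  run_one <- function() {
    adopted <- rep(FALSE, n); adopted[initial_adopters] <- TRUE
    counts <- integer(n_steps + 1L)
    counts[1L] <- sum(adopted)
    for (t in seq_len(n_steps)) {
      frontier <- which(adopted & bd > 0)
      newly <- integer(0)
      if (length(frontier) > 0L && transmit_prob > 0) {
        nb <- unlist(adj[frontier], use.names = FALSE)
        if (length(nb) > 0L) {
          w <- rep.int(bd[frontier], adj_len[frontier])
          keep <- !adopted[nb] & !is_immune[nb]
          nb <- nb[keep]; w <- w[keep]
          if (length(nb) > 0L) {
            # P(not adopted) = prod over adopter neighbors of 1 - p*bd
            lq <- rowsum(log1p(-transmit_prob * w), nb)
            uq <- as.integer(rownames(lq))
            newly <- uq[stats::runif(length(uq)) < -expm1(lq[, 1L])]
          }
        }
      }
      if (spontaneous_prob > 0) {
        cand <- which(!adopted & !is_immune)
        cand <- setdiff(cand, newly)
        if (length(cand) > 0L)
          newly <- c(newly,
                     cand[stats::runif(length(cand)) < spontaneous_prob])
      }
      adopted[newly] <- TRUE
      counts[t + 1L] <- sum(adopted)
    }
    counts
  }
  out <- with_seed(seed, lapply(seq_len(reps), function(r) run_one()))
  data.frame(rep = rep(seq_len(reps), each = n_steps + 1L),
             step = rep(0:n_steps, times = reps),
             adopted = unlist(out, use.names = FALSE))
}
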