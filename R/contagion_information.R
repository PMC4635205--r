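log_in_base <- function(x, base) {
  if (!is.numeric(base) || length(base) != 1L || base <= 0 || base == 1)
    stop("`base` must be positive and != 1", call. = FALSE)
  log(x) / log(base)
}

# p * log(1/p) terms with the 0 * log(1/0) := 0 convention, in nats
plog_terms <- function(p) ifelse(p > 0, -p * log(p), 0)

#' Contagion of an event
#'
#' The behavior-contagion measure of an event with probability `p`,
#' `I(p) = log(1/p)`: non-negative, additive over independent events, and
#' zero for a sure event.  `base` sets the unit (2 bits, 3 trits, `exp(1)`
#' nats, 10 Hartleys).
#'
#' @param p Probability, in (0, 1\]; `p = 0` returns `Inf`.
#' @param base Logarithm base (default 2).
#' @return `log_base(1/p)`, vectorised over `p`.
#' @examples
#' contagion(0.5)       # 1 bit
#' contagion(1)         # 0
#' @export
contagion <- function(p, base = 2) {
  if (any(p < 0) || any(p > 1))
    stop("`p` must be in [0, 1]", call. = FALSE)
  log_in_base(1 / p, base)
}

#' Entropy of a finite probability distribution
#'
#' `S(P) = sum_i p_i log(1/p_i)`, the expected contagion of the
#' distribution, with `0 * log(1/0) := 0`.
#'
#' @param dist Probability masses (>= 0, summing to 1 within 1e-9).
#' @param base Logarithm base (default 2).
#' @return The entropy in the units of `base`.
#' @examples
#' entropy(c(0.5, 0.25, 0.25)) # 1.5 bits
#' @export
entropy <- function(dist, base = 2) {
  check_dist(dist)
  sum(plog_terms(dist)) / log(base)
}

check_dist <- function(p, name = "dist", tol = 1e-9) {
  if (any(p < 0) || abs(sum(p) - 1) > tol)
    stop(sprintf("`%s` must be non-negative masses summing to 1", name),
         call. = FALSE)
  invisible(p)
}

#' Expected value of contagion values under a distribution
#'
#' `E[H] = sum_i h_i p_i`; when `h_i = I(p_i)` this equals the entropy of
#' the distribution.
#'
#' @param dist Probability masses.
#' @param values Contagion values aligned with `dist`.
#' @return The weighted mean.
#' @export
expected_contagion <- function(dist, values) {
  check_dist(dist)
  if (length(values) != length(dist))
    stop("`values` must align with `dist`", call. = FALSE)
  sum(values * dist)
}

#' Kraft-McMillan feasibility of a code
#'
#' Computes `K = sum_i base^(-l_i)`; a uniquely decodable code with the
#' given lengths exists iff `K <= 1`.
#'
#' @param lengths Positive integer code lengths.
#' @param code_base Code alphabet size (integer >= 2).
#' @return A list with `K` and logical `feasible`.
#' @examples
#' kraft_check(c(1, 2, 2)) # K = 1, feasible
#' @export
kraft_check <- function(lengths, code_base = 2) {
  if (length(lengths) == 0L)
    stop("`lengths` must be non-empty", call. = FALSE)
  if (any(lengths < 1) || any(lengths != round(lengths)))
    stop("`lengths` must be positive integers", call. = FALSE)
  stopifnot_scalar(code_base, "code_base", lower = 2, integer = TRUE)
  K <- sum(code_base^(-lengths))
  list(K = K, feasible = K <= 1 + 1e-12)
}

#' Source-coding lower bound
#'
#' The entropy bounds the efficiency of any uniquely decodable encoding:
#' `S(B) <= L log(beta)` with `L = sum_i p_i l_i` the mean code length and
#' `beta` the code alphabet size.  Both sides are returned in the units of
#' `base`.
#'
#' @param dist Source symbol probabilities.
#' @param lengths Code lengths aligned with `dist`.
#' @param code_base Code alphabet size.
#' @param base Logarithm base for the entropy unit (default 2).
#' @return A list with `entropy`, `bound` (`L log beta`), and logical
#'   `satisfied`.
#' @export
source_coding_bound <- function(dist, lengths, code_base = 2, base = 2) {
  check_dist(dist)
  if (length(lengths) != length(dist))
    stop("`lengths` must align with `dist`", call. = FALSE)
  S <- entropy(dist, base)
  L <- sum(dist * lengths)
  bound <- L * log_in_base(code_base, base)
  list(entropy = S, bound = bound, satisfied = S <= bound + 1e-12)
}

#' Mutual contagion and entropies of a joint distribution
#'
#' All quantities by direct summation over the joint matrix `P(f, g)`
#' (rows: input symbols F, columns: output symbols G): marginal entropies
#' `S(F)`, `S(G)`, conditional entropies `S(F|G)`, `S(G|F)`, joint entropy
#' `S(F,G)`, and the mutual contagion
#' `I(F;G) = sum P(f,g) log(P(f,g) / (P(f) P(g)))`, the reduction in
#' uncertainty about one individual's behavior given the other's.
#'
#' @param joint Matrix of joint probabilities (entries >= 0, total 1).
#' @param base Logarithm base (default 2).
#' @return A list with `mutual`, `S_F`, `S_G`, `S_F_given_G`,
#'   `S_G_given_F`, `S_FG`.
#' @export
mutual_contagion <- function(joint, base = 2) {
  if (!is.matrix(joint)) stop("`joint` must be a matrix", call. = FALSE)
  check_dist(as.numeric(joint), "joint")
  pf <- rowSums(joint)
  pg <- colSums(joint)
  lb <- log(base)
  S_F <- sum(plog_terms(pf)) / lb
  S_G <- sum(plog_terms(pg)) / lb
  S_FG <- sum(plog_terms(as.numeric(joint))) / lb
  # conditional entropies by direct summation
  cond_sum <- function(p_joint, p_cond_denom) {
    # sum P(f,g) log(denom / P(f,g)) over cells with P(f,g) > 0
    pos <- p_joint > 0
    sum(p_joint[pos] * log(p_cond_denom[pos] / p_joint[pos])) / lb
  }
  S_F_given_G <- cond_sum(joint, matrix(pg, nrow(joint), ncol(joint),
                                        byrow = TRUE))
  S_G_given_F <- cond_sum(joint, matrix(pf, nrow(joint), ncol(joint)))
  pos <- joint > 0
  ind <- outer(pf, pg)
  mutual <- sum(joint[pos] * log(joint[pos] / ind[pos])) / lb
  list(mutual = mutual, S_F = S_F, S_G = S_G,
       S_F_given_G = S_F_given_G, S_G_given_F = S_G_given_F, S_FG = S_FG)
}

#' Channel capacity by alternating maximisation
#'
#' `C = max over input distributions of I(F; G)` for a forward channel
#' matrix `P(g | f)` (rows: inputs, columns: outputs), computed with the
#' Blahut-Arimoto iteration.  The lower bound produced by the iteration is
#' non-decreasing, and the loop stops when the gap between the upper and
#' lower capacity bounds falls below `tol`.  A backward characterisation
#' `{P(f | g)}` together with an input prior can be converted with
#' [channel_from_backward()].
#'
#' @param channel Row-stochastic matrix `P(g | f)`.
#' @param base Logarithm base for the capacity unit (default 2).
#' @param tol Convergence tolerance on the capacity (default 1e-10).
#' @param max_iter Iteration cap.
#' @return A list with `capacity`, `input_dist`, `iterations`, and `trace`
#'   (the non-decreasing lower-bound sequence).
#' @examples
#' bsc <- matrix(c(0.89, 0.11, 0.11, 0.89), 2, byrow = TRUE)
#' channel_capacity(bsc)$capacity # ~ 1 - H2(0.11)
#' @export
channel_capacity <- function(channel, base = 2, tol = 1e-10,
                             max_iter = 10000L) {
  if (!is.matrix(channel)) stop("`channel` must be a matrix", call. = FALSE)
  if (any(channel < 0) || any(abs(rowSums(channel) - 1) > 1e-9))
    stop("rows of `channel` must be probability distributions",
         call. = FALSE)
  n <- nrow(channel)
  p <- rep(1 / n, n)
  lb <- log(base)
  trace <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    q <- as.numeric(p %*% channel)
    # D_i = KL(W_i || q) in nats; rows with support outside supp(q) cannot
    # occur since q >= p_i * W_ij and p > 0 throughout the iteration
    D <- vapply(seq_len(n), function(i) {
      w <- channel[i, ]
      pos <- w > 0
      sum(w[pos] * log(w[pos] / q[pos]))
    }, numeric(1))
    lower <- sum(p * D)
    upper <- max(D)
    trace <- c(trace, lower / lb)
    if (upper - lower < tol * lb || iter >= max_iter) break
    p <- p * exp(D - max(D))
    p <- p / sum(p)
  }
  list(capacity = max(lower, 0) / lb, input_dist = p, iterations = iter,
       trace = trace)
}

#' Forward channel matrix from a backward characterisation
#'
#' A channel can be characterised by the set `{P(f | g)}` together with the
#' output marginal `P(g)`; capacity is conventionally maximised over input
#' distributions, so this converts to the forward matrix
#' `P(g | f) = P(f | g) P(g) / P(f)`.
#'
#' @param backward Matrix `P(f | g)` with columns indexed by `g` (each
#'   column a distribution over `f`).
#' @param output_dist The marginal `P(g)`.
#' @return The row-stochastic forward matrix `P(g | f)`.
#' @export
channel_from_backward <- function(backward, output_dist) {
  if (!is.matrix(backward)) stop("`backward` must be a matrix", call. = FALSE)
  if (any(backward < 0) || any(abs(colSums(backward) - 1) > 1e-9))
    stop("columns of `backward` must be probability distributions",
         call. = FALSE)
  check_dist(output_dist, "output_dist")
  joint <- sweep(backward, 2, output_dist, `*`) # P(f, g)
  pf <- rowSums(joint)
  if (any(pf == 0))
    stop("input symbols with zero probability cannot be inverted",
         call. = FALSE)
  sweep(joint, 1, pf, `/`)
}

#' Maximum-entropy distribution under linear constraints
#'
#' Finds the distribution `f` on `n` states maximising the entropy
#' `sum_i f_i log(1/f_i)` subject to `f_i >= 0`, `sum_i f_i = 1` and the
#' macroscopic constraints `sum_i f_i s_i^(r) = s_r`.  The solution has the
#' exponential-family form `f_i = exp(-lambda - sum_r lambda_r s_i^(r))`
#' with `lambda = log(H)` and `H` the partition sum
#' `sum_i exp(-sum_r lambda_r s_i^(r))`.  The multipliers are found by
#' minimising the convex dual (quasi-Newton with analytic gradient).
#'
#' @param s_matrix Numeric matrix (`n` states x `K` constraints) of
#'   per-state constraint values `s_i^(r)`; use a 0-column matrix (or
#'   `NULL`) for no constraints beyond normalisation.
#' @param targets Constraint targets `s_r` (length `K`); must lie strictly
#'   inside the convex hull of the rows of `s_matrix` to be attainable.
#' @param n_states Number of states; required when `s_matrix` is `NULL`.
#' @param tol Maximum allowed constraint residual (default 1e-10).
#' @return A list with `dist`, `multipliers`, `log_partition`
#'   (`lambda = log H`), `residuals` and `entropy_nats`.
#' @examples
#' maxent_distribution(matrix(0:2), targets = 0.5)
#' @export
maxent_distribution <- function(s_matrix = NULL, targets = numeric(0),
                                n_states = NULL, tol = 1e-10) {
  if (is.null(s_matrix) || NCOL(s_matrix) == 0L || length(targets) == 0L) {
    if (is.null(n_states)) {
      if (is.null(s_matrix)) stop("`n_states` required", call. = FALSE)
      n_states <- nrow(as.matrix(s_matrix))
    }
    f <- rep(1 / n_states, n_states)
    return(list(dist = f, multipliers = numeric(0),
                log_partition = log(n_states), residuals = numeric(0),
                entropy_nats = log(n_states)))
  }
  s_matrix <- as.matrix(s_matrix)
  K <- ncol(s_matrix)
  if (length(targets) != K)
    stop("`targets` must have one value per constraint column",
         call. = FALSE)
  lo <- apply(s_matrix, 2, min); hi <- apply(s_matrix, 2, max)
  if (any(targets < lo - 1e-12) || any(targets > hi + 1e-12))
    stop("infeasible targets: outside the range of the constraint values",
         call. = FALSE)
  dist_for <- function(lam) {
    u <- -as.numeric(s_matrix %*% lam)
    u <- u - max(u)
    w <- exp(u)
    w / sum(w)
  }
  dual <- function(lam) {
    u <- -as.numeric(s_matrix %*% lam)
    m <- max(u)
    m + log(sum(exp(u - m))) + sum(lam * targets)
  }
  grad <- function(lam) {
    f <- dist_for(lam)
    targets - as.numeric(t(s_matrix) %*% f)
  }
  fit <- stats::optim(rep(0, K), dual, grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-16))
  # polish with a few damped gradient steps if needed
  lam <- fit$par
  for (it in seq_len(200L)) {
    res <- -grad(lam)
    if (max(abs(res)) <= tol) break
    f <- dist_for(lam)
    # Newton on the dual: Hessian = covariance of constraint values
    sc <- sweep(s_matrix, 2, as.numeric(t(s_matrix) %*% f))
    H <- t(sc) %*% (sc * f)
    step <- tryCatch(solve(H + diag(1e-12, K), res),
                     error = function(e) res)
    lam <- lam + step
  }
  f <- dist_for(lam)
  res <- as.numeric(t(s_matrix) %*% f) - targets
  if (max(abs(res)) > max(tol, 1e-8))
    stop("maximum-entropy solve did not reach the targets; they may be on ",
         "the boundary of the feasible set", call. = FALSE)
  u <- -as.numeric(s_matrix %*% lam)
  logH <- {
    m <- max(u); m + log(sum(exp(u - m)))
  }
  list(dist = f, multipliers = lam, log_partition = logH,
       residuals = res, entropy_nats = sum(plog_terms(f)))
}
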