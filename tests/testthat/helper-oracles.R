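# Independent oracles used across the suite.  These deliberately use the
# most naive formulation available (explicit loops, brute-force search)
# so they stay independent of the package implementation.

# Spreadsheet-style re-evaluation of the adoption recurrence.
oracle_recurrence <- function(alpha, beta, s0, n_steps) {
  s <- numeric(n_steps + 1)
  s[1] <- s0
  for (t in 1:n_steps) {
    prev <- s[t]
    s[t + 1] <- min(max(prev + alpha * (1 - prev) + beta * (1 - prev) * prev,
                        0), 1)
  }
  s
}

# Loop-based time-domain HRV statistics.
oracle_hrv <- function(nn) {
  n <- length(nn)
  avnn <- sum(nn) / n
  sdnn <- sqrt(sum((nn - avnn)^2) / (n - 1))
  sq <- 0; big <- 0
  for (i in 2:n) {
    d <- nn[i] - nn[i - 1]
    sq <- sq + d^2
    if (abs(d) > 50) big <- big + 1
  }
  list(avnn = avnn, sdnn = sdnn, rmssd = sqrt(sq / (n - 1)),
       pnn50 = 100 * big / (n - 1))
}

# Union-find connected components; returns the largest-component fraction.
oracle_giant_fraction <- function(n, edges) {
  if (n == 0) return(0)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (length(edges) > 0) {
    for (i in seq_len(nrow(edges))) {
      a <- find(edges[i, 1]); b <- find(edges[i, 2])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), function(x) as.integer(find(x)), integer(1))
  max(table(roots)) / n
}

# Binary entropy in bits.
h2 <- function(e) {
  if (e <= 0 || e >= 1) return(0)
  -e * log2(e) - (1 - e) * log2(1 - e)
}

# Brute-force capacity of a 2-input channel by grid search over the input
# distribution.
oracle_capacity_2input <- function(channel, grid = seq(0, 1, by = 1e-4)) {
  best <- 0
  for (p in grid) {
    px <- c(p, 1 - p)
    q <- px %*% channel
    mi <- 0
    for (i in 1:2) for (j in seq_len(ncol(channel))) {
      pij <- px[i] * channel[i, j]
      if (pij > 0) mi <- mi + pij * log2(pij / (px[i] * q[j]))
    }
    if (mi > best) best <- mi
  }
  best
}

# Random joint distribution over an n x m alphabet.
random_joint <- function(n, m) {
  x <- matrix(stats::rexp(n * m), n, m)
  x / sum(x)
}

# Rejection-sample distributions on the states {0, 1, 2} whose mean lies
# within `band` of `target`; one distribution per row.  Sampled laws are
# only band-feasible, so entropy comparisons against the exact-constraint
# optimum must allow |multiplier| * band of slack.
sample_feasible_mean3 <- function(n_keep, target, band) {
  out <- matrix(numeric(0), 0, 3)
  while (nrow(out) < n_keep) {
    f <- matrix(stats::rexp(3000 * 3), ncol = 3)
    f <- f / rowSums(f)
    keep <- abs(f %*% c(0, 1, 2) - target) < band
    out <- rbind(out, f[keep, , drop = FALSE])
  }
  out[seq_len(n_keep), , drop = FALSE]
}

simplex_entropy <- function(f) {
  apply(f, 1, function(x) -sum(ifelse(x > 0, x * log(x), 0)))
}

# Small synthetic delta table for direct rule checks: all indexes zero
# except the named ones.
delta_table_with <- function(..., subject = "S1", group = "g",
                             condition = "VR") {
  override <- list(...)
  idx <- c("EMG-Z", "EMG-CS", "SC_Mean", "RSA", "LFbyHF", "HF", "LF",
           "TOTPWR", "pNN50", "rMSSD", "SDNN", "AVNN", "Alpha", "Beta",
           "EEG_Asym", "SUS", "PMQ_Anxiety", "PMQ_Relax")
  delta <- stats::setNames(rep(0, length(idx)), idx)
  for (nm in names(override)) delta[[nm]] <- override[[nm]]
  data.frame(subject = subject, group = group, condition = condition,
             index = idx, delta = as.numeric(delta),
             missing = FALSE, stringsAsFactors = FALSE)
}
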