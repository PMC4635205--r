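test_that("Poisson graph generation hits its combinatorial anchors", {
  expect_equal(igraph::ecount(generate_poisson_graph(50, 0, seed = 1)), 0)
  expect_equal(igraph::ecount(generate_poisson_graph(10, 1, seed = 1)), 45)
  expect_error(generate_poisson_graph(10, 1.5), "p")
  md <- vapply(1:30, function(s) {
    mean(igraph::degree(generate_poisson_graph(1000, 0.01, seed = s)))
  }, numeric(1))
  # mean degree (n-1)p = 9.99; s.e. of the 30-seed mean
  se <- sd(md) / sqrt(30)
  expect_lt(abs(mean(md) - 9.99), 3 * se + 1e-9)
})

test_that("preferential-attachment graphs are trees with heavy-tailed degrees", {
  g <- generate_ba_graph(500, seed = 1)
  expect_equal(igraph::ecount(g), 499)
  expect_true(igraph::is_connected(g))
  expect_equal(sum(igraph::degree(g)), 2 * 499)
  alphas <- vapply(1:20, function(s) {
    gg <- generate_ba_graph(5000, seed = s)
    igraph::fit_power_law(igraph::degree(gg), xmin = 2)$alpha
  }, numeric(1))
  expect_gte(mean(alphas), 2)
  expect_error(generate_ba_graph(1), "n")
})

test_that("configuration-model graphs respect their degree sequences", {
  expect_equal(igraph::ecount(generate_configuration_graph(rep(0, 5))), 0)
  expect_equal(igraph::ecount(generate_configuration_graph(c(1, 1), seed = 1)),
               1)
  expect_error(generate_configuration_graph(c(1, 1, 1)), "even")
  g <- generate_configuration_graph(rep(3, 2000), seed = 2)
  expect_lt(abs(mean(igraph::degree(g)) - 3) / 3, 0.02)
})

test_that("immune-node removal is a binomial thinning of the graph", {
  g <- generate_poisson_graph(200, 0.05, seed = 1)
  all_kept <- remove_immune(g, 0, seed = 1)
  expect_equal(igraph::vcount(all_kept$graph), 200)
  expect_equal(igraph::ecount(all_kept$graph), igraph::ecount(g))
  none_kept <- remove_immune(g, 1, seed = 1)
  expect_equal(igraph::vcount(none_kept$graph), 0)
  surv <- vapply(1:30, function(s) {
    length(remove_immune(generate_poisson_graph(10000, 0, seed = s),
                         0.3, seed = 100 + s)$kept)
  }, numeric(1))
  se <- sd(surv) / sqrt(30)
  expect_lt(abs(mean(surv) - 7000), 3 * se + 1e-9)
})

test_that("giant-component fraction matches a union-find oracle", {
  expect_equal(giant_component_fraction(igraph::make_full_graph(8)), 1)
  two <- igraph::disjoint_union(igraph::make_full_graph(7),
                                igraph::make_full_graph(3))
  expect_equal(giant_component_fraction(two), 0.7)
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(2:50, 1)
    g <- generate_poisson_graph(n, runif(1, 0, 0.2))
    el <- igraph::as_edgelist(g)
    expect_equal(giant_component_fraction(g), oracle_giant_fraction(n, el))
  }
})

test_that("outbreak fixed point r = 1 - exp(-c r) is solved and inverted", {
  expect_equal(solve_outbreak_fraction(1), 0)
  expect_equal(solve_outbreak_fraction(0.5), 0)
  expect_equal(solve_outbreak_fraction(2), 0.7968, tolerance = 1e-4)
  expect_gte(solve_outbreak_fraction(50), 1 - 1e-15)
  expect_error(solve_outbreak_fraction(-1), "c")
  # continuity / monotonicity across the threshold
  cs <- seq(0.5, 3, by = 0.01)
  rs <- vapply(cs, solve_outbreak_fraction, numeric(1))
  expect_true(all(diff(rs) >= 0))
  expect_lt(max(abs(diff(rs))), 0.05)
  # inversion consistency: c = -log(1 - r)/r
  for (cc in c(1.5, 2, 3)) {
    expect_equal(outbreak_mean_degree(solve_outbreak_fraction(cc)), cc,
                 tolerance = 1e-8)
  }
})

test_that("simulated giant component matches the analytic outbreak fraction", {
  g <- generate_poisson_graph(10000, 2 / 9999, seed = 5)
  expect_lt(abs(giant_component_fraction(g) - solve_outbreak_fraction(2)),
            0.02)
})

test_that("connectivity regime classification follows both analytic bounds", {
  expect_equal(connectivity_regime(1000, 0, 0.0005), "subcritical")
  expect_equal(connectivity_regime(1000, 0, 0.005), "supercritical")
  expect_equal(connectivity_regime(1000, 0, 0.008), "connected")
  expect_equal(connectivity_regime(2000, 0.5, 0.0005), "subcritical")
  expect_error(connectivity_regime(2, 0.9, 0.5), "at least 2")
})

test_that("configuration-model percolation margin is <d^2> - 2<d>", {
  expect_equal(config_supercritical_margin(list(mean_deg = 1,
                                                second_moment = 1)), -1)
  expect_equal(config_supercritical_margin(list(mean_deg = 2,
                                                second_moment = 4)), 0)
  expect_equal(config_supercritical_margin(degree_moments(rep(3, 10))), 3)
  g <- generate_configuration_graph(rep(3, 100), seed = 1)
  expect_gt(config_supercritical_margin(degree_moments(g)), 0)
})

test_that("percolation threshold sweep recovers p (1-alpha) n ~ 1", {
  est <- estimate_percolation_threshold(1000, 0, reps = 10, seed = 3)
  expect_gte(est$product, 0.6)
  expect_lte(est$product, 1.4)
  expect_true(all(diff(est$curve$p) > 0))
  expect_warning(
    estimate_percolation_threshold(500, 0, p_grid = c(0.02, 0.03),
                                   reps = 5, seed = 1),
    "above the emergence cutoff")
  expect_error(
    estimate_percolation_threshold(500, 0, p_grid = c(1e-5, 2e-5),
                                   reps = 3, seed = 1),
    "no threshold")
})

test_that("homogeneous mean-field density follows the logistic solution", {
  ts <- seq(0, 20, by = 0.5)
  expect_true(all(meanfield_homogeneous(0.1, 4, 0, ts)$density == 0))
  expect_true(all(meanfield_homogeneous(0, 4, 0.3, ts)$density == 0.3))
  mf <- meanfield_homogeneous(0.1, 4, 0.01, ts)
  num <- deSolve::ode(y = c(i = 0.01), times = ts,
                      func = function(t, y, p) list(0.1 * 4 * y * (1 - y)),
                      parms = NULL, rtol = 1e-12, atol = 1e-12)
  expect_equal(mf$density, unname(num[, "i"]), tolerance = 1e-8)
  expect_error(meanfield_homogeneous(-0.1, 4, 0.5, ts), "lam")
})

test_that("degree-based mean field has the printed relaxation time and early-time closed form", {
  dist <- data.frame(k = c(2, 6), pk = c(0.5, 0.5)) # <k>=4, <k^2>=20
  p <- meanfield_sis_params(0.1, 0.01, dist)
  expect_equal(p$tau, 12.5)
  mf <- meanfield_degree_based(p, seq(0, 0.1 * p$tau, length.out = 6))
  expect_equal(unname(mf$closed_form[1, ]), c(0.01, 0.01))
  rel <- abs(mf$closed_form - mf$ode) / mf$closed_form
  expect_lt(max(rel), 0.05)
  expect_error(meanfield_sis_params(0.1, 0.01,
                                    data.frame(k = 1, pk = 1)),
               "k\\^2")
})

test_that("network contagion respects immunity, monotonicity and determinism", {
  g <- generate_poisson_graph(300, 0.02, seed = 9)
  none <- simulate_network_contagion(g, 0.5, 0, initial_adopters = integer(0),
                                     n_steps = 5, seed = 1)
  expect_true(all(none$adopted == 0))
  full <- simulate_network_contagion(igraph::make_full_graph(30), 1, 0,
                                     immune = 2:4, initial_adopters = 1,
                                     n_steps = 2, seed = 1)
  expect_equal(full$adopted[full$step == 1], 27)
  expect_equal(full$adopted[full$step == 2], 27) # immune never adopt
  tr <- simulate_network_contagion(g, 0.2, 0.01, immune = 1:30,
                                   initial_adopters = 31:33,
                                   n_steps = 20, seed = 4, reps = 5)
  for (r in 1:5)
    expect_true(all(diff(tr$adopted[tr$rep == r]) >= 0))
  tr2 <- simulate_network_contagion(g, 0.2, 0.01, immune = 1:30,
                                    initial_adopters = 31:33,
                                    n_steps = 20, seed = 4, reps = 5)
  expect_identical(tr, tr2)
  expect_error(simulate_network_contagion(g, 0.5, immune = 1:5,
                                          initial_adopters = 5,
                                          n_steps = 3),
               "immune")
})

test_that("immune nodes cap the reachable population", {
  g <- igraph::make_full_graph(40)
  tr <- simulate_network_contagion(g, 1, 0.5, immune = 1:10,
                                   initial_adopters = 11,
                                   n_steps = 10, seed = 2)
  expect_lte(max(tr$adopted), 30)
})

test_that("a denser network does not slow the spread", {
  seed_nodes <- 1:3
  median_t50 <- function(p) {
    g <- generate_poisson_graph(400, p, seed = 21)
    tr <- simulate_network_contagion(g, 0.3, 0,
                                     initial_adopters = seed_nodes,
                                     n_steps = 60, seed = 22, reps = 11)
    t50 <- vapply(1:11, function(r) {
      x <- tr[tr$rep == r, ]
      hit <- which(x$adopted >= 200)
      if (length(hit) == 0) Inf else x$step[hit[1]]
    }, numeric(1))
    median(t50)
  }
  expect_lte(median_t50(0.03), median_t50(0.01))
})

test_that("heterogeneous behavioral degree gates who spreads", {
  g <- igraph::make_full_graph(20)
  bd <- rep(0, 20); bd[1] <- 0 # seed refuses to diffuse
  tr <- simulate_network_contagion(g, 1, 0, initial_adopters = 1,
                                   n_steps = 3, seed = 1,
                                   behavioral_degree = bd)
  expect_true(all(tr$adopted == 1))
})
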