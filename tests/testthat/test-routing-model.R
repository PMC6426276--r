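# A 5-node graph where node 4 has two neighbors at unit edge distance whose
# geodesic distances to the target differ by 2, giving the closed-form
# two-way split 1 / (1 + e^-2) at lambda = 1.
two_route_network <- function() {
  w <- matrix(0, 4, 4)
  w[4, 2] <- w[2, 4] <- exp(-1)   # i -- j, d = 1
  w[4, 3] <- w[3, 4] <- exp(-1)   # i -- k, d = 1
  w[2, 1] <- w[1, 2] <- exp(-1)   # j -- t, d = 1  => g_jt = 1
  w[3, 1] <- w[1, 3] <- exp(-2.5) # k -- t, d = 2.5 => g_kt = 2.5
  weighted_network(w, normalize = FALSE)
}

test_that("unbiased rows are proportional to weights and target-independent", {
  net <- canonical_graph("toy_fig1")
  dg <- geodesic_distances(weights_to_distances(net))
  s <- build_strategy(net, dg, 0, 6)
  expect_identical(s$trans, reference_strategy(net, 6)$trans)
  for (i in 1:5)
    expect_equal(s$trans[i, ], net$norm_weights[i, ] / net$strengths[i])
  # two neighbors at normalized weights .6 / .3 split 2/3 vs 1/3
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.6
  w[1, 3] <- w[3, 1] <- 0.3
  w[2, 3] <- w[3, 2] <- 0.3
  net2 <- weighted_network(w, normalize = FALSE)
  dg2 <- geodesic_distances(weights_to_distances(net2))
  s2 <- build_strategy(net2, dg2, 0, 3)
  expect_equal(s2$trans[1, 2], 2 / 3)
  expect_equal(s2$trans[1, 3], 1 / 3)
  # absorbing row differs between targets, other rows coincide
  sA <- reference_strategy(net, 1)
  sB <- reference_strategy(net, 2)
  expect_equal(sA$trans[3:6, ], sB$trans[3:6, ])
})

test_that("finite-bias split matches the closed form at lambda = 1", {
  net <- two_route_network()
  dg <- geodesic_distances(weights_to_distances(net))
  s <- build_strategy(net, dg, 1, 1)
  # exponents -(1*(1+1)+1) vs -(1*(1+2.5)+1): split 1/(1 + e^-1.5)
  expect_equal(s$trans[4, 2], 1 / (1 + exp(-1.5)), tolerance = 1e-12)
  expect_equal(s$trans[4, 3], 1 - 1 / (1 + exp(-1.5)), tolerance = 1e-12)
})

test_that("strategies are row-stochastic with support exactly on edges", {
  nets <- list(canonical_graph("toy_fig1"),
               random_connected_network(10, 0.35, 21))
  for (net in nets) {
    dg <- geodesic_distances(weights_to_distances(net))
    for (lam in c(0, 0.3, 1, 8, Inf)) {
      for (t in c(1L, net$n_nodes)) {
        s <- build_strategy(net, dg, lam, t)
        expect_row_stochastic(s)
        expect_equal(s$trans[t, t], 1)
        expect_true(all(s$trans[t, -t] == 0))
        if (is.finite(lam)) {
          nonabs <- setdiff(seq_len(net$n_nodes), t)
          expect_identical(unname(s$trans[nonabs, ] > 0),
                           unname(net$norm_weights[nonabs, ] > 0))
        }
      }
    }
  }
  expect_error(build_strategy(nets[[1]],
                              geodesic_distances(weights_to_distances(nets[[1]])),
                              -0.1, 1), "non-negative")
})

test_that("shortest-path limit puts exp(-d) mass on degenerate ties", {
  # two shortest-path neighbors with d = 1 and d = 2: split e^-1 : e^-2
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- exp(-1)   # i--j d=1
  w[1, 3] <- w[3, 1] <- exp(-2)   # i--k d=2
  w[2, 4] <- w[4, 2] <- exp(-2)   # j--t d=2, so g via j = 3
  w[3, 4] <- w[4, 3] <- exp(-1)   # k--t d=1, so g via k = 3 (tie)
  net <- weighted_network(w, normalize = FALSE)
  dg <- geodesic_distances(weights_to_distances(net))
  s <- shortest_path_limit_strategy(net, dg, 4)
  expect_equal(s$trans[1, 2], exp(-1) / (exp(-1) + exp(-2)), tolerance = 1e-12)
  expect_equal(s$trans[1, 3], exp(-2) / (exp(-1) + exp(-2)), tolerance = 1e-12)
  # all-equal distances: uniform over the tie set (even ring)
  ring <- canonical_graph("ring_n", 4)
  dgr <- geodesic_distances(weights_to_distances(ring))
  sr <- shortest_path_limit_strategy(ring, dgr, 3)
  expect_equal(sr$trans[1, c(2, 4)], c(0.5, 0.5))
  # unique shortest path: deterministic steps
  p <- canonical_graph("path_3_unit")
  dgp <- geodesic_distances(weights_to_distances(p))
  sp <- shortest_path_limit_strategy(p, dgp, 3)
  expect_equal(sp$trans[1, 2], 1)
  expect_equal(sp$trans[2, 3], 1)
})

test_that("large finite bias converges to the symbolic limit on gap-separated graphs", {
  for (name in list(c("path_n", 6), c("ring_n", 5), c("star_n", 6))) {
    net <- canonical_graph(name[1], as.integer(name[2]))
    dg <- geodesic_distances(weights_to_distances(net))
    for (t in c(1L, 2L)) {
      a <- build_strategy(net, dg, 50, t)$trans
      b <- shortest_path_limit_strategy(net, dg, t)$trans
      expect_lt(max(abs(a - b)), 1e-6)
    }
  }
  # exact tie: finite lambda already splits evenly by symmetry
  ring <- canonical_graph("ring_n", 4)
  dgr <- geodesic_distances(weights_to_distances(ring))
  a <- build_strategy(ring, dgr, 50, 3)$trans
  b <- shortest_path_limit_strategy(ring, dgr, 3)$trans
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("fundamental matrix reproduces hand values and the enumeration oracle", {
  net <- canonical_graph("path_3_unit")
  dg <- geodesic_distances(weights_to_distances(net))
  ch <- fundamental_matrix(build_strategy(net, dg, 0, 3))
  expect_equal(ch$visits, matrix(c(2, 1, 2, 2), 2), tolerance = 1e-12)
  chI <- fundamental_matrix(shortest_path_limit_strategy(net, dg, 3))
  expect_equal(chI$visits[1, ], c(1, 1))

  # truncated exhaustive expectation over all walks, residual-bounded
  for (cfg in list(list(net = canonical_graph("path_n", 4), lam = 0.5, t = 4L),
                   list(net = random_connected_network(5, 0.6, 31), lam = 1, t = 2L))) {
    dg2 <- geodesic_distances(weights_to_distances(cfg$net))
    s <- build_strategy(cfg$net, dg2, cfg$lam, cfg$t)
    ch2 <- fundamental_matrix(s)
    for (src in setdiff(seq_len(cfg$net$n_nodes), cfg$t)) {
      en <- enum_visits(s$trans, src, cfg$t, max_len = 25)
      analytic <- ch2$visits[match(src, ch2$states), ]
      bound <- en$residual_mass * max(rowSums(ch2$visits))
      expect_true(all(abs(analytic - en$visits) <= bound + 1e-12))
      expect_true(all(en$visits <= analytic + 1e-12))
    }
  }

  # diagonal occupation of at least one visit, non-negativity
  expect_true(all(diag(ch$visits) >= 1))
  expect_true(all(ch$visits >= 0))
})

test_that("singular absorbing systems are reported, not patched", {
  # hybrid support from which the target is unreachable cannot arise on a
  # connected graph; simulate it by corrupting a strategy's support
  net <- canonical_graph("path_n", 3)
  dg <- geodesic_distances(weights_to_distances(net))
  s <- build_strategy(net, dg, 0, 3)
  s$trans[2, ] <- c(1, 0, 0)   # node 2 now always steps away from target
  expect_error(fundamental_matrix(s), "singular|unreachable")
})

test_that("single-walk simulation is deterministic where the strategy is", {
  net <- canonical_graph("path_3_unit")
  dg <- geodesic_distances(weights_to_distances(net))
  sI <- shortest_path_limit_strategy(net, dg, 3)
  for (seed in c(1, 99, 2024)) {
    wk <- simulate_walk(sI, dg, 1, rng_seed = seed)
    expect_equal(wk$nodes, c(1, 2, 3))
    expect_equal(wk$distance, 2)
    expect_false(wk$truncated)
  }
  expect_equal(simulate_walk(sI, dg, 3, 1),
               list(nodes = 3, distance = 0, truncated = FALSE))
  # truncation is flagged, not an error
  s0 <- build_strategy(net, dg, 0, 3)
  wk2 <- simulate_walk(s0, dg, 1, rng_seed = 5, max_steps = 1L)
  expect_true(wk2$truncated)
  # seeded reproducibility, global RNG untouched
  set.seed(777); before <- .Random.seed
  w1 <- simulate_walk(s0, dg, 1, rng_seed = 42)
  w2 <- simulate_walk(s0, dg, 1, rng_seed = 42)
  expect_identical(w1, w2)
  expect_identical(before, .Random.seed)
})

test_that("mean simulated walk distance matches the closed-form value on the path", {
  net <- canonical_graph("path_3_unit")
  dg <- geodesic_distances(weights_to_distances(net))
  s0 <- build_strategy(net, dg, 0, 3)
  mc <- simulate_walks(s0, dg, 1, n_walks = 1e5, rng_seed = 8)
  se <- stats::sd(mc$distance) / sqrt(length(mc$distance))
  expect_lt(abs(mean(mc$distance) - 4), 3 * se)
  expect_false(any(mc$truncated))
})
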