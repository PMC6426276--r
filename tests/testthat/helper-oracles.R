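# Independent oracles used across the suite. These never call the code
# paths they check.

# Brute-force geodesics: minimum edge-distance sum over all simple paths,
# enumerated by depth-first search. Tractable for n <= 9.
brute_geodesic <- function(edge_dist) {
  n <- nrow(edge_dist)
  nb <- lapply(seq_len(n), function(i)
    which(is.finite(edge_dist[i, ]) & seq_len(n) != i))
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  for (s in seq_len(n)) {
    dfs <- function(cur, dist, visited) {
      if (dist < best[s, cur]) best[s, cur] <<- dist
      for (j in nb[[cur]]) {
        if (!visited[j]) {
          visited[j] <- TRUE
          dfs(j, dist + edge_dist[cur, j], visited)
          visited[j] <- FALSE
        }
      }
    }
    v <- logical(n); v[s] <- TRUE
    dfs(s, 0, v)
  }
  best
}

# Truncated exhaustive expectation of visit counts: sums Pr(X_s = k, alive)
# over walk lengths s = 0..max_len. Returns the partial sums and the
# un-absorbed probability mass left after max_len steps, which bounds the
# truncation error via the chain's maximum expected future occupation.
enum_visits <- function(trans, source, target, max_len = 25) {
  n <- nrow(trans)
  states <- setdiff(seq_len(n), target)
  Q <- trans[states, states, drop = FALSE]
  v <- numeric(length(states))
  v[match(source, states)] <- 1
  acc <- v
  for (s in seq_len(max_len)) {
    v <- as.vector(v %*% Q)
    acc <- acc + v
  }
  list(visits = acc, residual_mass = sum(v), states = states)
}

# Deterministic random connected test network with weights already in (0,1).
random_connected_network <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  repeat {
    w <- matrix(0, n, n)
    iu <- which(upper.tri(w))
    on <- runif(length(iu)) < p
    w[iu[on]] <- runif(sum(on), 0.15, 0.85)
    w <- w + t(w)
    net <- try(weighted_network(w, normalize = FALSE), silent = TRUE)
    if (!inherits(net, "try-error")) return(net)
  }
}

expect_row_stochastic <- function(strategy, tol = 1e-12) {
  expect_lt(max(abs(rowSums(strategy$trans) - 1)), tol)
  expect_true(all(strategy$trans >= 0))
}
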