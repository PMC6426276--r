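#' Biased routing strategy toward one target
#'
#' Builds the row-stochastic transition matrix of a walker biased by global
#' topological information. For a walker at node \code{i} heading to target
#' \code{t}, the probability of stepping to neighbor \code{j} is
#' \deqn{P_\lambda(j \mid i, t) \propto
#'   \exp\{-(\lambda (d_{ij} + g_{jt}) + d_{ij})\}}
#' where \code{d_ij} is the edge distance (local information) and
#' \code{d_ij + g_jt} the shortest distance to the target through \code{j}
#' (global information). \code{lambda = 0} recovers the unbiased walk with
#' \code{P(j|i) = w_ij / s_i}; large \code{lambda} concentrates mass on
#' shortest paths. The target row is absorbing. Exponents are shifted by
#' their row maximum before exponentiation so large \code{lambda} cannot
#' underflow a whole row.
#'
#' @param net a \code{weighted_network}.
#' @param dg a \code{distance_graph} with geodesics computed.
#' @param lam non-negative finite bias, or \code{Inf} for the exact
#'   shortest-path limit (dispatches to
#'   \code{\link{shortest_path_limit_strategy}}).
#' @param target target node index.
#' @return a \code{routing_strategy}: list with \code{lam}, \code{target},
#'   \code{trans} (n x n row-stochastic matrix), \code{support}
#'   (logical edge mask of \code{trans}).
#' @export
build_strategy <- function(net, dg, lam, target) {
  stopifnot(inherits(net, "weighted_network"),
            inherits(dg, "distance_graph"))
  if (is.null(dg$geodesic)) stop("geodesics not computed; run geodesic_distances()")
  n <- net$n_nodes
  if (!(target %in% seq_len(n))) stop("invalid target node")
  if (!is.numeric(lam) || length(lam) != 1 || is.na(lam) || lam < 0)
    stop("lam must be a single non-negative number")
  if (is.infinite(lam)) return(shortest_path_limit_strategy(net, dg, target))
  if (lam == 0) {
    # exact unbiased-walk identity: exp(-d_ij)/Z = w_ij / s_i
    out <- reference_strategy(net, target)
    return(out)
  }

  d <- dg$edge_dist
  g_t <- dg$geodesic[, target]
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i == target) next
    nb <- which(is.finite(d[i, ]) & seq_len(n) != i)
    ex <- -(lam * (d[i, nb] + g_t[nb]) + d[i, nb])
    ex <- ex - max(ex)                      # log-sum-exp shift
    p <- exp(ex)
    P[i, nb] <- p / sum(p)
  }
  P[target, target] <- 1
  new_routing_strategy(lam, target, P)
}

new_routing_strategy <- function(lam, target, trans) {
  structure(list(lam = lam, target = target, trans = trans,
                 support = trans > 0),
            class = "routing_strategy")
}

#' @export
print.routing_strategy <- function(x, ...) {
  cat(sprintf("routing_strategy: lambda = %s, target = %d, %d nodes\n",
              if (is.infinite(x$lam)) "Inf" else format(x$lam),
              x$target, nrow(x$trans)))
  invisible(x)
}

#' Shortest-path limit strategy (lambda -> Inf)
#'
#' The exact limit of the biased walk: at each node, probability mass is
#' restricted to the set S of neighbors lying on shortest paths to the
#' target; within S, mass is proportional to \code{exp(-d_ij)}, so for a
#' unique shortest path the step is deterministic, and degenerate ties on
#' unweighted-equivalent input split uniformly. Implemented as a distinct
#' symbolic limb, never by plugging a huge lambda into the finite-bias
#' formula.
#'
#' @inheritParams build_strategy
#' @param tol degeneracy tolerance passed to \code{\link{sp_neighbors}}.
#' @return a \code{routing_strategy} with \code{lam = Inf}.
#' @export
shortest_path_limit_strategy <- function(net, dg, target, tol = 1e-9) {
  stopifnot(inherits(net, "weighted_network"),
            inherits(dg, "distance_graph"))
  if (is.null(dg$geodesic)) stop("geodesics not computed; run geodesic_distances()")
  n <- net$n_nodes
  if (!(target %in% seq_len(n))) stop("invalid target node")
  S <- sp_neighbors(dg, target, tol)
  d <- dg$edge_dist
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i == target) next
    s <- S[[i]]
    p <- exp(-d[i, s])
    P[i, s] <- p / sum(p)
  }
  P[target, target] <- 1
  new_routing_strategy(Inf, target, P)
}

#' Reference (unbiased) strategy
#'
#' The zero-bias walk: transition probabilities proportional to normalized
#' edge weights, \code{P(j|i) = w_ij / s_i}, independent of the target
#' except for the absorbing row. This is the null model of navigation
#' against which informational cost is measured.
#'
#' @inheritParams build_strategy
#' @return a \code{routing_strategy} with \code{lam = 0}.
#' @export
reference_strategy <- function(net, target) {
  stopifnot(inherits(net, "weighted_network"))
  n <- net$n_nodes
  if (!(target %in% seq_len(n))) stop("invalid target node")
  P <- net$norm_weights / net$strengths
  P[target, ] <- 0
  P[target, target] <- 1
  new_routing_strategy(0, target, P)
}

#' Fundamental matrix of the absorbing chain
#'
#' With the target absorbing, let Q be the transition matrix restricted to
#' non-absorbing states. The fundamental matrix \code{N = (I - Q)^{-1}}
#' gives in \code{N[i, k]} the expected number of times a walker started at
#' \code{i} occupies \code{k} before absorption. Solved by one dense LU
#' factorization per target (the factorization serves all sources); a
#' singular system signals a support from which the target is unreachable.
#'
#' @param strategy a \code{routing_strategy}.
#' @return an \code{absorbing_chain}: list with \code{target}, \code{states}
#'   (non-absorbing node indices), \code{Q}, and \code{visits} (the
#'   fundamental matrix, rows/cols indexed by \code{states}).
#' @export
fundamental_matrix <- function(strategy) {
  stopifnot(inherits(strategy, "routing_strategy"))
  n <- nrow(strategy$trans)
  t_idx <- strategy$target
  states <- setdiff(seq_len(n), t_idx)
  Q <- strategy$trans[states, states, drop = FALSE]
  visits <- tryCatch(
    solve(diag(length(states)) - Q),
    error = function(e)
      stop("absorption unreachable: (I - Q) is singular, the target ",
           "cannot be reached from some source under this strategy"))
  structure(list(target = t_idx, states = states, Q = Q, visits = visits),
            class = "absorbing_chain")
}

#' Simulate one walk under a strategy
#'
#' Samples a single trajectory from \code{source} until absorption at the
#' target or truncation at \code{max_steps}. The generator is local to the
#' call and fully determined by \code{rng_seed}; global RNG state is left
#' untouched.
#'
#' @param strategy a \code{routing_strategy}.
#' @param dg a \code{distance_graph} (for edge distances travelled).
#' @param source starting node.
#' @param rng_seed integer seed.
#' @param max_steps step budget.
#' @return list with \code{nodes} (visited sequence, starting at source),
#'   \code{distance} (total edge distance travelled), \code{truncated}.
#' @export
simulate_walk <- function(strategy, dg, source, rng_seed, max_steps = 10000L) {
  stopifnot(inherits(strategy, "routing_strategy"), max_steps > 0)
  n <- nrow(strategy$trans)
  if (!(source %in% seq_len(n))) stop("invalid source node")
  if (source == strategy$target)
    return(list(nodes = source, distance = 0, truncated = FALSE))
  rng <- local_rng(rng_seed)
  P <- strategy$trans
  d <- dg$edge_dist
  nodes <- integer(max_steps + 1L)
  nodes[1L] <- source
  total <- 0
  cur <- source
  for (s in seq_len(max_steps)) {
    nxt <- rng$sample_prob(n, P[cur, ])
    total <- total + d[cur, nxt]
    nodes[s + 1L] <- nxt
    cur <- nxt
    if (cur == strategy$target)
      return(list(nodes = nodes[seq_len(s + 1L)], distance = total,
                  truncated = FALSE))
  }
  list(nodes = nodes, distance = total, truncated = TRUE)
}

#' Simulate many walks from one source (vectorized)
#'
#' Monte-Carlo companion to \code{\link{fundamental_matrix}}: runs
#' \code{n_walks} independent walkers simultaneously and tallies per-walk
#' total distance and per-walk visit counts of every non-target node. Used
#' as the stochastic oracle for analytic visit counts and mean walk lengths.
#'
#' @inheritParams simulate_walk
#' @param n_walks number of walkers.
#' @return list with \code{distance} (numeric n_walks), \code{visits}
#'   (n_walks x n matrix of occupation counts including the start),
#'   \code{truncated} (logical n_walks).
#' @export
simulate_walks <- function(strategy, dg, source, n_walks, rng_seed,
                           max_steps = 100000L) {
  stopifnot(inherits(strategy, "routing_strategy"))
  n <- nrow(strategy$trans)
  tgt <- strategy$target
  rng <- local_rng(rng_seed)
  P <- strategy$trans
  d <- dg$edge_dist
  cur <- rep.int(source, n_walks)
  dist <- numeric(n_walks)
  visits <- matrix(0, n_walks, n)
  alive <- which(cur != tgt)
  if (length(alive) > 0) visits[cbind(alive, source)] <- 1
  step <- 0L
  while (length(alive) > 0 && step < max_steps) {
    step <- step + 1L
    cur_alive <- cur[alive]
    nxt <- integer(length(alive))
    for (i in unique(cur_alive)) {
      at_i <- which(cur_alive == i)
      nxt[at_i] <- rng$sample_prob_n(n, P[i, ], length(at_i))
    }
    dist[alive] <- dist[alive] + d[cbind(cur_alive, nxt)]
    cur[alive] <- nxt
    landed <- nxt != tgt
    if (any(landed))
      visits[cbind(alive[landed], nxt[landed])] <-
        visits[cbind(alive[landed], nxt[landed])] + 1
    alive <- alive[landed]
  }
  list(distance = dist, visits = visits, truncated = cur != tgt)
}

# Self-contained Mersenne-Twister stream: seeds a private copy of R's RNG,
# restoring global state on exit of each draw.
local_rng <- function(seed) {
  state <- NULL
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    if (is.null(state)) set.seed(seed) else assign(".Random.seed", state, globalenv())
    on.exit({
      state <<- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    f()
  }
  list(
    sample_prob = function(n, prob)
      with_state(function() sample.int(n, 1L, prob = prob)),
    sample_prob_n = function(n, prob, k)
      with_state(function() sample.int(n, k, replace = TRUE, prob = prob)),
    runif_n = function(k) with_state(function() stats::runif(k))
  )
}
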