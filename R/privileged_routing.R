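#' Rank nodes by centrality
#'
#' Orders nodes (descending) by one of the centralities used to pick
#' privileged nodes: \code{betweenness} (shortest-path betweenness on edge
#' distances), \code{strength} (sum of normalized weights),
#' \code{sp_closeness} (inverse mean geodesic distance to all other nodes),
#' \code{rw_closeness} (inverse mean first-passage time, in steps, of the
#' unbiased walk into the node: target closeness under the reference
#' strategy), or \code{random}. Ties are broken by ascending node index;
#' random ranking is a seeded permutation.
#'
#' @param net a \code{weighted_network}.
#' @param dg a \code{distance_graph} with geodesics.
#' @param method one of \code{"betweenness"}, \code{"strength"},
#'   \code{"sp_closeness"}, \code{"rw_closeness"}, \code{"random"}.
#' @param rng_seed seed (random method only).
#' @return integer vector of node indices, most central first.
#' @export
rank_nodes <- function(net, dg, method, rng_seed = 1L) {
  stopifnot(inherits(net, "weighted_network"))
  n <- net$n_nodes
  score <- switch(method,
    betweenness = {
      d <- dg$edge_dist
      ij <- which(upper.tri(d) & is.finite(d), arr.ind = TRUE)
      g <- igraph::graph_from_edgelist(ij, directed = FALSE)
      g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
      igraph::betweenness(g, weights = d[ij])
    },
    strength = net$strengths,
    sp_closeness = {
      if (is.null(dg$geodesic)) stop("geodesics not computed")
      1 / (rowSums(dg$geodesic) / (n - 1))
    },
    rw_closeness = {
      mfpt_in <- vapply(seq_len(n), function(t) {
        chain <- fundamental_matrix(reference_strategy(net, t))
        mean(rowSums(chain$visits))     # steps from each source into t
      }, numeric(1))
      1 / mfpt_in
    },
    random = NULL,
    stop("unknown ranking method: ", method)
  )
  if (method == "random") {
    rng <- local_rng(rng_seed)
    return(order(rng$runif_n(n)))
  }
  order(-score, seq_len(n))
}

#' Select a privileged node set
#'
#' The top \code{round(fraction * N)} nodes of a centrality ranking.
#'
#' @inheritParams rank_nodes
#' @param fraction of nodes to privilege, in [0, 1].
#' @return a \code{privileged_set}: list with \code{members} (integer
#'   indices), \code{ranking}, \code{fraction}, \code{rng_seed}.
#' @export
privileged_set <- function(net, dg, method, fraction, rng_seed = 1L) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  k <- round(fraction * net$n_nodes)
  members <- if (k == 0) integer(0)
             else rank_nodes(net, dg, method, rng_seed)[seq_len(k)]
  structure(list(members = sort(members), ranking = method,
                 fraction = fraction, rng_seed = rng_seed),
            class = "privileged_set")
}

#' Hybrid routing strategy: bias only privileged nodes
#'
#' Rows of privileged nodes follow the biased model at the given lambda
#' (the exact shortest-path limit at \code{lam = Inf}); rows of all other
#' nodes remain the unbiased reference walk. The target row is absorbing
#' regardless.
#'
#' @inheritParams build_strategy
#' @param privileged a \code{privileged_set} (or integer vector of node
#'   indices).
#' @return a \code{routing_strategy} (with a \code{privileged} attribute).
#' @export
hybrid_strategy <- function(net, dg, privileged, lam, target) {
  members <- if (inherits(privileged, "privileged_set")) privileged$members
             else as.integer(privileged)
  biased <- build_strategy(net, dg, lam, target)
  ref <- reference_strategy(net, target)
  P <- ref$trans
  rows <- setdiff(members, target)
  P[rows, ] <- biased$trans[rows, , drop = FALSE]
  out <- new_routing_strategy(lam, target, P)
  attr(out, "privileged") <- members
  out
}

#' Walk stretch of partially informed routing
#'
#' How much longer walks get when only privileged nodes are informed: for
#' each source i, the mean over targets t of
#' \code{|C_hybrid(i,t) - g(i,t)|}, where C_hybrid is the expected walk
#' length under the hybrid strategy (default at the shortest-path limit for
#' the privileged rows) and g the geodesic — the fully informed walk length.
#' With every node privileged the stretch is identically zero.
#'
#' @inheritParams hybrid_strategy
#' @param lam bias applied to privileged rows (default \code{Inf}).
#' @return a \code{stretch_result}: list with \code{per_node_stretch},
#'   \code{summary} (median and quartiles), and the hybrid pairwise cost
#'   matrix \code{trans_cost}.
#' @export
node_stretch <- function(net, dg, privileged, lam = Inf) {
  stopifnot(inherits(net, "weighted_network"))
  if (is.null(dg$geodesic)) dg <- geodesic_distances(dg)
  n <- net$n_nodes
  C <- matrix(0, n, n)
  for (t in seq_len(n)) {
    strat <- hybrid_strategy(net, dg, privileged, lam, t)
    chain <- fundamental_matrix(strat)
    C[, t] <- pairwise_transmission_cost(chain, strat, dg)
  }
  per_node <- rowMeans(abs(C - dg$geodesic))
  structure(list(
    per_node_stretch = per_node,
    summary = stats::quantile(per_node, c(0.25, 0.5, 0.75), names = FALSE),
    trans_cost = C
  ), class = "stretch_result")
}

#' Cost curves under privileged-node routing
#'
#' Same contract as \code{\link{cost_curves}} with the hybrid strategy
#' substituted: only privileged rows are biased, so non-privileged nodes
#' contribute exactly zero informational cost.
#'
#' @inheritParams cost_curves
#' @param privileged a \code{privileged_set} (or integer vector).
#' @return a \code{cost_profile}.
#' @export
privileged_cost_curves <- function(net, dg = NULL,
                                   privileged,
                                   lam_grid = default_lambda_grid()) {
  cost_curves(net, dg, lam_grid,
              strategy_fun = function(net, dg, lam, target)
                hybrid_strategy(net, dg, privileged, lam, target))
}
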