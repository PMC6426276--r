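#' Immediate transmission cost at a node
#'
#' The expected edge distance a walker at \code{node} travels on its next
#' step: \code{sum_j P(j | node, t) d_node,j}. Zero at the target.
#'
#' @param strategy a \code{routing_strategy}.
#' @param dg a \code{distance_graph}.
#' @param node node index.
#' @return non-negative scalar.
#' @export
immediate_transmission_cost <- function(strategy, dg, node) {
  if (node == strategy$target) return(0)
  p <- strategy$trans[node, ]
  on <- p > 0
  sum(p[on] * dg$edge_dist[node, on])
}

# vector of immediate costs for all nodes (0 at the target)
immediate_costs_all <- function(strategy, dg) {
  P <- strategy$trans
  d <- dg$edge_dist
  d0 <- d
  d0[!is.finite(d0)] <- 0          # masked by P = 0 off the support
  cc <- rowSums(P * d0)
  cc[strategy$target] <- 0
  cc
}

#' Pairwise transmission cost toward one target
#'
#' The mean walk length from every source to the target: expected visit
#' counts from the fundamental matrix, weighted by each visited node's
#' immediate cost, \code{C(i,t) = sum_k n_t(i,k) c(k,t)}. Equals the
#' geodesic distance in the shortest-path limit.
#'
#' @param chain an \code{absorbing_chain}.
#' @param strategy the \code{routing_strategy} that produced it.
#' @param dg a \code{distance_graph}.
#' @return numeric vector of length n (cost from each source; 0 at target).
#' @export
pairwise_transmission_cost <- function(chain, strategy, dg) {
  stopifnot(chain$target == strategy$target)
  cc <- immediate_costs_all(strategy, dg)[chain$states]
  out <- numeric(nrow(strategy$trans))
  out[chain$states] <- as.vector(chain$visits %*% cc)
  out
}

#' Informational cost at a node (bits)
#'
#' Kullback-Leibler divergence, in bits, between the biased transition row
#' and the unbiased reference row at \code{node}: the extra information
#' needed to reshape the node's outgoing probabilities. Terms with
#' \code{p = 0} contribute 0; mass where the reference has none makes the
#' divergence infinite and is an error (cannot occur when both strategies
#' share the graph's edge support).
#'
#' @param strategy a \code{routing_strategy}.
#' @param reference the reference \code{routing_strategy} (same target).
#' @param node node index.
#' @return non-negative scalar, bits.
#' @export
node_informational_cost <- function(strategy, reference, node) {
  if (node == strategy$target) return(0)
  p <- strategy$trans[node, ]
  q <- reference$trans[node, ]
  on <- p > 0
  if (any(q[on] == 0))
    stop("infinite divergence: strategy places mass outside the ",
         "reference support")
  sum(p[on] * log2(p[on] / q[on]))
}

info_costs_all <- function(strategy, reference) {
  n <- nrow(strategy$trans)
  vapply(seq_len(n), function(i)
    node_informational_cost(strategy, reference, i), numeric(1))
}

#' Pairwise informational cost toward one target
#'
#' Visit-frequency-weighted average of node informational costs along the
#' walk: \code{C(i,t) = sum_k (n(i,k) / sum_r n(i,r)) c_info(k,t)}. The
#' weights sum to one, so this is the mean per-visit divergence (bits).
#'
#' @inheritParams pairwise_transmission_cost
#' @param reference the reference \code{routing_strategy}.
#' @return numeric vector of length n (0 at target).
#' @export
pairwise_informational_cost <- function(chain, strategy, reference) {
  stopifnot(chain$target == strategy$target)
  ci <- info_costs_all(strategy, reference)[chain$states]
  freq <- chain$visits / rowSums(chain$visits)
  out <- numeric(nrow(strategy$trans))
  out[chain$states] <- as.vector(freq %*% ci)
  out
}

#' Nodal source/target averages of a cost matrix
#'
#' Source cost of node i is the row mean over all targets,
#' \code{(1/N) sum_t C(i,t)}; target cost of t is the column mean
#' \code{(1/N) sum_i C(i,t)}. The zero self term is included in the
#' divisor, exactly as the measures are defined.
#'
#' @param cost n x n matrix with sources in rows, targets in columns.
#' @return list with \code{source} and \code{target} numeric vectors.
#' @export
nodal_averages <- function(cost) {
  stopifnot(is.matrix(cost), nrow(cost) == ncol(cost))
  list(source = rowMeans(cost), target = colMeans(cost))
}

#' Default lambda grid
#'
#' 60 points uniform in \code{ln(lambda)} from -6 to 3.2, optionally
#' prefixed with the exact 0 (unbiased walk) and suffixed with \code{Inf}
#' (shortest-path limit).
#'
#' @param n_points grid resolution.
#' @param min_ln,max_ln log-lambda range.
#' @param include_zero,include_inf include the exact endpoints.
#' @return increasing numeric vector.
#' @export
default_lambda_grid <- function(n_points = 60, min_ln = -6, max_ln = 3.2,
                                include_zero = TRUE, include_inf = FALSE) {
  grid <- exp(seq(min_ln, max_ln, length.out = n_points))
  if (include_zero) grid <- c(0, grid)
  if (include_inf) grid <- c(grid, Inf)
  grid
}

#' Cost curves over a lambda grid
#'
#' For every lambda in the grid and every target node, builds the routing
#' strategy and its absorbing chain and fills pairwise transmission and
#' informational cost matrices, nodal source/target averages, and grand
#' means over all ordered pairs i != t (self pairs are zero by definition
#' and excluded from the grand-mean divisor; nodal averages keep the 1/N
#' convention of their defining formulas).
#'
#' @param net a \code{weighted_network}.
#' @param dg a \code{distance_graph} with geodesics (computed here if
#'   missing).
#' @param lam_grid strictly increasing non-negative grid; \code{Inf} allowed
#'   only as the final element.
#' @param strategy_fun function \code{(net, dg, lam, target)} returning a
#'   \code{routing_strategy}; defaults to \code{\link{build_strategy}}.
#'   Substituted by privileged hybrids.
#' @return a \code{cost_profile}: list with \code{lam_grid}, \code{trans}
#'   and \code{info} (n x n x L arrays, sources in rows), nodal average
#'   matrices \code{src_trans}, \code{tgt_trans}, \code{src_info},
#'   \code{tgt_info} (L x n), and \code{mean_trans}, \code{mean_info}
#'   (length L).
#' @export
cost_curves <- function(net, dg = NULL, lam_grid = default_lambda_grid(),
                        strategy_fun = NULL) {
  stopifnot(inherits(net, "weighted_network"))
  if (is.null(dg)) dg <- weights_to_distances(net)
  if (is.null(dg$geodesic)) dg <- geodesic_distances(dg)
  if (any(lam_grid < 0) || is.unsorted(lam_grid, strictly = TRUE))
    stop("lam_grid must be strictly increasing and non-negative")
  if (any(is.infinite(lam_grid[-length(lam_grid)])))
    stop("Inf allowed only as the final grid element")
  if (is.null(strategy_fun))
    strategy_fun <- function(net, dg, lam, target)
      build_strategy(net, dg, lam, target)

  n <- net$n_nodes
  L <- length(lam_grid)
  trans <- array(0, c(n, n, L))
  info <- array(0, c(n, n, L))
  refs <- lapply(seq_len(n), function(t) reference_strategy(net, t))
  for (li in seq_len(L)) {
    lam <- lam_grid[li]
    for (t in seq_len(n)) {
      strat <- strategy_fun(net, dg, lam, t)
      chain <- tryCatch(fundamental_matrix(strat), error = function(e)
        stop(sprintf("routing failed at lambda = %g, target %d: %s",
                     lam, t, conditionMessage(e))))
      trans[, t, li] <- pairwise_transmission_cost(chain, strat, dg)
      info[, t, li] <- pairwise_informational_cost(chain, strat, refs[[t]])
    }
  }
  src_trans <- t(apply(trans, 3, rowMeans))
  tgt_trans <- t(apply(trans, 3, colMeans))
  src_info <- t(apply(info, 3, rowMeans))
  tgt_info <- t(apply(info, 3, colMeans))
  structure(list(
    lam_grid = lam_grid,
    trans = trans, info = info,
    src_trans = src_trans, tgt_trans = tgt_trans,
    src_info = src_info, tgt_info = tgt_info,
    mean_trans = apply(trans, 3, sum) / (n * (n - 1)),
    mean_info = apply(info, 3, sum) / (n * (n - 1)),
    geodesic = dg$geodesic,
    node_labels = net$node_labels
  ), class = "cost_profile")
}

#' @export
print.cost_profile <- function(x, ...) {
  cat(sprintf("cost_profile: %d nodes, %d lambda points (%s ... %s)\n",
              dim(x$trans)[1], length(x$lam_grid),
              format(x$lam_grid[1]), format(x$lam_grid[length(x$lam_grid)])))
  cat(sprintf("  mean trans %.4g -> %.4g, mean info %.4g -> %.4g\n",
              x$mean_trans[1], x$mean_trans[length(x$lam_grid)],
              x$mean_info[1], x$mean_info[length(x$lam_grid)]))
  invisible(x)
}

#' Normalized trade-off curves and their areas
#'
#' The transmission curve is normalized by its value at \code{lambda = 0}
#' (its maximum, the unbiased walk) and the informational curve by its value
#' at the largest finite grid point (its maximum). Areas under the
#' normalized curves are computed by the trapezoid rule over
#' \code{ln(lambda)} between the smallest positive and largest finite grid
#' points; the exact-zero point cannot enter the log-domain integral and
#' serves only for normalization.
#'
#' @param profile a \code{cost_profile} whose grid contains lambda = 0 and
#'   at least two positive finite points.
#' @return a \code{tradeoff_summary}: list with \code{lam_grid},
#'   \code{norm_trans_curve}, \code{norm_info_curve}, \code{auc_trans},
#'   \code{auc_info}.
#' @export
tradeoff_summary <- function(profile) {
  stopifnot(inherits(profile, "cost_profile"))
  grid <- profile$lam_grid
  if (grid[1] != 0)
    stop("grid lacks lambda = 0: transmission curve cannot be normalized")
  finite <- which(is.finite(grid) & grid > 0)
  if (length(finite) < 2)
    stop("grid needs at least two positive finite lambda points")
  max_fin <- finite[length(finite)]
  norm_trans <- profile$mean_trans / profile$mean_trans[grid == 0]
  norm_info <- profile$mean_info / profile$mean_info[max_fin]
  x <- log(grid[finite])
  auc <- function(y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  structure(list(
    lam_grid = grid,
    norm_trans_curve = norm_trans,
    norm_info_curve = norm_info,
    auc_trans = auc(norm_trans[finite]),
    auc_info = auc(norm_info[finite])
  ), class = "tradeoff_summary")
}

#' Export a cost profile as tidy tables
#'
#' @param profile a \code{cost_profile}.
#' @return a data.frame with columns lambda, source, target, trans_cost,
#'   info_cost (one row per ordered pair per lambda).
#' @export
cost_table <- function(profile) {
  stopifnot(inherits(profile, "cost_profile"))
  n <- dim(profile$trans)[1]
  L <- length(profile$lam_grid)
  labels <- profile$node_labels
  data.frame(
    lambda = rep(profile$lam_grid, each = n * n),
    source = rep(rep(labels, times = n), times = L),
    target = rep(rep(labels, each = n), times = L),
    trans_cost = as.vector(profile$trans),
    info_cost = as.vector(profile$info),
    stringsAsFactors = FALSE
  )
}
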