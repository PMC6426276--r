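#' Degree-preserving rewiring of the binary backbone
#'
#' Maslov-Sneppen double-edge swaps on the binarized graph: repeatedly pick
#' two edges {a,b}, {c,d} and replace them with {a,d}, {c,b}, rejecting
#' swaps that create self-loops, multi-edges, or disconnect the graph. The
#' binary degree sequence is exactly preserved. Aims for
#' \code{n_swap_per_edge * E} accepted swaps within a bounded number of
#' attempts; falling short issues a partial-randomization warning.
#'
#' @param net a \code{weighted_network}.
#' @param n_swap_per_edge accepted swaps per edge to aim for.
#' @param rng_seed integer seed.
#' @return list with \code{adj} (logical adjacency), \code{swaps_done},
#'   \code{swaps_target}.
#' @export
rewire_binary <- function(net, n_swap_per_edge = 10L, rng_seed = 1L) {
  stopifnot(inherits(net, "weighted_network"))
  A <- net$norm_weights > 0
  n <- nrow(A)
  edges <- which(upper.tri(A) & A, arr.ind = TRUE)
  E <- nrow(edges)
  target <- n_swap_per_edge * E
  max_attempts <- 50L * target
  rng <- local_rng(rng_seed)
  done <- 0L
  attempts <- 0L
  while (done < target && attempts < max_attempts) {
    attempts <- attempts + 1L
    pick <- floor(rng$runif_n(2L) * E) + 1L
    if (pick[1] == pick[2]) next
    a <- edges[pick[1], 1]; b <- edges[pick[1], 2]
    c_ <- edges[pick[2], 1]; d <- edges[pick[2], 2]
    # randomize orientation of the second edge
    if (rng$runif_n(1L) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
    if (a == c_ || a == d || b == c_ || b == d) next
    if (A[a, d] || A[c_, b]) next
    A[a, b] <- A[b, a] <- FALSE
    A[c_, d] <- A[d, c_] <- FALSE
    A[a, d] <- A[d, a] <- TRUE
    A[c_, b] <- A[b, c_] <- TRUE
    if (!is_connected_adj(A)) {       # reject: restore
      A[a, d] <- A[d, a] <- FALSE
      A[c_, b] <- A[b, c_] <- FALSE
      A[a, b] <- A[b, a] <- TRUE
      A[c_, d] <- A[d, c_] <- TRUE
      next
    }
    edges[pick[1], ] <- sort(c(a, d))
    edges[pick[2], ] <- sort(c(c_, b))
    done <- done + 1L
  }
  if (done < target)
    warning(sprintf("partial randomization: %d of %d swaps achieved",
                    done, target))
  list(adj = A, swaps_done = done, swaps_target = target)
}

#' Default annealing schedule
#'
#' 123 temperature stages starting at t0 = 100, temperature multiplied by
#' 0.125 after each stage (taken literally; the schedule is effectively
#' greedy after roughly ten stages). Proposals per stage default to
#' \code{ceiling(E * log(E))}.
#'
#' @param iterations temperature stages.
#' @param t0 starting temperature.
#' @param cooling geometric cooling factor per stage.
#' @param proposals_per_stage NULL for the E*log(E) default.
#' @return list of schedule parameters.
#' @export
anneal_config <- function(iterations = 123L, t0 = 100, cooling = 0.125,
                          proposals_per_stage = NULL) {
  list(iterations = as.integer(iterations), t0 = t0, cooling = cooling,
       proposals_per_stage = proposals_per_stage)
}

#' Anneal a weight assignment onto a binary graph
#'
#' Assigns the supplied weight multiset to the edges of a binary graph and
#' then minimizes the strength-sequence discrepancy
#' \code{C = sum_i |s_i - r_i|} (s = target strengths, r = current) by
#' randomly permuting weight assignments across edge pairs, accepting
#' energy-increasing moves with Metropolis probability
#' \code{exp(-dC / T)} under the geometric cooling schedule.
#'
#' @param adj logical adjacency of the (connected) binary graph.
#' @param weight_multiset numeric vector, one weight per edge.
#' @param target_strengths numeric vector of strengths to approximate.
#' @param config schedule from \code{\link{anneal_config}}.
#' @param rng_seed integer seed.
#' @return list with \code{weights} (symmetric matrix), \code{energy}
#'   (final C), \code{energy_trace} (per stage).
#' @export
anneal_weights <- function(adj, weight_multiset, target_strengths,
                           config = anneal_config(), rng_seed = 1L) {
  edges <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  E <- nrow(edges)
  if (length(weight_multiset) != E)
    stop("weight multiset size must equal edge count")
  rng <- local_rng(rng_seed)
  # initial random assignment (a shuffle of the multiset onto the edges)
  ord <- order(rng$runif_n(E))
  wvec <- weight_multiset[ord]
  ea <- edges[, 1]; eb <- edges[, 2]
  r <- numeric(nrow(adj))
  for (k in seq_len(E)) {
    r[ea[k]] <- r[ea[k]] + wvec[k]
    r[eb[k]] <- r[eb[k]] + wvec[k]
  }
  dev <- r - target_strengths        # per-node strength deviation
  energy <- sum(abs(dev))
  n_prop <- config$proposals_per_stage
  if (is.null(n_prop)) n_prop <- max(100L, ceiling(E * log(E)))
  temp <- config$t0
  trace <- numeric(config$iterations)
  for (stage in seq_len(config$iterations)) {
    u_pick <- rng$runif_n(2L * n_prop)
    u_acc <- rng$runif_n(n_prop)
    for (p in seq_len(n_prop)) {
      i <- floor(u_pick[2L * p - 1L] * E) + 1L
      j <- floor(u_pick[2L * p] * E) + 1L
      if (i == j) next
      wi <- wvec[i]; wj <- wvec[j]
      if (wi == wj) next
      delta <- wj - wi
      nodes <- c(ea[i], eb[i], ea[j], eb[j])
      sgn <- c(delta, delta, -delta, -delta)
      # two distinct edges share at most one endpoint; a shared endpoint's
      # strength is unchanged by the swap and cancels out
      if (nodes[3] == nodes[1] || nodes[3] == nodes[2]) {
        keep <- c(if (nodes[3] == nodes[1]) 2L else 1L, 4L)
        nodes <- nodes[keep]; sgn <- sgn[keep]
      } else if (nodes[4] == nodes[1] || nodes[4] == nodes[2]) {
        keep <- c(if (nodes[4] == nodes[1]) 2L else 1L, 3L)
        nodes <- nodes[keep]; sgn <- sgn[keep]
      }
      d_new <- dev[nodes] + sgn
      dE <- sum(abs(d_new)) - sum(abs(dev[nodes]))
      if (dE <= 0 || (temp > 0 && u_acc[p] < exp(-dE / temp))) {
        wvec[i] <- wj; wvec[j] <- wi
        dev[nodes] <- d_new
        energy <- energy + dE
      }
    }
    trace[stage] <- energy
    temp <- temp * config$cooling
  }
  W <- matrix(0, nrow(adj), ncol(adj))
  W[cbind(ea, eb)] <- wvec
  W[cbind(eb, ea)] <- wvec
  list(weights = W, energy = sum(abs(dev)), energy_trace = trace)
}

#' Randomize a network preserving degree, weights, and approximate strength
#'
#' The full null-model pipeline: rewire the binary backbone
#' (degree-preserving, connectivity-enforcing), shuffle the empirical weight
#' multiset onto the rewired edges, then anneal the assignment toward the
#' empirical strength sequence. Degree sequence and weight multiset are
#' preserved exactly; strengths approximately (final energy reported).
#'
#' @param net a \code{weighted_network}.
#' @param config annealing schedule (\code{\link{anneal_config}}).
#' @param rng_seed integer seed.
#' @param n_swap_per_edge rewiring effort.
#' @return a \code{weighted_network} (already-normalized weights) with
#'   attributes \code{final_energy} and \code{swaps_done}.
#' @export
randomize_network <- function(net, config = anneal_config(), rng_seed = 1L,
                              n_swap_per_edge = 10L) {
  stopifnot(inherits(net, "weighted_network"))
  rw <- rewire_binary(net, n_swap_per_edge, rng_seed = rng_seed)
  w <- net$norm_weights
  multiset <- w[upper.tri(w) & w > 0]
  ann <- anneal_weights(rw$adj, multiset, net$strengths, config,
                        rng_seed = rng_seed + 1L)
  out <- weighted_network(ann$weights, normalize = FALSE,
                          node_labels = net$node_labels)
  attr(out, "final_energy") <- ann$energy
  attr(out, "swaps_done") <- rw$swaps_done
  out
}

#' Generate a null ensemble
#'
#' @param net a \code{weighted_network}.
#' @param size ensemble size (500 in typical use; smaller for tests).
#' @param seed master seed; member k uses \code{seed + 1000 * k}.
#' @param config annealing schedule.
#' @param n_swap_per_edge rewiring effort.
#' @return a \code{null_ensemble}: list with \code{networks},
#'   \code{final_energies}, \code{seed}, \code{config}.
#' @export
null_ensemble <- function(net, size = 500L, seed = 1L,
                          config = anneal_config(), n_swap_per_edge = 10L) {
  nets <- vector("list", size)
  energies <- numeric(size)
  for (k in seq_len(size)) {
    nets[[k]] <- randomize_network(net, config, rng_seed = seed + 1000L * k,
                                   n_swap_per_edge = n_swap_per_edge)
    energies[k] <- attr(nets[[k]], "final_energy")
  }
  structure(list(networks = nets, final_energies = energies,
                 seed = seed, config = config),
            class = "null_ensemble")
}

#' Normalize empirical costs against a null ensemble
#'
#' Given the empirical cost profile and the profiles of the ensemble
#' members (same lambda grid), computes the normalized curves
#' \code{||C|| = empirical grand mean / mean of ensemble grand means} for
#' transmission and informational cost, and nodal z-scores
#' \code{(empirical - ensemble mean) / ensemble SD} per node, per lambda,
#' for all four nodal measures, with a two-sided significance mask at level
#' \code{alpha}. Nodes with zero ensemble SD get \code{NA} z and are
#' excluded from the mask.
#'
#' @param empirical a \code{cost_profile}.
#' @param ensemble_profiles list of \code{cost_profile} on the same grid.
#' @param alpha two-sided significance level for the z mask.
#' @return list with \code{norm_trans}, \code{norm_info} (per-lambda
#'   curves), \code{z} (list of L x n matrices: src_trans, tgt_trans,
#'   src_info, tgt_info), \code{significant} (same shape, logical),
#'   \code{alpha}.
#' @export
ensemble_costs <- function(empirical, ensemble_profiles, alpha = 0.01) {
  stopifnot(inherits(empirical, "cost_profile"), length(ensemble_profiles) > 0)
  for (p in ensemble_profiles)
    if (!isTRUE(all.equal(p$lam_grid, empirical$lam_grid)))
      stop("all profiles must share the empirical lambda grid")
  ens_mean_trans <- rowMeans(sapply(ensemble_profiles, `[[`, "mean_trans"))
  ens_mean_info <- rowMeans(sapply(ensemble_profiles, `[[`, "mean_info"))
  norm_trans <- empirical$mean_trans / ens_mean_trans
  norm_info <- empirical$mean_info / ens_mean_info

  zcut <- stats::qnorm(1 - alpha / 2)
  zscore <- function(field) {
    stack <- simplify2array(lapply(ensemble_profiles, `[[`, field))  # L x n x K
    mu <- apply(stack, c(1, 2), mean)
    sd <- apply(stack, c(1, 2), stats::sd)
    z <- (empirical[[field]] - mu) / sd
    z[sd == 0] <- NA_real_
    z
  }
  fields <- c("src_trans", "tgt_trans", "src_info", "tgt_info")
  z <- lapply(fields, zscore)
  names(z) <- fields
  sig <- lapply(z, function(m) !is.na(m) & abs(m) > zcut)
  list(norm_trans = norm_trans, norm_info = norm_info,
       z = z, significant = sig, alpha = alpha)
}
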