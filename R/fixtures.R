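#' Canonical toy networks
#'
#' Small graphs with exact, documented edge weights, used throughout the
#' tests and examples:
#' \itemize{
#'   \item \code{"path_n"}: a chain of \code{n} nodes, every edge at
#'     normalized weight \code{exp(-1)} so each edge distance is exactly 1
#'     (\code{"path_3_unit"} is \code{path_n} with n = 3).
#'   \item \code{"ring_n"}: a cycle of \code{n} nodes, unit edge distances.
#'   \item \code{"star_n"}: one hub joined to \code{n - 1} leaves, unit edge
#'     distances.
#'   \item \code{"toy_fig1"}: a 6-node weighted illustration graph with a
#'     hub-and-community flavor and heterogeneous weights.
#' }
#'
#' @param name one of \code{"path_n"}, \code{"ring_n"}, \code{"star_n"},
#'   \code{"path_3_unit"}, \code{"toy_fig1"}.
#' @param n node count (for the parameterized names).
#' @return a \code{weighted_network} (weights already normalized).
#' @export
canonical_graph <- function(name, n = 3L) {
  u <- exp(-1)
  w <- switch(name,
    path_3_unit = { n <- 3L; path_adj(3L, u) },
    path_n = path_adj(n, u),
    ring_n = {
      stopifnot(n >= 3)
      w <- path_adj(n, u)
      w[1, n] <- w[n, 1] <- u
      w
    },
    star_n = {
      stopifnot(n >= 2)
      w <- matrix(0, n, n)
      w[1, 2:n] <- w[2:n, 1] <- u
      w
    },
    toy_fig1 = {
      w <- matrix(0, 6, 6)
      edge <- function(i, j, v) w[i, j] <<- w[j, i] <<- v
      edge(1, 2, 0.8); edge(1, 3, 0.3); edge(2, 3, 0.6)
      edge(3, 4, 0.7); edge(4, 5, 0.5); edge(4, 6, 0.4)
      edge(5, 6, 0.6); edge(2, 5, 0.2)
      w
    },
    stop("unknown canonical graph: ", name)
  )
  weighted_network(w, normalize = FALSE)
}

path_adj <- function(n, u) {
  stopifnot(n >= 2)
  w <- matrix(0, n, n)
  idx <- cbind(seq_len(n - 1), seq_len(n - 1) + 1)
  w[idx] <- u
  w[idx[, 2:1, drop = FALSE]] <- u
  w
}

#' Synthetic connectome-like network configuration
#'
#' @param n_nodes node count.
#' @param n_modules number of communities (balanced round-robin
#'   assignment).
#' @param intra_density,inter_density edge probability within / between
#'   modules.
#' @param weight_logmean,weight_logsd meanlog/sdlog of the log-normal edge
#'   distances (weights are \code{exp(-distance)}).
#' @param hub_count number of hub nodes (spread evenly across modules).
#' @param hub_boost multiplier (>= 1) on a hub's connection probability.
#' @param seed integer seed; the draw is fully determined by it.
#' @return a \code{synth_config} list.
#' @export
synth_config <- function(n_nodes = 64L, n_modules = 4L,
                         intra_density = 0.35, inter_density = 0.06,
                         weight_logmean = 0.5, weight_logsd = 0.5,
                         hub_count = 4L, hub_boost = 6,
                         seed = 1L) {
  stopifnot(n_nodes >= 8, n_modules >= 1,
            intra_density > 0, intra_density <= 1,
            inter_density > 0, inter_density <= 1,
            weight_logsd > 0, hub_boost >= 1)
  structure(list(n_nodes = as.integer(n_nodes),
                 n_modules = as.integer(n_modules),
                 intra_density = intra_density,
                 inter_density = inter_density,
                 weight_logmean = weight_logmean,
                 weight_logsd = weight_logsd,
                 hub_count = as.integer(hub_count),
                 hub_boost = hub_boost,
                 seed = as.integer(seed)), class = "synth_config")
}

#' Generate a synthetic connectome-like network
#'
#' Emulates the statistical signature of structural brain networks the
#' routing model is meant for: sparse, community-structured (denser
#' intra-module connectivity), with a few high-degree/high-strength hubs,
#' and edge weights whose distance transform \code{-ln(w)} is log-normal by
#' construction (distances are drawn log-normal and weights set to
#' \code{exp(-distance)}, so weights land in (0,1) automatically).
#' Disconnected draws are regenerated with an incremented sub-seed, up to a
#' bound.
#'
#' @param cfg a \code{synth_config}.
#' @return a \code{weighted_network} (weights already normalized); the hub
#'   indices are attached as attribute \code{"hubs"}.
#' @export
synth_connectome <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  for (attempt in 0:19) {
    net <- try(synth_draw(cfg, cfg$seed + attempt), silent = TRUE)
    if (!inherits(net, "try-error")) return(net)
  }
  stop("failed to draw a connected network in 20 attempts; ",
       "increase densities or node count")
}

synth_draw <- function(cfg, sub_seed) {
  n <- cfg$n_nodes
  rng <- local_rng(sub_seed)
  module <- rep(seq_len(cfg$n_modules), length.out = n)
  # hubs spread evenly across modules: first node of each module, cycling
  hubs <- integer(0)
  if (cfg$hub_count > 0) {
    by_mod <- split(seq_len(n), module)
    hubs <- unlist(lapply(seq_len(cfg$hub_count), function(k) {
      m <- ((k - 1) %% cfg$n_modules) + 1
      by_mod[[m]][ceiling(k / cfg$n_modules)]
    }))
  }
  same <- outer(module, module, "==")
  p <- ifelse(same, cfg$intra_density, cfg$inter_density)
  boost <- rep(1, n)
  boost[hubs] <- cfg$hub_boost
  p <- p * outer(boost, boost, pmax)
  p <- pmin(p, 1)
  iu <- which(upper.tri(p))
  draw <- rng$runif_n(length(iu)) < p[iu]
  A <- matrix(FALSE, n, n)
  A[iu[draw]] <- TRUE
  A <- A | t(A)
  m <- sum(A) / 2
  # log-normal edge distances -> weights exp(-dist) in (0,1)
  z <- stats::qnorm(rng$runif_n(m))
  dist <- exp(cfg$weight_logmean + cfg$weight_logsd * z)
  w <- exp(-dist)
  W <- matrix(0, n, n)
  W[which(upper.tri(W) & A)] <- w
  W <- W + t(W)
  net <- weighted_network(W, normalize = FALSE)   # errors if disconnected
  attr(net, "hubs") <- hubs
  net
}
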