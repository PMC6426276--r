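#' Weighted undirected network
#'
#' Constructs the basic substrate all routing dynamics run on: a symmetric
#' non-negative proximity matrix with zero diagonal, its normalized
#' counterpart with off-diagonal support in (0, 1), and node strengths.
#' Proximity weights express how strongly two nodes are connected (larger =
#' closer); they are mapped to topological edge distances by
#' \code{d = -ln(w)} after normalization, so normalized weights must lie
#' strictly inside the unit interval.
#'
#' @param weights square symmetric numeric matrix of raw proximities
#'   (0 = no edge, diagonal 0).
#' @param epsilon normalization offset in (0, 0.5), or \code{"auto"} to use
#'   the minimum nonzero weight (the default convention). Ignored when
#'   \code{normalize = FALSE}.
#' @param normalize if \code{FALSE}, \code{weights} are taken to be already
#'   normalized (all nonzero entries strictly in (0,1)) and are used as-is;
#'   \code{epsilon} is then recorded as half the minimum entry.
#' @param node_labels optional character vector of node names.
#' @return an object of class \code{weighted_network} with fields
#'   \code{n_nodes}, \code{weights}, \code{norm_weights}, \code{strengths},
#'   \code{epsilon}, \code{node_labels}.
#' @export
weighted_network <- function(weights, epsilon = "auto", normalize = TRUE,
                             node_labels = NULL) {
  weights <- as.matrix(weights)
  validate_adjacency(weights)
  n <- nrow(weights)
  if (is.null(node_labels)) {
    node_labels <- if (!is.null(rownames(weights))) rownames(weights)
                   else as.character(seq_len(n))
  }
  stopifnot(length(node_labels) == n)
  dimnames(weights) <- NULL

  if (normalize) {
    norm_w <- normalize_weights(weights, epsilon)
    eps <- attr(norm_w, "epsilon")
    attr(norm_w, "epsilon") <- NULL
  } else {
    nz <- weights[weights > 0]
    if (any(nz >= 1))
      stop("normalize = FALSE requires all nonzero weights strictly in (0,1)")
    norm_w <- weights
    eps <- min(nz) / 2
  }

  net <- structure(list(
    n_nodes = n,
    weights = weights,
    norm_weights = norm_w,
    strengths = rowSums(norm_w),
    epsilon = eps,
    node_labels = node_labels
  ), class = "weighted_network")

  if (!is_connected_adj(norm_w))
    stop("network is disconnected: all routing machinery requires that ",
         "every node can be reached from every node")
  net
}

#' @export
print.weighted_network <- function(x, ...) {
  m <- sum(x$norm_weights > 0) / 2
  cat(sprintf(
    "weighted_network: %d nodes, %d edges, epsilon = %.4g\n",
    x$n_nodes, m, x$epsilon))
  cat(sprintf("  normalized weights in [%.4g, %.4g], mean strength %.4g\n",
              min(x$norm_weights[x$norm_weights > 0]),
              max(x$norm_weights), mean(x$strengths)))
  invisible(x)
}

validate_adjacency <- function(w) {
  if (!is.numeric(w) || nrow(w) != ncol(w))
    stop("adjacency must be a square numeric matrix")
  if (any(!is.finite(w))) stop("adjacency contains non-finite entries")
  if (any(w < 0)) stop("negative weights are not allowed")
  if (any(diag(w) != 0)) stop("diagonal (self-loops) must be zero")
  if (!isTRUE(all.equal(w, t(w), tolerance = 1e-8, check.attributes = FALSE)))
    stop("adjacency is not symmetric (relative tolerance 1e-8)")
  if (sum(w > 0) == 0) stop("network has no edges")
  invisible(TRUE)
}

# connectivity over the nonzero support, simple BFS
is_connected_adj <- function(w) {
  n <- nrow(w)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue) > 0) {
    i <- queue[1L]; queue <- queue[-1L]
    nb <- which(w[i, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Normalize proximity weights onto (0, 1)
#'
#' Applies the unique affine map sending the minimum nonzero weight to
#' \code{epsilon} and the maximum to \code{1 - epsilon}:
#' \deqn{\bar w = \frac{(1-2\epsilon) w + (2\epsilon-1)\,\mathrm{MIN}}
#'   {\mathrm{MAX}-\mathrm{MIN}} + \epsilon}
#' Zeros (non-edges) stay zero and the rank order of edge weights is
#' preserved. Keeping weights strictly inside (0,1) guarantees strictly
#' positive, finite edge distances under \code{d = -ln(w)}.
#'
#' @param raw symmetric non-negative matrix with zero diagonal.
#' @param epsilon offset in (0, 0.5) or \code{"auto"} (= MIN of nonzero
#'   weights).
#' @return matrix of normalized weights; attribute \code{"epsilon"} records
#'   the offset used.
#' @export
normalize_weights <- function(raw, epsilon = "auto") {
  validate_adjacency(raw)
  nz <- raw > 0
  w_min <- min(raw[nz])
  w_max <- max(raw[nz])
  if (w_max == w_min)
    stop("degenerate weight range: all nonzero weights are equal, ",
         "the affine normalization is undefined")
  if (identical(epsilon, "auto")) epsilon <- w_min
  if (!is.numeric(epsilon) || length(epsilon) != 1 ||
      epsilon <= 0 || epsilon >= 0.5)
    stop("epsilon must be a single number in (0, 0.5)")
  out <- raw
  out[nz] <- ((1 - 2 * epsilon) * raw[nz] + (2 * epsilon - 1) * w_min) /
    (w_max - w_min) + epsilon
  attr(out, "epsilon") <- epsilon
  out
}

#' Map normalized proximities to edge distances
#'
#' Edge distances are \code{d_ij = -ln(w_ij)} on the edge support; absent
#' edges are marked unreachable (\code{Inf}). The natural log is forced by
#' the unbiased-walk identity at zero bias, where transition probabilities
#' reduce to \code{exp(-d_ij) = w_ij} divided by node strength.
#'
#' @param net a \code{weighted_network}.
#' @return a \code{distance_graph} with \code{edge_dist} filled and
#'   \code{geodesic} empty (see \code{\link{geodesic_distances}}).
#' @export
weights_to_distances <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  w <- net$norm_weights
  on_edge <- w > 0
  if (any(w[on_edge] >= 1))
    stop("normalized weights must lie strictly in (0,1) on edges")
  d <- matrix(Inf, net$n_nodes, net$n_nodes)
  d[on_edge] <- -log(w[on_edge])
  diag(d) <- 0
  structure(list(
    edge_dist = d,
    geodesic = NULL,
    n_nodes = net$n_nodes,
    node_labels = net$node_labels
  ), class = "distance_graph")
}

#' All-pairs geodesic distances
#'
#' Fills the \code{geodesic} matrix of a \code{distance_graph} with
#' shortest-path distances over the edge distances (Dijkstra, via igraph).
#' Shortest-path predecessor sets are derived on demand from the optimality
#' condition \code{d_ij + g_jt = g_it} (see \code{\link{sp_neighbors}}).
#'
#' @param dg a \code{distance_graph} from \code{\link{weights_to_distances}}.
#' @return the same object with \code{geodesic} filled.
#' @export
geodesic_distances <- function(dg) {
  stopifnot(inherits(dg, "distance_graph"))
  d <- dg$edge_dist
  n <- dg$n_nodes
  ij <- which(upper.tri(d) & is.finite(d), arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(ij, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  geo <- igraph::distances(g, weights = d[ij], algorithm = "dijkstra")
  if (any(!is.finite(geo))) {
    bad <- which(!is.finite(geo), arr.ind = TRUE)[1, ]
    stop(sprintf("unreachable pair: no path between nodes %d and %d",
                 bad[1], bad[2]))
  }
  dimnames(geo) <- NULL
  dg$geodesic <- geo
  dg
}

#' Shortest-path neighbor sets toward one target
#'
#' For target \code{t}, returns for every node \code{i} the set of neighbors
#' \code{j} lying on some shortest path from \code{i} to \code{t}, i.e.
#' satisfying \code{|d_ij + g_jt - g_it| <= tol * max(1, g_it)}. The
#' tolerance absorbs floating-point error in weighted geodesics and decides
#' degenerate-path ties.
#'
#' @param dg a \code{distance_graph} with geodesics computed.
#' @param target node index.
#' @param tol relative degeneracy tolerance.
#' @return list of integer vectors, one per node (empty at the target).
#' @export
sp_neighbors <- function(dg, target, tol = 1e-9) {
  stopifnot(inherits(dg, "distance_graph"), !is.null(dg$geodesic))
  n <- dg$n_nodes
  d <- dg$edge_dist
  g_t <- dg$geodesic[, target]
  out <- vector("list", n)
  for (i in seq_len(n)) {
    if (i == target) { out[[i]] <- integer(0); next }
    nb <- which(is.finite(d[i, ]) & seq_len(n) != i)
    ok <- abs(d[i, nb] + g_t[nb] - g_t[i]) <= tol * max(1, g_t[i])
    out[[i]] <- nb[ok]
  }
  out
}

#' Read a network from disk
#'
#' Two plain-text formats are supported: \code{"adjacency_csv"}, a dense
#' square CSV (optionally with a header row and first label column), and
#' \code{"edgelist_tsv"}, tab-separated \code{label_a label_b weight} lines,
#' undirected, one per edge. Near-symmetric adjacencies (relative
#' discrepancy below 1e-8) are symmetrized by averaging with a warning;
#' larger asymmetry is an error. Self-loops are stripped with a warning.
#'
#' @param path file path.
#' @param format \code{"adjacency_csv"} or \code{"edgelist_tsv"}.
#' @param ... passed to \code{\link{weighted_network}} (e.g.
#'   \code{normalize}, \code{epsilon}).
#' @return a \code{weighted_network}.
#' @export
read_network <- function(path, format = c("adjacency_csv", "edgelist_tsv"),
                         ...) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "adjacency_csv") {
    first <- strsplit(readLines(path, n = 1L), ",")[[1]]
    has_header <- first[1] == "" ||
      any(is.na(suppressWarnings(as.numeric(first))))
    if (has_header) {
      df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
      w <- as.matrix(df)
      labels <- rownames(w)
    } else {
      w <- as.matrix(utils::read.csv(path, header = FALSE))
      labels <- NULL
    }
    storage.mode(w) <- "double"
    if (nrow(w) != ncol(w)) stop("adjacency is not square")
    if (any(w < 0)) stop("negative weights are not allowed")
    asym <- max(abs(w - t(w))) / max(abs(w), 1e-300)
    if (asym > 1e-8)
      stop(sprintf("adjacency asymmetric beyond tolerance (rel. %.3g)", asym))
    if (asym > 0) {
      warning("near-symmetric adjacency symmetrized by averaging")
      w <- (w + t(w)) / 2
    }
    if (any(diag(w) != 0)) {
      warning("self-loops stripped")
      diag(w) <- 0
    }
    dimnames(w) <- NULL
  } else {
    df <- utils::read.delim(path, header = FALSE,
                            col.names = c("a", "b", "weight"),
                            colClasses = c("character", "character",
                                           "numeric"))
    if (any(df$weight < 0)) stop("negative weights are not allowed")
    loops <- df$a == df$b
    if (any(loops)) {
      warning("self-loops stripped")
      df <- df[!loops, , drop = FALSE]
    }
    labels <- sort(unique(c(df$a, df$b)))
    n <- length(labels)
    w <- matrix(0, n, n)
    ia <- match(df$a, labels)
    ib <- match(df$b, labels)
    w[cbind(ia, ib)] <- df$weight
    w[cbind(ib, ia)] <- df$weight
  }
  weighted_network(w, node_labels = labels, ...)
}

#' Write a network to disk
#'
#' Raw proximity weights are written with 15 significant digits so a
#' write/read round trip reproduces them to at least 12 significant digits.
#'
#' @param net a \code{weighted_network}.
#' @param path output file.
#' @param format \code{"adjacency_csv"} or \code{"edgelist_tsv"}.
#' @export
write_network <- function(net, path,
                          format = c("adjacency_csv", "edgelist_tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "weighted_network"))
  if (format == "adjacency_csv") {
    w <- net$weights
    lines <- c(
      paste(c("", net$node_labels), collapse = ","),
      vapply(seq_len(net$n_nodes), function(i) {
        paste(c(net$node_labels[i],
                formatC(w[i, ], format = "g", digits = 15)),
              collapse = ",")
      }, character(1)))
    writeLines(lines, path)
  } else {
    idx <- which(upper.tri(net$weights) & net$weights > 0, arr.ind = TRUE)
    lines <- sprintf("%s\t%s\t%s",
                     net$node_labels[idx[, 1]],
                     net$node_labels[idx[, 2]],
                     formatC(net$weights[cbind(idx[, 1], idx[, 2])],
                             format = "g", digits = 15))
    writeLines(lines, path)
  }
  invisible(path)
}
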