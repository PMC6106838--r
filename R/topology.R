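#' Weighted degree
#'
#' \eqn{deg_w(v) = \sum_{u \in N(v)} w_{v,u}}, the total reliability mass
#' incident to a node. With all weights at most 1, `weighted_degree(v)` never
#' exceeds the plain degree.
#'
#' @param net a [ppi_network].
#' @param v protein identifier, or `NULL` for all nodes.
#' @return a numeric value, or a named vector over all nodes when `v` is
#'   `NULL`.
#' @export
weighted_degree <- function(net, v = NULL) {
  stopifnot(inherits(net, "ppi_network"))
  if (is.null(v))
    return(vapply(net$adj, sum, numeric(1L)))
  check_node(net, v)
  sum(net$adj[[v]])
}

#' Plain degree
#' @inheritParams weighted_degree
#' @return integer degree(s), the number of direct neighbors.
#' @export
node_degree <- function(net, v = NULL) {
  stopifnot(inherits(net, "ppi_network"))
  if (is.null(v))
    return(vapply(net$adj, length, integer(1L)))
  check_node(net, v)
  length(net$adj[[v]])
}

#' Node betweenness centrality
#'
#' Betweenness on the unweighted topology (hop-count shortest paths):
#' \eqn{B(v) = \sum_{s \ne v \ne t} \delta_{s,t}(v) / \delta_{s,t}} over
#' unordered pairs, unnormalized; pairs in different components contribute
#' zero. Edge weights deliberately play no role here -- betweenness is only
#' ever compared against its own neighborhood average, where any path-metric
#' convention would cancel anyway.
#'
#' @param net a [ppi_network].
#' @return named numeric vector of B(v) over all nodes.
#' @export
node_betweenness <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  g <- as_igraph(net)
  b <- igraph::betweenness(g, directed = FALSE, weights = NA)
  b[net$nodes]
}

#' Local weighted clustering coefficient
#'
#' The weighted density of the neighborhood graph \eqn{GN_v}:
#' \deqn{LWCC_w(v) = \frac{\sum_{i \in V_v} \sum_{j \in N(i) \cap V_v}
#'   w_{i,j}}{|V_v| (|V_v| - 1)}}
#' The numerator counts each induced edge twice (once per endpoint), so the
#' value equals (sum of \eqn{GN_v} edge weights) / (max possible edge count)
#' and lies in \[0, 1\].
#'
#' @param net a [ppi_network].
#' @param v protein identifier with degree at least 1.
#' @return numeric in \[0, 1\].
#' @export
local_clustering <- function(net, v) {
  check_node(net, v)
  nb <- names(net$adj[[v]])
  if (length(nb) == 0L) stop("local clustering undefined for isolated node")
  members <- c(v, nb)
  num <- 0
  for (i in members) {
    w <- net$adj[[i]]
    num <- num + sum(w[names(w) %in% members])
  }
  k <- length(members)
  min(1, num / (k * (k - 1)))
}

#' Neighborhood averages of degree, betweenness and clustering
#'
#' For each node the averages run over \eqn{V_v = \{v\} \cup N(v)} of
#' quantities measured in the full network (not recomputed inside
#' \eqn{GN_v}): `avdeg` averages plain degrees, `avg_betweenness` averages
#' B(u), `avg_lwcc` averages the local weighted clustering coefficient.
#'
#' @name neighborhood-averages
#' @param net a [ppi_network].
#' @param v protein identifier.
#' @param b named betweenness map covering `V_v` (from [node_betweenness]).
#' @param lw named clustering map covering `V_v`.
#' @return numeric average over \eqn{V_v}.
NULL

#' @rdname neighborhood-averages
#' @export
neighborhood_avg_degree <- function(net, v) {
  check_node(net, v)
  members <- c(v, names(net$adj[[v]]))
  mean(vapply(net$adj[members], length, integer(1L)))
}

#' @rdname neighborhood-averages
#' @export
neighborhood_avg_betweenness <- function(net, v, b) {
  check_node(net, v)
  members <- c(v, names(net$adj[[v]]))
  if (!all(members %in% names(b)))
    stop("betweenness map does not cover the neighborhood of ", v)
  mean(b[members])
}

#' @rdname neighborhood-averages
#' @export
neighborhood_avg_lwcc <- function(net, v, lw) {
  check_node(net, v)
  members <- c(v, names(net$adj[[v]]))
  if (!all(members %in% names(lw)))
    stop("clustering map does not cover the neighborhood of ", v)
  mean(lw[members])
}

#' Per-node topology profile
#'
#' Computes, for every node, the statistics driving overlapping-node
#' identification and seed selection: degree, weighted degree, betweenness,
#' local weighted clustering coefficient, and the neighborhood averages of
#' degree, betweenness and clustering.
#'
#' @param net a [ppi_network].
#' @return a data frame with one row per node, columns `node`, `degree`,
#'   `weighted_degree`, `betweenness`, `lwcc`, `avdeg`, `avg_betweenness`,
#'   `avg_lwcc`, ordered by node identifier.
#' @export
node_profiles <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  nodes <- net$nodes
  deg <- node_degree(net)
  wdeg <- weighted_degree(net)
  btw <- node_betweenness(net)
  lw <- vapply(nodes, function(v) local_clustering(net, v), numeric(1L))
  names(lw) <- nodes
  avdeg <- numeric(length(nodes))
  avgb <- numeric(length(nodes))
  avglw <- numeric(length(nodes))
  for (i in seq_along(nodes)) {
    members <- c(nodes[i], names(net$adj[[nodes[i]]]))
    avdeg[i] <- mean(deg[members])
    avgb[i] <- mean(btw[members])
    avglw[i] <- mean(lw[members])
  }
  data.frame(node = nodes, degree = as.integer(deg),
             weighted_degree = as.numeric(wdeg),
             betweenness = as.numeric(btw), lwcc = as.numeric(lw),
             avdeg = avdeg, avg_betweenness = avgb, avg_lwcc = avglw,
             stringsAsFactors = FALSE, row.names = NULL)
}
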