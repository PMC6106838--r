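#' Identify overlapping (hub-bottleneck) nodes
#'
#' A node shared by several complexes shows both a high degree and a high
#' betweenness relative to its neighborhood, because inter-complex shortest
#' paths are funneled through it. A node `v` is flagged as overlapping iff
#' both conditions hold:
#' \deqn{deg(v) \ge Avdeg(GN_v) \quad and \quad B(v) > AvgB(GN_v)}
#' Such nodes are withheld from seeding: growing a cluster from a shared
#' node tends to fuse two complexes into one false prediction.
#'
#' @param net a [ppi_network].
#' @param profiles optional precomputed [node_profiles] table.
#' @return character vector of overlapping node identifiers (sorted).
#' @export
overlapping_nodes <- function(net, profiles = NULL) {
  if (is.null(profiles)) profiles <- node_profiles(net)
  sort(profiles$node[profiles$degree >= profiles$avdeg &
                       profiles$betweenness > profiles$avg_betweenness])
}

#' Select and order seed nodes
#'
#' Non-overlapping nodes qualify as seeds when they look like complex-core
#' members: either locally dense (clustering coefficient at or above its
#' neighborhood average) or a hub-nonbottleneck (betweenness at or below its
#' neighborhood average). At least one of
#' \deqn{LWCC_w(v) \ge AvgLWCC_w(v) \quad or \quad B(v) \le AvgB(GN_v)}
#' must hold. The queue is ordered by descending weighted degree, ties
#' broken by ascending node identifier, so runs are deterministic.
#'
#' @param net a [ppi_network].
#' @param overlapping overlapping-node set; computed via
#'   [overlapping_nodes] when `NULL`.
#' @param profiles optional precomputed [node_profiles] table.
#' @return ordered character vector of seed identifiers (the seed queue Ss).
#' @export
select_seeds <- function(net, overlapping = NULL, profiles = NULL) {
  if (is.null(profiles)) profiles <- node_profiles(net)
  if (is.null(overlapping)) overlapping <- overlapping_nodes(net, profiles)
  ok <- !(profiles$node %in% overlapping) &
    (profiles$lwcc >= profiles$avg_lwcc |
       profiles$betweenness <= profiles$avg_betweenness)
  cand <- profiles[ok, , drop = FALSE]
  cand$node[order(-cand$weighted_degree, cand$node)]
}

#' Classify every node for inspection
#'
#' @param net a [ppi_network].
#' @param profiles optional precomputed [node_profiles] table.
#' @return data frame `node`, `class` with class one of `"overlapping"`,
#'   `"seed"`, `"other"`.
#' @export
classify_nodes <- function(net, profiles = NULL) {
  if (is.null(profiles)) profiles <- node_profiles(net)
  ov <- overlapping_nodes(net, profiles)
  sd <- select_seeds(net, ov, profiles)
  cls <- ifelse(profiles$node %in% ov, "overlapping",
                ifelse(profiles$node %in% sd, "seed", "other"))
  data.frame(node = profiles$node, class = cls, stringsAsFactors = FALSE)
}
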