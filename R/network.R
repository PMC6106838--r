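#' Weighted protein-protein interaction networks
#'
#' A `ppi_network` models a PPI network as an undirected, self-loop-free
#' graph whose edges carry a reliability weight in (0, 1]. Isolated proteins
#' cannot exist by construction (a node only enters the network through an
#' edge). The object stores a canonical edge table (each unordered pair once,
#' endpoints in lexicographic order) and an adjacency list of neighbor
#' weights for fast local queries.
#'
#' @param edges a data frame with columns `from`, `to` and optionally
#'   `weight`; rows lacking a weight receive `default_weight`. Self-loops are
#'   dropped; duplicate pairs collapse to the maximum weight seen.
#' @param default_weight weight assigned to unweighted rows (default 1.0, so
#'   unweighted interactomes run unchanged).
#' @return an object of class `ppi_network` with fields `nodes` (sorted
#'   character vector), `edges` (data frame `from`, `to`, `weight`) and
#'   `adj` (named list: node -> named numeric vector of neighbor weights).
#' @examples
#' net <- ppi_network(data.frame(from = c("A", "B"), to = c("B", "C"),
#'                               weight = c(0.5, 0.7)))
#' network_stats(net)
#' @export
ppi_network <- function(edges, default_weight = 1) {
  if (!is.data.frame(edges) || ncol(edges) < 2)
    stop("`edges` must be a data frame with at least two columns")
  from <- as.character(edges[[1L]])
  to <- as.character(edges[[2L]])
  if (ncol(edges) >= 3L) {
    weight <- as.numeric(edges[[3L]])
    weight[is.na(edges[[3L]])] <- default_weight
  } else {
    weight <- rep(default_weight, length(from))
  }
  if (anyNA(weight) || any(weight <= 0) || any(weight > 1))
    stop("edge weights must lie in (0, 1]")
  keep <- from != to
  from <- from[keep]; to <- to[keep]; weight <- weight[keep]
  if (length(from) == 0L)
    stop("network is empty after removing self-loops")
  a <- pmin(from, to)
  b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  # duplicate pairs collapse to the maximum reliability seen
  w <- tapply(weight, key, max)
  pair <- strsplit(names(w), "\r", fixed = TRUE)
  df <- data.frame(from = vapply(pair, `[`, "", 1L),
                   to = vapply(pair, `[`, "", 2L),
                   weight = as.numeric(w),
                   stringsAsFactors = FALSE)
  new_ppi_network(df)
}

new_ppi_network <- function(edges) {
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$from, edges$to)))
  both <- data.frame(a = c(edges$from, edges$to),
                     b = c(edges$to, edges$from),
                     w = c(edges$weight, edges$weight),
                     stringsAsFactors = FALSE)
  adj <- lapply(split(both[, c("b", "w")], factor(both$a, levels = nodes)),
                function(d) {
                  v <- d$w
                  names(v) <- d$b
                  v[order(names(v))]
                })
  structure(list(nodes = nodes, edges = edges, adj = adj),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d proteins, %d weighted interactions\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a weighted edge list
#'
#' Parses a whitespace- or tab-delimited edge list with columns
#' `protein_a protein_b [weight]`. Lines starting with `#` and blank lines
#' are skipped. Two-column rows are assigned `default_weight`; weights must
#' parse as reals in (0, 1]. Self-loops are dropped and duplicate pairs keep
#' the maximum weight.
#'
#' @param path path to the edge-list file.
#' @param default_weight weight for two-column rows (default 1.0).
#' @return a [ppi_network].
#' @export
read_ppi_network <- function(path, default_weight = 1) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty network file: ", path)
  lineno <- seq_along(lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (length(lines) == 0L) stop("no edges in network file: ", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  nt <- lengths(toks)
  bad <- which(nt < 2L | nt > 3L)
  if (length(bad))
    stop(sprintf("line %d: expected 2 or 3 columns, found %d",
                 lineno[bad[1L]], nt[bad[1L]]))
  from <- vapply(toks, `[`, "", 1L)
  to <- vapply(toks, `[`, "", 2L)
  wtok <- vapply(toks, function(t) if (length(t) >= 3L) t[3L] else NA_character_, "")
  weight <- suppressWarnings(as.numeric(wtok))
  badw <- which(!is.na(wtok) & (is.na(weight) | weight <= 0 | weight > 1))
  if (length(badw))
    stop(sprintf("line %d: weight '%s' is not a real in (0, 1]",
                 lineno[badw[1L]], wtok[badw[1L]]))
  weight[is.na(wtok)] <- default_weight
  df <- data.frame(from = from, to = to, weight = weight,
                   stringsAsFactors = FALSE)
  tryCatch(ppi_network(df),
           error = function(e) stop(conditionMessage(e), " (", path, ")",
                                    call. = FALSE))
}

#' Write a network back to an edge list
#'
#' Emits the canonical edge table (`protein_a<TAB>protein_b<TAB>weight`, one
#' unordered pair per line) in the same dialect [read_ppi_network] accepts,
#' so that load/write round-trips reproduce the edge set and weights.
#'
#' @param net a [ppi_network].
#' @param path output path.
#' @export
write_ppi_network <- function(net, path) {
  stopifnot(inherits(net, "ppi_network"))
  writeLines(sprintf("%s\t%s\t%.15g", net$edges$from, net$edges$to,
                     net$edges$weight), path)
  invisible(path)
}

#' Basic network summary statistics
#'
#' @param net a [ppi_network].
#' @return a list with `n_nodes`, `n_edges`, `density`
#'   (2|E| / (|V|(|V|-1))) and `avg_neighbors` (2|E|/|V|).
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  nv <- length(net$nodes)
  ne <- nrow(net$edges)
  if (nv < 2L) stop("density undefined for a network with fewer than 2 nodes")
  list(n_nodes = nv, n_edges = ne,
       density = 2 * ne / (nv * (nv - 1)),
       avg_neighbors = 2 * ne / nv)
}

check_node <- function(net, v) {
  if (!v %in% net$nodes) stop("unknown node: ", v)
  invisible(v)
}

#' Neighbors of a node
#' @param net a [ppi_network].
#' @param v protein identifier.
#' @return character vector of direct neighbors of `v`.
#' @export
neighbors_of <- function(net, v) {
  check_node(net, v)
  names(net$adj[[v]])
}

#' Local neighborhood graph
#'
#' The induced subgraph on a node and its direct neighbors,
#' \eqn{GN_v = (V_v, E_v)} with \eqn{V_v = \{v\} \cup N(v)}. Edges among
#' neighbors of `v` are included even when not incident to `v`.
#'
#' @inheritParams neighbors_of
#' @return a `ppi_network` restricted to \eqn{V_v}, with attributes `center`
#'   and `members` (members are kept even if, degenerately, a neighbor had no
#'   induced edge -- impossible here since all members touch `v`).
#' @export
neighborhood_graph <- function(net, v) {
  check_node(net, v)
  members <- sort(c(v, names(net$adj[[v]])))
  sub <- induced_subnetwork(net, members)
  attr(sub, "center") <- v
  attr(sub, "members") <- members
  sub
}

induced_subnetwork <- function(net, members) {
  e <- net$edges
  keep <- e$from %in% members & e$to %in% members
  new_ppi_network(e[keep, , drop = FALSE])
}

#' Convert to an igraph graph
#'
#' @param net a [ppi_network].
#' @return an undirected `igraph` graph with a `weight` edge attribute.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}
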