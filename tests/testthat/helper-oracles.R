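# Small named networks used across the suite, plus brute-force oracles
# kept deliberately independent of the implementation paths they check.

net_from <- function(from, to, weight = 1) {
  ppi_network(data.frame(from = from, to = to, weight = weight,
                         stringsAsFactors = FALSE))
}

triangle_net <- function(w = 1)
  net_from(c("A", "A", "B"), c("B", "C", "C"), w)

path3_net <- function(w = 1)
  net_from(c("A", "B"), c("B", "C"), w)

star_net <- function(w = 1)  # K_{1,3} centered at "c"
  net_from(rep("c", 3), c("a", "b", "d"), w)

complete_net <- function(n, w = 1) {
  v <- sprintf("n%02d", seq_len(n))
  p <- combn(v, 2)
  net_from(p[1, ], p[2, ], w)
}

cycle_net <- function(n, w = 1) {
  v <- sprintf("n%02d", seq_len(n))
  net_from(v, v[c(2:n, 1)], w)
}

# two triangles sharing the center "c"
bowtie_net <- function(w = 1)
  net_from(c("c", "c", "a", "c", "c", "d"),
           c("a", "b", "b", "d", "e", "e"), w)

random_net <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  v <- sprintf("n%02d", seq_len(n))
  pairs <- combn(v, 2)
  keep <- runif(ncol(pairs)) < p
  if (!any(keep)) keep[sample(length(keep), 1L)] <- TRUE
  net_from(pairs[1, keep], pairs[2, keep],
           round(runif(sum(keep), 0.1, 1), 3))
}

# ---- betweenness oracle: enumerate every shortest path explicitly ----

bfs_dist <- function(adj, s) {
  d <- stats::setNames(rep(Inf, length(adj)), names(adj))
  d[s] <- 0
  q <- s
  while (length(q)) {
    v <- q[1L]; q <- q[-1L]
    for (u in adj[[v]]) if (!is.finite(d[u])) {
      d[u] <- d[v] + 1
      q <- c(q, u)
    }
  }
  d
}

enumerate_shortest_paths <- function(adj, d_from_s, t) {
  # walk back from t along strictly decreasing BFS distance
  walk <- function(v) {
    if (d_from_s[v] == 0) return(list(v))
    preds <- adj[[v]][d_from_s[adj[[v]]] == d_from_s[v] - 1]
    unlist(lapply(preds, function(p)
      lapply(walk(p), function(pp) c(pp, v))), recursive = FALSE)
  }
  walk(t)
}

brute_betweenness <- function(net) {
  adj <- lapply(net$adj, names)
  nodes <- net$nodes
  b <- stats::setNames(rep(0, length(nodes)), nodes)
  for (i in seq_along(nodes)) {
    d <- bfs_dist(adj, nodes[i])
    for (j in seq_along(nodes)) {
      if (j <= i || !is.finite(d[nodes[j]])) next
      paths <- enumerate_shortest_paths(adj, d, nodes[j])
      for (pth in paths) {
        interior <- pth[-c(1L, length(pth))]
        b[interior] <- b[interior] + 1 / length(paths)
      }
    }
  }
  b
}

# ---- maximum-weight matching oracle: exhaustive assignment search ----

brute_mmr <- function(ref, pred, threshold = 0.25) {
  os <- matrix(0, length(ref), length(pred))
  for (i in seq_along(ref))
    for (j in seq_along(pred))
      os[i, j] <- overlap_score(ref[[i]], pred[[j]])
  os[os <= threshold] <- 0
  best <- function(i, used) {
    if (i > nrow(os)) return(0)
    top <- best(i + 1L, used)  # leave reference i unmatched
    for (j in seq_len(ncol(os))) {
      if (!used[j] && os[i, j] > 0) {
        used[j] <- TRUE
        top <- max(top, os[i, j] + best(i + 1L, used))
        used[j] <- FALSE
      }
    }
    top
  }
  best(1L, rep(FALSE, ncol(os))) / length(ref)
}

# ---- merge oracle at omega = 1: plain dedupe + size filter ----

naive_dedupe <- function(sets, min_size = 3) {
  canon <- vapply(lapply(sets, function(s) sort(unique(s))),
                  paste, "", collapse = "\r")
  sets <- lapply(sets[!duplicated(canon)], function(s) sort(unique(s)))
  Filter(function(s) length(s) >= min_size, sets)
}

random_catalog <- function(n, universe, min_size = 3, max_size = 6) {
  complex_catalog(lapply(seq_len(n), function(i)
    sample(universe, sample(min_size:max_size, 1L))))
}
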