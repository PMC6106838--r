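#' Support of a border node for a cluster
#'
#' The fraction of a node's total incident weight that lands inside the
#' cluster:
#' \deqn{support(u, C_p) = \frac{\sum_{v \in C_p \cap N(u)} w_{u,v}}
#'   {\sum_{v \in N(u)} w_{u,v}}}
#' Support ranks border nodes during greedy growth: core and peripheral
#' proteins score high even when attached by few edges, while overlapping
#' nodes -- whose weight is split across complexes -- score low. The value
#' is 1 exactly when every neighbor of `u` lies in the cluster.
#'
#' @param net a [ppi_network].
#' @param u protein identifier, not a member of `members`.
#' @param members character vector of cluster members.
#' @return numeric in \[0, 1\].
#' @export
support_score <- function(net, u, members) {
  check_node(net, u)
  if (u %in% members) stop("support is undefined for a cluster member: ", u)
  w <- net$adj[[u]]
  sum(w[names(w) %in% members]) / sum(w)
}

#' Internal and boundary weight of a member set
#'
#' `weight_in` sums each edge with both endpoints inside exactly once;
#' `weight_out` sums each edge with exactly one endpoint inside.
#'
#' @param net a [ppi_network].
#' @param members character vector of cluster members (may be empty).
#' @return named numeric `c(weight_in =, weight_out =)`.
#' @export
cluster_weights <- function(net, members) {
  stopifnot(inherits(net, "ppi_network"))
  win <- 0
  wout <- 0
  for (v in members) {
    w <- net$adj[[v]]
    inside <- names(w) %in% members
    win <- win + sum(w[inside])
    wout <- wout + sum(w[!inside])
  }
  c(weight_in = win / 2, weight_out = wout)
}

#' Local modularity fitness
#'
#' The noise-corrected local modularity of a member set:
#' \deqn{F(C_p) = \frac{weight_{in}}{(weight_{in} + weight_{out} +
#'   \delta |V_p|)^{\alpha}}}
#' The per-node penalty \eqn{\delta} models the interactions each protein is
#' expected to gain or lose to experimental noise, so low-density but
#' well-separated complexes are not rejected outright. With \eqn{\alpha = 1}
#' and \eqn{\delta = 0} this is the classic ratio of internal to total
#' weight (1 on an isolated clique).
#'
#' @param net a [ppi_network].
#' @param members nonempty character vector of cluster members.
#' @param delta per-node uncertainty correction, \eqn{\delta \ge 0}; see
#'   [default_delta].
#' @param alpha exponent \eqn{\alpha > 0} (default 1).
#' @return numeric fitness in \[0, 1\]; defined as 0 when the denominator
#'   vanishes.
#' @export
local_fitness <- function(net, members, delta, alpha = 1) {
  if (length(members) == 0L) stop("fitness undefined for an empty cluster")
  stopifnot(delta >= 0, alpha > 0)
  cw <- cluster_weights(net, members)
  den <- (cw[["weight_in"]] + cw[["weight_out"]] +
            delta * length(members))^alpha
  if (den == 0) return(0)
  cw[["weight_in"]] / den
}

#' Default noise correction
#'
#' Half of the network's average node degree, \eqn{(2|E|/|V|)/2 = |E|/|V|},
#' reflecting that interactome screens carry noise rates approaching half
#' the reported interactions.
#'
#' @param net a [ppi_network].
#' @return numeric \eqn{\delta}.
#' @export
default_delta <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  if (length(net$nodes) == 0L) stop("empty network")
  nrow(net$edges) / length(net$nodes)
}

#' Grow one cluster from a seed
#'
#' Greedy seed expansion. Starting from `{seed}`, the border set (nodes
#' adjacent to a member, not members) and the support of every border node
#' against the current cluster are recomputed after each acceptance. At
#' every step the maximum-support border node (ties: higher weighted
#' degree, then lexicographic identifier) is tested and accepted iff the
#' fitness does not decrease. Growth stops when the border set is empty or
#' the top candidate fails the fitness test -- unless
#' `fallback_next_best = TRUE`, in which case the remaining border nodes
#' are tried in descending support order before giving up, and growth
#' resumes if any of them is accepted.
#'
#' @param net a [ppi_network].
#' @param seed protein identifier to start from.
#' @param delta noise correction; defaults to [default_delta].
#' @param alpha fitness exponent (default 1).
#' @param fallback_next_best keep trying lower-support border nodes within a
#'   pass after a rejection (default `FALSE`, the strict greedy reading).
#' @return an object of class `grown_cluster`: list with `members` (sorted),
#'   `seed`, `weight_in`, `weight_out`, `fitness`, `delta`, `alpha` and
#'   `trace`, a data frame of every accept/reject decision
#'   (`step`, `node`, `support`, `fitness_before`, `fitness_after`,
#'   `accepted`).
#' @export
grow_cluster <- function(net, seed, delta = default_delta(net), alpha = 1,
                         fallback_next_best = FALSE) {
  check_node(net, seed)
  members <- seed
  f_cur <- local_fitness(net, members, delta, alpha)
  trace <- list()
  step <- 0L
  repeat {
    bn <- setdiff(unique(unlist(lapply(members, function(v)
      names(net$adj[[v]])), use.names = FALSE)), members)
    if (length(bn) == 0L) break
    sup <- vapply(bn, function(u) support_score(net, u, members), numeric(1L))
    wd <- vapply(bn, function(u) sum(net$adj[[u]]), numeric(1L))
    ord <- order(-sup, -wd, bn)
    bn <- bn[ord]
    sup <- sup[ord]
    grew <- FALSE
    for (k in seq_along(bn)) {
      step <- step + 1L
      f_new <- local_fitness(net, c(members, bn[k]), delta, alpha)
      accepted <- f_new >= f_cur
      trace[[length(trace) + 1L]] <-
        data.frame(step = step, node = bn[k], support = sup[k],
                   fitness_before = f_cur, fitness_after = f_new,
                   accepted = accepted, stringsAsFactors = FALSE)
      if (accepted) {
        members <- c(members, bn[k])
        f_cur <- f_new
        grew <- TRUE
        break  # border and supports are recomputed against the new cluster
      }
      if (!fallback_next_best) break
    }
    if (!grew) break
  }
  cw <- cluster_weights(net, members)
  structure(list(members = sort(members), seed = seed,
                 weight_in = cw[["weight_in"]],
                 weight_out = cw[["weight_out"]], fitness = f_cur,
                 delta = delta, alpha = alpha,
                 trace = do.call(rbind, c(trace, list(make.row.names = FALSE)))),
            class = "grown_cluster")
}

#' @export
print.grown_cluster <- function(x, ...) {
  cat(sprintf("grown_cluster from seed '%s': %d members, F = %.4f\n",
              x$seed, length(x$members), x$fitness))
  cat(" ", paste(x$members, collapse = " "), "\n")
  invisible(x)
}

#' Generate candidate clusters from the seed queue
#'
#' Expands every seed exactly once, in queue order. Duplicate clusters are
#' deliberately retained here; [merge_and_filter] resolves them.
#'
#' @param net a [ppi_network].
#' @param seeds ordered seed queue from [select_seeds].
#' @inheritParams grow_cluster
#' @return list of `grown_cluster` objects, one per seed, in queue order.
#' @export
generate_candidates <- function(net, seeds, delta = default_delta(net),
                                alpha = 1, fallback_next_best = FALSE) {
  lapply(seeds, function(s)
    grow_cluster(net, s, delta = delta, alpha = alpha,
                 fallback_next_best = fallback_next_best))
}
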