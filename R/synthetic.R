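#' Worked-example network (22 nodes)
#'
#' A fixed 22-node reconstruction of the core-attachment worked example:
#' nodes 0-9 form a complex (core 0-4, peripherals 5-7, overlapping nodes
#' 8-9) and nodes 10-21 lie outside, partly forming a second dense region
#' that the overlapping nodes 8 and 9 bridge into. Edge weights are 0.2
#' everywhere except among the core, whose pairwise weights are high. The
#' reconstruction pins down every quantity the example prescribes:
#' node 1 has incident weights 0.98, 0.87, 0.87 and three of 0.2 (weighted
#' degree 3.32, all six neighbors inside the complex); node 5 has 9
#' neighbors of which 6 are complex-internal; node 8 has 13 neighbors of
#' which 6 are complex-internal; and greedy growth from seed 0 accepts
#' nodes 1, 2, 3, 4 in order and then rejects node 5 on the fitness test,
#' leaving the core \{0,1,2,3,4\}. The remaining topology (neighbors of
#' nodes 6, 7, 9 and the outside nodes) is one consistent choice among
#' many and is frozen here.
#'
#' @return a [ppi_network] with 22 nodes and 51 edges; node identifiers are
#'   `"0"` ... `"21"`.
#' @seealso [fig2_complex] for the depicted complex membership.
#' @export
fig2_network <- function() {
  e <- function(u, v, w = 0.2) data.frame(from = as.character(u),
                                          to = as.character(v), weight = w,
                                          stringsAsFactors = FALSE)
  edges <- rbind(
    # core clique-minus-one: (1,4) is deliberately absent so node 1 keeps
    # exactly the six incident weights the example prescribes
    e(0, 1, 0.98), e(0, 2, 0.95), e(0, 3, 0.88), e(0, 4, 0.78),
    e(1, 2, 0.87), e(1, 3, 0.87),
    e(2, 3, 0.85), e(2, 4, 0.85), e(3, 4, 0.85),
    # core to attachments / overlapping nodes
    e(0, 5), e(0, 8), e(0, 9),
    e(1, 5), e(1, 8), e(1, 9),
    e(2, 5), e(2, 8),
    e(3, 5), e(3, 9),
    e(4, 6), e(4, 7), e(4, 8),
    # peripherals
    e(5, 6), e(5, 7), e(5, 10), e(5, 11), e(5, 12),
    e(6, 7),
    e(7, 8), e(7, 9),
    e(8, 9),
    # overlapping nodes reach outside the complex
    e(8, 10), e(8, 11), e(8, 13), e(8, 14), e(8, 15), e(8, 16), e(8, 17),
    e(9, 13), e(9, 14), e(9, 15),
    # the outside region: a small dense block plus a chain
    e(13, 14), e(13, 15), e(13, 16), e(14, 15), e(14, 16), e(15, 16),
    e(17, 18), e(18, 19), e(19, 20), e(20, 21))
  ppi_network(edges)
}

#' Membership roles in the worked-example complex
#'
#' @return list with `complex` (nodes 0-9), `core` (0-4), `peripheral`
#'   (5-7) and `overlapping` (8-9), all as character vectors.
#' @export
fig2_complex <- function() {
  list(complex = as.character(0:9),
       core = as.character(0:4),
       peripheral = as.character(5:7),
       overlapping = as.character(8:9))
}

#' Simulate a network with planted core-attachment complexes
#'
#' Generates a weighted PPI network whose ground truth is known: each
#' planted complex is a high-weight core clique plus loosely attached
#' peripheral proteins; a configurable number of two-node overlap modules
#' are shared by exactly two complexes each; background noise edges connect
#' uniform random pairs; and a false-negative process deletes planted edges
#' (skipping any deletion that would isolate a node, so every truth protein
#' stays in the network). All weights are rounded to 3 decimals so edge
#' lists round-trip through text exactly.
#'
#' @param n_complexes number of planted complexes (default 10).
#' @param core_size_range inclusive range of core-clique sizes (default
#'   4-6; minimum 3).
#' @param n_attach_range range of peripheral proteins per complex (default
#'   2-4), each linked to `attach_links_range` (default 2-3) core nodes.
#' @param n_overlap_modules number of two-complex overlap modules (default
#'   3).
#' @param overlap_module_size proteins per module (default 2); must not
#'   exceed the smallest core size.
#' @param core_weight_range,attach_weight_range,background_weight_range
#'   uniform weight ranges for core, attachment and noise edges (defaults
#'   0.7-1.0, 0.3-0.6, 0.1-0.3).
#' @param background_prob probability of a noise edge for each unplanted
#'   node pair (default 0.01).
#' @param deletion_rate probability each planted edge is deleted as a false
#'   negative (default 0.1).
#' @param seed integer RNG seed; identical seeds give identical benchmarks.
#' @return an object of class `planted_benchmark`: list with `network`
#'   (a [ppi_network]), `truth` (a [complex_catalog]) and `params`.
#' @examples
#' bench <- simulate_planted_network(n_complexes = 3, seed = 1)
#' bench$truth
#' @export
simulate_planted_network <- function(n_complexes = 10,
                                     core_size_range = c(4, 6),
                                     n_attach_range = c(2, 4),
                                     attach_links_range = c(2, 3),
                                     n_overlap_modules = 3,
                                     overlap_module_size = 2,
                                     core_weight_range = c(0.7, 1.0),
                                     attach_weight_range = c(0.3, 0.6),
                                     background_prob = 0.01,
                                     background_weight_range = c(0.1, 0.3),
                                     deletion_rate = 0.1,
                                     seed = NULL) {
  if (n_complexes < 1) stop("need at least one complex")
  if (core_size_range[1L] < 3) stop("core size must be at least 3")
  if (n_overlap_modules > 0 && n_complexes < 2)
    stop("overlap modules require at least two complexes")
  if (overlap_module_size >= core_size_range[1L])
    stop("overlap module larger than the smallest core")
  if (deletion_rate < 0 || deletion_rate >= 1)
    stop("deletion_rate must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)

  rint <- function(rng) if (rng[1L] == rng[2L]) rng[1L] else
    sample(rng[1L]:rng[2L], 1L)
  rw <- function(n, rng) round(stats::runif(n, rng[1L], rng[2L]), 3)
  counter <- 0L
  new_ids <- function(n) {
    ids <- sprintf("P%03d", counter + seq_len(n))
    counter <<- counter + n
    ids
  }
  edges <- list()
  add_edge <- function(u, v, w) {
    edges[[length(edges) + 1L]] <<- data.frame(from = u, to = v, weight = w,
                                               stringsAsFactors = FALSE)
  }
  cores <- vector("list", n_complexes)
  members <- vector("list", n_complexes)
  for (k in seq_len(n_complexes)) {
    core <- new_ids(rint(core_size_range))
    cores[[k]] <- core
    pairs <- utils::combn(core, 2L)
    for (j in seq_len(ncol(pairs)))
      add_edge(pairs[1L, j], pairs[2L, j], rw(1L, core_weight_range))
    periph <- new_ids(rint(n_attach_range))
    for (p in periph) {
      links <- sample(core, min(rint(attach_links_range), length(core)))
      for (u in links) add_edge(p, u, rw(1L, attach_weight_range))
    }
    members[[k]] <- c(core, periph)
  }
  # overlap modules: a small protein set shared by exactly two complexes,
  # attached to core nodes on both sides
  if (n_overlap_modules > 0) {
    for (m in seq_len(n_overlap_modules)) {
      pair <- sample(n_complexes, 2L)
      module <- new_ids(overlap_module_size)
      if (length(module) > 1L) {
        mp <- utils::combn(module, 2L)
        for (j in seq_len(ncol(mp)))
          add_edge(mp[1L, j], mp[2L, j], rw(1L, attach_weight_range))
      }
      for (side in pair) {
        core <- cores[[side]]
        for (p in module) {
          links <- sample(core, min(rint(attach_links_range), length(core)))
          for (u in links) add_edge(p, u, rw(1L, attach_weight_range))
        }
        members[[side]] <- c(members[[side]], module)
      }
    }
  }
  planted <- do.call(rbind, edges)
  # false negatives: delete planted edges, skipping any deletion that
  # would leave an endpoint with no remaining edge
  if (deletion_rate > 0) {
    u <- stats::runif(nrow(planted))
    keep <- rep(TRUE, nrow(planted))
    for (r in which(u < deletion_rate)) {
      cand <- keep
      cand[r] <- FALSE
      present <- c(planted$from[cand], planted$to[cand])
      if (all(c(planted$from[r], planted$to[r]) %in% present))
        keep <- cand
    }
    planted <- planted[keep, , drop = FALSE]
  }
  # background noise over unplanted pairs
  all_ids <- sprintf("P%03d", seq_len(counter))
  noise <- NULL
  if (background_prob > 0 && counter >= 2L) {
    pairs <- utils::combn(all_ids, 2L)
    key <- paste(pmin(planted$from, planted$to),
                 pmax(planted$from, planted$to))
    pk <- paste(pairs[1L, ], pairs[2L, ])
    open <- which(!pk %in% key)
    hit <- open[stats::runif(length(open)) < background_prob]
    if (length(hit))
      noise <- data.frame(from = pairs[1L, hit], to = pairs[2L, hit],
                          weight = rw(length(hit), background_weight_range),
                          stringsAsFactors = FALSE)
  }
  net <- ppi_network(rbind(planted, noise))
  truth <- complex_catalog(lapply(members, sort),
                           names = sprintf("complex%d", seq_len(n_complexes)))
  structure(list(network = net, truth = truth,
                 params = list(n_complexes = n_complexes,
                               core_size_range = core_size_range,
                               n_attach_range = n_attach_range,
                               attach_links_range = attach_links_range,
                               n_overlap_modules = n_overlap_modules,
                               overlap_module_size = overlap_module_size,
                               core_weight_range = core_weight_range,
                               attach_weight_range = attach_weight_range,
                               background_prob = background_prob,
                               background_weight_range = background_weight_range,
                               deletion_rate = deletion_rate,
                               seed = seed)),
            class = "planted_benchmark")
}

#' @export
print.planted_benchmark <- function(x, ...) {
  cat(sprintf("planted_benchmark: %d complexes, %d proteins, %d edges\n",
              length(x$truth), length(x$network$nodes),
              nrow(x$network$edges)))
  invisible(x)
}
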