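#' End-to-end overlapping complex detection
#'
#' Runs the full seed-and-extend pipeline on a weighted PPI network:
#' topology profiling, overlapping-node identification, seed-queue
#' construction, greedy cluster growth from every seed, and merge/removal
#' of highly overlapping candidates with the minimum-size filter.
#'
#' @param net a [ppi_network], or a path to an edge-list file.
#' @param delta noise correction \eqn{\delta}; `"auto"` (default) uses
#'   [default_delta], i.e. half the average node degree.
#' @param alpha fitness exponent (default 1).
#' @param omega merge threshold in (0, 1\] (default 1: pure deduplication).
#' @param min_size minimum complex size kept (default 3).
#' @param fallback_next_best see [grow_cluster] (default `FALSE`).
#' @param verbose emit per-stage counts via [message()] (default `FALSE`).
#' @return a [complex_catalog] of predicted complexes, with attributes
#'   `overlapping` (node set), `seeds` (the seed queue), `n_candidates`
#'   and `params`.
#' @examples
#' pred <- detect_complexes(fig2_network())
#' pred
#' @export
detect_complexes <- function(net, delta = "auto", alpha = 1, omega = 1,
                             min_size = 3, fallback_next_best = FALSE,
                             verbose = FALSE) {
  if (is.character(net) && length(net) == 1L) net <- read_ppi_network(net)
  stopifnot(inherits(net, "ppi_network"))
  if (identical(delta, "auto") || is.null(delta)) delta <- default_delta(net)
  stopifnot(is.numeric(delta), delta >= 0)
  say <- function(...) if (verbose) message(sprintf(...))
  say("network: %d nodes, %d edges", length(net$nodes), nrow(net$edges))
  profiles <- node_profiles(net)
  ov <- overlapping_nodes(net, profiles)
  say("overlapping nodes: %d", length(ov))
  seeds <- select_seeds(net, ov, profiles)
  say("seed queue: %d", length(seeds))
  if (length(seeds) == 0L)
    warning("no seeds selected; returning an empty prediction set")
  cands <- generate_candidates(net, seeds, delta = delta, alpha = alpha,
                               fallback_next_best = fallback_next_best)
  say("candidate clusters: %d", length(cands))
  out <- merge_and_filter(cands, omega = omega, min_size = min_size)
  say("final complexes: %d", length(out))
  attr(out, "overlapping") <- ov
  attr(out, "seeds") <- seeds
  attr(out, "n_candidates") <- length(cands)
  attr(out, "params") <- list(delta = delta, alpha = alpha, omega = omega,
                              min_size = min_size,
                              fallback_next_best = fallback_next_best)
  out
}

#' Evaluate prediction and reference files
#'
#' Reads both catalogs (reference filtered to complexes with at least 3
#' members, the field convention for CYC2008/NewMIPS-style gold standards)
#' and computes the full evaluation report.
#'
#' @param pred a [complex_catalog] or path to a predictions file.
#' @param ref a [complex_catalog] or path to a reference file.
#' @param match_threshold OS threshold (default 0.25).
#' @param named_ref,named_pred whether the files carry a leading name
#'   column.
#' @return a `complex_evaluation` report; see [evaluate_complexes].
#' @export
run_evaluation <- function(pred, ref, match_threshold = 0.25,
                           named_ref = FALSE, named_pred = FALSE) {
  if (is.character(ref))
    ref <- read_complex_catalog(ref, min_size = 3, named = named_ref)
  if (is.character(pred))
    pred <- read_complex_catalog(pred, min_size = 1, named = named_pred)
  if (length(ref) == 0L)
    stop("reference catalog is empty after the size-3 filter")
  evaluate_complexes(ref, pred, match_threshold = match_threshold)
}
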