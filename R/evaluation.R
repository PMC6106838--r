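#' Confusion matrix between reference and predicted complexes
#'
#' \eqn{t_{ij} = |N_i \cap M_j|}: shared-protein counts for every
#' reference/prediction pair.
#'
#' @param ref,pred [complex_catalog]s (reference and predictions).
#' @return integer matrix, references in rows, predictions in columns.
#' @export
confusion_matrix <- function(ref, pred) {
  t_ij <- matrix(0L, nrow = length(ref), ncol = length(pred),
                 dimnames = list(names(ref), names(pred)))
  for (i in seq_along(ref))
    for (j in seq_along(pred))
      t_ij[i, j] <- length(intersect(ref[[i]], pred[[j]]))
  t_ij
}

#' Clustering-wise sensitivity, PPV and geometric accuracy
#'
#' \deqn{Sn = \frac{\sum_i \max_j t_{ij}}{\sum_i |N_i|}, \quad
#'   PPV = \frac{\sum_j \max_i t_{ij}}{\sum_j \sum_i t_{ij}}, \quad
#'   ACC = \sqrt{Sn \cdot PPV}}
#' Predictions sharing no protein with any reference contribute zero to
#' both PPV sums; an empty prediction set scores (0, 0, 0). PPV is known to
#' penalize overlapping prediction sets (a protein can be counted in
#' several columns of the denominator); ACC balances the two.
#'
#' @inheritParams confusion_matrix
#' @return named numeric `c(sn =, ppv =, acc =)`.
#' @export
complex_accuracy <- function(ref, pred) {
  if (length(ref) == 0L) stop("empty reference catalog")
  if (length(pred) == 0L) return(c(sn = 0, ppv = 0, acc = 0))
  t_ij <- confusion_matrix(ref, pred)
  sn <- sum(apply(t_ij, 1L, max)) / sum(lengths(ref))
  den <- sum(t_ij)
  ppv <- if (den == 0) 0 else sum(apply(t_ij, 2L, max)) / den
  c(sn = sn, ppv = ppv, acc = sqrt(sn * ppv))
}

#' Fraction of reference complexes matched
#'
#' The share of references matched by at least one prediction at
#' \eqn{OS(p, r) \ge} `threshold`:
#' \deqn{Fraction = \frac{|\{r \in R : \exists p \in P,\; OS(p,r) \ge w\}|}{|R|}}
#' The default threshold 0.25 corresponds to "half the proteins in common
#' on both sides".
#'
#' @inheritParams confusion_matrix
#' @param threshold match threshold in (0, 1\] (default 0.25).
#' @return numeric fraction in \[0, 1\].
#' @export
complex_fraction <- function(ref, pred, threshold = 0.25) {
  if (length(ref) == 0L) stop("empty reference catalog")
  stopifnot(threshold > 0, threshold <= 1)
  if (length(pred) == 0L) return(0)
  matched <- vapply(ref, function(r)
    any(vapply(pred, function(p) overlap_score(p, r), numeric(1L)) >=
          threshold), logical(1L))
  mean(matched)
}

#' Maximum matching ratio
#'
#' Builds a bipartite graph between references and predictions with an edge
#' of weight \eqn{OS(r, p)} for every pair whose overlap score exceeds
#' `threshold` (strictly), computes a maximum-weight matching (each complex
#' used at most once), and returns the total matched weight divided by the
#' number of references. MMR penalizes splitting a reference across several
#' predictions: only one part can claim the match.
#'
#' @inheritParams complex_fraction
#' @return numeric MMR in \[0, 1\].
#' @export
complex_mmr <- function(ref, pred, threshold = 0.25) {
  if (length(ref) == 0L) stop("empty reference catalog")
  stopifnot(threshold > 0, threshold <= 1)
  if (length(pred) == 0L) return(0)
  os <- matrix(0, nrow = length(ref), ncol = length(pred))
  for (i in seq_along(ref))
    for (j in seq_along(pred))
      os[i, j] <- overlap_score(ref[[i]], pred[[j]])
  idx <- which(os > threshold, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0)
  rnames <- paste0("r::", seq_along(ref))
  pnames <- paste0("p::", seq_along(pred))
  el <- data.frame(from = rnames[idx[, 1L]], to = pnames[idx[, 2L]],
                   weight = os[idx], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    el, directed = FALSE,
    vertices = data.frame(name = c(rnames, pnames),
                          type = c(rep(FALSE, length(ref)),
                                   rep(TRUE, length(pred))),
                          stringsAsFactors = FALSE))
  m <- igraph::max_bipartite_match(g, weights = igraph::E(g)$weight)
  m$matching_weight / length(ref)
}

#' Evaluate a prediction set against a reference catalog
#'
#' Computes the full report: Sn, PPV, ACC, Fraction, MMR and the composite
#' score ACC + Fraction + MMR (in \[0, 3\], 3 for a perfect prediction of a
#' disjoint reference).
#'
#' @inheritParams confusion_matrix
#' @param match_threshold OS threshold for Fraction (inclusive) and MMR
#'   (exclusive), default 0.25.
#' @return an object of class `complex_evaluation`: list with `sn`, `ppv`,
#'   `acc`, `fraction`, `mmr`, `composite`.
#' @examples
#' ref <- complex_catalog(list(c("a", "b", "c"), c("d", "e", "f")))
#' evaluate_complexes(ref, ref)  # perfect: composite 3
#' @export
evaluate_complexes <- function(ref, pred, match_threshold = 0.25) {
  acc <- complex_accuracy(ref, pred)
  fr <- complex_fraction(ref, pred, match_threshold)
  mm <- complex_mmr(ref, pred, match_threshold)
  structure(list(sn = unname(acc["sn"]), ppv = unname(acc["ppv"]),
                 acc = unname(acc["acc"]), fraction = fr, mmr = mm,
                 composite = unname(acc["acc"]) + fr + mm),
            class = "complex_evaluation")
}

#' @export
print.complex_evaluation <- function(x, ...) {
  cat(sprintf(
    "Sn %.4f  PPV %.4f  ACC %.4f  Fraction %.4f  MMR %.4f  composite %.4f\n",
    x$sn, x$ppv, x$acc, x$fraction, x$mmr, x$composite))
  invisible(x)
}

#' @export
as.data.frame.complex_evaluation <- function(x, ...) {
  data.frame(sn = x$sn, ppv = x$ppv, acc = x$acc, fraction = x$fraction,
             mmr = x$mmr, composite = x$composite)
}
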