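#' Overlap score of two protein sets
#'
#' \deqn{OS(A, B) = \frac{|A \cap B|^2}{|A| \, |B|}}
#' Symmetric, in \[0, 1\], equal to 1 iff the sets coincide. Used both as
#' the merge criterion between candidate clusters (threshold \eqn{\omega})
#' and as the match score between predictions and reference complexes
#' (threshold 0.25).
#'
#' @param a,b nonempty character vectors (protein sets).
#' @return numeric overlap score.
#' @export
overlap_score <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("overlap score undefined for an empty set")
  length(intersect(a, b))^2 / (length(a) * length(b))
}

#' Merge overlapping candidates and filter by size
#'
#' Single forward scan over the candidates: each surviving cluster absorbs
#' (by set union) every later cluster whose overlap score with it reaches
#' `omega`, continuing the scan with the updated set. Afterwards clusters
#' smaller than `min_size` are dropped. At the default `omega = 1` the merge
#' step is exact set-deduplication (OS = 1 iff equal sets); `omega < 1` is
#' exploratory, and there the candidate order (the seed-queue order) is the
#' tie-breaking convention.
#'
#' @param candidates list of protein sets (character vectors) or of
#'   `grown_cluster` objects.
#' @param omega merge threshold in (0, 1\] (default 1).
#' @param min_size minimum complex size kept (default 3); tiny clusters are
#'   dropped because a pair of proteins trivially reaches OS = 0.25 against
#'   many references.
#' @return a [complex_catalog] of final complexes, ordered by decreasing
#'   size then lexicographic first member, named `C1`, `C2`, ...
#' @export
merge_and_filter <- function(candidates, omega = 1, min_size = 3) {
  if (!is.numeric(omega) || length(omega) != 1L || omega <= 0 || omega > 1)
    stop("`omega` must be a single value in (0, 1]")
  stopifnot(min_size >= 1)
  sets <- lapply(candidates, function(x)
    if (inherits(x, "grown_cluster")) x$members else unique(as.character(x)))
  i <- 1L
  while (i <= length(sets)) {
    j <- i + 1L
    while (j <= length(sets)) {
      if (overlap_score(sets[[i]], sets[[j]]) >= omega) {
        sets[[i]] <- sort(union(sets[[i]], sets[[j]]))
        sets[[j]] <- NULL
      } else {
        j <- j + 1L
      }
    }
    i <- i + 1L
  }
  sets <- Filter(function(s) length(s) >= min_size, sets)
  sets <- lapply(sets, sort)
  if (length(sets)) {
    first <- vapply(sets, `[`, "", 1L)
    sets <- sets[order(-lengths(sets), first)]
  }
  complex_catalog(sets)
}
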