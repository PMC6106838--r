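#' Complex catalogs
#'
#' A `complex_catalog` is a named list of protein sets -- either a reference
#' catalog (CYC2008/NewMIPS style) or a prediction set. Every complex is a
#' nonempty character vector with no duplicate members; names are unique.
#'
#' @param complexes list of character vectors.
#' @param names optional character vector of unique complex names; defaults
#'   to `C1`, `C2`, ...
#' @return an object of class `complex_catalog`.
#' @export
complex_catalog <- function(complexes, names = NULL) {
  complexes <- lapply(complexes, function(x) unique(as.character(x)))
  if (any(lengths(complexes) == 0L))
    stop("catalog contains an empty complex")
  if (is.null(names)) names <- sprintf("C%d", seq_along(complexes))
  if (anyDuplicated(names)) stop("complex names must be unique")
  if (length(names) != length(complexes))
    stop("one name per complex required")
  names(complexes) <- names
  structure(complexes, class = "complex_catalog")
}

#' @export
print.complex_catalog <- function(x, ...) {
  cat(sprintf("complex_catalog: %d complexes, %d distinct proteins\n",
              length(x), length(unique(unlist(x)))))
  if (length(x)) {
    sz <- lengths(x)
    cat(sprintf("  sizes: min %d / median %g / max %d\n",
                min(sz), stats::median(sz), max(sz)))
  }
  invisible(x)
}

#' Read a complex catalog file
#'
#' One complex per line, whitespace-separated member identifiers (the
#' de-facto format of MCL/ClusterONE-style tools). With `named = TRUE` the
#' first token of each line is taken as the complex name. Complexes smaller
#' than `min_size` are dropped; for reference catalogs the field convention
#' is `min_size = 3`.
#'
#' @param path file path.
#' @param min_size minimum members kept (default 3).
#' @param named whether lines carry a leading name column (default FALSE).
#' @return a [complex_catalog].
#' @export
read_complex_catalog <- function(path, min_size = 3, named = FALSE) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  toks <- strsplit(trimws(lines), "[ \t]+")
  nms <- NULL
  if (named) {
    nms <- vapply(toks, `[`, "", 1L)
    toks <- lapply(toks, `[`, -1L)
  }
  keep <- lengths(lapply(toks, unique)) >= min_size
  complex_catalog(toks[keep], names = if (named) nms[keep] else NULL)
}

#' Write a complex catalog
#'
#' One complex per line, tab-separated members, in catalog order.
#'
#' @param catalog a [complex_catalog] (or plain list of character vectors).
#' @param path output path.
#' @param named prepend the complex name as a first column (default FALSE).
#' @export
write_complex_catalog <- function(catalog, path, named = FALSE) {
  lines <- vapply(seq_along(catalog), function(i) {
    body <- paste(catalog[[i]], collapse = "\t")
    if (named) paste(names(catalog)[i], body, sep = "\t") else body
  }, "")
  writeLines(lines, path)
  invisible(path)
}
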