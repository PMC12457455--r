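#' Land-cover transition matrix between two maps
#'
#' Counts ordered (from, to) class changes between two categorical grids,
#' over changed pixels only: pixels whose class is identical in both maps do
#' not constitute a transition and are excluded, so the counts sum to the
#' number of changed pixels.
#'
#' @param first,last Integer matrices of class codes with the same shape
#'   (typically the first and last year of a cell's series).
#' @return An object of class `transition_matrix`: data frame with columns
#'   `from`, `to`, `count` (sorted by decreasing count), with attribute
#'   `total_changed`.
#' @examples
#' a <- matrix(2L, 3, 3); b <- a; b[1:2, 1] <- 1L
#' transition_matrix(a, b)   # two forest -> cropland pixels
#' @export
transition_matrix <- function(first, last) {
  if (!identical(dim(first), dim(last)))
    stop("maps must have the same shape")
  changed <- first != last
  from <- as.integer(first[changed]); to <- as.integer(last[changed])
  if (length(from) == 0L) {
    out <- data.frame(from = integer(0), to = integer(0), count = integer(0))
  } else {
    tab <- table(from = from, to = to)
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    df <- df[df$Freq > 0L, , drop = FALSE]
    out <- data.frame(from = as.integer(df$from), to = as.integer(df$to),
                      count = as.integer(df$Freq))
    out <- out[order(-out$count, out$from, out$to), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "total_changed") <- sum(out$count)
  class(out) <- c("transition_matrix", "data.frame")
  out
}

#' Dominant land-cover transition of a cell
#'
#' Identifies the most frequent ordered class change of a transition matrix
#' and its certainty, i.e. the share of all changed pixels represented by
#' the dominant pair.  Ties are broken deterministically: transitions
#' involving the forest class are preferred, then the fixed category order
#' (see [ipcc_classes()]) on the `from` then `to` codes; tied maxima are
#' flagged.
#'
#' @param m A [transition_matrix()].
#' @param forest_class Integer code of the forest category (default 2).
#' @return `NULL` when no pixel changed (the no-change signal); otherwise an
#'   object of class `dominant_transition`: list with `from`, `to`, `count`,
#'   `certainty`, `tie`, `involves_forest` and `transition_lc` (the
#'   non-forest side of the pair; `NA` when forest is not involved).
#' @export
dominant_transition <- function(m, forest_class = 2L) {
  stopifnot(inherits(m, "transition_matrix"))
  total <- attr(m, "total_changed")
  if (nrow(m) == 0L || total == 0L) return(NULL)
  top <- m$count == max(m$count)
  tie <- sum(top) > 1L
  cand <- m[top, , drop = FALSE]
  inv <- cand$from == forest_class | cand$to == forest_class
  if (any(inv)) cand <- cand[inv, , drop = FALSE]
  cand <- cand[order(cand$from, cand$to), , drop = FALSE]
  pick <- cand[1L, ]
  involves <- pick$from == forest_class || pick$to == forest_class
  structure(list(
    from = pick$from, to = pick$to, count = pick$count,
    certainty = pick$count / total, tie = tie,
    involves_forest = involves,
    transition_lc = if (involves)
      if (pick$from == forest_class) pick$to else pick$from
    else NA_integer_),
    class = "dominant_transition")
}

#' @export
print.dominant_transition <- function(x, ...) {
  cat(sprintf("dominant transition %d -> %d (n = %d, certainty = %.3f%s)\n",
              x$from, x$to, x$count, x$certainty,
              if (x$tie) ", tied" else ""))
  invisible(x)
}
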