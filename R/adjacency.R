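#' Queen-contiguity pixel pairs of a grid
#'
#' Enumerates every unordered pair of Queen-adjacent pixels (8-neighbourhood,
#' no wraparound) of a `rows` x `cols` grid.  Corner, edge and interior pixels
#' therefore participate in 3, 5 and 8 pairs respectively.
#'
#' @param rows,cols Grid dimensions (positive integers).
#' @return A two-column integer matrix of linear pixel indices
#'   (column-major, as used by R matrices); one row per adjacent pair.
#' @examples
#' nrow(queen_pairs(3, 3))  # 20 pairs on a 3 x 3 grid
#' @export
queen_pairs <- function(rows, cols) {
  stopifnot(rows >= 1, cols >= 1)
  idx <- matrix(seq_len(rows * cols), rows, cols)
  pair <- function(a, b) cbind(as.vector(a), as.vector(b))
  out <- list()
  if (cols > 1) out$h <- pair(idx[, -cols], idx[, -1])
  if (rows > 1) out$v <- pair(idx[-rows, ], idx[-1, ])
  if (rows > 1 && cols > 1) {
    out$d1 <- pair(idx[-rows, -cols], idx[-1, -1])     # down-right
    out$d2 <- pair(idx[-1, -cols], idx[-rows, -1])     # up-right
  }
  do.call(rbind, out)
}

#' Unlike-adjacency of a binary landscape
#'
#' Counts Queen-adjacent pixel pairs whose two members fall on opposite sides
#' of a binary mask (e.g. transition land cover versus its complementary
#' landscape).  Each mixed pair is counted once; grid boundaries truncate the
#' neighbourhood (3 neighbours at corners, 5 on edges, 8 in the core), with no
#' wraparound.  Higher values indicate interspersion of the two classes,
#' lower values compact arrangements.
#'
#' @param mask Logical matrix (`TRUE` = focal class).
#' @return Integer count of mixed Queen-adjacent pairs.
#' @examples
#' m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
#' unlike_adjacency(m)  # 8: an interior pixel has 8 unlike neighbours
#' @export
unlike_adjacency <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  r <- nrow(mask); c <- ncol(mask)
  n <- 0L
  if (c > 1) n <- n + sum(mask[, -c, drop = FALSE] != mask[, -1, drop = FALSE])
  if (r > 1) n <- n + sum(mask[-r, , drop = FALSE] != mask[-1, , drop = FALSE])
  if (r > 1 && c > 1) {
    n <- n + sum(mask[-r, -c, drop = FALSE] != mask[-1, -1, drop = FALSE])
    n <- n + sum(mask[-1, -c, drop = FALSE] != mask[-r, -1, drop = FALSE])
  }
  as.integer(n)
}

# Number of TRUE Queen-neighbours of every pixel (matrix of counts).
neighbor_true_counts <- function(mask) {
  r <- nrow(mask); c <- ncol(mask)
  p <- matrix(0L, r + 2L, c + 2L)
  p[2:(r + 1L), 2:(c + 1L)] <- mask
  out <- matrix(0L, r, c)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    out <- out + p[(2:(r + 1L)) + dr, (2:(c + 1L)) + dc]
  }
  out
}

# Queen-neighbourhood size of every pixel (8 core, 5 edge, 3 corner).
neighbor_degree <- function(rows, cols) {
  neighbor_true_counts(matrix(TRUE, rows, cols))
}
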