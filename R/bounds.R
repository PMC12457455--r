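# Combinatorial bounds on unlike-adjacency -------------------------------
#
# For a fixed number k of focal-class pixels on a rows x cols grid, the
# unlike-adjacency (UA) can range between a minimum (achieved by compact,
# corner-anchored arrangements, where grid boundaries truncate the exposed
# neighbourhood) and a maximum (achieved by dispersed arrangements).  These
# bounds normalize observed UA values into the Landscape Configuration Index.
#
# Small grids (<= 20 pixels) are solved exactly by exhaustive enumeration of
# all C(n, k) placements.  Larger grids use deterministic constructive
# heuristics -- greedy sequential placement plus analytic seed patterns
# (corner-anchored quasi-square block for the minimum; spaced lattice /
# alternating stripes for the maximum) -- followed by a steepest
# single-swap refinement pass.  Exact optimality is not claimed for large
# grids; the constructions are certified in the test suite by (a) agreement
# with exhaustive enumeration on small grids and (b) randomized dominance:
# no sampled arrangement ever falls outside the bounds.

EXHAUSTIVE_LIMIT <- 20L

# UA increments along a fixed placement order: ua_seq[k] = UA of the mask
# made of the first k pixels of `order` (linear indices).
ua_sequence <- function(order, rows, cols) {
  deg <- neighbor_degree(rows, cols)
  tn <- matrix(0L, rows, cols)
  nbr <- neighbor_offsets(rows, cols)
  ua <- integer(length(order))
  cur <- 0L
  for (i in seq_along(order)) {
    p <- order[i]
    cur <- cur + deg[p] - 2L * tn[p]
    ua[i] <- cur
    for (q in nbr[[p]]) tn[q] <- tn[q] + 1L
  }
  ua
}

# List of Queen-neighbour linear indices for every pixel.
neighbor_offsets <- function(rows, cols) {
  key <- sprintf("nbr_%dx%d", rows, cols)
  if (!is.null(.ft_cache[[key]])) return(.ft_cache[[key]])
  out <- vector("list", rows * cols)
  for (c0 in seq_len(cols)) for (r0 in seq_len(rows)) {
    p <- (c0 - 1L) * rows + r0
    rs <- max(1L, r0 - 1L):min(rows, r0 + 1L)
    cs <- max(1L, c0 - 1L):min(cols, c0 + 1L)
    q <- as.vector(outer(rs, (cs - 1L) * rows, "+"))
    out[[p]] <- q[q != p]
  }
  .ft_cache[[key]] <- out
  out
}

# Greedy sequential placement: at each step add the pixel whose toggle moves
# UA most in the requested direction (ties: smallest linear index, which
# anchors compact growth in the north-west corner).
greedy_order <- function(rows, cols, maximize) {
  n <- rows * cols
  deg <- as.vector(neighbor_degree(rows, cols))
  tn <- integer(n)
  nbr <- neighbor_offsets(rows, cols)
  free <- rep(TRUE, n)
  ord <- integer(n)
  for (i in seq_len(n)) {
    delta <- deg - 2L * tn
    delta[!free] <- if (maximize) -Inf else Inf
    p <- if (maximize) which.max(delta) else which.min(delta)
    ord[i] <- p
    free[p] <- FALSE
    for (q in nbr[[p]]) tn[q] <- tn[q] + 1L
  }
  ord
}

# Corner-anchored quasi-square fill order (analytic minimum seed).
square_order <- function(rows, cols) {
  g <- expand.grid(r = seq_len(rows), c = seq_len(cols))
  key <- pmax(g$r, g$c)
  ord <- order(key, g$r + g$c, g$r)
  (g$c[ord] - 1L) * rows + g$r[ord]
}

# Alternating-stripe fill order (analytic maximum seed for dense k):
# odd columns first (column by column), then even columns.
stripe_order <- function(rows, cols) {
  g <- expand.grid(r = seq_len(rows), c = seq_len(cols))
  ord <- order(g$c %% 2L == 0L, g$c, g$r)
  (g$c[ord] - 1L) * rows + g$r[ord]
}

# Spaced-lattice fill order (analytic maximum seed for sparse k):
# pixels with both coordinates even first (spacing 2, interior-preferring),
# then the remainder in greedy-friendly order.
lattice_order <- function(rows, cols) {
  g <- expand.grid(r = seq_len(rows), c = seq_len(cols))
  tier <- 2L - (g$r %% 2L == 0L) - (g$c %% 2L == 0L)
  ord <- order(tier, g$c, g$r)
  (g$c[ord] - 1L) * rows + g$r[ord]
}

# Steepest single-swap refinement of a k-pixel mask.
refine_mask <- function(mask, maximize, max_iter = 100L, n_cand = 8L) {
  deg <- neighbor_degree(nrow(mask), ncol(mask))
  nbr <- neighbor_offsets(nrow(mask), ncol(mask))
  sgn <- if (maximize) 1 else -1
  for (it in seq_len(max_iter)) {
    tn <- neighbor_true_counts(mask)
    gain_rm <- 2L * tn - deg    # UA change when a TRUE pixel is removed
    gain_add <- deg - 2L * tn   # UA change when a FALSE pixel is added
    tr <- which(mask); fa <- which(!mask)
    if (!length(tr) || !length(fa)) break
    ps <- tr[order(sgn * gain_rm[tr], decreasing = TRUE)]
    ps <- ps[seq_len(min(n_cand, length(ps)))]
    best <- NULL; best_d <- 0L
    qs_base <- fa[order(sgn * gain_add[fa], decreasing = TRUE)]
    qs_base <- qs_base[seq_len(min(n_cand, length(qs_base)))]
    for (p in ps) {
      qs <- unique(c(qs_base, intersect(nbr[[p]], fa)))
      adj <- as.integer(qs %in% nbr[[p]])
      d <- gain_rm[p] + gain_add[qs] + 2L * adj
      j <- which.max(sgn * d)
      if (sgn * d[j] > sgn * best_d) { best_d <- d[j]; best <- c(p, qs[j]) }
    }
    if (is.null(best) || sgn * best_d <= 0L) break
    mask[best[1L]] <- FALSE
    mask[best[2L]] <- TRUE
  }
  mask
}

mask_from_order <- function(order, k, rows, cols) {
  m <- matrix(FALSE, rows, cols)
  if (k > 0L) m[order[seq_len(k)]] <- TRUE
  m
}

# Full constructive bounds table (and extremal masks) for a grid size.
# Unlike-adjacency is invariant under complementing the mask, so the bounds
# are symmetric in k <-> n - k: only the sparse half is constructed, the
# dense half reuses the complemented extremal arrangements.
build_constructive_table <- function(rows, cols) {
  n <- rows * cols
  min_orders <- list(greedy_order(rows, cols, maximize = FALSE),
                     square_order(rows, cols))
  max_orders <- list(greedy_order(rows, cols, maximize = TRUE),
                     stripe_order(rows, cols),
                     lattice_order(rows, cols))
  min_seqs <- lapply(min_orders, ua_sequence, rows = rows, cols = cols)
  max_seqs <- lapply(max_orders, ua_sequence, rows = rows, cols = cols)
  ua_min <- integer(n + 1L); ua_max <- integer(n + 1L)
  min_masks <- vector("list", n + 1L); max_masks <- vector("list", n + 1L)
  min_masks[[1L]] <- matrix(FALSE, rows, cols)
  max_masks[[1L]] <- matrix(FALSE, rows, cols)
  for (k in seq_len(n %/% 2L)) {
    vals <- vapply(min_seqs, `[`, integer(1), k)
    m <- mask_from_order(min_orders[[which.min(vals)]], k, rows, cols)
    m <- refine_mask(m, maximize = FALSE)
    ua_min[k + 1L] <- unlike_adjacency(m)
    min_masks[[k + 1L]] <- m
    vals <- vapply(max_seqs, `[`, integer(1), k)
    m <- mask_from_order(max_orders[[which.max(vals)]], k, rows, cols)
    m <- refine_mask(m, maximize = TRUE)
    ua_max[k + 1L] <- unlike_adjacency(m)
    max_masks[[k + 1L]] <- m
  }
  for (k in seq.int(n %/% 2L + 1L, n)) {
    ua_min[k + 1L] <- ua_min[n - k + 1L]
    ua_max[k + 1L] <- ua_max[n - k + 1L]
    min_masks[[k + 1L]] <- !min_masks[[n - k + 1L]]
    max_masks[[k + 1L]] <- !max_masks[[n - k + 1L]]
  }
  list(table = data.frame(k = 0:n, ua_min = ua_min, ua_max = ua_max,
                          method = "constructive"),
       min_masks = min_masks, max_masks = max_masks)
}

# Exhaustive bounds (all C(n, k) placements) for small grids.
build_exhaustive_table <- function(rows, cols) {
  n <- rows * cols
  stopifnot(n <= EXHAUSTIVE_LIMIT)
  qp <- queen_pairs(rows, cols)
  ua_min <- integer(n + 1L); ua_max <- integer(n + 1L)
  min_masks <- vector("list", n + 1L); max_masks <- vector("list", n + 1L)
  min_masks[[1L]] <- matrix(FALSE, rows, cols)
  max_masks[[1L]] <- matrix(FALSE, rows, cols)
  for (k in seq_len(n)) {
    cmb <- combn(n, k)
    nc <- ncol(cmb)
    m <- matrix(FALSE, n, nc)
    m[cmb + n * rep(0:(nc - 1L), each = k)] <- TRUE
    ua <- as.integer(colSums(m[qp[, 1L], , drop = FALSE] !=
                               m[qp[, 2L], , drop = FALSE]))
    i_min <- which.min(ua); i_max <- which.max(ua)
    ua_min[k + 1L] <- ua[i_min]; ua_max[k + 1L] <- ua[i_max]
    min_masks[[k + 1L]] <- matrix(m[, i_min], rows, cols)
    max_masks[[k + 1L]] <- matrix(m[, i_max], rows, cols)
  }
  list(table = data.frame(k = 0:n, ua_min = ua_min, ua_max = ua_max,
                          method = "exhaustive"),
       min_masks = min_masks, max_masks = max_masks)
}

bounds_cache <- function(rows, cols, method = c("auto", "exhaustive",
                                                "constructive")) {
  method <- match.arg(method)
  if (method == "auto")
    method <- if (rows * cols <= EXHAUSTIVE_LIMIT) "exhaustive" else
      "constructive"
  key <- sprintf("bounds_%s_%dx%d", method, rows, cols)
  if (is.null(.ft_cache[[key]])) {
    .ft_cache[[key]] <- if (method == "exhaustive")
      build_exhaustive_table(rows, cols) else
      build_constructive_table(rows, cols)
  }
  .ft_cache[[key]]
}

#' Minimum and maximum unlike-adjacency for a pixel count
#'
#' Returns the theoretical bounds of unlike-adjacency attainable with exactly
#' `k` focal pixels on a `rows` x `cols` grid.  Grids with at most 20 pixels
#' are solved exactly by exhaustive enumeration; larger grids use
#' deterministic constructive extremal arrangements (compact corner-anchored
#' block for the minimum, dispersed placements for the maximum) with a local
#' swap refinement.  The full table for a grid size is computed once and
#' cached for the session.
#'
#' @param k Number of focal pixels, `0 <= k <= rows * cols`.
#' @param rows,cols Grid dimensions.
#' @param method `"auto"` (default), `"exhaustive"`, or `"constructive"`.
#' @return An object of class `ua_bounds`: list with elements `k`, `ua_min`,
#'   `ua_max`, `method`.  Both bounds are 0 when `k` is 0 or fills the grid.
#' @examples
#' ua_bounds(1, 18, 18)  # min 3 (corner), max 8 (core)
#' @seealso [ua_bounds_table()], [ua_extremal_mask()], [lci()]
#' @export
ua_bounds <- function(k, rows, cols, method = c("auto", "exhaustive",
                                                "constructive")) {
  n <- rows * cols
  if (k < 0 || k > n) stop("k must be between 0 and rows * cols = ", n)
  bc <- bounds_cache(rows, cols, method)
  row <- bc$table[k + 1L, ]
  structure(list(k = as.integer(k), ua_min = row$ua_min, ua_max = row$ua_max,
                 method = row$method),
            class = "ua_bounds")
}

#' Full unlike-adjacency bounds table for a grid size
#'
#' @inheritParams ua_bounds
#' @return A data frame with columns `k`, `ua_min`, `ua_max`, `method`, one
#'   row per `k` in `0:(rows * cols)`.
#' @export
ua_bounds_table <- function(rows, cols, method = c("auto", "exhaustive",
                                                   "constructive")) {
  bounds_cache(rows, cols, method)$table
}

#' Extremal arrangement attaining an unlike-adjacency bound
#'
#' @inheritParams ua_bounds
#' @param which `"min"` or `"max"`.
#' @return Logical mask with `k` `TRUE` pixels whose unlike-adjacency equals
#'   the corresponding bound reported by [ua_bounds()].
#' @export
ua_extremal_mask <- function(k, rows, cols, which = c("min", "max"),
                             method = c("auto", "exhaustive",
                                        "constructive")) {
  which <- match.arg(which)
  n <- rows * cols
  if (k < 0 || k > n) stop("k must be between 0 and rows * cols = ", n)
  bc <- bounds_cache(rows, cols, method)
  if (which == "min") bc$min_masks[[k + 1L]] else bc$max_masks[[k + 1L]]
}

#' Persist an unlike-adjacency bounds table as CSV
#'
#' @inheritParams ua_bounds
#' @param path Output CSV path (columns `k`, `ua_min`, `ua_max`, `method`).
#' @return `path`, invisibly.
#' @export
write_ua_bounds_table <- function(path, rows, cols,
                                  method = c("auto", "exhaustive",
                                             "constructive")) {
  write.csv(ua_bounds_table(rows, cols, method), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.ua_bounds <- function(x, ...) {
  cat(sprintf("UA bounds (k = %d, %s): min = %d, max = %d\n",
              x$k, x$method, x$ua_min, x$ua_max))
  invisible(x)
}
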