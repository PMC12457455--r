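# Reading and writing categorical land-cover stacks ----------------------
#
# Two plain, loss-free on-disk forms are supported:
#   * one single-band TIFF per year (class codes stored in 8-bit samples),
#   * long-format CSV (year, row, col, class), which also round-trips
#     per-cell series.
# Pixel indices are row-major, 1-based; the cell/raster origin is the
# north-west corner (row 1 = northernmost).

#' Write a categorical grid as an 8-bit TIFF
#'
#' @param grid Integer matrix of class codes (0-255).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_lc_tiff <- function(grid, path) {
  stopifnot(is.matrix(grid), all(grid >= 0 & grid <= 255, na.rm = TRUE))
  tiff::writeTIFF(grid / 255, path, bits.per.sample = 8L,
                  compression = "none")
  invisible(path)
}

#' Read a categorical grid from a single-band TIFF
#'
#' @param path TIFF file written by [write_lc_tiff()] (or any single-band
#'   integer-valued TIFF).
#' @return Integer matrix of class codes.
#' @export
read_lc_tiff <- function(path) {
  g <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(g)) == 3L) g <- g[, , 1L]
  storage.mode(g) <- "integer"
  g
}

#' Read an annual land-cover stack from per-year TIFF files
#'
#' @param paths Character vector of TIFF files, one per year, in
#'   chronological order.  All must share the same dimensions.
#' @return Integer array with dimensions `(year, row, col)`.
#' @export
read_lc_stack_tiff <- function(paths) {
  grids <- lapply(paths, read_lc_tiff)
  dims <- unique(lapply(grids, dim))
  if (length(dims) != 1L) stop("stack years disagree in shape")
  arr <- array(NA_integer_, c(length(grids), dims[[1L]]))
  for (t in seq_along(grids)) arr[t, , ] <- grids[[t]]
  arr
}

#' Write a land-cover series / stack as long-format CSV
#'
#' @param series Integer array `(year, row, col)` of class codes (an
#'   `lc_series` works directly).
#' @param path Output CSV (columns `year`, `row`, `col`, `class`).
#' @return `path`, invisibly.
#' @export
write_lc_series_csv <- function(series, path) {
  d <- dim(series)
  stopifnot(length(d) == 3L)
  long <- data.frame(year = rep(seq_len(d[1L]), times = d[2L] * d[3L]),
                     row = rep(rep(seq_len(d[2L]), each = d[1L]), d[3L]),
                     col = rep(seq_len(d[3L]), each = d[1L] * d[2L]),
                     class = as.integer(series))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read a land-cover series / stack from long-format CSV
#'
#' @param path CSV written by [write_lc_series_csv()].
#' @return Integer array `(year, row, col)`.
#' @export
read_lc_series_csv <- function(path) {
  long <- read.csv(path)
  stopifnot(all(c("year", "row", "col", "class") %in% names(long)))
  d <- c(max(long$year), max(long$row), max(long$col))
  arr <- array(NA_integer_, d)
  arr[cbind(long$year, long$row, long$col)] <- as.integer(long$class)
  arr
}

#' Tessellate a raster stack into fixed-size analysis cells
#'
#' Partitions the raster into mutually exclusive square cells of
#' `cell_pixels` x `cell_pixels` pixels, anchored at the north-west corner.
#' Complete cells are emitted with their series; cells that are incomplete
#' (edge remainders smaller than the target size, or containing a nodata
#' pixel in any year) are flagged excluded with reason `"incomplete"` -- the
#' conservative reading of the rule that every analysed cell must carry its
#' full pixel complement in every year.
#'
#' @param stack Integer array `(year, row, col)` of class codes; `NA` (or
#'   `nodata`) marks missing pixels.
#' @param cell_pixels Cell edge length in pixels (>= 2); e.g. 18, 36 and 180
#'   pixels of a 10 arc-second product correspond to 3, 6 and 30 arc-minute
#'   cells -- scale is a parameter, not new code.
#' @param extent Optional geographic extent of the whole raster,
#'   `c(xmin, xmax, ymin, ymax)` in degrees (row 1 at `ymax`); when given,
#'   per-cell bounds are included in the index.
#' @param nodata Optional code to treat as missing in addition to `NA`.
#' @return List with `cells` (data frame: `cell_id`, `row_off`, `col_off`,
#'   `rows`, `cols`, `complete`, `reason`, and bounds when `extent` is given)
#'   and `series` (named list of `(year, row, col)` arrays for complete
#'   cells).
#' @export
tessellate <- function(stack, cell_pixels, extent = NULL, nodata = NULL) {
  d <- dim(stack)
  if (length(d) != 3L) stop("stack must be a (year, row, col) array")
  if (cell_pixels < 2L) stop("cell_pixels must be >= 2")
  if (!is.null(nodata)) stack[stack %in% nodata] <- NA_integer_
  nr <- d[2L]; nc <- d[3L]
  r_breaks <- seq(1L, nr, by = cell_pixels)
  c_breaks <- seq(1L, nc, by = cell_pixels)
  cells <- list(); series <- list()
  id <- 0L
  for (ro in r_breaks) for (co in c_breaks) {
    id <- id + 1L
    cid <- sprintf("cell_r%03d_c%03d", ro, co)
    rows <- min(cell_pixels, nr - ro + 1L)
    cols <- min(cell_pixels, nc - co + 1L)
    sub <- stack[, ro:(ro + rows - 1L), co:(co + cols - 1L), drop = FALSE]
    complete <- rows == cell_pixels && cols == cell_pixels && !anyNA(sub)
    rec <- data.frame(cell_id = cid, row_off = ro, col_off = co,
                      rows = rows, cols = cols, complete = complete,
                      reason = if (complete) NA_character_ else "incomplete")
    if (!is.null(extent)) {
      px_w <- (extent[2L] - extent[1L]) / nc
      px_h <- (extent[4L] - extent[3L]) / nr
      rec$xmin <- extent[1L] + (co - 1L) * px_w
      rec$xmax <- extent[1L] + (co - 1L + cols) * px_w
      rec$ymax <- extent[4L] - (ro - 1L) * px_h
      rec$ymin <- extent[4L] - (ro - 1L + rows) * px_h
    }
    cells[[id]] <- rec
    if (complete) series[[cid]] <- sub
  }
  list(cells = do.call(rbind, cells), series = series)
}
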