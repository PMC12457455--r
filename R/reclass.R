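#' IPCC land-category codes
#'
#' The eight aggregated land categories at which change detection in the
#' CCI-LC product line is considered reliable, with the fixed ordering used
#' throughout the package (e.g. for deterministic tie-breaking):
#' cropland < forest < grassland < wetland < settlement < shrubland <
#' bare < water.  Sparse vegetation is folded into bare.
#'
#' @return Named integer vector of category codes.
#' @examples
#' ipcc_classes()[["forest"]]
#' @export
ipcc_classes <- function() {
  c(cropland = 1L, forest = 2L, grassland = 3L, wetland = 4L,
    settlement = 5L, shrubland = 6L, bare = 7L, water = 8L)
}

#' Default CCI-LC to IPCC reclassification table
#'
#' Maps the 22 primary CCI-LC classes (plus their regional sub-classes) onto
#' the eight IPCC categories, following the aggregation recommended in the
#' CCI-LC user documentation: mosaic tree cover and flooded-tree classes
#' follow their woody component or wetland character, mosaic herbaceous
#' cover goes to grassland, lichens/mosses and sparse vegetation are folded
#' into bare (as is permanent snow/ice, i.e. "other land"). The table is a
#' package default and fully overridable: any data frame (or CSV read via
#' [read_reclass_table()]) with columns `code` and `category` works.
#'
#' @return Data frame with columns `code` (CCI-LC class code), `category`
#'   (IPCC code, see [ipcc_classes()]) and `category_name`.
#' @export
default_reclass_table <- function() {
  ic <- ipcc_classes()
  map <- list(
    cropland   = c(10, 11, 12, 20, 30, 40),
    forest     = c(50, 60, 61, 62, 70, 71, 72, 80, 81, 82, 90, 100),
    grassland  = c(110, 130),
    wetland    = c(160, 170, 180),
    settlement = 190,
    shrubland  = c(120, 121, 122),
    bare       = c(140, 150, 151, 152, 153, 200, 201, 202, 220),
    water      = 210)
  out <- do.call(rbind, lapply(names(map), function(nm)
    data.frame(code = as.integer(map[[nm]]), category = ic[[nm]],
               category_name = nm)))
  out[order(out$code), , drop = FALSE]
}

#' Read a reclassification table from CSV
#'
#' @param path CSV file with columns `code` and `category` (extra columns
#'   are kept).
#' @return Data frame usable by [reclassify()].
#' @export
read_reclass_table <- function(path) {
  tab <- read.csv(path)
  if (!all(c("code", "category") %in% names(tab)))
    stop("reclass table must have columns 'code' and 'category'")
  tab
}

#' Reclassify a categorical grid
#'
#' Maps every class code of a grid (matrix, or array whose trailing
#' dimensions are spatial) through a reclassification table.  Codes missing
#' from the table raise an error naming them, so silent misclassification is
#' impossible.
#'
#' @param grid Integer matrix or array of class codes.
#' @param table Data frame with columns `code` and `category`
#'   (default: [default_reclass_table()]).
#' @return Grid of the same shape containing only category codes.
#' @examples
#' g <- matrix(c(150, 153), 1, 2)       # sparse vegetation variants
#' reclassify(g)                        # both become bare (7)
#' @export
reclassify <- function(grid, table = default_reclass_table()) {
  codes <- as.integer(grid)
  idx <- match(codes, table$code)
  if (anyNA(idx[!is.na(codes)])) {
    bad <- sort(unique(codes[is.na(idx) & !is.na(codes)]))
    stop("unmapped class code(s): ", paste(bad, collapse = ", "))
  }
  out <- grid
  out[] <- as.integer(table$category)[idx]
  out
}
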