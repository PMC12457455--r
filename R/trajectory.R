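# Interval, rate, amount and persistence of forest change ----------------

#' Per-year forest pixel counts of a cell series
#'
#' @param series Integer array `(year, row, col)` of class codes.
#' @param forest_class Integer code of the forest category (default 2).
#' @return Integer vector of forest pixel counts, one per year.
#' @export
forest_series <- function(series, forest_class = 2L) {
  apply(series == forest_class, 1L, sum)
}

#' Interval of forest change
#'
#' The interval spans from the last year before any change in the forest
#' count (start `S`: the largest index up to which all counts equal the
#' first) to the first year after which the count stays constant to the end
#' (end `E`).  Duration is the number of inter-annual steps spanned,
#' `E - S`, so a single-step change has duration 1 and a series of 29 annual
#' maps can have durations 1 through 28.
#'
#' @param counts Integer vector of forest pixel counts per year (length
#'   >= 2), e.g. from [forest_series()].
#' @return `NULL` when the series is constant (no-change signal); otherwise
#'   an object of class `change_interval`: list with `start`, `end` (1-based
#'   year indices) and `duration` (years).
#' @examples
#' change_interval(c(100, 100, 70, 70))  # start 2, end 3, duration 1
#' @export
change_interval <- function(counts) {
  n <- length(counts)
  if (n < 2L) stop("need at least two annual values")
  if (all(counts == counts[1L])) return(NULL)
  ch <- which(diff(counts) != 0L)
  s <- ch[1L]            # last index of the leading constant run
  e <- ch[length(ch)] + 1L
  structure(list(start = s, end = e, duration = e - s),
            class = "change_interval")
}

#' Relative rate of forest change
#'
#' The reciprocal of the duration of the interval of forest change, in
#' 1/years.  A cell losing 30 pixels spread over 30 years and one losing 30
#' pixels in a single year have the same absolute rate (1 pixel/year) but
#' relative rates of 1/30 and 1: the metric separates gradual from abrupt
#' trajectories.
#'
#' @param interval A [change_interval()].
#' @return Numeric rate in `(0, 1]` (units: 1/year).
#' @export
rate_of_change <- function(interval) {
  stopifnot(inherits(interval, "change_interval"), interval$duration >= 1L)
  1 / interval$duration
}

#' Classify the persistence of a forest-change trajectory
#'
#' Within the interval of change, a trajectory is persistent loss when all
#' year-over-year differences are non-positive (with at least one negative),
#' persistent gain symmetrically, and non-persistent when both a loss and a
#' gain occur.  Plateaus (zero-change years inside the interval) do not
#' break persistence: stepped decline is still persistent loss.
#'
#' @param counts Forest pixel counts per year.
#' @param interval A [change_interval()], or `NULL` for a constant series.
#' @return One of `"persistent_loss"`, `"persistent_gain"`,
#'   `"non_persistent"`, `"no_change"`.
#' @export
classify_trajectory <- function(counts, interval = change_interval(counts)) {
  if (is.null(interval)) return("no_change")
  d <- diff(counts[interval$start:interval$end])
  has_loss <- any(d < 0L); has_gain <- any(d > 0L)
  if (has_loss && has_gain) "non_persistent"
  else if (has_loss) "persistent_loss"
  else "persistent_gain"
}

#' Amount of forest change over the interval
#'
#' Absolute difference of forest pixel counts between the end and start of
#' the interval, expressed as a proportion of the cell size.
#'
#' @inheritParams classify_trajectory
#' @param cell_size Total pixels in the cell (default 324 for 18 x 18).
#' @return Proportion in `[0, 1]` (0 when `interval` is `NULL`).
#' @export
amount_of_change <- function(counts, interval = change_interval(counts),
                             cell_size = 324L) {
  if (is.null(interval)) return(0)
  abs(counts[interval$end] - counts[interval$start]) / cell_size
}

#' Initial amount and configuration of the transition land cover
#'
#' Captures the state of the transition land cover at the start of the
#' interval of forest change: its amount as a proportion of the cell, and
#' the LCI of its arrangement.  When the transition class is absent or fills
#' the whole cell at that time-step, no configuration is defined and the LCI
#' is flagged invalid (such cells are excluded downstream).
#'
#' @param series Integer array `(year, row, col)` of class codes.
#' @param interval A [change_interval()].
#' @param transition_class Integer code of the transition land cover.
#' @return List with `amount` (proportion), `lci` (in `[0, 1]` or `NA`) and
#'   `lci_valid` (logical).
#' @export
initial_state <- function(series, interval, transition_class) {
  stopifnot(inherits(interval, "change_interval"))
  grid <- series[interval$start, , ]
  mask <- grid == transition_class
  k <- sum(mask)
  n <- length(mask)
  val <- mask_lci(mask)
  list(amount = k / n, lci = val, lci_valid = !is.na(val))
}

#' Mean pixel dimensions and area of a geographic cell
#'
#' Great-circle (haversine, spherical Earth of radius 6371 km) lengths of
#' the cell's mid-edges divided by its column and row counts give the mean
#' pixel width and height; their product is the mean pixel area.  These are
#' reporting conveniences for translating pixel counts into km2.
#'
#' @param bounds Numeric `c(xmin, xmax, ymin, ymax)` in degrees.
#' @param rows,cols Pixel dimensions of the cell.
#' @return List with `pixel_width_km`, `pixel_height_km`, `pixel_area_km2`,
#'   `cell_area_km2`.
#' @examples
#' pixel_area(c(0, 0.05, -0.025, 0.025), 18, 18)  # 3' cell at the equator
#' @export
pixel_area <- function(bounds, rows, cols) {
  stopifnot(length(bounds) == 4L, rows >= 1L, cols >= 1L)
  xmin <- bounds[1L]; xmax <- bounds[2L]
  ymin <- bounds[3L]; ymax <- bounds[4L]
  if (xmax <= xmin || ymax <= ymin) stop("degenerate cell bounds")
  if (abs(ymin) > 90 || abs(ymax) > 90) stop("latitude out of range")
  r_km <- 6371
  ymid <- (ymin + ymax) / 2; xmid <- (xmin + xmax) / 2
  width_km <- geosphere::distHaversine(c(xmin, ymid), c(xmax, ymid),
                                       r = r_km * 1000) / 1000
  height_km <- geosphere::distHaversine(c(xmid, ymin), c(xmid, ymax),
                                        r = r_km * 1000) / 1000
  pw <- width_km / cols; ph <- height_km / rows
  list(pixel_width_km = pw, pixel_height_km = ph,
       pixel_area_km2 = pw * ph, cell_area_km2 = width_km * height_km)
}
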