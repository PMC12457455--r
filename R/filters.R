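# Per-cell records and exclusion filters ---------------------------------

#' Derived record for one cell
#'
#' Runs the per-cell stages end to end: transition matrix between the first
#' and last year, dominant transition and certainty, forest-change interval,
#' persistence class, amount and relative rate of change, and the initial
#' amount and LCI of the transition land cover at the start of the interval.
#'
#' @param series Integer array `(year, row, col)` of class codes.
#' @param cell_id Identifier for the output row.
#' @param forest_class Integer code of the forest category (default 2).
#' @return One-row data frame (see [cell_records()] for the schema).
#' @export
cell_record <- function(series, cell_id = "cell", forest_class = 2L) {
  d <- dim(series)
  cell_size <- d[2L] * d[3L]
  tm <- transition_matrix(series[1L, , ], series[d[1L], , ])
  dom <- dominant_transition(tm, forest_class)
  counts <- forest_series(series, forest_class)
  iv <- change_interval(counts)
  traj <- classify_trajectory(counts, iv)
  rec <- data.frame(
    cell_id = cell_id, cell_size = cell_size,
    dom_from = NA_integer_, dom_to = NA_integer_, dom_count = NA_integer_,
    certainty = NA_real_, tie = NA, involves_forest = FALSE,
    transition_lc = NA_integer_,
    trajectory_class = traj,
    start = NA_integer_, end = NA_integer_, duration = NA_integer_,
    amount = 0, rate = NA_real_,
    forest_first = counts[1L], forest_last = counts[d[1L]],
    change_first_last = abs(counts[d[1L]] - counts[1L]),
    initial_amount = NA_real_, initial_lci = NA_real_, lci_valid = NA)
  if (!is.null(dom)) {
    rec$dom_from <- dom$from; rec$dom_to <- dom$to
    rec$dom_count <- dom$count; rec$certainty <- dom$certainty
    rec$tie <- dom$tie; rec$involves_forest <- dom$involves_forest
    rec$transition_lc <- dom$transition_lc
  }
  if (!is.null(iv)) {
    rec$start <- iv$start; rec$end <- iv$end; rec$duration <- iv$duration
    rec$amount <- amount_of_change(counts, iv, cell_size)
    rec$rate <- rate_of_change(iv)
    if (!is.null(dom) && dom$involves_forest) {
      st <- initial_state(series, iv, dom$transition_lc)
      rec$initial_amount <- st$amount
      rec$initial_lci <- st$lci
      rec$lci_valid <- st$lci_valid
    }
  }
  rec
}

#' Records for a list of cell series
#'
#' @param series_list Named list of `(year, row, col)` arrays (e.g. the
#'   `series` element of [generate_mosaic()] or [tessellate()]).
#' @param forest_class Integer code of the forest category.
#' @return Data frame with one row per cell: identifiers, dominant-transition
#'   fields (`dom_from`, `dom_to`, `dom_count`, `certainty`, `tie`,
#'   `involves_forest`, `transition_lc`), trajectory fields
#'   (`trajectory_class`, `start`, `end`, `duration`, `amount`, `rate`),
#'   first/last forest counts, and initial conditions (`initial_amount`,
#'   `initial_lci`, `lci_valid`).
#' @export
cell_records <- function(series_list, forest_class = 2L) {
  ids <- names(series_list) %||% sprintf("cell_%04d", seq_along(series_list))
  out <- do.call(rbind, lapply(seq_along(series_list), function(i)
    cell_record(series_list[[i]], ids[i], forest_class)))
  rownames(out) <- NULL
  out
}

#' Minimum-change threshold for a cell size
#'
#' The analysis keeps cells whose net forest change exceeds 5% of the cell:
#' the threshold is the smallest pixel count strictly above 5% of
#' `cell_size`, i.e. `floor(0.05 * cell_size) + 1`; 17 pixels for the
#' default 324-pixel cell (16/324 = 4.9% is still excluded).
#'
#' @param cell_size Total pixels in the cell.
#' @return Integer threshold in pixels.
#' @export
min_change_threshold <- function(cell_size = 324L) {
  as.integer(floor(0.05 * cell_size)) + 1L
}

#' Apply the exclusion filters to cell records
#'
#' Excludes cells (a) whose dominant transition does not involve forest (or
#' that show no change at all), (b) whose net forest change between the
#' first and last year is below `min_change_pixels`, (c) with non-persistent
#' trajectories, and (d) whose transition land cover is absent or fills the
#' cell at the start of the interval, making the LCI undefined.  Every
#' excluded row carries all reasons that apply, so the exclusion accounting
#' is order-independent; retained and excluded rows partition the input.
#'
#' @param records Data frame from [cell_records()] (an optional logical
#'   column `complete` from tessellation adds an `"incomplete"` reason).
#' @param min_change_pixels Minimum net forest change in pixels (default
#'   [min_change_threshold()] of the records' cell size).
#' @return List with data frames `retained` and `excluded` (the latter with
#'   a `reason` column of ;-separated reasons).
#' @export
apply_filters <- function(records,
                          min_change_pixels =
                            min_change_threshold(records$cell_size[1L])) {
  reasons <- vector("list", nrow(records))
  add <- function(idx, why) for (i in which(idx)) reasons[[i]] <<-
    c(reasons[[i]], why)
  if ("complete" %in% names(records)) add(!records$complete, "incomplete")
  add(!records$involves_forest, "non_forest_dominant")
  add(records$change_first_last < min_change_pixels, "min_change")
  add(records$trajectory_class == "non_persistent", "non_persistent")
  add(records$involves_forest &
        records$trajectory_class %in% c("persistent_loss",
                                        "persistent_gain") &
        !is.na(records$lci_valid) & !records$lci_valid, "degenerate_lci")
  drop <- vapply(reasons, function(r) length(r) > 0L, logical(1))
  excluded <- records[drop, , drop = FALSE]
  if (nrow(excluded))
    excluded$reason <- vapply(reasons[drop], paste, character(1),
                              collapse = ";")
  else excluded$reason <- character(0)
  rownames(excluded) <- NULL
  retained <- records[!drop, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, excluded = excluded)
}
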