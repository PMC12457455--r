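# Synthetic landscape generator ------------------------------------------
#
# Produces annual categorical land-cover grids with the structural properties
# the downstream analysis assumes: a focal "transition" land cover embedded
# in forest, a controllable starting amount and spatial arrangement (target
# LCI), and a forest-count trajectory with a prescribed direction, shape,
# timing and magnitude.  Forest <-> transition conversions happen at the
# class interface preferentially, so arrangements stay plausible as the
# series evolves.  Everything is deterministic given a seed.

#' Trajectory specification for a synthetic cell
#'
#' Describes how the forest pixel count of one cell evolves: the direction of
#' change, how many pixels change, when the interval of change starts, how
#' long it lasts, and its shape.
#'
#' Shapes: `"gradual"` spreads the change as evenly as possible over the
#' interval (requires `change_pixels >= duration_years` so every step changes);
#' `"abrupt"` puts all change in a single annual step (`duration_years` must
#' be 1); `"plateaued"` changes at the first and last step with zero-change
#' years in between (`duration_years >= 3`); `"mixed"` (only for
#' `direction = "non_persistent"`) loses forest in the first half of the
#' interval and regains in the second half, so both signs occur.
#'
#' @param direction One of `"none"`, `"loss"`, `"gain"`, `"non_persistent"`.
#' @param change_pixels Total number of forest pixels changed over the series
#'   (gross count for `"non_persistent"`).
#' @param start_step Index (1-based) of the last year before change begins;
#'   the first conversion happens between years `start_step` and
#'   `start_step + 1`.
#' @param duration_years Length of the interval of change in annual steps.
#' @param shape One of `"gradual"`, `"abrupt"`, `"plateaued"`, `"mixed"`.
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(direction = c("none", "loss", "gain",
                                          "non_persistent"),
                            change_pixels = 0L, start_step = 1L,
                            duration_years = 1L,
                            shape = c("gradual", "abrupt", "plateaued",
                                      "mixed")) {
  direction <- match.arg(direction)
  shape <- match.arg(shape)
  change_pixels <- as.integer(change_pixels)
  start_step <- as.integer(start_step)
  duration_years <- as.integer(duration_years)
  stopifnot(change_pixels >= 0L, duration_years >= 1L, start_step >= 1L)
  if (direction == "none") {
    change_pixels <- 0L
  } else {
    if (change_pixels < 1L) stop("change_pixels must be positive when ",
                                 "direction is not 'none'")
    if (direction == "non_persistent") {
      shape <- "mixed"
      if (change_pixels < 2L || duration_years < 2L)
        stop("non-persistent change needs change_pixels >= 2 and ",
             "duration_years >= 2")
    } else if (shape == "mixed") {
      stop("shape 'mixed' is reserved for direction 'non_persistent'")
    }
    if (shape == "abrupt" && duration_years != 1L)
      stop("abrupt change implies duration_years = 1")
    if (shape == "gradual" && change_pixels < duration_years)
      stop("gradual change needs change_pixels >= duration_years ",
           "(at least one pixel per year)")
    if (shape == "plateaued" && (duration_years < 3L || change_pixels < 2L))
      stop("plateaued change needs duration_years >= 3 and ",
           "change_pixels >= 2")
  }
  structure(list(direction = direction, change_pixels = change_pixels,
                 start_step = start_step, duration_years = duration_years,
                 shape = shape),
            class = "trajectory_spec")
}

#' Specification of one synthetic land-cover cell
#'
#' @param n_years Number of annual maps (default 29).
#' @param cell_rows,cell_cols Pixel dimensions of the cell (default 18 x 18).
#' @param forest_class,transition_class Integer category codes (defaults:
#'   IPCC forest and cropland); must differ.
#' @param initial_transition_amount Pixel count of the transition land cover
#'   in the first year.
#' @param target_lci Optional target Landscape Configuration Index in
#'   `[0, 1]` for the initial arrangement (see [arrange_binary()]).
#' @param trajectory A [trajectory_spec()].
#' @param background_classes Integer codes of static non-forest,
#'   non-transition land covers sprinkled into the initial landscape.
#' @param background_amount Number of static background pixels (default 0).
#' @param seed Integer seed controlling all randomness for this cell.
#' @param cell_id Optional identifier used by [generate_mosaic()].
#' @return An object of class `cell_spec`.
#' @export
cell_spec <- function(n_years = 29L, cell_rows = 18L, cell_cols = 18L,
                      forest_class = 2L, transition_class = 1L,
                      initial_transition_amount = 0L, target_lci = NULL,
                      trajectory = trajectory_spec("none"),
                      background_classes = integer(0),
                      background_amount = 0L, seed = NULL, cell_id = NULL) {
  stopifnot(inherits(trajectory, "trajectory_spec"),
            n_years >= 2L, cell_rows >= 2L, cell_cols >= 2L)
  n <- cell_rows * cell_cols
  if (forest_class == transition_class)
    stop("forest_class and transition_class must differ")
  if (initial_transition_amount < 0L || initial_transition_amount > n)
    stop("initial_transition_amount must be between 0 and ", n)
  if (background_amount < 0L ||
      background_amount > n - initial_transition_amount)
    stop("background_amount exceeds the pixels left by the transition LC")
  if (background_amount > 0L && length(background_classes) == 0L)
    stop("background_amount > 0 requires background_classes")
  if (any(background_classes %in% c(forest_class, transition_class)))
    stop("background_classes must differ from forest and transition classes")
  if (!is.null(target_lci) &&
      (target_lci < 0 || target_lci > 1))
    stop("target_lci must be in [0, 1]")
  tr <- trajectory
  if (tr$direction != "none" &&
      tr$start_step + tr$duration_years > n_years)
    stop("trajectory does not fit: start_step + duration_years must be ",
         "<= n_years")
  spec <- list(n_years = as.integer(n_years),
               cell_rows = as.integer(cell_rows),
               cell_cols = as.integer(cell_cols),
               forest_class = as.integer(forest_class),
               transition_class = as.integer(transition_class),
               initial_transition_amount = as.integer(initial_transition_amount),
               target_lci = target_lci, trajectory = tr,
               background_classes = as.integer(background_classes),
               background_amount = as.integer(background_amount),
               seed = seed, cell_id = cell_id)
  class(spec) <- "cell_spec"
  # feasibility of the forest / transition budget along the whole path
  d <- schedule_deltas(tr, spec$n_years)
  forest0 <- n - spec$initial_transition_amount - spec$background_amount
  fpath <- forest0 + cumsum(c(0, d))
  tpath <- spec$initial_transition_amount - cumsum(c(0, d))
  if (any(fpath < 0L))
    stop("infeasible spec: forest losses exceed available forest pixels")
  if (any(tpath < 0L))
    stop("infeasible spec: forest gains exceed available transition pixels")
  spec
}

# Signed per-step forest change (length n_years - 1).  Negative = loss
# (forest -> transition), positive = gain (transition -> forest).
schedule_deltas <- function(traj, n_years) {
  d <- integer(n_years - 1L)
  if (traj$direction == "none") return(d)
  c0 <- traj$change_pixels
  dur <- traj$duration_years
  steps <- traj$start_step:(traj$start_step + dur - 1L)
  sgn <- if (traj$direction == "loss") -1L else 1L
  if (traj$direction == "non_persistent") {
    a <- ceiling(c0 / 2); b <- c0 - a            # a losses then b gains
    d1 <- max(1L, dur %/% 2L); d2 <- dur - d1
    l <- a %/% d1; rl <- a %% d1
    loss <- -(l + as.integer(seq_len(d1) <= rl))  # remainder first
    g <- b %/% d2; rg <- b %% d2
    gain <- g + as.integer(seq_len(d2) > d2 - rg) # remainder last
    d[steps] <- c(loss, gain)
  } else if (traj$shape == "abrupt") {
    d[steps] <- sgn * c0
  } else if (traj$shape == "plateaued") {
    first <- as.integer(ceiling(c0 / 2))
    d[steps[1L]] <- sgn * first
    d[steps[dur]] <- sgn * (c0 - first)
  } else {                                        # gradual
    base <- c0 %/% dur; rem <- c0 %% dur
    d[steps] <- sgn * (base + as.integer(seq_len(dur) <= rem))
  }
  d
}

#' Arrange a binary class on a grid, optionally targeting an LCI
#'
#' Places exactly `k` focal pixels on a `rows` x `cols` grid.  Without a
#' target the placement is uniform at random.  With `target_lci` set, the
#' arrangement is searched by stochastic hill-climbing on single-pixel swaps
#' toward the unlike-adjacency corresponding to the target; the search stops
#' once the realized LCI is within `tol` of the target (or returns the
#' closest arrangement found within the iteration cap; with integer-valued
#' unlike-adjacency some targets are only approximately achievable).
#' Targets of exactly 0 or 1 return the constructed extremal arrangement.
#'
#' @param k Number of focal pixels (`0 <= k <= rows * cols`; a target LCI
#'   additionally requires `0 < k < rows * cols`).
#' @param rows,cols Grid dimensions.
#' @param target_lci Optional target in `[0, 1]`.
#' @param seed Optional integer seed (result is deterministic given it).
#' @param tol Acceptable absolute LCI deviation (default 0.05).
#' @param max_iter Hill-climbing iteration cap.
#' @return Logical mask with exactly `k` `TRUE` pixels.
#' @export
arrange_binary <- function(k, rows, cols, target_lci = NULL, seed = NULL,
                           tol = 0.05, max_iter = 5000L) {
  n <- rows * cols
  k <- as.integer(k)
  if (k < 0L || k > n) stop("k must be between 0 and rows * cols = ", n)
  if (!is.null(target_lci)) {
    if (target_lci < 0 || target_lci > 1)
      stop("target_lci must be in [0, 1]")
    if (k == 0L || k == n)
      stop("a target LCI requires 0 < k < rows * cols")
  }
  with_seed(seed, {
    mask <- matrix(FALSE, rows, cols)
    if (k == 0L) return(mask)
    if (k == n) { mask[] <- TRUE; return(mask) }
    mask[sample.int(n, k)] <- TRUE
    if (is.null(target_lci)) return(mask)
    b <- ua_bounds(k, rows, cols)
    if (b$ua_max <= b$ua_min) return(mask)   # all arrangements equivalent
    if (target_lci == 0) return(ua_extremal_mask(k, rows, cols, "min"))
    if (target_lci == 1) return(ua_extremal_mask(k, rows, cols, "max"))
    target_ua <- b$ua_min + target_lci * (b$ua_max - b$ua_min)
    ok_dev <- tol * (b$ua_max - b$ua_min)
    deg <- neighbor_degree(rows, cols)
    nbr <- neighbor_offsets(rows, cols)
    tn <- neighbor_true_counts(mask)
    ua <- unlike_adjacency(mask)
    best <- mask; best_dev <- abs(ua - target_ua)
    for (it in seq_len(max_iter)) {
      if (best_dev <= min(ok_dev, 0.5)) break
      tr <- which(mask); fa <- which(!mask)
      ps <- tr[sample.int(length(tr), min(8L, length(tr)))]
      qs <- fa[sample.int(length(fa), min(8L, length(fa)))]
      gain_rm <- 2L * tn[ps] - deg[ps]
      gain_add <- deg[qs] - 2L * tn[qs]
      dev_best <- Inf; pick <- NULL
      for (i in seq_along(ps)) {
        adj <- as.integer(qs %in% nbr[[ps[i]]])
        d <- gain_rm[i] + gain_add + 2L * adj
        j <- which.min(abs(ua + d - target_ua))
        if (abs(ua + d[j] - target_ua) < dev_best) {
          dev_best <- abs(ua + d[j] - target_ua)
          pick <- c(ps[i], qs[j], d[j])
        }
      }
      if (!is.null(pick) && dev_best < abs(ua - target_ua)) {
        p <- pick[1L]; q <- pick[2L]
        mask[p] <- FALSE; mask[q] <- TRUE
        for (x in nbr[[p]]) tn[x] <- tn[x] - 1L
        for (x in nbr[[q]]) tn[x] <- tn[x] + 1L
        ua <- ua + pick[3L]
        if (abs(ua - target_ua) < best_dev) {
          best <- mask; best_dev <- abs(ua - target_ua)
        }
      }
    }
    best
  })
}

# Convert `count` pixels of `from` into `to`, preferring pixels on the
# from/to interface (Queen-adjacent to the other class) when available.
convert_pixels <- function(grid, from, to, count) {
  if (count == 0L) return(grid)
  cand <- which(grid == from)
  if (length(cand) < count)
    stop("not enough '", from, "' pixels to convert")
  touching <- neighbor_true_counts(grid == to)[cand] > 0L
  iface <- cand[touching]
  pick <- iface[sample.int(length(iface), min(count, length(iface)))]
  if (length(pick) < count) {
    rest <- setdiff(cand, pick)
    pick <- c(pick, rest[sample.int(length(rest), count - length(pick))])
  }
  grid[pick] <- to
  grid
}

#' Generate the annual land-cover series of one synthetic cell
#'
#' Builds `n_years` categorical grids.  The first year carries exactly
#' `initial_transition_amount` transition-class pixels (arranged per
#' `target_lci` when set) plus optional static background pixels; all other
#' pixels are forest.  Forest counts then follow the cell's
#' [trajectory_spec()] exactly, through forest <-> transition conversions
#' placed preferentially at the class interface.
#'
#' @param spec A [cell_spec()].
#' @return An object of class `lc_series`: integer array with dimensions
#'   `(year, row, col)`, with the spec attached as attribute `"spec"`.
#' @export
generate_lc_series <- function(spec) {
  stopifnot(inherits(spec, "cell_spec"))
  r <- spec$cell_rows; c <- spec$cell_cols; n <- r * c
  with_seed(spec$seed, {
    mask <- arrange_binary(spec$initial_transition_amount, r, c,
                           target_lci = spec$target_lci)
    grid <- matrix(spec$forest_class, r, c)
    grid[mask] <- spec$transition_class
    if (spec$background_amount > 0L) {
      free <- which(!mask)
      bg <- free[sample.int(length(free), spec$background_amount)]
      grid[bg] <- spec$background_classes[
        1L + (seq_along(bg) - 1L) %% length(spec$background_classes)]
    }
    deltas <- schedule_deltas(spec$trajectory, spec$n_years)
    arr <- array(NA_integer_, dim = c(spec$n_years, r, c))
    arr[1L, , ] <- grid
    for (t in seq_len(spec$n_years - 1L)) {
      d <- deltas[t]
      if (d < 0L)
        grid <- convert_pixels(grid, spec$forest_class,
                               spec$transition_class, -d)
      else if (d > 0L)
        grid <- convert_pixels(grid, spec$transition_class,
                               spec$forest_class, d)
      arr[t + 1L, , ] <- grid
    }
    structure(arr, class = "lc_series", spec = spec)
  })
}

#' Generate a mosaic of synthetic cells
#'
#' @param cell_specs Non-empty list of [cell_spec()] objects.  Cells without
#'   their own seed receive one drawn deterministically from `seed`.
#' @param seed Integer master seed for the mosaic.
#' @return A list of class `lc_mosaic` with elements `series` (named list of
#'   `lc_series`) and `meta` (data frame of the generating parameters, one
#'   row per cell).
#' @export
generate_mosaic <- function(cell_specs, seed = NULL) {
  stopifnot(is.list(cell_specs), length(cell_specs) > 0L)
  ids <- vapply(seq_along(cell_specs), function(i)
    cell_specs[[i]]$cell_id %||% names(cell_specs)[i] %||%
      sprintf("cell_%04d", i), character(1))
  ids[ids == ""] <- sprintf("cell_%04d", which(ids == ""))
  if (anyDuplicated(ids))
    stop("duplicate cell identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  with_seed(seed, {
    cell_seeds <- sample.int(.Machine$integer.max, length(cell_specs))
    series <- vector("list", length(cell_specs))
    for (i in seq_along(cell_specs)) {
      sp <- cell_specs[[i]]
      if (is.null(sp$seed)) sp$seed <- cell_seeds[i]
      sp$cell_id <- ids[i]
      series[[i]] <- generate_lc_series(sp)
      cell_specs[[i]] <- sp
    }
    names(series) <- ids
    meta <- do.call(rbind, lapply(cell_specs, function(sp)
      data.frame(cell_id = sp$cell_id,
                 direction = sp$trajectory$direction,
                 shape = sp$trajectory$shape,
                 change_pixels = sp$trajectory$change_pixels,
                 start_step = sp$trajectory$start_step,
                 duration_years = sp$trajectory$duration_years,
                 initial_transition_amount = sp$initial_transition_amount,
                 target_lci = sp$target_lci %||% NA_real_,
                 forest_class = sp$forest_class,
                 transition_class = sp$transition_class,
                 n_years = sp$n_years, seed = sp$seed)))
    rownames(meta) <- NULL
    structure(list(series = series, meta = meta), class = "lc_mosaic")
  })
}

#' Perturb a land-cover series with symmetric misclassification noise
#'
#' Independently relabels each pixel-year, with probability `rate`, to a
#' different class drawn uniformly from `classes`.  This is a one-parameter
#' stand-in for classification uncertainty, sufficient to probe whether the
#' direction of downstream relationships survives label noise.
#'
#' @param series An `lc_series` (or any integer array/matrix of class codes).
#' @param rate Per-pixel-year misclassification probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @param classes Integer code universe to draw replacement labels from;
#'   defaults to the eight IPCC categories ([ipcc_classes()]).  Every label
#'   in `series` must be a member.
#' @return A perturbed copy of `series` (attributes preserved).
#' @export
apply_misclassification <- function(series, rate, seed = NULL,
                                    classes = ipcc_classes()) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  classes <- as.integer(classes)
  vals <- as.integer(series)
  if (!all(vals %in% classes))
    stop("series contains codes outside `classes`")
  if (length(classes) < 2L) stop("need at least two classes to relabel")
  with_seed(seed, {
    flip <- which(runif(length(vals)) < rate)
    if (length(flip)) {
      pos <- match(vals[flip], classes)
      u <- 1L + as.integer(floor(runif(length(flip)) * (length(classes) - 1L)))
      vals[flip] <- classes[u + (u >= pos)]
    }
    out <- series
    out[] <- vals
    out
  })
}

#' Random persistent cell specifications
#'
#' Draws feasible random [cell_spec()]s with persistent loss or gain
#' trajectories, useful for parameter-recovery experiments and demo mosaics.
#' Change magnitudes, interval timing, initial amounts and shapes are sampled
#' within feasible ranges; all cells have a valid (non-degenerate) transition
#' amount at the start of the interval.
#'
#' @param n Number of specs.
#' @param seed Integer seed.
#' @param direction `"loss"`, `"gain"`, or `"both"` (alternating).
#' @param n_years,cell_rows,cell_cols Cell geometry (defaults 29, 18, 18).
#' @param min_change,max_change Range of `change_pixels` (defaults 17, 80).
#' @param transition_classes Pool of non-forest category codes each cell's
#'   transition land cover is drawn from (default: all seven non-forest
#'   IPCC categories).
#' @return List of `cell_spec` objects.
#' @export
random_cell_specs <- function(n, seed = NULL,
                              direction = c("both", "loss", "gain"),
                              n_years = 29L, cell_rows = 18L,
                              cell_cols = 18L, min_change = 17L,
                              max_change = 80L,
                              transition_classes =
                                setdiff(ipcc_classes(),
                                        ipcc_classes()[["forest"]])) {
  direction <- match.arg(direction)
  npix <- cell_rows * cell_cols
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      dir <- switch(direction, both = c("loss", "gain")[1L + i %% 2L],
                    direction)
      tc <- transition_classes[sample.int(length(transition_classes), 1L)]
      change <- sample(min_change:max_change, 1L)
      abrupt <- runif(1) < 0.3
      dur <- if (abrupt) 1L else
        sample(2L:min(change, n_years - 2L), 1L)
      start <- sample.int(n_years - dur, 1L)
      k0 <- if (dir == "loss")
        sample(20L:(npix - change - 20L), 1L) else
        sample((change + 1L):(npix - 40L), 1L)
      cell_spec(n_years = n_years, cell_rows = cell_rows,
                cell_cols = cell_cols,
                transition_class = tc,
                initial_transition_amount = k0,
                trajectory = trajectory_spec(
                  dir, change_pixels = change, start_step = start,
                  duration_years = dur,
                  shape = if (abrupt) "abrupt" else "gradual"),
                seed = sample.int(.Machine$integer.max, 1L))
    })
  })
}
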