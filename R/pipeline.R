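# End-to-end pipeline ----------------------------------------------------

#' Read a pipeline run configuration
#'
#' Loads a YAML run configuration.  Recognized fields: `seed`,
#' `min_change_pixels`, `basis_dim`, `forest_class`, `out_dir`, and a
#' `synthetic` block (`n_loss`, `n_gain`, `n_years`, `cell_pixels`,
#' `min_change`, `max_change`) describing a random mosaic to generate.
#'
#' @param path YAML file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

# Polynomial rolling hash of a serialized R object (stable run fingerprint).
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

ipcc_name <- function(code) {
  ic <- ipcc_classes()
  nm <- names(ic)[match(code, ic)]
  ifelse(is.na(nm), as.character(code), nm)
}

#' Run the forest-change trajectory pipeline
#'
#' Orchestrates the full analysis: per-cell records (dominant transition,
#' interval, persistence class, amount, relative rate, initial conditions),
#' exclusion filters, group summaries and pairwise Cliff's deltas of amount
#' and rate by transition land cover, and penalized smooth-effect models of
#' mean amount/rate against the initial amount and initial LCI of the
#' transition land cover.  Outputs are deterministic given the seed.
#'
#' Input is one of: a list of per-cell series, a list of [cell_spec()]s (a
#' synthetic mosaic is generated), or a `config` (list or YAML path, see
#' [read_run_config()]) whose `synthetic` block requests a random mosaic.
#'
#' @param series_list Named list of `(year, row, col)` arrays.
#' @param specs List of [cell_spec()] objects.
#' @param config List or YAML path.
#' @param out_dir Optional output directory; when set, all tables are
#'   written as CSV plus a `manifest.json`.
#' @param min_change_pixels Minimum net forest change filter (default:
#'   [min_change_threshold()] of the cell size).
#' @param basis_dim Basis cap for the smooth-effect models (default 4).
#' @param grid_n Evaluation grid size for smooth summaries (default 200).
#' @param min_group_n Minimum retained cells for a group to be modelled
#'   (default 30).
#' @param lci_cap Interpretation cap for LCI effects (default 0.6): the
#'   share of cells above the cap is reported per model as
#'   `prop_lci_gt_cap`; fitting is not constrained.
#' @param forest_class Integer forest category code (default 2).
#' @param seed Master seed for synthetic generation.
#' @return List of class `ft_pipeline` with elements `records`, `retained`,
#'   `excluded`, `summaries`, `deltas`, `effects`, `manifest`.
#' @export
run_pipeline <- function(series_list = NULL, specs = NULL, config = NULL,
                         out_dir = NULL, min_change_pixels = NULL,
                         basis_dim = 4L, grid_n = 200L, min_group_n = 30L,
                         lci_cap = 0.6, forest_class = 2L, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (!is.null(config)) {
    seed <- seed %||% config$seed
    min_change_pixels <- min_change_pixels %||% config$min_change_pixels
    basis_dim <- config$basis_dim %||% basis_dim
    forest_class <- config$forest_class %||% forest_class
    out_dir <- out_dir %||% config$out_dir
    if (is.null(series_list) && is.null(specs) &&
        !is.null(config$synthetic)) {
      sy <- config$synthetic
      specs <- c(
        random_cell_specs(sy$n_loss %||% 20L, seed = (seed %||% 1L),
                          direction = "loss",
                          n_years = sy$n_years %||% 29L,
                          cell_rows = sy$cell_pixels %||% 18L,
                          cell_cols = sy$cell_pixels %||% 18L,
                          min_change = sy$min_change %||% 17L,
                          max_change = sy$max_change %||% 80L),
        random_cell_specs(sy$n_gain %||% 20L, seed = (seed %||% 1L) + 1L,
                          direction = "gain",
                          n_years = sy$n_years %||% 29L,
                          cell_rows = sy$cell_pixels %||% 18L,
                          cell_cols = sy$cell_pixels %||% 18L,
                          min_change = sy$min_change %||% 17L,
                          max_change = sy$max_change %||% 80L))
    }
  }
  mosaic_meta <- NULL
  if (is.null(series_list)) {
    if (is.null(specs)) stop("provide series_list, specs, or a config with ",
                             "a synthetic block")
    mosaic <- generate_mosaic(specs, seed = seed)
    series_list <- mosaic$series
    mosaic_meta <- mosaic$meta
  }
  records <- cell_records(series_list, forest_class)
  if (is.null(min_change_pixels))
    min_change_pixels <- min_change_threshold(records$cell_size[1L])
  filt <- apply_filters(records, min_change_pixels)
  retained <- filt$retained
  if (nrow(retained)) {
    retained$direction <- sub("persistent_", "", retained$trajectory_class)
    retained$transition_lc_name <- ipcc_name(retained$transition_lc)
  }
  summaries <- NULL; deltas <- NULL; effects <- NULL
  if (nrow(retained) == 0L) {
    warning("no cells retained after filtering; statistical stages skipped")
  } else {
    responses <- c(amount = "amount", rate = "rate")
    predictors <- c(initial_amount = "initial_amount",
                    initial_lci = "initial_lci")
    summaries <- do.call(rbind, lapply(unique(retained$direction),
                                       function(dir) {
      sub <- retained[retained$direction == dir, ]
      do.call(rbind, lapply(names(responses), function(resp) {
        s <- summarize_groups(sub[[responses[[resp]]]],
                              sub$transition_lc_name)
        cbind(direction = dir, response = resp, s)
      }))
    }))
    deltas <- do.call(rbind, lapply(unique(retained$direction),
                                    function(dir) {
      sub <- retained[retained$direction == dir, ]
      if (length(unique(sub$transition_lc_name)) < 2L) return(NULL)
      do.call(rbind, lapply(names(responses), function(resp) {
        d <- pairwise_cliffs_delta(sub[[responses[[resp]]]],
                                   sub$transition_lc_name)
        cbind(direction = dir, response = resp, d)
      }))
    }))
    eff <- list()
    for (dir in unique(retained$direction)) {
      sub <- retained[retained$direction == dir, ]
      for (g in unique(sub$transition_lc_name)) {
        gs <- sub[sub$transition_lc_name == g, ]
        if (nrow(gs) < min_group_n) next
        for (p in names(predictors)) for (resp in names(responses)) {
          xv <- gs[[predictors[[p]]]]; yv <- gs[[responses[[resp]]]]
          fit <- tryCatch(fit_smooth(xv, yv, basis_dim, predictor = p,
                                     response = resp),
                          error = function(e) NULL)
          if (is.null(fit)) next
          su <- summarize_fit(fit, grid_n)
          eff[[length(eff) + 1L]] <- data.frame(
            direction = dir, transition_lc = g, predictor = p,
            response = resp, n = nrow(gs), edf = su$edf,
            null_dev_prop = su$null_dev_prop, argmax_x = su$argmax_x,
            argmin_x = su$argmin_x, mean_rate = su$mean_rate,
            mean_abs_rate = su$mean_abs_rate,
            prop_lci_gt_cap = mean(gs$initial_lci > lci_cap, na.rm = TRUE))
        }
      }
    }
    effects <- if (length(eff)) do.call(rbind, eff) else NULL
  }
  reason_counts <- if (nrow(filt$excluded))
    table(unlist(strsplit(filt$excluded$reason, ";"))) else table(character(0))
  manifest <- list(
    package_version = as.character(utils::packageVersion("foresttraj")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed, min_change_pixels = min_change_pixels,
    basis_dim = basis_dim, grid_n = grid_n, lci_cap = lci_cap,
    config_hash = config_hash(list(config = config,
                                   min_change_pixels = min_change_pixels,
                                   basis_dim = basis_dim, seed = seed)),
    n_cells = nrow(records),
    n_forest_dominant = sum(records$involves_forest),
    n_persistent = sum(records$trajectory_class %in%
                         c("persistent_loss", "persistent_gain")),
    n_retained = nrow(retained),
    n_excluded = nrow(filt$excluded),
    exclusions_by_reason = as.list(reason_counts))
  out <- structure(list(records = records, retained = retained,
                        excluded = filt$excluded, summaries = summaries,
                        deltas = deltas, effects = effects,
                        mosaic_meta = mosaic_meta, manifest = manifest),
                   class = "ft_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir, series_list)
  out
}

write_pipeline_outputs <- function(result, out_dir, series_list) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) if (!is.null(df))
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wr(result$records, "records.csv")
  wr(result$retained, "retained.csv")
  wr(result$excluded, "excluded.csv")
  wr(result$summaries, "group_summaries.csv")
  wr(result$deltas, "cliffs_delta.csv")
  wr(result$effects, "smooth_effects.csv")
  wr(result$mosaic_meta, "mosaic_meta.csv")
  d <- dim(series_list[[1L]])
  write_ua_bounds_table(file.path(out_dir, "ua_bounds.csv"), d[2L], d[3L])
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.ft_pipeline <- function(x, ...) {
  m <- x$manifest
  cat("forest-change trajectory pipeline run\n")
  cat(sprintf("  cells: %d total | %d forest-dominant | %d persistent | %d retained\n",
              m$n_cells, m$n_forest_dominant, m$n_persistent, m$n_retained))
  if (length(m$exclusions_by_reason))
    cat("  exclusions:",
        paste(sprintf("%s = %s", names(m$exclusions_by_reason),
                      unlist(m$exclusions_by_reason)), collapse = ", "),
        "\n")
  if (!is.null(x$effects))
    cat(sprintf("  smooth-effect models fitted: %d\n", nrow(x$effects)))
  invisible(x)
}
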