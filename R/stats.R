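# Group summaries and non-parametric effect sizes ------------------------

#' Group-level summary statistics
#'
#' Summarizes a per-cell metric by group: sample size, quartiles (linear
#' interpolation, R's default type-7 definition), mean, standard deviation,
#' and the divergence of each group mean from the pooled mean over all
#' groups (`mean_diff = group mean - global mean`).
#'
#' @param values Numeric vector of the metric (e.g. amount or rate of
#'   forest change).
#' @param groups Vector of group labels, same length as `values`.
#' @return Data frame with one row per non-empty group: `group`, `n`, `q1`,
#'   `median`, `mean`, `q3`, `sd`, `mean_diff`.  Empty groups are dropped
#'   with a warning.
#' @export
summarize_groups <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  all_levels <- if (is.factor(groups)) levels(groups) else
    unique(as.character(groups[!is.na(groups)]))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups[keep])
  if (!length(values)) stop("no non-missing observations")
  global_mean <- mean(values)
  lv <- unique(groups)
  empty <- setdiff(all_levels, lv)
  if (length(empty))
    warning("omitting empty group(s): ", paste(empty, collapse = ", "))
  out <- do.call(rbind, lapply(lv, function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v),
               q1 = unname(quantile(v, 0.25)),
               median = unname(quantile(v, 0.5)),
               mean = mean(v),
               q3 = unname(quantile(v, 0.75)),
               sd = if (length(v) > 1L) sd(v) else 0,
               mean_diff = mean(v) - global_mean)
  }))
  rownames(out) <- NULL
  out[order(out$group), , drop = FALSE]
}

#' Cliff's delta effect size
#'
#' The probability-based effect size
#' `delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (n_x * n_y)`,
#' in `[-1, 1]`: values near +/-1 indicate minimal overlap between the two
#' distributions, values near 0 near-complete overlap; ties contribute zero.
#' The confidence interval uses Cliff's consistent asymptotic variance with
#' the usual asymmetric transformation, which keeps the interval inside
#' `[-1, 1]` and collapses toward the point estimate in the degenerate
#' complete-separation case.
#'
#' Computation is counting-based (sort + `findInterval`), so large samples
#' are handled without forming the n_x by n_y dominance matrix.
#'
#' @param x,y Non-empty numeric samples.
#' @param conf.level Confidence level (default 0.95).
#' @return An object of class `effect_size`: list with `delta`, `ci_low`,
#'   `ci_high`, `n_x`, `n_y`, `conf.level`.
#' @examples
#' cliffs_delta(c(4, 5), c(1, 2))$delta  # 1: complete separation
#' @export
cliffs_delta <- function(x, y, conf.level = 0.95) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both samples must be non-empty")
  sy <- sort(y)
  lt_y <- findInterval(x, sy, left.open = TRUE)   # per x_i: #{y_j < x_i}
  le_y <- findInterval(x, sy)                     # per x_i: #{y_j <= x_i}
  di <- (lt_y - (n2 - le_y)) / n2                 # row dominance means
  sx <- sort(x)
  lt_x <- findInterval(y, sx, left.open = TRUE)
  le_x <- findInterval(y, sx)
  dj <- ((n1 - le_x) - lt_x) / n1                 # column dominance means
  d <- sum(di) / n1
  ties <- sum(le_y - lt_y)                        # tied pairs
  sum_dij_sq <- n1 * n2 - ties                    # d_ij in {-1, 0, 1}
  z <- qnorm(1 - (1 - conf.level) / 2)
  if (n1 > 1L && n2 > 1L) {
    s2 <- (n2^2 * sum((di - d)^2) + n1^2 * sum((dj - d)^2) -
             (sum_dij_sq - n1 * n2 * d^2)) /
      (n1 * n2 * (n1 - 1) * (n2 - 1))
    s2 <- max(s2, 0)
    den <- 1 - d^2 + z^2 * s2
    if (den <= 0) {
      ci <- c(d, d)   # complete separation: interval collapses to the point
    } else {
      half <- z * sqrt(s2) * sqrt((1 - d^2)^2 + z^2 * s2)
      ci <- c((d - d^3 - half) / den, (d - d^3 + half) / den)
    }
  } else {
    ci <- c(-1, 1)
  }
  structure(list(delta = d, ci_low = max(-1, min(ci, d)),
                 ci_high = min(1, max(ci, d)), n_x = n1, n_y = n2,
                 conf.level = conf.level),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Cliff's delta = %.3f [%.3f, %.3f] (n = %d vs %d, %.0f%%)\n",
              x$delta, x$ci_low, x$ci_high, x$n_x, x$n_y,
              100 * x$conf.level))
  invisible(x)
}

#' Pairwise Cliff's delta matrix
#'
#' @param values Numeric metric vector.
#' @param groups Group labels.
#' @param conf.level Confidence level passed to [cliffs_delta()].
#' @return Data frame of all ordered group pairs with `delta`, `ci_low`,
#'   `ci_high` and sample sizes.
#' @export
pairwise_cliffs_delta <- function(values, groups, conf.level = 0.95) {
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  pairs <- which(upper.tri(matrix(0, length(lv), length(lv))), arr.ind = TRUE)
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    a <- lv[pairs[i, 1L]]; b <- lv[pairs[i, 2L]]
    es <- cliffs_delta(values[groups == a], values[groups == b], conf.level)
    data.frame(group_x = a, group_y = b, delta = es$delta,
               ci_low = es$ci_low, ci_high = es$ci_high,
               n_x = es$n_x, n_y = es$n_y)
  }))
  out
}
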