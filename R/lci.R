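#' Landscape Configuration Index
#'
#' Normalizes an observed unlike-adjacency against the theoretical minimum
#' and maximum attainable with the same number of focal pixels:
#' `LCI = (UA_obs - UA_min) / (UA_max - UA_min)`.  A value of 0 corresponds
#' to a maximally compact arrangement of the focal class, 1 to maximum
#' fragmentation.
#'
#' When the focal class is absent or fills the whole grid the bounds collapse
#' (`UA_min = UA_max = 0`) and no configuration can be distinguished; the
#' index is then undefined and `NA` is returned (cells in this state are
#' excluded downstream as degenerate).
#'
#' @param ua_obs Observed unlike-adjacency (integer, see
#'   [unlike_adjacency()]).
#' @param bounds A `ua_bounds` object from [ua_bounds()] (or any list with
#'   `ua_min`/`ua_max` elements).
#' @return Numeric LCI in `[0, 1]`, or `NA_real_` for degenerate bounds.
#' @examples
#' b <- ua_bounds(9, 6, 6)
#' lci(b$ua_min, b)  # 0: compact block
#' lci(b$ua_max, b)  # 1: maximal fragmentation
#' @export
lci <- function(ua_obs, bounds) {
  if (bounds$ua_max <= bounds$ua_min) return(NA_real_)
  (ua_obs - bounds$ua_min) / (bounds$ua_max - bounds$ua_min)
}

# LCI of a binary mask, using (cached) bounds for its dimensions.
mask_lci <- function(mask) {
  lci(unlike_adjacency(mask), ua_bounds(sum(mask), nrow(mask), ncol(mask)))
}
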