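# Independent brute-force oracles used to certify the implementation.
# These deliberately share no code with the package internals.

# Mixed Queen-adjacent pairs by explicit enumeration over all pixels and
# all 8 neighbour offsets (each unordered pair visited twice, so halve).
ua_oracle <- function(mask) {
  r <- nrow(mask); c <- ncol(mask)
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  total <- 0L
  for (i in seq_len(r)) for (j in seq_len(c)) {
    for (o in seq_len(8L)) {
      ii <- i + offs[o, 1L]; jj <- j + offs[o, 2L]
      if (ii >= 1L && ii <= r && jj >= 1L && jj <= c &&
          mask[i, j] != mask[ii, jj])
        total <- total + 1L
    }
  }
  total %/% 2L
}

# Exact UA range over all C(n, k) placements, via the oracle above.
ua_range_oracle <- function(rows, cols, k) {
  n <- rows * cols
  if (k == 0L || k == n) return(c(0L, 0L))
  cmb <- utils::combn(n, k)
  vals <- apply(cmb, 2L, function(ix) {
    m <- matrix(FALSE, rows, cols); m[ix] <- TRUE
    ua_oracle(m)
  })
  range(vals)
}

# Cliff's delta by explicit double-loop pair counting.
cliff_brute <- function(x, y) {
  s <- 0
  for (a in x) for (b in y) s <- s + sign(a - b)
  s / (length(x) * length(y))
}

random_mask <- function(rows, cols, k) {
  m <- matrix(FALSE, rows, cols)
  m[sample.int(rows * cols, k)] <- TRUE
  m
}
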