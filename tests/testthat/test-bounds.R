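test_that("bounds are exact and trivial at the degenerate pixel counts", {
  for (k in c(0L, 324L)) {
    b <- ua_bounds(k, 18, 18)
    expect_identical(b$ua_min, 0L)
    expect_identical(b$ua_max, 0L)
  }
  expect_error(ua_bounds(-1, 18, 18))
  expect_error(ua_bounds(325, 18, 18))
})

test_that("a single pixel ranges from corner (3) to core (8) adjacency", {
  b <- ua_bounds(1, 18, 18)
  expect_identical(b$ua_min, 3L)
  expect_identical(b$ua_max, 8L)
})

test_that("constructive minima match exhaustive enumeration on small grids", {
  ex <- foresttraj:::build_exhaustive_table(4, 4)$table
  co <- foresttraj:::build_constructive_table(4, 4)$table
  expect_identical(co$ua_min, ex$ua_min)
  # constructive maxima may be conservative near half-filling but can never
  # exceed the exhaustive optimum, and must stay attainable
  expect_true(all(co$ua_max <= ex$ua_max))
  expect_true(all(co$ua_max >= ex$ua_max - 1L))
})

test_that("extremal arrangements attain the tabulated bounds", {
  tb <- ua_bounds_table(18, 18)
  for (k in c(1, 7, 40, 100, 162, 250, 323)) {
    mn <- ua_extremal_mask(k, 18, 18, "min")
    mx <- ua_extremal_mask(k, 18, 18, "max")
    expect_identical(sum(mn), as.integer(k))
    expect_identical(sum(mx), as.integer(k))
    expect_identical(unlike_adjacency(mn), tb$ua_min[k + 1])
    expect_identical(unlike_adjacency(mx), tb$ua_max[k + 1])
  }
})

test_that("bounds are symmetric under complementation of the focal class", {
  tb <- ua_bounds_table(18, 18)
  expect_identical(tb$ua_min, rev(tb$ua_min))
  expect_identical(tb$ua_max, rev(tb$ua_max))
})

test_that("random arrangements never escape the bounds", {
  tb <- ua_bounds_table(18, 18)
  set.seed(303)
  for (k in c(3, 20, 81, 162, 243, 310)) {
    for (i in 1:300) {
      ua <- unlike_adjacency(random_mask(18, 18, k))
      expect_gte(ua, tb$ua_min[k + 1])
      expect_lte(ua, tb$ua_max[k + 1])
    }
  }
})

test_that("the bounds table round-trips through its CSV form", {
  path <- tempfile(fileext = ".csv")
  write_ua_bounds_table(path, 4, 4)
  tab <- read.csv(path)
  expect_identical(tab$k, 0:16)
  expect_identical(as.integer(tab$ua_min), ua_bounds_table(4, 4)$ua_min)
})
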