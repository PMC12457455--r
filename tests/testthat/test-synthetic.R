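test_that("trajectory and cell specs validate their invariants", {
  expect_error(trajectory_spec("loss", 0), "positive")
  expect_error(trajectory_spec("loss", 30, duration_years = 2,
                               shape = "abrupt"), "duration_years = 1")
  expect_error(trajectory_spec("loss", 3, duration_years = 10,
                               shape = "gradual"), "gradual")
  expect_error(trajectory_spec("loss", 5, duration_years = 2,
                               shape = "mixed"), "reserved")
  expect_error(cell_spec(forest_class = 1L, transition_class = 1L),
               "must differ")
  expect_error(cell_spec(initial_transition_amount = 400), "between 0 and")
  # trajectory must fit the series
  expect_error(cell_spec(n_years = 10, initial_transition_amount = 50,
                         trajectory = trajectory_spec("loss", 20,
                                                      start_step = 5,
                                                      duration_years = 6)),
               "does not fit")
  # infeasible budgets
  expect_error(cell_spec(initial_transition_amount = 320,
                         trajectory = trajectory_spec("loss", 30,
                                                      duration_years = 1,
                                                      shape = "abrupt")),
               "exceed available forest")
  expect_error(cell_spec(initial_transition_amount = 10,
                         trajectory = trajectory_spec("gain", 30,
                                                      duration_years = 1,
                                                      shape = "abrupt")),
               "exceed available transition")
})

test_that("every generated year carries a full complement of labels", {
  sp <- cell_spec(initial_transition_amount = 80,
                  background_classes = c(3L, 8L), background_amount = 20L,
                  trajectory = trajectory_spec("loss", 40,
                                               duration_years = 10),
                  seed = 1)
  s <- generate_lc_series(sp)
  expect_identical(dim(s), c(29L, 18L, 18L))
  expect_false(anyNA(s))
  expect_true(all(apply(s, 1, length) == 324))
  # background pixels are static
  bg_mask <- s[1, , ] %in% c(3L, 8L)
  expect_identical(sum(bg_mask), 20L)
  for (t in c(10, 29)) expect_true(all(s[t, , ][bg_mask] == s[1, , ][bg_mask]))
})

test_that("a no-change spec yields identical grids every year", {
  sp <- cell_spec(initial_transition_amount = 50, seed = 2)
  s <- generate_lc_series(sp)
  for (t in 2:29) expect_identical(s[t, , ], s[1, , ])
})

test_that("gradual persistent loss decreases forest evenly, one per year", {
  sp <- cell_spec(n_years = 31, initial_transition_amount = 60,
                  trajectory = trajectory_spec("loss", 30, start_step = 1,
                                               duration_years = 30,
                                               shape = "gradual"),
                  seed = 3)
  fc <- forest_series(generate_lc_series(sp))
  expect_true(all(diff(fc) == -1L))
  expect_identical(fc[1] - fc[31], 30L)
})

test_that("non-persistent series show both a loss and a gain", {
  sp <- cell_spec(initial_transition_amount = 100,
                  trajectory = trajectory_spec("non_persistent", 40,
                                               start_step = 4,
                                               duration_years = 12),
                  seed = 4)
  fc <- forest_series(generate_lc_series(sp))
  expect_true(any(diff(fc) > 0))
  expect_true(any(diff(fc) < 0))
})

test_that("the first year matches the requested amount and arrangement", {
  sp <- cell_spec(initial_transition_amount = 90, target_lci = 0.2, seed = 5)
  s <- generate_lc_series(sp)
  mask <- s[1, , ] == sp$transition_class
  expect_identical(sum(mask), 90L)
  realized <- lci(unlike_adjacency(mask), ua_bounds(90, 18, 18))
  expect_lt(abs(realized - 0.2), 0.05 + 1e-9)
})

test_that("mosaics are reproducible and reject duplicate identifiers", {
  specs <- random_cell_specs(6, seed = 10)
  m1 <- generate_mosaic(specs, seed = 99)
  m2 <- generate_mosaic(specs, seed = 99)
  expect_identical(m1$series, m2$series)
  expect_identical(m1$meta, m2$meta)
  specs2 <- lapply(specs, function(s) { s$cell_id <- "same"; s })
  expect_error(generate_mosaic(specs2, seed = 1), "duplicate")
})

test_that("misclassification noise behaves like a binomial relabel", {
  sp <- cell_spec(initial_transition_amount = 80,
                  trajectory = trajectory_spec("loss", 30,
                                               duration_years = 5),
                  seed = 6)
  s <- generate_lc_series(sp)
  expect_identical(unclass(apply_misclassification(s, 0, seed = 1))[],
                   unclass(s)[])
  expect_true(all(apply_misclassification(s, 1, seed = 1) != s))
  rate <- 0.1
  n <- length(s)
  noisy <- apply_misclassification(s, rate, seed = 7)
  frac <- mean(noisy != s)
  expect_lt(abs(frac - rate), 3 * sqrt(rate * (1 - rate) / n))
  expect_error(apply_misclassification(s, 1.2), "rate")
})
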