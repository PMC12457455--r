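test_that("the change interval brackets first and last change", {
  expect_null(change_interval(rep(100L, 10)))
  iv <- change_interval(seq(100L, 70L, by = -1L))  # 31 values
  expect_identical(c(iv$start, iv$end, iv$duration), c(1L, 31L, 30L))
  iv2 <- change_interval(c(100L, 100L, 70L, 70L))
  expect_identical(c(iv2$start, iv2$end, iv2$duration), c(2L, 3L, 1L))
  # leading/trailing plateaus are outside the interval
  iv3 <- change_interval(c(5L, 5L, 5L, 4L, 3L, 3L, 2L, 2L, 2L))
  expect_identical(c(iv3$start, iv3$end), c(3L, 7L))
})

test_that("relative rate is the reciprocal duration", {
  mk <- function(d) structure(list(start = 1L, end = 1L + d, duration = d),
                              class = "change_interval")
  expect_equal(rate_of_change(mk(30L)), 1 / 30)
  expect_equal(rate_of_change(mk(1L)), 1)
  expect_equal(rate_of_change(mk(28L)), 1 / 28)
})

test_that("persistence classification honours plateaus and reversals", {
  expect_identical(classify_trajectory(c(10L, 9L, 8L, 7L)),
                   "persistent_loss")
  expect_identical(classify_trajectory(c(7L, 8L, 9L)), "persistent_gain")
  expect_identical(classify_trajectory(c(10L, 8L, 9L, 9L)),
                   "non_persistent")
  # interior zero-change years do not break persistence
  expect_identical(classify_trajectory(c(10L, 8L, 8L, 8L, 6L)),
                   "persistent_loss")
  expect_identical(classify_trajectory(rep(4L, 6)), "no_change")
})

test_that("amount of change is the interval endpoint difference", {
  counts <- c(rep(100L, 3), 90L, 80L, 70L, rep(70L, 4))
  iv <- change_interval(counts)
  expect_equal(amount_of_change(counts, iv, 324L), 30 / 324)
  expect_equal(amount_of_change(rep(5L, 4), NULL, 324L), 0)
  expect_equal(amount_of_change(c(0L, 324L), change_interval(c(0L, 324L)),
                                324L), 1)
})

test_that("initial state captures amount and LCI at the interval start", {
  sp <- cell_spec(initial_transition_amount = 189, target_lci = 0,
                  trajectory = trajectory_spec("loss", 30, start_step = 3,
                                               duration_years = 5),
                  seed = 8)
  s <- generate_lc_series(sp)
  iv <- change_interval(forest_series(s))
  st <- initial_state(s, iv, sp$transition_class)
  expect_equal(st$amount, 189 / 324)
  expect_true(st$lci_valid)
  expect_lt(st$lci, 0.05)
  # absent transition LC at the start -> invalid LCI
  sp2 <- cell_spec(initial_transition_amount = 0,
                   trajectory = trajectory_spec("loss", 30,
                                                duration_years = 5),
                   seed = 9)
  s2 <- generate_lc_series(sp2)
  st2 <- initial_state(s2, change_interval(forest_series(s2)), 1L)
  expect_false(st2$lci_valid)
  expect_true(is.na(st2$lci))
})

test_that("pixel areas follow spherical geometry", {
  # 3 arc-minute cell on the equator: edge ~5.56 km, pixel ~0.095 km2
  pa <- pixel_area(c(0, 0.05, -0.025, 0.025), 18, 18)
  expect_equal(pa$pixel_width_km, 5.56 / 18, tolerance = 0.01)
  expect_equal(pa$pixel_area_km2, (5.56 / 18)^2, tolerance = 0.02)
  # at 60 N the pixel width halves (cos-latitude scaling)
  pa60 <- pixel_area(c(0, 0.05, 59.975, 60.025), 18, 18)
  expect_equal(pa60$pixel_width_km / pa$pixel_width_km, 0.5,
               tolerance = 0.01)
  expect_error(pixel_area(c(0, 0, 0, 0), 18, 18), "degenerate")
  expect_error(pixel_area(c(0, 0.05, 89.99, 91), 18, 18), "latitude")
})

test_that("recovery: noise-free synthetic cells reproduce their spec", {
  specs <- random_cell_specs(40, seed = 77)
  mos <- generate_mosaic(specs, seed = 78)
  recs <- cell_records(mos$series)
  meta <- mos$meta
  for (i in seq_len(nrow(meta))) {
    r <- recs[recs$cell_id == meta$cell_id[i], ]
    expect_identical(r$trajectory_class,
                     paste0("persistent_", meta$direction[i]))
    expect_identical(r$duration, meta$duration_years[i])
    expect_equal(r$rate, 1 / meta$duration_years[i])
    expect_equal(r$amount, meta$change_pixels[i] / 324)
    expect_identical(r$start, meta$start_step[i])
    expect_equal(r$initial_amount,
                 meta$initial_transition_amount[i] / 324)
    expect_identical(r$transition_lc, meta$transition_class[i])
  }
})
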