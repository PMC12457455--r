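test_that("the minimum-change threshold is the first count above 5%", {
  expect_identical(min_change_threshold(324L), 17L)
  expect_true(16 / 324 <= 0.05)    # 16 pixels is within noise tolerance
  expect_true(17 / 324 > 0.05)     # 17 pixels exceeds it
  expect_identical(min_change_threshold(1296L), 65L)  # 36 x 36 cells
})

test_that("filters exclude with reasons and partition the records", {
  specs <- list(
    # too little change: 16 pixels
    cell_spec(initial_transition_amount = 60,
              trajectory = trajectory_spec("loss", 16, duration_years = 4),
              seed = 1, cell_id = "small"),
    # clean persistent loss
    cell_spec(initial_transition_amount = 60,
              trajectory = trajectory_spec("loss", 30, duration_years = 5),
              seed = 2, cell_id = "ok"),
    # transition LC absent at the interval start
    cell_spec(initial_transition_amount = 0,
              trajectory = trajectory_spec("loss", 30, duration_years = 5),
              seed = 3, cell_id = "degenerate"),
    # non-persistent
    cell_spec(initial_transition_amount = 100,
              trajectory = trajectory_spec("non_persistent", 60,
                                           duration_years = 10),
              seed = 4, cell_id = "np"),
    # constant cell: no transition at all
    cell_spec(initial_transition_amount = 50, seed = 5, cell_id = "flat"))
  recs <- cell_records(generate_mosaic(specs, seed = 11)$series)
  out <- apply_filters(recs)
  expect_identical(nrow(out$retained) + nrow(out$excluded), nrow(recs))
  expect_identical(out$retained$cell_id, "ok")
  reason_of <- function(id) out$excluded$reason[out$excluded$cell_id == id]
  expect_match(reason_of("small"), "min_change")
  expect_match(reason_of("degenerate"), "degenerate_lci")
  expect_match(reason_of("np"), "non_persistent")
  expect_match(reason_of("flat"), "non_forest_dominant")
})

test_that("incomplete cells flagged by tessellation are excluded", {
  recs <- cell_records(list(
    a = generate_lc_series(cell_spec(initial_transition_amount = 60,
                                     trajectory = trajectory_spec(
                                       "loss", 30, duration_years = 5),
                                     seed = 6))))
  recs$complete <- FALSE
  out <- apply_filters(recs)
  expect_identical(nrow(out$retained), 0L)
  expect_match(out$excluded$reason, "incomplete")
})

test_that("every cell receives exactly one trajectory class", {
  specs <- random_cell_specs(12, seed = 21)
  recs <- cell_records(generate_mosaic(specs, seed = 22)$series)
  expect_true(all(recs$trajectory_class %in%
                    c("persistent_loss", "persistent_gain",
                      "non_persistent", "no_change")))
  expect_identical(nrow(recs), 12L)
})
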