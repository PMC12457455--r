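test_that("transition matrix counts changed pixels only", {
  a <- matrix(2L, 3, 3)
  expect_identical(nrow(transition_matrix(a, a)), 0L)
  expect_identical(attr(transition_matrix(a, a), "total_changed"), 0L)
  # 5 forest->cropland, 3 forest->grassland, 1 cropland->forest
  first <- matrix(2L, 3, 3); last <- first
  last[1:5] <- 1L
  last[6:8] <- 3L
  first[9] <- 1L; last[9] <- 2L
  m <- transition_matrix(first, last)
  expect_identical(attr(m, "total_changed"), 9L)
  expect_identical(m$count[m$from == 2 & m$to == 1], 5L)
  expect_identical(m$count[m$from == 2 & m$to == 3], 3L)
  expect_identical(m$count[m$from == 1 & m$to == 2], 1L)
  expect_error(transition_matrix(a, matrix(2L, 2, 2)), "shape")
  # saturated change
  b <- matrix(8L, 18, 18)
  m2 <- transition_matrix(matrix(2L, 18, 18), b)
  expect_identical(nrow(m2), 1L)
  expect_identical(m2$count, 324L)
})

test_that("dominant transition takes the argmax with certainty over changes", {
  first <- matrix(2L, 3, 3); last <- first
  last[1:5] <- 1L; last[6:8] <- 3L
  first[9] <- 1L; last[9] <- 2L
  dom <- dominant_transition(transition_matrix(first, last))
  expect_identical(dom$from, 2L)
  expect_identical(dom$to, 1L)
  expect_equal(dom$certainty, 5 / 9)
  expect_false(dom$tie)
  expect_true(dom$involves_forest)
  expect_identical(dom$transition_lc, 1L)
  # certainties over all pairs sum to one
  m <- transition_matrix(first, last)
  expect_equal(sum(m$count / attr(m, "total_changed")), 1)
})

test_that("ties break on the fixed category order and are flagged", {
  first <- matrix(2L, 2, 4); last <- first
  last[1:4] <- 1L   # forest -> cropland x4
  last[5:8] <- 3L   # forest -> grassland x4
  dom <- dominant_transition(transition_matrix(first, last))
  expect_identical(c(dom$from, dom$to), c(2L, 1L))  # cropland preferred
  expect_true(dom$tie)
  # forest-involving pairs are preferred over a tied non-forest pair
  first2 <- matrix(c(rep(1L, 4), rep(2L, 4)), 2, 4)
  last2 <- matrix(c(rep(3L, 4), rep(8L, 4)), 2, 4)
  dom2 <- dominant_transition(transition_matrix(first2, last2))
  expect_true(dom2$involves_forest)
  expect_identical(dom2$transition_lc, 8L)
})

test_that("no pixel change yields the no-change signal", {
  a <- matrix(5L, 4, 4)
  expect_null(dominant_transition(transition_matrix(a, a)))
})
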