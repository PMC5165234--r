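test_that("the division Hill function hits its anchors", {
  p <- dnd_params()
  expect_equal(dnd_divisions(0, p), 1)
  expect_equal(dnd_divisions(1e6, p), 6, tolerance = 1e-5)
  # Hill midpoint convention: at K_P half of the span is added
  expect_equal(dnd_divisions(11.619, p), 3.5, tolerance = 1e-12)
  expect_error(dnd_divisions(-1, p), "non-negative")
  a <- seq(0, 100, by = 0.5)
  v <- dnd_divisions(a, p)
  expect_true(all(diff(v) > 0))          # strictly increasing
  expect_true(all(v >= 1 & v <= 6))
})

test_that("stochastic rounding is unbiased and stays within the bounds", {
  p <- dnd_params()
  set.seed(21)
  d <- draw_dnd_divisions(11.619, p, n = 4e4)
  expect_true(all(d %in% 3:4))
  expect_equal(mean(d), 3.5, tolerance = 0.02)
  d0 <- draw_dnd_divisions(0, p, n = 100)
  expect_true(all(d0 == 1L))
  dmix <- draw_dnd_divisions(runif(2e4, 0, 60), p)
  expect_true(all(dmix >= 1L & dmix <= 6L))
})
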