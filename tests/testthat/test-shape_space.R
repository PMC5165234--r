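test_that("shape distance is the L1 metric with its basic identities", {
  expect_equal(shape_distance(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0)
  expect_equal(shape_distance(c(0, 0, 0, 0), c(1, 0, 0, 0)), 1)
  expect_equal(shape_distance(c(0, 0, 0, 0), c(1, 2, 0, 1)), 4)
  expect_error(shape_distance(c(0, 0, 0), c(0, 0, 0, 0)), "dimension")
  # symmetry and triangle inequality over random triples
  set.seed(11)
  for (i in 1:50) {
    a <- sample(-10:10, 4, TRUE); b <- sample(-10:10, 4, TRUE)
    cc <- sample(-10:10, 4, TRUE)
    expect_identical(shape_distance(a, b), shape_distance(b, a))
    expect_gte(shape_distance(a, b) + shape_distance(b, cc),
               shape_distance(a, cc))
  }
})

test_that("affinity is 1 at the optimum, exp(-1) at the width, and decays", {
  m <- affinity_model(gamma = 2.8)
  expect_equal(affinity(0, m), 1)
  expect_equal(affinity(2.8, m), exp(-1))
  expect_lt(affinity(40, m), 1e-80)
  expect_error(affinity(-1, m), "non-negative")
  # monotone non-increasing in distance over random pairs
  set.seed(12)
  d <- sort(runif(100, 0, 20))
  expect_true(all(diff(affinity(d, m)) <= 0))
})

test_that("mutation moves one unit with probability p_mut and respects bounds", {
  m0 <- affinity_model(p_mut = 0)
  m1 <- affinity_model(p_mut = 1)
  set.seed(13)
  for (i in 1:20) expect_identical(mutate_shape(c(1, 2, 3, 4), m0),
                                   c(1L, 2L, 3L, 4L))
  # p_mut = 1: always a unit neighbor, dimension and bounds conserved
  p <- c(0L, 0L, 0L, 0L)
  for (i in 1:200) {
    q <- mutate_shape(p, m1)
    expect_equal(shape_distance(p, q), 1)
    expect_length(q, 4)
  }
  # boundary point: stays in bounds
  bpt <- c(10L, -10L, 10L, 0L)
  for (i in 1:200) {
    q <- mutate_shape(bpt, m1)
    expect_true(all(abs(q) <= 10))
    expect_equal(shape_distance(bpt, q), 1)
  }
})

test_that("empirical mutation fraction converges to p_mut", {
  m <- affinity_model(p_mut = 0.3)
  set.seed(14)
  p <- c(0L, 0L, 0L, 0L)
  n <- 1e5
  mutated <- sum(vapply(seq_len(n), function(i)
    any(mutate_shape(p, m) != p), logical(1)))
  frac <- mutated / n
  expect_equal(frac, 0.3, tolerance = 0.005 / 0.3)
  expect_gt(stats::binom.test(mutated, n, 0.3)$p.value, 0.01)
})

test_that("the founder pool holds exactly the shells at distance 5-10", {
  pool <- gcsim:::founder_shape_pool(5, 10, 10)
  d <- rowSums(abs(pool))
  expect_true(all(d >= 5 & d <= 10))
  expect_true(all(abs(pool) <= 10))
  # every unit-neighbor class present: shells are complete
  expect_equal(sort(unique(d)), 5:10)
})
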