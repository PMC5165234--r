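test_that("arena geometry partitions the GC into two zones", {
  ar <- small_arena()
  inside1 <- ar$inside + 1L
  z <- ar$zone[inside1]
  expect_true(all(z %in% c(0L, 1L)))
  expect_equal(sum(z == 0L) + sum(z == 1L), length(ar$inside))
  # boundary plane belongs to the light zone by convention
  n <- ar$n; c0 <- ar$center
  zcoord <- (inside1 - 1L) %/% (n * n)
  expect_true(all(ar$zone[inside1[zcoord == ceiling(c0)]] == 1L))
  # FDC somata sit in the light zone, CXCL12 sources on the dark side
  expect_true(all(ar$zone[ar$soma] == 1L))
})

test_that("reference arena has the expected size and zero-FDC arenas work", {
  ar <- reference_arena()
  expect_equal(ar$radius_nodes, 32)       # 160 um at 5 um spacing
  expect_equal(ar$dx, 5)
  cfg0 <- gc_config(arena = list(radius_um = 60, n_fdc = 0, seed = 3L))
  ar0 <- build_arena(cfg0)
  expect_equal(length(ar0$fdc_free), 0)
  expect_true(all(ar0$c13 == 0))          # no sources, zero field
})

test_that("a coarser lattice is more densely packed at fixed cell number", {
  ar5 <- reference_arena()
  ar10 <- build_arena(gc_config(arena = list(dx_um = 10, seed = 3L),
                                motility = list(dt_min = 1))) # v*dt <= dx
  expect_gt(packing_fraction(ar10, 3000), packing_fraction(ar5, 3000))
})

test_that("steady-state field of a point source decays away from it and its
           gradient points back toward the source", {
  n <- 17
  src <- cbind(8, 8, 8)
  src_idx <- 1 + src[1] + n * (src[2] + n * src[3])
  conc <- solve_chemokine_steady_state(n, src_idx, rate = 1, D = 100,
                                       k_deg = 0.5, dx = 5)
  ii <- seq_len(n^3)
  x <- (ii - 1) %% n; y <- ((ii - 1) %/% n) %% n; z <- (ii - 1) %/% (n * n)
  r <- sqrt((x - 8)^2 + (y - 8)^2 + (z - 8)^2)
  expect_true(all(conc[r > 0] < conc[src_idx]))
  # radially binned means decrease (maximum principle)
  rb <- round(r)
  m <- tapply(conc[rb <= 7], rb[rb <= 7], mean)
  expect_true(all(diff(m) < 0))
  # gradient at off-source nodes points toward the source
  set.seed(31)
  for (node in sample(which(r > 2 & r < 6), 10)) {
    g <- gradient_at(conc, n, node, dx = 5)
    to_src <- c(8 - x[node], 8 - y[node], 8 - z[node])
    expect_gt(sum(g * to_src), 0)
  }
})

test_that("gradients of uniform and linear-ramp fields are exact", {
  n <- 9
  unif <- rep(2.5, n^3)
  expect_equal(gradient_at(unif, n, 200, dx = 5), c(0, 0, 0))
  ii <- seq_len(n^3)
  x <- (ii - 1) %% n
  ramp <- 0.3 * x * 5                     # slope 0.3 per um along x
  interior <- which(x > 0 & x < n - 1)
  for (node in interior[c(1, 50, 100)])
    expect_equal(gradient_at(ramp, n, node, dx = 5), c(0.3, 0, 0),
                 tolerance = 1e-12)
  expect_error(gradient_at(unif, n, n^3 + 1), "outside")
})

test_that("steady state balances production against degradation plus
           boundary flux to 1%", {
  n <- 15
  src_idx <- 1 + 7 + n * (7 + n * 7)
  D <- 80; k <- 0.3; dx <- 5; rate <- 2
  conc <- solve_chemokine_steady_state(n, src_idx, rate, D, k, dx)
  production <- rate
  degradation <- k * sum(conc)
  # flux through the zero-Dirichlet faces: D/h^2 * sum of (c_interior - 0)
  # over interior nodes adjacent to the boundary ring
  ii <- seq_len(n^3)
  x <- (ii - 1) %% n; y <- ((ii - 1) %/% n) %% n; z <- (ii - 1) %/% (n * n)
  edge <- (x == 1 | x == n - 2) + (y == 1 | y == n - 2) + (z == 1 | z == n - 2)
  flux <- D / dx^2 * sum(conc * edge)
  expect_equal(degradation + flux, production, tolerance = 0.01)
})

test_that("iterative solve matches a direct sparse solve and the transient
           solver relaxes to the same state", {
  n <- 13
  src <- c(1 + 6 + n * (6 + n * 6), 1 + 3 + n * (9 + n * 6))
  D <- 60; k <- 0.4; dx <- 5
  c_cg <- solve_chemokine_steady_state(n, src, 1, D, k, dx, tol = 1e-10)
  A <- gcsim:::chemokine_operator(n, D, k, dx)
  b <- numeric(n^3); b[src] <- 1
  c_direct <- as.numeric(Matrix::solve(A, b))
  expect_equal(c_cg, pmax(c_direct, 0), tolerance = 1e-6)
  c_t <- solve_chemokine_transient(n, src, 1, D, k, dx, t_end = 60)
  expect_equal(c_t, c_cg, tolerance = 0.02)
})

test_that("field construction is deterministic for equal configurations", {
  cfg <- gc_config(arena = list(radius_um = 70, n_fdc = 25, seed = 9L))
  a1 <- build_arena(cfg, cache = FALSE)
  a2 <- build_arena(cfg, cache = FALSE)
  expect_identical(a1$c12, a2$c12)
  expect_identical(a1$c13, a2$c13)
  expect_identical(a1$soma, a2$soma)
})

test_that("zone classification is total and deterministic", {
  ar <- small_arena()
  nodes <- ar$inside[c(1, 100, 1000)] + 1L
  z1 <- classify_zone(ar, nodes)
  expect_true(all(z1 %in% c("DZ", "LZ")))
  expect_identical(z1, classify_zone(ar, nodes))
  expect_true(all(classify_zone(ar, ar$soma) == "LZ"))
})

test_that("the solver reports non-convergence with the residual", {
  expect_error(
    solve_chemokine_steady_state(15, 500, 1, D = 600, k_deg = 1e-6,
                                 dx = 5, tol = 1e-14, max_iter = 2),
    "did not converge")
})
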