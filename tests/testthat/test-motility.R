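test_that("sensitivity switching is hysteretic", {
  cd <- 2; cr <- 1
  expect_false(update_sensitivity(TRUE, 2.0, cd, cr))   # at c_D: desensitize
  expect_false(update_sensitivity(TRUE, 5.0, cd, cr))
  expect_true(update_sensitivity(FALSE, 1.0, cd, cr))   # at c_R: resensitize
  expect_true(update_sensitivity(FALSE, 0.2, cd, cr))
  expect_false(update_sensitivity(FALSE, 1.5, cd, cr))  # band: unchanged
  expect_true(update_sensitivity(TRUE, 1.5, cd, cr))    # band: unchanged
  expect_error(update_sensitivity(TRUE, 1, 1, 2), "c_r < c_d")
})

test_that("transitions only happen at the thresholds along random
           concentration paths", {
  set.seed(41)
  cd <- 2; cr <- 1
  s <- TRUE
  c_prev <- 0
  for (i in 1:2000) {
    c_now <- runif(1, 0, 3)
    s_new <- update_sensitivity(s, c_now, cd, cr)
    if (s_new != s) {
      if (s) expect_gte(c_now, cd)   # lost sensitivity only at c >= c_D
      else expect_lte(c_now, cr)     # regained it only at c <= c_R
    }
    s <- s_new
  }
})

test_that("polarity draws are unit vectors turning 60 degrees on average", {
  set.seed(42)
  old <- c(1, 0, 0)
  p <- new_polarity(old, sensitive = FALSE, n = 2e4)
  expect_equal(rowSums(p^2), rep(1, nrow(p)), tolerance = 1e-10)
  ang <- acos(pmin(1, pmax(-1, p %*% old))) * 180 / pi
  expect_equal(mean(ang), 60, tolerance = 0.02)
  # zero polarity re-initializes isotropically
  p0 <- new_polarity(c(0, 0, 0), n = 5e3)
  expect_equal(colMeans(p0), c(0, 0, 0), tolerance = 0.05)
})

test_that("a gradient biases polarity toward it only when sensitive", {
  set.seed(43)
  old <- c(1, 0, 0)
  grad <- c(0, 0, 4)
  p_on <- new_polarity(old, grad, sensitive = TRUE, w = 1, n = 2e4)
  p_off <- new_polarity(old, grad, sensitive = FALSE, w = 1, n = 2e4)
  expect_gt(mean(p_on[, 3]), 0.2)
  expect_equal(mean(p_off[, 3]), 0, tolerance = 0.02)
  # chemotactic bias reduces the turning angle below the 60-degree mean
  ang_on <- acos(pmin(1, pmax(-1, p_on %*% c(0, 0, 1)))) * 180 / pi
  ang_off <- acos(pmin(1, pmax(-1, p_off %*% c(0, 0, 1)))) * 180 / pi
  expect_lt(mean(ang_on), mean(ang_off))
  # zero gradient behaves like insensitive
  pg0 <- new_polarity(old, c(0, 0, 0), sensitive = TRUE, n = 2e4)
  angg0 <- acos(pmin(1, pmax(-1, pg0 %*% old))) * 180 / pi
  expect_equal(mean(angg0), 60, tolerance = 0.02)
})

test_that("lattice directions follow the polarity projections", {
  set.seed(44)
  expect_true(all(choose_lattice_direction(c(1, 0, 0), 500) == 1L))
  d <- choose_lattice_direction(c(1, 1, 0) / sqrt(2), 2e4)
  expect_true(all(d %in% c(1L, 3L)))
  expect_equal(mean(d == 1L), 0.5, tolerance = 0.03)
})

test_that("opposing cells exchange with probability one half", {
  set.seed(45)
  f <- exchange_fraction(c(1, 0, 0), c(-1, 0, 0), n = 1e5)
  expect_equal(f, 0.5, tolerance = 0.01 / 0.5)
  expect_equal(exchange_fraction(c(1, 0, 0), c(1, 0, 0), n = 1e3), 0)
})

test_that("the free run-and-tumble walker obeys the persistent-random-walk
           displacement law", {
  v <- 10; tau <- 1
  tr <- generate_fixture_tracks("prw", n_tracks = 3000, duration_min = 30,
                                interval_s = 30, v = v, tau = tau, seed = 46)
  sp <- split(tr, tr$cell_id)
  lags <- c(10, 20, 30)
  for (lag in lags) {
    msd <- mean(vapply(sp, function(d) {
      i <- which.min(abs(d$t_min - lag))
      (d$x_um[i] - d$x_um[1])^2 + (d$y_um[i] - d$y_um[1])^2 +
        (d$z_um[i] - d$z_um[1])^2
    }, numeric(1)))
    furth <- 2 * v^2 * tau * (lag - tau * (1 - exp(-lag / tau)))
    expect_equal(msd, furth, tolerance = 0.05)
  }
})

test_that("a coarser lattice at the same cell number crowds the grid and
           lowers the realized motility coefficient", {
  n_cells <- 3000
  m5 <- motility_coefficient(mean_displacement_curve(
    run_motility_only(gc_config(), n_cells = n_cells, duration_min = 12,
                      seed = 47, arena = reference_arena())$tracks))
  cfg10 <- gc_config(arena = list(dx_um = 10, seed = 3L),
                     motility = list(dt_min = 1))
  ar10 <- build_arena(cfg10)
  m10 <- motility_coefficient(mean_displacement_curve(
    run_motility_only(cfg10, n_cells = n_cells, duration_min = 12,
                      seed = 47, interval_s = 60, arena = ar10)$tracks))
  expect_gt(packing_fraction(ar10, n_cells),
            packing_fraction(reference_arena(), n_cells))
  expect_gt(m5$M, m10$M)
})
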