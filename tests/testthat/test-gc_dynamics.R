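# integration tests on a reduced arena (80 um radius) so each run stays in
# the seconds range; population-scale behaviour is covered by the
# acceptance suite

test_that("founder influx follows the gated Poisson process", {
  set.seed(61)
  n <- sample_founder_counts(50, rate_per_h = 2, window_h = 96)
  expect_equal(mean(n), 192, tolerance = 3 * 13.9 / sqrt(50) / 192)
  expect_true(all(n > 100 & n < 260))
  expect_true(all(sample_founder_counts(20, rate_per_h = 0) == 0))
  # inside a run: no arrivals after the influx window
  cfg <- small_config(gc = list(influx_window_days = 0.5))
  r1 <- run_gc(cfg, days = 0.5, seed = 62, arena = small_arena())
  r2 <- run_gc(cfg, days = 1.5, seed = 62, arena = small_arena())
  expect_equal(r1$counters$founders, r2$counters$founders)
  expect_equal(r1$counters$founders, 24, tolerance = 0.5) # 2/h over 12 h
})

test_that("founders expand to 64 descendants before light-zone death can
           intervene", {
  # long collection window disables apoptosis within the horizon, and
  # an antigen-free FDC network prevents any selection
  cfg <- gc_config(arena = list(radius_um = 80, n_fdc = 40, seed = 7L,
                                fdc_antigen_per_node = 0),
                   gc = list(influx_window_days = 0.25,
                             collect_window_h = 200),
                   shape = list(p_mut = 0))
  r <- run_gc(cfg, days = 4, seed = 63)
  founders <- r$counters$founders
  last <- r$ts[nrow(r$ts), ]
  expect_equal(last$n_b, 64 * founders)
  expect_equal(r$counters$selections, 0)
})

test_that("Tfh polarize to the highest-antigen contact with uniform
           tie-breaks", {
  expect_equal(gcsim:::cpp_pick_max_antigen(c(2, 5, 3)), 2L)
  expect_equal(gcsim:::cpp_pick_max_antigen(7), 1L)
  set.seed(64)
  picks <- replicate(1e4, gcsim:::cpp_pick_max_antigen(c(4, 4)))
  expect_equal(mean(picks == 1L), 0.5, tolerance = 0.02 / 0.5)
})

test_that("antigen is conserved across collection, division, death and
           output", {
  cfg <- small_config()
  r <- run_gc(cfg, days = 6, seed = 65, arena = small_arena())
  cc <- r$counters
  expect_gt(cc$collected_events, 0)
  held <- cc$antigen_held_live + cc$antigen_held_corpse
  sunk <- cc$antigen_sink_recycled + cc$antigen_sink_dead +
    cc$antigen_sink_plasma
  expect_equal(held + sunk, cc$collected_events + cc$granted_exogenous,
               tolerance = 1e-9)
  # FDC bookkeeping: portions removed equal collection events
  expect_equal(cc$fdc_antigen_initial - cc$fdc_antigen_left,
               cc$collected_events, tolerance = 1e-9)
})

test_that("every granted division count respects the Hill bounds and the
           run advances with non-negative populations", {
  cfg <- small_config()
  r <- run_gc(cfg, days = 6, seed = 66, arena = small_arena())
  expect_gt(r$counters$selections, 0)
  expect_true(all(r$counters$sel_divisions >= 1L &
                    r$counters$sel_divisions <= 6L))
  expect_true(all(r$ts$n_b >= 0))
  expect_true(all(diff(r$ts$day) > 0))
  expect_true(all(r$ts$n_dz + r$ts$n_lz == r$ts$n_b))
})

test_that("masking kinetics converge to the closed-form equilibrium and
           free antigen never recovers", {
  ab <- 2e-7; kon <- 1e5; koff <- 1e-3
  b <- masked_fraction(ab, kon, koff, t_end = 4e3, dt = 0.5)
  expect_equal(b[length(b)], kon * ab / (kon * ab + koff), tolerance = 1e-4)
  expect_true(all(diff(b) >= -1e-12))     # monotone approach from below
  cfg <- small_config()
  r <- run_gc(cfg, days = 6, seed = 67, arena = small_arena())
  expect_true(all(diff(r$ts$free_antigen[-1]) <= 1e-12))
  expect_true(all(diff(r$ts$masked) >= -1e-12))
})

test_that("switching off targeted delivery keeps both DEC205 subsets
           indistinguishable from the untreated run", {
  cfg <- small_config()
  r <- run_gc(cfg, days = 2, seed = 68, arena = small_arena())
  expect_true(all(r$ts$dec_pos_dz == 0))
  expect_true(all(r$counters$granted_exogenous == 0))
})

test_that("photoactivated labels are conserved and transzone fractions
           start at zero", {
  cfg <- small_config()
  r <- run_gc(cfg, days = 2.25, seed = 70, arena = small_arena(),
              photoactivation = photoactivation_request("DZ", day = 2,
                                                        radius_um = 30,
                                                        sample_min = 30))
  expect_gt(r$photo_n0, 0)
  fr <- photoactivation_fractions(r)
  expect_equal(fr$frac_opposite[1], 0)
  expect_true(all(fr$frac_opposite >= 0 & fr$frac_opposite <= 1))
  # the label marks a fixed cohort: visible labeled cells never increase
  expect_true(all(diff(fr$labeled_visible) <= 0))
})

test_that("targeted antigen delivery hands flagged light-zone cells a full
           antigen load and shifts them toward the dark zone", {
  cfg <- small_config(dec205 = list(enabled = TRUE, injection_day = 2,
                                    window_h = 24),
                      feedback = list(enabled = FALSE))
  r <- run_gc(cfg, days = 3.5, seed = 71, arena = small_arena())
  expect_gt(r$counters$granted_exogenous, 0)
  rp <- dz_lz_ratio(r, "dec205_pos")
  rn <- dz_lz_ratio(r, "dec205_neg")
  late <- rp$day > 2.5
  ok <- late & is.finite(rp$ratio) & is.finite(rn$ratio)
  # boosted cells re-enter division en masse: their DZ/LZ ratio exceeds
  # the untreated subset after the injection
  expect_gt(mean(rp$ratio[ok]), mean(rn$ratio[ok]))
})

test_that("a selected cohort exports exactly one plasma cell", {
  cfg <- small_config()
  r <- run_gc(cfg, days = 7, seed = 69, arena = small_arena())
  cc <- r$counters
  expect_gt(cc$plasma, 0)
  # one plasma cell per resolved cohort; cohorts still dividing at the end
  # keep plasma at or below the selection count
  expect_lte(cc$plasma, cc$selections)
  # recycling dominates: with at least one division per selection, at most
  # half of each finishing cohort can leave
  expect_gte(cc$selections + 0.0, cc$plasma)
})
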