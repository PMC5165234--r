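#' Track recording request
#'
#' @param start_min Simulation time (min) at which all live B cells become
#'   tracked.
#' @param duration_min Length of the tracking window (min).
#' @param interval_s Sampling interval (s); must be a multiple of the
#'   simulation step.
#' @return List used by [run_gc()].
#' @export
track_request <- function(start_min = 0, duration_min = 60, interval_s = 20) {
  list(start_min = start_min, duration_min = duration_min,
       interval_s = interval_s)
}

#' Photoactivation request
#'
#' Labels all B cells inside a sphere in the chosen zone at a given day and
#' follows the labeled cells (apoptotic ones at their death position until
#' cleared).
#'
#' @param zone "DZ" or "LZ".
#' @param day Day of photoactivation.
#' @param radius_um Radius of the photoactivated region.
#' @param sample_min Sampling interval of labeled-cell counts (min).
#' @return List used by [run_gc()].
#' @export
photoactivation_request <- function(zone = c("DZ", "LZ"), day = 6,
                                    radius_um = 40, sample_min = 30) {
  zone <- match.arg(zone)
  list(zone = zone, day = day, radius_um = radius_um, sample_min = sample_min)
}

build_core_par <- function(config, arena, days, track = NULL, photo = NULL,
                           motility_only = FALSE, n_motile = 0) {
  m <- config$motility; g <- config$gc; s <- config$shape
  d <- config$dnd; f <- config$feedback; dec <- config$dec205
  dt <- m$dt_min
  # inclusive of the final sample time: a 9-min track at 20 s has 28 points
  n_steps <- as.integer(round(days * 1440 / dt)) + 1L
  pre <- resolve_preset(m)
  cb <- arena$boundary_conc
  steps <- function(minutes) as.integer(round(minutes / dt))

  tr <- list(start = -1L, end = -1L, every = 0L)
  if (!is.null(track)) {
    k <- track$interval_s / 60 / dt
    if (abs(k - round(k)) > 1e-9)
      stop("track interval must be a multiple of the simulation step",
           call. = FALSE)
    tr <- list(start = steps(track$start_min),
               end = steps(track$start_min + track$duration_min),
               every = as.integer(round(k)))
  }

  pa <- list(on = FALSE, step = -1L, zone = 0L, cx = 0, cy = 0, cz = 0,
             rad = 0, every = 1L)
  if (!is.null(photo)) {
    zc <- arena$center
    off <- arena$radius_nodes / 2
    pa <- list(on = TRUE, step = steps(photo$day * 1440),
               zone = if (photo$zone == "LZ") 1L else 0L,
               cx = zc, cy = zc,
               cz = if (photo$zone == "LZ") zc + off else zc - off,
               rad = photo$radius_um, every = steps(photo$sample_min))
  }

  aff_mid <- c(0.125, 0.375, 0.625, 0.875)
  kd <- 10^(log10(f$kd_range[1]) +
              aff_mid * (log10(f$kd_range[2]) - log10(f$kd_range[1])))

  list(
    dt = dt, n_steps = n_steps,
    p_move_b = m$v_um_min * dt / arena$dx,
    p_move_t = min(1, m$v_tfh_um_min * dt / arena$dx),
    mean_turn = m$mean_turn_deg, sd_turn = m$sigma_turn_deg,
    w_chemo = m$w_chemo,
    tau_min = m$tau_range_min[1], tau_max = m$tau_range_min[2],
    cD12 = pre$cd_mult * cb[["cxcl12"]], cR12 = pre$cr_mult * cb[["cxcl12"]],
    cD13 = pre$cd_mult * cb[["cxcl13"]], cR13 = pre$cr_mult * cb[["cxcl13"]],
    influx_per_step = g$influx_per_h * dt / 60,
    influx_end_step = steps(g$influx_window_days * 1440),
    initial_divisions = as.integer(g$initial_divisions),
    cycle_steps = steps(g$cycle_h * 60),
    cycle_jitter = g$cycle_jitter,
    mphase_steps = steps(g$mphase_h * 60),
    collect_steps = steps(g$collect_window_h * 60),
    contact_steps = steps(g$contact_freeze_min),
    capture_eff = g$capture_efficiency,
    tfh_window_steps = steps(g$tfh_window_h * 60),
    tfh_required_min = g$tfh_required_h * 60,
    corpse_steps = steps(g$corpse_visible_h * 60),
    p_asym = g$p_asym, f_asym = g$f_asym,
    p_mut = s$p_mut, n_tfh = as.integer(g$n_tfh),
    gamma = s$gamma, shape_bound = as.integer(s$bound),
    p_min = d$p_min, p_max = d$p_max, n_p = d$n_p, k_p = d$k_p,
    dnd_on = isTRUE(d$enabled),
    feedback_on = isTRUE(f$enabled),
    k_on = f$k_on,
    ab_rate = f$production_mol_min * f$n_gc / f$volume_l,
    ab_decay = log(2) / (f$ab_halflife_days * 1440),
    k_off = f$k_on * kd,
    dec_on = isTRUE(dec$enabled), dec_frac = dec$fraction,
    dec_step = steps(dec$injection_day * 1440),
    dec_window_steps = steps(dec$window_h * 60),
    dec_antigen = dec$antigen_boost,
    motility_only = motility_only, n_motile = as.integer(n_motile),
    track_start = tr$start, track_end = tr$end, track_every = tr$every,
    pa_on = pa$on, pa_step = pa$step, pa_zone = pa$zone,
    pa_cx = pa$cx, pa_cy = pa$cy, pa_cz = pa$cz, pa_rad = pa$rad,
    pa_every = max(1L, pa$every),
    ts_every = steps(30)
  )
}

core_arena_list <- function(arena) {
  list(nx = arena$n, ny = arena$n, nz = arena$n, dx = arena$dx,
       occ = arena$occ, zone = arena$zone,
       fdc_site = arena$fdc_site, fdc_free = arena$fdc_free,
       c12 = arena$c12, c13 = arena$c13,
       g12 = unname(arena$g12), g13 = unname(arena$g13),
       inside = arena$inside,
       founder_shapes = founder_shape_pool(
         arena$config$shape$founder_dist[1],
         arena$config$shape$founder_dist[2],
         arena$config$shape$bound))
}

ts_names <- c("day", "n_b", "n_dz", "n_lz", "n_cb", "n_cc", "n_corpse",
              "plasma", "plasma_mean_aff", "mean_aff", "free_antigen",
              "masked", "founders", "selections", "mean_divisions",
              "dec_pos_dz", "dec_pos_lz", "dec_neg_dz", "dec_neg_lz")

as_run <- function(res, config, arena, seed, days) {
  ts <- as.data.frame(res$ts)
  names(ts) <- ts_names
  tracks <- as.data.frame(res$tracks)
  names(tracks) <- c("cell_id", "t_min", "x_um", "y_um", "z_um",
                     "zone", "frozen")
  photo <- as.data.frame(res$photo)
  if (ncol(photo) == 5)
    names(photo) <- c("t_min", "in_dz", "in_lz", "corpses", "gone")
  structure(list(
    ts = ts, tracks = tracks, photo = photo, photo_n0 = res$photo_n0,
    counters = res[setdiff(names(res), c("ts", "tracks", "photo"))],
    config = config, seed = seed, days = days,
    boundary_conc = arena$boundary_conc,
    zone_boundary_um = arena$center * arena$dx
  ), class = "gc_run")
}

#' Run a germinal-center simulation
#'
#' Executes the full agent-based GC reaction: continuous founder influx
#' over the first days, initial expansion with six divisions, mutation at
#' division, two-step light-zone selection (antigen collection on the FDC
#' network, then competition for Tfh help), Hill-controlled number of
#' divisions on recycling, asymmetric antigen inheritance, plasma-cell
#' output of the highest-antigen sibling, antibody feedback masking free
#' antigen, and transient chemotaxis keeping the zones separated.
#'
#' @param config A [gc_config()].
#' @param days Simulated real time in days (reference reactions run 21
#'   days).
#' @param seed Integer seed; a run is fully reproducible from
#'   `config` + `seed`.
#' @param arena Optionally a prebuilt [build_arena()] arena (rebuilt from
#'   `config` otherwise; fields are cached per configuration).
#' @param track Optional [track_request()].
#' @param photoactivation Optional [photoactivation_request()].
#' @return Object of class `gc_run` with elements `ts` (half-hourly time
#'   series), `tracks`, `photo`, and `counters` (founders, selections,
#'   realized division numbers, antigen bookkeeping, plasma output).
#' @export
run_gc <- function(config = gc_config(), days = 21, seed = 1,
                   arena = NULL, track = NULL, photoactivation = NULL) {
  validate_config(config)
  if (is.null(arena)) arena <- build_arena(config)
  set.seed(seed)
  par <- build_core_par(config, arena, days, track = track,
                        photo = photoactivation)
  res <- cpp_run(core_arena_list(arena), par)
  as_run(res, config, arena, seed, days)
}

#' Run a motility-only arena
#'
#' A GC-shaped arena populated with freely moving B cells (no birth, death
#' or selection): dark-zone phenotype cells start in the dark zone and
#' light-zone phenotype cells in the light zone, all subject to the
#' persistent random walk with transient chemotaxis. All cells are tracked
#' from `start_min` at `interval_s`. This is the fast setting for the
#' displacement, speed, and turning-angle read-outs.
#'
#' @param config A [gc_config()].
#' @param n_cells Number of B cell walkers (default 300).
#' @param duration_min Simulated minutes (default 12).
#' @param seed Integer seed.
#' @param interval_s Track sampling interval (default 20 s).
#' @param start_min Tracking start (default 0).
#' @param arena Optional prebuilt arena.
#' @return `gc_run` whose `tracks` hold all cells.
#' @export
run_motility_only <- function(config = gc_config(), n_cells = 300,
                              duration_min = 12, seed = 1, interval_s = 20,
                              start_min = 0, arena = NULL) {
  validate_config(config)
  if (is.null(arena)) arena <- build_arena(config)
  set.seed(seed)
  par <- build_core_par(
    config, arena, days = duration_min / 1440,
    track = track_request(start_min, duration_min - start_min, interval_s),
    motility_only = TRUE, n_motile = n_cells)
  res <- cpp_run(core_arena_list(arena), par)
  as_run(res, config, arena, seed, duration_min / 1440)
}

#' Founder-arrival counts
#'
#' Total founder B cells entering a GC: a Poisson process at `rate_per_h`
#' restricted to the influx window.
#'
#' @param n_runs Number of simulated GCs.
#' @param rate_per_h Influx rate (default 2 cells/h).
#' @param window_h Influx window (default 96 h).
#' @return Integer vector of founder totals, one per run.
#' @export
sample_founder_counts <- function(n_runs, rate_per_h = 2, window_h = 96) {
  stopifnot(rate_per_h >= 0, window_h >= 0)
  stats::rpois(n_runs, rate_per_h * window_h)
}

#' @export
print.gc_run <- function(x, ...) {
  last <- x$ts[nrow(x$ts), ]
  cat("gc_run: ", x$days, " days, seed ", x$seed, "\n",
      "  founders ", x$counters$founders,
      ", live B cells ", last$n_b,
      " (DZ ", last$n_dz, " / LZ ", last$n_lz, ")",
      ", plasma output ", x$counters$plasma, "\n", sep = "")
  if (x$counters$selections > 0)
    cat("  selections ", x$counters$selections,
        ", mean divisions granted ",
        round(mean(x$counters$sel_divisions), 2), "\n", sep = "")
  invisible(x)
}
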