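#' Run a named in-silico experiment
#'
#' Drivers for the standard virtual two-photon experiments, each executed
#' as `n_replicates` independently seeded runs (replicate seeds are
#' derived from `seed`):
#' \describe{
#'   \item{baseline}{full GC reaction; pooled half-hourly time series.}
#'   \item{motility_only}{walkers in a GC-shaped arena; pooled
#'     displacement curve and motility coefficient.}
#'   \item{photoactivation}{full GC with photoactivation in each zone at
#'     day `pa_day`; pooled opposite-zone fractions.}
#'   \item{transzone}{full GC tracked for 1 h at `track_day`; transzone
#'     rates and directional counts per replicate.}
#'   \item{dec205}{full GC with targeted antigen delivery; dark/light
#'     ratio time courses for both subsets.}
#' }
#'
#' @param name Experiment name.
#' @param config A [gc_config()].
#' @param n_replicates Number of replicate simulations (figure-style
#'   pooling uses 20).
#' @param seed Master seed.
#' @param days Simulated days for the full-GC experiments.
#' @param pa_day,track_day Day of photoactivation / tracking onset.
#' @param out_dir If given, a run bundle (config echo, CSV tables, summary
#'   JSON) is written there.
#' @return List of class `gc_experiment` with per-replicate and pooled
#'   results.
#' @export
run_experiment <- function(name = c("baseline", "motility_only",
                                    "photoactivation", "transzone",
                                    "dec205"),
                           config = gc_config(), n_replicates = 5,
                           seed = 1, days = 8, pa_day = 6, track_day = 6,
                           out_dir = NULL) {
  name <- match.arg(name)
  arena <- build_arena(config)
  seeds <- seed + seq_len(n_replicates) - 1L
  out <- switch(name,
    motility_only = {
      runs <- lapply(seeds, function(s)
        run_motility_only(config, n_cells = 300, duration_min = 12,
                          seed = s, arena = arena))
      tracks <- do.call(rbind, lapply(seq_along(runs), function(i) {
        tr <- runs[[i]]$tracks
        tr$cell_id <- tr$cell_id + i * 1e6
        tr
      }))
      curve <- mean_displacement_curve(tracks)
      list(tracks = tracks, curve = curve,
           motility = motility_coefficient(curve),
           zero_speed = zero_speed_fraction(tracks))
    },
    baseline = {
      runs <- lapply(seeds, function(s)
        run_gc(config, days = days, seed = s, arena = arena))
      list(runs = runs, ts = pool_ts(runs))
    },
    photoactivation = {
      res <- lapply(c("DZ", "LZ"), function(zn) {
        lapply(seeds, function(s)
          run_gc(config, days = pa_day + 0.25, seed = s, arena = arena,
                 photoactivation = photoactivation_request(zn, day = pa_day,
                                                           sample_min = 30)))
      })
      names(res) <- c("DZ", "LZ")
      list(runs = res,
           fractions = lapply(res, function(rs)
             pool_photo(lapply(rs, photoactivation_fractions))))
    },
    transzone = {
      runs <- lapply(seeds, function(s)
        run_gc(config, days = track_day + 0.05, seed = s, arena = arena,
               track = track_request(track_day * 1440, 60, 20)))
      rates <- lapply(runs, function(r) transzone_event_rate(r$tracks))
      list(runs = runs, rates = rates,
           rate_pct = mean(vapply(rates, `[[`, numeric(1), "rate_pct")))
    },
    dec205 = {
      cfg <- config
      cfg$dec205$enabled <- TRUE
      runs <- lapply(seeds, function(s)
        run_gc(cfg, days = days, seed = s, arena = build_arena(cfg)))
      list(runs = runs,
           ratio_pos = lapply(runs, dz_lz_ratio, "dec205_pos"),
           ratio_neg = lapply(runs, dz_lz_ratio, "dec205_neg"))
    })
  out$name <- name
  out$config <- config
  out$seed <- seed
  out$n_replicates <- n_replicates
  class(out) <- "gc_experiment"
  if (!is.null(out_dir)) write_run_bundle(out, out_dir)
  out
}

pool_ts <- function(runs) {
  ts <- runs[[1]]$ts[, "day", drop = FALSE]
  for (col in c("n_b", "n_dz", "n_lz", "plasma", "mean_aff",
                "free_antigen")) {
    m <- vapply(runs, function(r) r$ts[[col]][seq_len(nrow(ts))],
                numeric(nrow(ts)))
    ts[[paste0(col, "_mean")]] <- rowMeans(m, na.rm = TRUE)
    ts[[paste0(col, "_sd")]] <- apply(m, 1, stats::sd, na.rm = TRUE)
  }
  ts
}

pool_photo <- function(fr_list) {
  n <- min(vapply(fr_list, nrow, integer(1)))
  f <- vapply(fr_list, function(d) d$frac_opposite[seq_len(n)], numeric(n))
  data.frame(t_h = fr_list[[1]]$t_h[seq_len(n)],
             mean = rowMeans(f), sd = apply(f, 1, stats::sd))
}

#' Write a self-describing run bundle
#'
#' Writes the resolved configuration (YAML echo), the pooled tables (CSV)
#' and a summary (JSON) of an experiment so it can be reproduced from the
#' bundle alone.
#'
#' @param experiment A `gc_experiment`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_run_bundle <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- experiment$config
  class(cfg) <- "list"
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  summary <- list(name = experiment$name, seed = experiment$seed,
                  n_replicates = experiment$n_replicates,
                  package_version = as.character(
                    utils::packageVersion("gcsim")))
  if (!is.null(experiment$motility)) {
    summary$motility_coefficient <- experiment$motility$M
    summary$zero_speed_fraction <- experiment$zero_speed
    utils::write.csv(experiment$curve,
                     file.path(dir, "displacement_curve.csv"),
                     row.names = FALSE)
  }
  if (!is.null(experiment$ts))
    utils::write.csv(experiment$ts, file.path(dir, "timeseries.csv"),
                     row.names = FALSE)
  if (!is.null(experiment$rate_pct))
    summary$transzone_rate_pct <- experiment$rate_pct
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
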