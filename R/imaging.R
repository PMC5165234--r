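#' Mean displacement curve ("reached distance")
#'
#' Ensemble statistics of the distance of each tracked cell from its
#' starting point as a function of elapsed time. Plotted against the
#' square root of time this curve is linear for a random walk and
#' quadratic for ballistic motion; a persistent random walk starts
#' quadratic and merges into the linear regime whose steepness reflects
#' the motility coefficient.
#'
#' @param tracks Track data frame (`cell_id`, `t_min`, `x_um`, `y_um`,
#'   `z_um`, ...), e.g. from [run_motility_only()] or
#'   [generate_fixture_tracks()].
#' @return Data frame with `t_min`, `mean_um`, `sd_um`, `n` per lag; the
#'   zero-lag row has mean displacement 0.
#' @export
mean_displacement_curve <- function(tracks) {
  if (nrow(tracks) == 0) stop("no tracks", call. = FALSE)
  sp <- split(tracks, tracks$cell_id)
  disp <- lapply(sp, function(tr) {
    tr <- tr[order(tr$t_min), ]
    d <- sqrt((tr$x_um - tr$x_um[1])^2 + (tr$y_um - tr$y_um[1])^2 +
                (tr$z_um - tr$z_um[1])^2)
    data.frame(lag = tr$t_min - tr$t_min[1], d = d)
  })
  all <- do.call(rbind, disp)
  lags <- sort(unique(all$lag))
  out <- do.call(rbind, lapply(lags, function(l) {
    v <- all$d[all$lag == l]
    data.frame(t_min = l, mean_um = mean(v),
               sd_um = if (length(v) > 1) stats::sd(v) else 0,
               n = length(v))
  }))
  rownames(out) <- NULL
  out
}

#' Motility coefficient from the linear regime
#'
#' The motility coefficient of a three-dimensional walker is
#' `M = <|r(t)|>^2 / (6 t)`. Because the initial part of the displacement
#' curve is quadratic (persistence), `M` is estimated from the slope `s`
#' of a linear regression of mean displacement against `sqrt(t)` over a
#' fitting window in the linear regime (default 4-9 min): `M = s^2 / 6`.
#' The pointwise estimator (the same formula applied per time point and
#' averaged over the window) is available as `method = "pointwise"`.
#'
#' @param curve Data frame from [mean_displacement_curve()].
#' @param window Fit window in minutes (default `c(4, 9)`).
#' @param method "regression" (default) or "pointwise".
#' @return List of class `motility_result`: `M` (um^2/min), `slope`,
#'   `intercept`, `window`, `method`.
#' @export
motility_coefficient <- function(curve, window = c(4, 9),
                                 method = c("regression", "pointwise")) {
  method <- match.arg(method)
  sel <- curve$t_min >= window[1] & curve$t_min <= window[2]
  if (sum(sel) < 2 || max(curve$t_min) < window[2])
    stop("fit window not covered by the displacement curve", call. = FALSE)
  d <- curve[sel, ]
  if (method == "regression") {
    fit <- stats::lm(mean_um ~ sqrt(t_min), data = d)
    slope <- unname(stats::coef(fit)[2])
    M <- slope^2 / 6
    out <- list(M = M, slope = slope,
                intercept = unname(stats::coef(fit)[1]),
                window = window, method = method)
  } else {
    out <- list(M = mean(d$mean_um^2 / (6 * d$t_min)), slope = NA_real_,
                intercept = NA_real_, window = window, method = method)
  }
  class(out) <- "motility_result"
  out
}

#' @export
print.motility_result <- function(x, ...) {
  cat("motility coefficient M = ", signif(x$M, 4), " um^2/min (",
      x$method, ", window ", x$window[1], "-", x$window[2], " min)\n",
      sep = "")
  invisible(x)
}

# per-interval displacements at a possibly coarsened sampling interval
interval_steps <- function(tracks, interval_s = NULL, exclude_frozen = FALSE) {
  sp <- split(tracks, tracks$cell_id)
  do.call(rbind, lapply(sp, function(tr) {
    tr <- tr[order(tr$t_min), ]
    if (nrow(tr) < 2) return(NULL)
    dt0 <- tr$t_min[2] - tr$t_min[1]
    k <- 1L
    if (!is.null(interval_s)) {
      k <- as.integer(round(interval_s / 60 / dt0))
      if (k < 1) stop("interval below the track sampling interval",
                      call. = FALSE)
      tr <- tr[seq(1, nrow(tr), by = k), , drop = FALSE]
      if (nrow(tr) < 2) return(NULL)
    }
    n <- nrow(tr)
    dx <- diff(tr$x_um); dy <- diff(tr$y_um); dz <- diff(tr$z_um)
    out <- data.frame(
      cell_id = tr$cell_id[1],
      t_min = tr$t_min[-n],
      dt_min = diff(tr$t_min),
      disp_um = sqrt(dx^2 + dy^2 + dz^2),
      dx = dx, dy = dy, dz = dz)
    if (exclude_frozen && "frozen" %in% names(tr)) {
      keep <- !(tr$frozen[-n] > 0 | tr$frozen[-1] > 0)
      out <- out[keep, , drop = FALSE]
    }
    out
  }))
}

#' Observed speed distribution
#'
#' Per-interval displacements divided by the observation interval, binned
#' and expressed as percent of the maximum bin frequency. The distribution
#' is a read-out of the measurement interval, not of the cells themselves:
#' on a lattice it populates speeds corresponding to the node distances
#' reachable within one interval, and lengthening the interval lowers the
#' observed mean speed because intervening movements cancel.
#'
#' @param tracks Track data frame.
#' @param interval_s Observation interval; defaults to the track sampling
#'   interval, coarser values subsample the tracks.
#' @param binwidth_um_min Histogram bin width (default 1 um/min).
#' @param exclude_frozen Drop intervals bordering frozen samples
#'   (interactions, M phase).
#' @return Data frame `speed_um_min` (bin midpoint), `count`, `pct_max`;
#'   the per-interval speeds are attached as attribute `"speeds"`.
#' @export
speed_distribution <- function(tracks, interval_s = NULL,
                               binwidth_um_min = 1, exclude_frozen = FALSE) {
  st <- interval_steps(tracks, interval_s, exclude_frozen)
  if (is.null(st) || nrow(st) == 0) stop("no observation intervals",
                                         call. = FALSE)
  sp <- st$disp_um / st$dt_min
  br <- seq(0, max(sp) + binwidth_um_min, by = binwidth_um_min)
  h <- graphics::hist(sp, breaks = br, plot = FALSE, right = FALSE)
  out <- data.frame(speed_um_min = h$mids, count = h$counts,
                    pct_max = 100 * h$counts / max(h$counts))
  attr(out, "speeds") <- sp
  out
}

#' Zero-speed fraction of observation intervals
#'
#' @inheritParams speed_distribution
#' @return Fraction of intervals with zero displacement.
#' @export
zero_speed_fraction <- function(tracks, interval_s = NULL,
                                exclude_frozen = FALSE) {
  st <- interval_steps(tracks, interval_s, exclude_frozen)
  mean(st$disp_um < 1e-9)
}

#' Observed turning-angle distribution
#'
#' Angle between successive displacement vectors of each track.
#' Zero-displacement intervals are skipped, and angles at or below
#' `min_angle_deg` (default 10) are excluded: an accumulation of 0-degree
#' angles is an artifact of the space discretization. Unlike the speed
#' distribution, this read-out is widely invariant against the choice of
#' the observation interval.
#'
#' @param tracks Track data frame (tracks need at least 3 samples).
#' @param min_angle_deg Lower exclusion threshold (default 10).
#' @param interval_s Optional coarser observation interval.
#' @param binwidth_deg Histogram bin width (default 10 degrees).
#' @return Data frame `angle_deg` (bin midpoint), `count`, `pct_max`, with
#'   the retained angles attached as attribute `"angles"`.
#' @export
turning_angle_distribution <- function(tracks, min_angle_deg = 10,
                                       interval_s = NULL,
                                       binwidth_deg = 10) {
  st <- interval_steps(tracks, interval_s)
  if (is.null(st) || nrow(st) == 0) stop("no observation intervals",
                                         call. = FALSE)
  angles <- unlist(lapply(split(st, st$cell_id), function(d) {
    d <- d[order(d$t_min), ]
    d <- d[d$disp_um > 1e-9, , drop = FALSE]
    if (nrow(d) < 2) return(numeric(0))
    v <- as.matrix(d[, c("dx", "dy", "dz")])
    n <- nrow(v)
    dots <- rowSums(v[-n, , drop = FALSE] * v[-1, , drop = FALSE])
    nrm <- sqrt(rowSums(v^2))
    cosang <- pmin(1, pmax(-1, dots / (nrm[-n] * nrm[-1])))
    acos(cosang) * 180 / pi
  }), use.names = FALSE)
  angles <- angles[angles > min_angle_deg]
  if (length(angles) == 0) {
    out <- data.frame(angle_deg = numeric(0), count = integer(0),
                      pct_max = numeric(0))
    attr(out, "angles") <- angles
    return(out)
  }
  br <- seq(0, 180 + binwidth_deg, by = binwidth_deg)
  h <- graphics::hist(angles, breaks = br, plot = FALSE, right = TRUE)
  out <- data.frame(angle_deg = h$mids, count = h$counts,
                    pct_max = 100 * h$counts / max(h$counts))
  attr(out, "angles") <- angles
  out
}

#' Transzone migration rate from short tracks
#'
#' Fraction of tracked B cells scored as migrating across the dark/light
#' zone boundary within the observation window (at most ~1 h in the
#' corresponding two-photon experiments), with directional counts. In the
#' reference GC the rate is a few percent and asymmetric: dark-to-light
#' transitions outnumber light-to-dark ones, because every dark-zone cell
#' eventually migrates for selection while only selected light-zone cells
#' return.
#'
#' A migration event requires more than a change of the instantaneous
#' zone label: cells sitting near the boundary plane flip labels by
#' single-node excursions that no experimenter would score as migration.
#' A cell is therefore scored as crossing only when it is observed at
#' least `margin_um` beyond the boundary (about one cell diameter by
#' default) and either stays in the opposite zone for `dwell_min` minutes
#' or is still there when its track ends. With `margin_um = 0` (or
#' without boundary information) the plain zone-label change is used.
#'
#' @param x A `gc_run` (tracked) or a track data frame with a `zone`
#'   column (0 dark, 1 light).
#' @param window_min Observation window; samples beyond it are ignored.
#' @param margin_um Depth beyond the boundary plane required to switch
#'   the scored zone (default 10).
#' @param dwell_min Minimum stay in the opposite zone (default 20 min).
#' @param boundary_um z-position of the boundary plane (light zone at
#'   `z >= boundary_um`); taken from the run when `x` is a `gc_run`.
#' @return List: `rate_pct`, `n_tracked`, `n_crossed`, `n_dz_to_lz`,
#'   `n_lz_to_dz`.
#' @export
transzone_event_rate <- function(x, window_min = 60, margin_um = 10,
                                 dwell_min = 20, boundary_um = NULL) {
  if (inherits(x, "gc_run")) {
    tracks <- x$tracks
    if (is.null(boundary_um)) boundary_um <- x$zone_boundary_um
  } else tracks <- x
  use_margin <- margin_um > 0 && !is.null(boundary_um)
  sp <- split(tracks, tracks$cell_id)
  res <- t(vapply(sp, function(tr) {
    tr <- tr[order(tr$t_min), ]
    tr <- tr[tr$t_min - tr$t_min[1] <= window_min + 1e-9, , drop = FALSE]
    if (nrow(tr) < 2) return(c(0, 0, 0))
    if (use_margin) {
      lab0 <- if (tr$z_um[1] >= boundary_um) 1 else 0
      lab <- lab0
      labs <- numeric(nrow(tr)); labs[1] <- lab0
      for (i in 2:nrow(tr)) {
        z <- tr$z_um[i]
        lab <- if (z >= boundary_um + margin_um) 1
               else if (z < boundary_um - margin_um) 0 else lab
        labs[i] <- lab
      }
      opp <- labs != lab0
      if (!any(opp)) return(c(0, lab0, 0))
      r <- rle(opp)
      dt0 <- tr$t_min[2] - tr$t_min[1]
      stay <- max(r$lengths[r$values]) * dt0
      ok <- stay >= dwell_min || opp[length(opp)]
      c(as.numeric(ok), lab0, 0)
    } else {
      z0 <- tr$zone[1]
      c(as.numeric(any(tr$zone != z0)), z0, 0)
    }
  }, numeric(3)))
  crossed <- res[, 1] > 0
  list(rate_pct = 100 * mean(crossed),
       n_tracked = nrow(res),
       n_crossed = sum(crossed),
       n_dz_to_lz = sum(crossed & res[, 2] == 0),
       n_lz_to_dz = sum(crossed & res[, 2] == 1))
}

#' Dark-zone to light-zone ratio
#'
#' Ratio of B cells located in the dark zone to those in the light zone,
#' optionally for the DEC205-positive or -negative subpopulation, per
#' time-series sample of a run.
#'
#' @param run A `gc_run`.
#' @param subpopulation "all", "dec205_pos" or "dec205_neg".
#' @return Data frame `day`, `ratio` (NA where the light zone is empty).
#' @export
dz_lz_ratio <- function(run, subpopulation = c("all", "dec205_pos",
                                               "dec205_neg")) {
  subpopulation <- match.arg(subpopulation)
  ts <- run$ts
  num <- switch(subpopulation, all = ts$n_dz, dec205_pos = ts$dec_pos_dz,
                dec205_neg = ts$dec_neg_dz)
  den <- switch(subpopulation, all = ts$n_lz, dec205_pos = ts$dec_pos_lz,
                dec205_neg = ts$dec_neg_lz)
  data.frame(day = ts$day, ratio = ifelse(den > 0, num / den, NA_real_))
}

#' Photoactivation transzone time course
#'
#' Fraction of cells photoactivated in one zone that are found in the
#' opposite zone over time (labeled apoptotic cells count at their death
#' position until cleared; the label is conserved, so the labeled count
#' never increases).
#'
#' @param run A `gc_run` executed with a [photoactivation_request()].
#' @return Data frame `t_h` (hours since photoactivation), `frac_opposite`
#'   (of the initially labeled cells), `labeled_visible`.
#' @export
photoactivation_fractions <- function(run) {
  if (is.null(run$photo) || nrow(run$photo) == 0 || run$photo_n0 == 0)
    stop("run has no photoactivated cells", call. = FALSE)
  ph <- run$photo
  # all labeled cells start in the activated zone, so the opposite zone is
  # the minority zone of the first sample
  opposite <- if (ph$in_dz[1] >= ph$in_lz[1]) "in_lz" else "in_dz"
  data.frame(
    t_h = (ph$t_min - ph$t_min[1]) / 60,
    frac_opposite = ph[[opposite]] / run$photo_n0,
    labeled_visible = ph$in_dz + ph$in_lz)
}
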