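#' Analytic fixture tracks for the imaging analytics
#'
#' Off-lattice tracks with known ground truth, used to test the
#' displacement, speed and turning-angle operators independently of the
#' lattice simulation:
#' \describe{
#'   \item{stationary}{cells that never move (all analytics zero/empty).}
#'   \item{ballistic}{straight motion at speed `v` in a random fixed
#'     direction; mean displacement is exactly `v t`.}
#'   \item{prw}{run-and-tumble persistent random walk: ballistic segments
#'     at speed `v` with fully randomized direction at Poisson rate
#'     `1/tau`. Its velocity autocorrelation is `exp(-t/tau)`, so the mean
#'     squared displacement follows the persistent-random-walk closed form
#'     `MSD(t) = 2 v^2 tau (t - tau (1 - exp(-t/tau)))` with long-time
#'     diffusivity `D = v^2 tau / 3`.}
#'   \item{prw_drift}{the same walk plus a constant drift velocity,
#'     biasing turning angles toward smaller values.}
#' }
#'
#' @param kind One of "stationary", "ballistic", "prw", "prw_drift".
#' @param n_tracks Number of tracks.
#' @param duration_min Track duration (min).
#' @param interval_s Sampling interval (s).
#' @param v Speed (um/min).
#' @param tau Persistence time (min).
#' @param drift Drift velocity 3-vector (um/min), for "prw_drift".
#' @param seed Integer seed.
#' @return Track data frame (`cell_id`, `t_min`, `x_um`, `y_um`, `z_um`,
#'   `zone`, `frozen`).
#' @export
generate_fixture_tracks <- function(kind = c("stationary", "ballistic",
                                             "prw", "prw_drift"),
                                    n_tracks = 50, duration_min = 30,
                                    interval_s = 20, v = 7.5, tau = 1.5,
                                    drift = c(2, 0, 0), seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  dt <- interval_s / 60
  t_s <- seq(0, duration_min, by = dt)
  one <- function(id) {
    pos <- switch(kind,
      stationary = matrix(0, length(t_s), 3),
      ballistic = {
        u <- random_direction()
        outer(t_s, u) * v
      },
      prw = prw_positions(t_s, v, tau),
      prw_drift = prw_positions(t_s, v, tau) + outer(t_s, drift)
    )
    data.frame(cell_id = id, t_min = t_s, x_um = pos[, 1], y_um = pos[, 2],
               z_um = pos[, 3], zone = 0, frozen = 0)
  }
  do.call(rbind, lapply(seq_len(n_tracks), one))
}

random_direction <- function() {
  z <- stats::rnorm(3)
  z / sqrt(sum(z^2))
}

# exact event-driven run-and-tumble: exponential segment durations,
# positions integrated piecewise-ballistically at the sample times
prw_positions <- function(t_s, v, tau) {
  t_end <- max(t_s)
  # tumble times
  tt <- 0
  while (sum(tt) < t_end) tt <- c(tt, stats::rexp(1, rate = 1 / tau))
  bounds <- cumsum(tt)
  dirs <- t(vapply(seq_along(bounds), function(i) random_direction(),
                   numeric(3)))
  pos <- matrix(0, length(t_s), 3)
  cur <- c(0, 0, 0)
  seg <- 1
  seg_start <- 0
  for (i in seq_along(t_s)[-1]) {
    target <- t_s[i]
    t_now <- t_s[i - 1]
    while (bounds[seg] < target) {
      cur <- cur + v * (bounds[seg] - t_now) * dirs[seg, ]
      t_now <- bounds[seg]
      seg <- seg + 1
    }
    cur <- cur + v * (target - t_now) * dirs[seg, ]
    pos[i, ] <- cur
  }
  pos
}
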