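#' Hysteretic chemokine sensitivity update
#'
#' A cell sensitive to its chemokine desensitizes when the local
#' concentration reaches the critical value `c_D`; an insensitive cell
#' resensitizes only once the concentration has fallen to `c_R < c_D`.
#' Between the two thresholds the state is unchanged (hysteresis), which is
#' what makes chemotaxis transient: cells inside their zone do a random
#' walk and are only pulled back when they stray toward the boundary.
#'
#' @param sensitive Logical vector of current sensitivity states.
#' @param c_local Local chemokine concentration(s), non-negative.
#' @param c_d Desensitization threshold.
#' @param c_r Resensitization threshold (must be `< c_d`).
#' @return Updated logical sensitivity vector.
#' @export
update_sensitivity <- function(sensitive, c_local, c_d, c_r) {
  if (c_r >= c_d) stop("hysteresis requires c_r < c_d", call. = FALSE)
  if (any(c_local < 0)) stop("concentration must be non-negative",
                             call. = FALSE)
  n <- max(length(sensitive), length(c_local))
  cpp_update_sensitivity(rep_len(as.logical(sensitive), n),
                         rep_len(as.numeric(c_local), n), c_d, c_r)
}

#' Draw new polarity vectors
#'
#' Repolarization of the persistent random walk: a new direction is drawn
#' at a turning angle sampled from a Gaussian (default mean 60 degrees)
#' around the old polarity with uniform azimuth. If the cell is sensitive
#' and a gradient is present, the normalized gradient direction is added
#' with weight `w` and the sum is renormalized, biasing turning angles
#' below the Gaussian mean.
#'
#' @param old Current polarity (3-vector; a zero vector re-initializes
#'   uniformly at random).
#' @param grad Chemokine gradient 3-vector.
#' @param sensitive Whether the cell currently senses the chemokine.
#' @param w Gradient weight.
#' @param mean_turn_deg,sigma_turn_deg Turning-angle Gaussian parameters.
#' @param n Number of draws.
#' @return `n x 3` matrix of unit polarity vectors.
#' @export
new_polarity <- function(old, grad = c(0, 0, 0), sensitive = TRUE, w = 1,
                         mean_turn_deg = 60, sigma_turn_deg = 25, n = 1) {
  cpp_new_polarity(as.numeric(old), as.numeric(grad), isTRUE(sensitive),
                   w, mean_turn_deg, sigma_turn_deg, as.integer(n))
}

#' Lattice direction choice from a continuous polarity
#'
#' Samples one of the six lattice directions with probability proportional
#' to the positive projection of the polarity vector, which realizes
#' off-axis net motion on the lattice.
#'
#' @param pol Polarity 3-vector.
#' @param n Number of draws.
#' @return Integer directions 1..6 in the order +x, -x, +y, -y, +z, -z.
#' @export
choose_lattice_direction <- function(pol, n = 1) {
  cpp_choose_direction(as.numeric(pol), as.integer(n)) + 1L
}

#' Exchange fraction of two opposing cells
#'
#' When a cell attempts to move onto an occupied node and the two cells'
#' polarity vectors oppose each other (negative scalar product), the cells
#' exchange positions with probability 0.5; otherwise the move fails. This
#' helper runs the exchange rule in isolation.
#'
#' @param pol_a,pol_b Polarity 3-vectors of the mover and the resident.
#' @param n Number of trials.
#' @return Fraction of trials in which the cells swapped.
#' @export
exchange_fraction <- function(pol_a, pol_b, n = 1e5) {
  cpp_exchange_fraction(as.numeric(pol_a), as.numeric(pol_b), as.integer(n))
}

#' Masked antigen fraction at fixed antibody concentration
#'
#' Integrates the antibody-antigen binding kinetics
#' `db/dt = k_on * Ab * (1 - b) - k_off * b` used by the feedback module,
#' at a constant antibody concentration. Converges to the closed-form
#' equilibrium `k_on*Ab / (k_on*Ab + k_off)` (equivalently the free
#' fraction converges to `k_off / (k_off + k_on*Ab)`).
#'
#' @param ab Antibody concentration (M).
#' @param k_on Association rate (1/(M min)).
#' @param k_off Dissociation rate (1/min).
#' @param t_end Integration time (min).
#' @param dt Step (min).
#' @return Bound (masked) fraction trajectory.
#' @export
masked_fraction <- function(ab, k_on = 1e5, k_off = 1e-3,
                            t_end = 1e4, dt = 1) {
  cpp_masking_ode(ab, k_on, k_off, dt, as.integer(ceiling(t_end / dt)))
}
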