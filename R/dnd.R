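#' Hill-function parameters for the dynamic number of divisions (DND)
#'
#' Upon positive selection, the number of divisions granted to a B cell is
#' a Hill function of the number of antigen collection events `a`:
#' `P(a) = P_min + (P_max - P_min) * a^n_P / (a^n_P + K_P^n_P)`.
#'
#' @param p_min Minimal number of divisions (default 1).
#' @param p_max Maximal number of divisions (default 6).
#' @param n_p Hill coefficient (default 1.3).
#' @param k_p Antigen collection events at the Hill midpoint, i.e. where
#'   `P = (P_min + P_max)/2` (default 11.619).
#' @return Object of class `dnd_params`.
#' @export
dnd_params <- function(p_min = 1, p_max = 6, n_p = 1.3, k_p = 11.619) {
  stopifnot(p_min <= p_max, n_p > 0, k_p > 0)
  structure(list(p_min = p_min, p_max = p_max, n_p = n_p, k_p = k_p),
            class = "dnd_params")
}

#' Number of divisions granted for a given antigen count
#'
#' Evaluates the DND Hill function. The real-valued result is what the
#' stochastic rounding of [draw_dnd_divisions()] realizes in expectation.
#'
#' @param a Antigen collection events (non-negative, vectorized).
#' @param params A [dnd_params()].
#' @return Real-valued divisions in `[p_min, p_max]`.
#' @export
dnd_divisions <- function(a, params = dnd_params()) {
  if (any(a < 0)) stop("antigen count must be non-negative", call. = FALSE)
  cpp_hill_divisions(as.numeric(a), params$p_min, params$p_max,
                     params$n_p, params$k_p)
}

#' Stochastically rounded division numbers
#'
#' The fractional part of the Hill value is realized as one extra division
#' with matching probability, so the mean equals the Hill value exactly.
#'
#' @param a Antigen collection events (vectorized; recycled draws).
#' @param params A [dnd_params()].
#' @param n Number of draws (default `length(a)`).
#' @return Integer divisions, each in `[p_min, p_max]`.
#' @export
draw_dnd_divisions <- function(a, params = dnd_params(), n = length(a)) {
  vals <- dnd_divisions(rep_len(a, n), params)
  cpp_stochastic_round(vals)
}
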