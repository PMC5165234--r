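#' Affinity model on the discrete shape space
#'
#' B cell receptor genotypes live on a bounded integer lattice ("shape
#' space"); one unit step along one axis is one point mutation. The binding
#' probability (affinity) of a receptor decays as a Gaussian in the L1
#' distance `d` to the optimal clone: `exp(-(d/gamma)^2)`, so the optimal
#' clone binds with probability 1 and affinity falls to `exp(-1)` at
#' distance `gamma`.
#'
#' @param optimal Integer vector, position of the best possible receptor
#'   (default the origin in 4 dimensions).
#' @param gamma Affinity width in mutation steps (> 0).
#' @param p_mut Mutation probability per division.
#' @param bound Per-axis bound of the shape space (coordinates in
#'   `[-bound, bound]`).
#' @return Object of class `affinity_model`.
#' @export
affinity_model <- function(optimal = rep(0L, 4), gamma = 2.8, p_mut = 0.3,
                           bound = 10L) {
  stopifnot(gamma > 0, p_mut >= 0, p_mut <= 1, all(abs(optimal) <= bound))
  structure(list(optimal = as.integer(optimal), gamma = gamma,
                 p_mut = p_mut, bound = as.integer(bound)),
            class = "affinity_model")
}

#' L1 distance between two shape-space points
#'
#' Counts the minimal number of point mutations separating two receptor
#' genotypes.
#'
#' @param a,b Integer coordinate vectors of equal length.
#' @return Non-negative integer distance.
#' @export
shape_distance <- function(a, b) {
  if (length(a) != length(b))
    stop("shape points must have the same dimension", call. = FALSE)
  sum(abs(as.numeric(a) - as.numeric(b)))
}

#' Affinity of a receptor at a given shape-space distance
#'
#' @param dist Non-negative distance(s) to the optimal clone.
#' @param model An [affinity_model()].
#' @return Binding probability in (0, 1]; 1 at distance 0, strictly
#'   decreasing in `dist`.
#' @export
affinity <- function(dist, model = affinity_model()) {
  if (any(dist < 0)) stop("distance must be non-negative", call. = FALSE)
  exp(-(dist / model$gamma)^2)
}

#' Mutate a shape-space point
#'
#' With probability `model$p_mut` the point moves to a uniformly chosen
#' in-bound unit neighbor (one point mutation); otherwise it is returned
#' unchanged. Points on the boundary choose among their in-bound neighbors
#' only.
#'
#' @param p Integer coordinate vector.
#' @param model An [affinity_model()].
#' @return Integer coordinate vector of the same dimension.
#' @export
mutate_shape <- function(p, model = affinity_model()) {
  p <- as.integer(p)
  if (any(abs(p) > model$bound))
    stop("point outside shape-space bounds", call. = FALSE)
  if (stats::runif(1) >= model$p_mut) return(p)
  d <- length(p)
  moves <- cbind(rep(seq_len(d), each = 2), c(-1L, 1L))
  ok <- abs(p[moves[, 1]] + moves[, 2]) <= model$bound
  moves <- moves[ok, , drop = FALSE]
  if (nrow(moves) == 0) return(p)
  k <- sample.int(nrow(moves), 1)
  p[moves[k, 1]] <- p[moves[k, 1]] + moves[k, 2]
  p
}

# All 4-d integer points with L1 norm within [dmin, dmax]: the pool founder
# clones are drawn from ("5-10 mutations from the germline").
founder_shape_pool <- function(dmin = 5L, dmax = 10L, bound = 10L) {
  r <- -min(dmax, bound):min(dmax, bound)
  g <- as.matrix(expand.grid(r, r, r, r))
  d <- rowSums(abs(g))
  m <- g[d >= dmin & d <= dmax, , drop = FALSE]
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  m
}
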