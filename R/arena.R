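#' Build the simulation arena
#'
#' Constructs the 3D lattice (a spherical GC inside a bounding box), the
#' dark/light-zone geometry (equatorial plane perpendicular to the z axis;
#' nodes on the plane belong to the light zone), the FDC network (somata at
#' random light-zone nodes with dendrites reaching out along the axes;
#' dendrite nodes are transparent to movement and act as antigen contact
#' sites), the CXCL12 source cap on the dark-zone boundary toward the T
#' zone, and the precomputed steady-state chemokine fields with their
#' gradients. The chemokine thresholds of the transient-chemotaxis model
#' are calibrated against the concentration at the zone boundary.
#'
#' Fields are cached per geometry/chemokine configuration (see
#' `options(gcsim.cache = FALSE)` to disable).
#'
#' @param config A [gc_config()].
#' @param cache Reuse a previously solved field for the same configuration.
#' @return Object of class `gc_arena`.
#' @export
build_arena <- function(config = gc_config(), cache = TRUE) {
  a <- config$arena
  rn <- a$radius_um / a$dx_um              # radius in nodes
  n <- 2L * as.integer(ceiling(rn)) + 3L   # nodes per axis incl. margin
  c0 <- (n - 1L) / 2                        # 0-based center
  ax <- 0:(n - 1L)
  X <- rep(ax, times = n * n)
  Y <- rep(rep(ax, each = n), times = n)
  Z <- rep(ax, each = n * n)
  r2 <- (X - c0)^2 + (Y - c0)^2 + (Z - c0)^2
  inside <- r2 <= rn^2
  zone <- ifelse(!inside, -1L, ifelse(Z >= c0, 1L, 0L))

  # FDC network in the light zone; drawn from the arena's own seed so the
  # FDC distribution (and hence the cached fields) is fixed across runs,
  # without disturbing the caller's RNG stream
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(a$seed)
  lz_idx <- which(inside & Z >= c0 + 1 & r2 <= (rn - a$dendrite_nodes)^2)
  if (length(lz_idx) < a$n_fdc)
    stop("arena too small for the requested number of FDCs", call. = FALSE)
  soma <- if (a$n_fdc > 0) sample(lz_idx, a$n_fdc) else integer(0)
  node_xyz <- function(i) cbind((i - 1L) %% n,
                                ((i - 1L) %/% n) %% n,
                                (i - 1L) %/% (n * n))
  dend <- integer(0)
  if (length(soma) > 0 && a$dendrite_nodes > 0) {
    sx <- node_xyz(soma)
    for (k in seq_len(a$dendrite_nodes)) {
      for (d in list(c(k, 0, 0), c(-k, 0, 0), c(0, k, 0), c(0, -k, 0),
                     c(0, 0, k), c(0, 0, -k))) {
        nx <- sx[, 1] + d[1]; ny <- sx[, 2] + d[2]; nz <- sx[, 3] + d[3]
        ok <- nx >= 0 & ny >= 0 & nz >= 0 & nx < n & ny < n & nz < n
        ii <- 1L + nx[ok] + n * (ny[ok] + n * nz[ok])
        dend <- c(dend, ii[inside[ii]])
      }
    }
    dend <- setdiff(unique(dend), soma)
  }
  fdc_site <- rep(-1L, n^3)
  if (length(dend) > 0) fdc_site[dend] <- seq_along(dend) - 1L
  fdc_free <- rep(a$fdc_antigen_per_node, length(dend))

  # CXCL12 sources: stromal shell cap on the dark-zone pole
  shell <- inside & r2 >= (rn - 1.5)^2
  cap12 <- which(shell & (Z - c0) <= -a$cxcl12_cap * rn)
  src13 <- soma

  key <- list(n = n, rn = rn, soma = soma, cap12 = cap12,
              D = a$diffusion_um2_min, k = a$degradation_min,
              q = a$source_rate, dx = a$dx_um)
  fields <- solve_fields_cached(key, a, n, src13, cap12, cache)

  # threshold calibration: own-chemokine concentration at the zone boundary
  bnd <- inside & Z == floor(c0) + 1L  # first LZ plane (boundary by convention)
  cb12 <- mean(fields$c12[bnd])
  cb13 <- mean(fields$c13[bnd])

  occ <- rep(-1L, n^3)
  occ[!inside] <- -9L
  occ[soma] <- -9L

  structure(list(
    n = n, dx = a$dx_um, center = c0, radius_nodes = rn,
    inside = which(inside) - 1L,          # 0-based for the core
    zone = zone, occ = occ,
    fdc_site = fdc_site, fdc_free = fdc_free,
    soma = soma, n_dendrite_nodes = length(dend),
    c12 = fields$c12, c13 = fields$c13,
    g12 = fields$g12, g13 = fields$g13,
    boundary_conc = c(cxcl12 = cb12, cxcl13 = cb13),
    config = config
  ), class = "gc_arena")
}

#' @export
print.gc_arena <- function(x, ...) {
  cat("gc_arena: ", x$n, "^3 lattice (", x$dx, " um), GC radius ",
      x$radius_nodes * x$dx, " um, ", length(x$inside), " nodes inside\n",
      "  FDC somata: ", length(x$soma), ", antigen contact nodes: ",
      x$n_dendrite_nodes, "\n",
      "  boundary concentrations: CXCL12 ", signif(x$boundary_conc[1], 3),
      ", CXCL13 ", signif(x$boundary_conc[2], 3), "\n", sep = "")
  invisible(x)
}

#' Packing fraction of an arena for a given cell number
#'
#' Fraction of GC nodes occupied by a given number of cells; a coarser
#' lattice at the same target cell number is more densely packed, which
#' inhibits movement.
#'
#' @param arena A `gc_arena`.
#' @param n_cells Number of resident cells.
#' @return Occupied fraction of GC nodes.
#' @export
packing_fraction <- function(arena, n_cells) {
  n_cells / length(arena$inside)
}

# ---------------------------------------------------------------- chemokines

# 7-point-stencil operator for  -D lap(c) + k c = s  with zero-Dirichlet
# boundary conditions on the box faces.
chemokine_operator <- function(n, D, k, dx) {
  h2 <- dx^2
  ii <- seq_len(n^3)
  x <- (ii - 1L) %% n
  y <- ((ii - 1L) %/% n) %% n
  z <- (ii - 1L) %/% (n * n)
  interior <- x > 0 & x < n - 1 & y > 0 & y < n - 1 & z > 0 & z < n - 1
  from <- ii[interior]
  nbr <- cbind(from - 1L, from + 1L, from - n, from + n,
               from - n * n, from + n * n)
  i_idx <- c(from, rep(from, 6L))
  j_idx <- c(from, as.vector(nbr))
  v <- c(rep(k + 6 * D / h2, length(from)), rep(-D / h2, 6L * length(from)))
  # boundary rows: identity (c = 0)
  bnd <- ii[!interior]
  i_idx <- c(i_idx, bnd); j_idx <- c(j_idx, bnd)
  v <- c(v, rep(1, length(bnd)))
  Matrix::sparseMatrix(i = i_idx, j = j_idx, x = v, dims = c(n^3, n^3))
}

# Conjugate gradients on the (symmetric after boundary elimination,
# positive definite) stencil; residual-checked with an iteration cap.
solve_cg <- function(A, b, tol = 1e-8, max_iter = 5000) {
  x <- numeric(length(b))
  r <- b - as.numeric(A %*% x)
  p <- r
  rs <- sum(r * r)
  b2 <- sqrt(sum(b * b))
  if (b2 == 0) return(x)
  for (it in seq_len(max_iter)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rs / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r * r)
    if (sqrt(rs_new) / b2 < tol) return(x)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  stop(sprintf(
    "chemokine solver did not converge in %d iterations (relative residual %.3g)",
    max_iter, sqrt(rs) / b2), call. = FALSE)
}

#' Steady-state chemokine field
#'
#' Solves the discrete diffusion-production-degradation balance
#' `-D lap(c) + k_deg c = s` on the lattice (7-point stencil, zero
#' concentration on the bounding-box faces, conjugate gradients with a
#' residual tolerance and iteration cap). Consumption of chemokine by
#' receptor internalization is neglected, so the field can be precomputed
#' once per FDC configuration and reused.
#'
#' @param n Nodes per axis of the cubic lattice.
#' @param sources 1-based node indices of producing nodes.
#' @param rate Production rate per source node (concentration/min).
#' @param D Diffusion constant (um^2/min).
#' @param k_deg Degradation rate (1/min).
#' @param dx Lattice constant (um).
#' @param tol Relative residual tolerance.
#' @param max_iter Iteration cap; exceeding it is an error reporting the
#'   residual.
#' @return Numeric vector of concentrations per node (length `n^3`).
#' @export
solve_chemokine_steady_state <- function(n, sources, rate = 1, D = 600,
                                         k_deg = 0.24, dx = 5,
                                         tol = 1e-8, max_iter = 5000) {
  stopifnot(D > 0, k_deg > 0)
  A <- chemokine_operator(n, D, k_deg, dx)
  b <- numeric(n^3)
  b[sources] <- rate
  c <- solve_cg(A, b, tol = tol, max_iter = max_iter)
  pmax(c, 0)
}

#' Time-dependent chemokine relaxation (cross-check solver)
#'
#' Explicit-Euler integration of `dc/dt = D lap(c) - k_deg c + s` used to
#' cross-validate the steady-state solve on small lattices.
#'
#' @inheritParams solve_chemokine_steady_state
#' @param t_end Integration time (min).
#' @param dt Time step (min); must satisfy the diffusion stability limit.
#' @return Concentration vector after `t_end`.
#' @export
solve_chemokine_transient <- function(n, sources, rate = 1, D = 600,
                                      k_deg = 0.24, dx = 5,
                                      t_end = 50, dt = NULL) {
  stab <- dx^2 / (6 * D) * 0.9
  if (is.null(dt)) dt <- stab
  if (dt > dx^2 / (6 * D)) stop("dt violates the diffusion stability limit",
                                call. = FALSE)
  A <- chemokine_operator(n, D, k_deg, dx)  # A c = s at steady state
  b <- numeric(n^3)
  b[sources] <- rate
  c <- numeric(n^3)
  steps <- ceiling(t_end / dt)
  for (i in seq_len(steps)) {
    c <- c + dt * (b - as.numeric(A %*% c))
    c[c < 0] <- 0
  }
  c
}

# central differences, one-sided at the box faces; returns list(x=,y=,z=)
field_gradient <- function(c, n, dx) {
  arr <- array(c, dim = c(n, n, n))
  grad1 <- function(a, d) {
    g <- array(0, dim = dim(a))
    idx <- function(i) switch(d,
      a[i, , , drop = FALSE], a[, i, , drop = FALSE], a[, , i, drop = FALSE])
    asn <- function(i, v) switch(d,
      g[i, , ] <<- v, g[, i, ] <<- v, g[, , i] <<- v)
    asn(2:(n - 1), (idx(3:n) - idx(1:(n - 2))) / (2 * dx))
    asn(1, (idx(2) - idx(1)) / dx)
    asn(n, (idx(n) - idx(n - 1)) / dx)
    g
  }
  list(x = as.numeric(grad1(arr, 1L)),
       y = as.numeric(grad1(arr, 2L)),
       z = as.numeric(grad1(arr, 3L)))
}

#' Chemokine gradient at a node
#'
#' Discrete gradient (central differences; one-sided at the box faces) of a
#' concentration field at one node.
#'
#' @param conc Concentration vector (length `n^3`).
#' @param n Nodes per axis.
#' @param node 1-based node index.
#' @param dx Lattice constant (um).
#' @return Numeric 3-vector (concentration per um).
#' @export
gradient_at <- function(conc, n, node, dx = 5) {
  if (node < 1 || node > n^3) stop("node outside lattice", call. = FALSE)
  g <- field_gradient(conc, n, dx)
  c(g$x[node], g$y[node], g$z[node])
}

#' Zone classification of a node
#'
#' Deterministic dark/light-zone label by position relative to the
#' equatorial boundary plane; nodes on the plane count as light zone.
#'
#' @param arena A `gc_arena`.
#' @param node 1-based node index (vectorized).
#' @return Character vector "DZ"/"LZ" (NA outside the GC).
#' @export
classify_zone <- function(arena, node) {
  z <- arena$zone[node]
  out <- ifelse(z == 1L, "LZ", ifelse(z == 0L, "DZ", NA_character_))
  out
}

# ------------------------------------------------------------------- cache

the_field_cache <- new.env(parent = emptyenv())

config_hash <- function(key) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(key, f, version = 2)
  unname(tools::md5sum(f))
}

solve_fields_cached <- function(key, a, n, src13, cap12, cache) {
  h <- config_hash(key)
  if (cache && !is.null(the_field_cache[[h]])) return(the_field_cache[[h]])
  disk <- NULL
  if (cache && isTRUE(getOption("gcsim.cache", TRUE))) {
    dir <- file.path(tempdir(), "gcsim-fields")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    disk <- file.path(dir, paste0(h, ".rds"))
    if (file.exists(disk)) {
      out <- readRDS(disk)
      the_field_cache[[h]] <- out
      return(out)
    }
  }
  c13 <- solve_chemokine_steady_state(n, src13, a$source_rate,
                                      a$diffusion_um2_min, a$degradation_min,
                                      a$dx_um, a$tol, a$max_iter)
  c12 <- solve_chemokine_steady_state(n, cap12, a$source_rate,
                                      a$diffusion_um2_min, a$degradation_min,
                                      a$dx_um, a$tol, a$max_iter)
  out <- list(c12 = c12, c13 = c13,
              g12 = field_gradient(c12, n, a$dx_um),
              g13 = field_gradient(c13, n, a$dx_um))
  the_field_cache[[h]] <- out
  if (!is.null(disk)) saveRDS(out, disk, version = 2)
  out
}
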