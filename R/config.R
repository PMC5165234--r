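#' Default simulation configuration
#'
#' Returns the full nested configuration of the germinal-center simulation
#' with reference defaults. Every entry can be overridden through
#' [gc_config()] or a YAML file read with [load_config()].
#'
#' Sections:
#' \describe{
#'   \item{arena}{lattice geometry, FDC network and chemokine field solver:
#'     `radius_um` (GC radius, 160), `dx_um` (lattice constant, 5),
#'     `n_fdc` (FDC somata, 200), `dendrite_nodes` (dendrite reach in nodes,
#'     2), `fdc_antigen_per_node` (antigen portions per contact node, 20),
#'     `cxcl12_cap` (fraction of the radius defining the polar source cap on
#'     the dark-zone side, 0.5), `diffusion_um2_min` (600),
#'     `degradation_min` (0.24), `source_rate` (1), `tol`, `max_iter`.}
#'   \item{shape}{discrete shape space: `dim` (4), `bound` (per-axis bound,
#'     10), `gamma` (affinity width in mutation steps, 2.8), `p_mut`
#'     (mutation probability per division, 0.3), `founder_dist` (range of
#'     founder distances from the optimal clone, c(5, 10)).}
#'   \item{motility}{`v_um_min` (B cell speed, 7.5), `v_tfh_um_min` (10),
#'     `tau_range_min` (persistence time range, c(1, 2)), `mean_turn_deg`
#'     (60), `sigma_turn_deg` (25), `w_chemo` (gradient weight, 1),
#'     `dt_min` (timestep, 1/3 min = 20 s), `preset` (chemotaxis preset,
#'     one of "reference", "low_resens", "boundary_desens"), `cd_mult`,
#'     `cr_mult` (optional explicit threshold multiples of the
#'     zone-boundary concentration; override the preset).}
#'   \item{gc}{`influx_per_h` (founder influx, 2), `influx_window_days` (4),
#'     `initial_divisions` (6), `cycle_h` (7), `cycle_jitter` (0.1),
#'     `mphase_h` (0.5), `collect_window_h` (10), `contact_freeze_min` (5),
#'     `capture_efficiency` (success scale of one antigen-capture test,
#'     0.15), `tfh_window_h` (6), `tfh_required_h` (accumulated conjugate
#'     time for positive selection, 3), `n_tfh` (250),
#'     `corpse_visible_h` (6), `p_asym` (0.72), `f_asym` (0.72).}
#'   \item{dnd}{Hill-function division control: `p_min` (1), `p_max` (6),
#'     `n_p` (1.3), `k_p` (11.619), `enabled`.}
#'   \item{feedback}{antibody feedback: `enabled`, `k_on` (1/(M min), 1e5),
#'     `production_mol_min` (antibody production per plasma cell, 1e-17),
#'     `n_gc` (GCs per organism, 100), `volume_l` (dilution volume, 0.01),
#'     `kd_range` (dissociation constants at affinity 0 and 1,
#'     c(1e-6, 1e-8), log-interpolated), `ab_halflife_days` (antibody
#'     elimination half-life, 5).}
#'   \item{dec205}{targeted antigen delivery: `enabled`, `fraction` (0.5),
#'     `injection_day` (5), `window_h` (12), `antigen_boost` (35).}
#' }
#'
#' @return Nested list of configuration sections.
#' @export
gc_defaults <- function() {
  list(
    arena = list(
      radius_um = 160, dx_um = 5, n_fdc = 200, dendrite_nodes = 2,
      fdc_antigen_per_node = 50, cxcl12_cap = 0.5,
      diffusion_um2_min = 600, degradation_min = 0.24, source_rate = 1,
      tol = 1e-8, max_iter = 5000, seed = 1L
    ),
    shape = list(
      dim = 4L, bound = 10L, gamma = 2.8, p_mut = 0.3,
      founder_dist = c(5L, 10L)
    ),
    motility = list(
      v_um_min = 7.5, v_tfh_um_min = 10,
      tau_range_min = c(1, 2), mean_turn_deg = 60, sigma_turn_deg = 25,
      w_chemo = 1, dt_min = 1 / 3,
      preset = "reference", cd_mult = NULL, cr_mult = NULL
    ),
    gc = list(
      influx_per_h = 2, influx_window_days = 4, initial_divisions = 6L,
      cycle_h = 7, cycle_jitter = 0.1, mphase_h = 0.5,
      collect_window_h = 10, contact_freeze_min = 5,
      capture_efficiency = 0.15,
      tfh_window_h = 6, tfh_required_h = 3, n_tfh = 250L,
      corpse_visible_h = 6, p_asym = 0.72, f_asym = 0.72
    ),
    dnd = list(p_min = 1, p_max = 6, n_p = 1.3, k_p = 11.619, enabled = TRUE),
    feedback = list(
      enabled = TRUE, k_on = 1e5, production_mol_min = 1e-17,
      n_gc = 100, volume_l = 0.01, kd_range = c(1e-6, 1e-8),
      ab_halflife_days = 5
    ),
    dec205 = list(
      enabled = FALSE, fraction = 0.5, injection_day = 5,
      window_h = 12, antigen_boost = 35
    )
  )
}

#' Chemotaxis sensitivity presets
#'
#' Desensitization (`cd_mult`) and resensitization (`cr_mult`) thresholds as
#' multiples of the chemokine concentration at the dark/light-zone boundary.
#' The reference scenario desensitizes cells well inside their zone and
#' resensitizes them at the zone boundary, keeping zones tight. The two
#' alternative presets produce leaky zones: `low_resens` moves the
#' resensitization surface deep into the opposite zone, `boundary_desens`
#' desensitizes already at the boundary with resensitization 30% lower.
#'
#' @param preset One of "reference", "low_resens", "boundary_desens".
#' @return List with `cd_mult` and `cr_mult`.
#' @export
chemotaxis_preset <- function(preset = c("reference", "low_resens",
                                         "boundary_desens")) {
  preset <- match.arg(preset)
  switch(preset,
    reference       = list(cd_mult = 2.0, cr_mult = 1.25),
    low_resens      = list(cd_mult = 2.0, cr_mult = 0.4),
    boundary_desens = list(cd_mult = 1.0, cr_mult = 0.7)
  )
}

merge_config <- function(defaults, override, path = "") {
  if (is.null(override)) return(defaults)
  if (!is.list(override)) stop("config section '", path, "' must be a list",
                               call. = FALSE)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "),
         call. = FALSE)
  for (nm in names(override)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], override[[nm]],
                                     paste0(path, ".", nm))
    } else {
      defaults[nm] <- list(override[[nm]])   # NULL-safe assignment
    }
  }
  defaults
}

validate_config <- function(cfg) {
  a <- cfg$arena; m <- cfg$motility; s <- cfg$shape
  if (a$dx_um <= 0) stop("arena.dx_um must be positive", call. = FALSE)
  if (a$radius_um < 4 * a$dx_um)
    stop("arena.radius_um must be at least 4 lattice constants", call. = FALSE)
  if (s$gamma <= 0) stop("shape.gamma must be positive", call. = FALSE)
  if (s$p_mut < 0 || s$p_mut > 1)
    stop("shape.p_mut must be a probability", call. = FALSE)
  if (s$dim != 4L)
    stop("the simulation core uses a 4-dimensional shape space", call. = FALSE)
  if (m$v_um_min <= 0 || any(m$tau_range_min <= 0))
    stop("speeds and persistence times must be positive", call. = FALSE)
  if (m$v_um_min * m$dt_min > a$dx_um)
    stop("motility.dt_min too large: a cell must not hop more than one node ",
         "per step (v*dt must not exceed dx)", call. = FALSE)
  pre <- resolve_preset(m)
  if (pre$cr_mult >= pre$cd_mult)
    stop("resensitization threshold must lie below the desensitization ",
         "threshold (cr_mult < cd_mult)", call. = FALSE)
  if (!is.null(cfg$dnd)) {
    d <- cfg$dnd
    if (d$p_min > d$p_max || d$n_p <= 0 || d$k_p <= 0)
      stop("invalid dnd parameters", call. = FALSE)
  }
  invisible(cfg)
}

resolve_preset <- function(motility) {
  pre <- chemotaxis_preset(motility$preset)
  if (!is.null(motility$cd_mult)) pre$cd_mult <- motility$cd_mult
  if (!is.null(motility$cr_mult)) pre$cr_mult <- motility$cr_mult
  pre
}

#' Build a simulation configuration
#'
#' Starts from [gc_defaults()] and applies overrides given as nested lists,
#' e.g. `gc_config(motility = list(preset = "low_resens"))`. Unknown keys are
#' rejected and the resulting configuration is validated.
#'
#' @param ... Named configuration sections with overriding entries.
#' @return Validated configuration list of class `gc_config`.
#' @export
gc_config <- function(...) {
  override <- list(...)
  cfg <- merge_config(gc_defaults(), override)
  validate_config(cfg)
  structure(cfg, class = c("gc_config", "list"))
}

#' Load a configuration from a YAML file
#'
#' Reads a YAML file with any subset of the configuration sections of
#' [gc_defaults()], fills missing entries with defaults, rejects unknown
#' keys and validates invariants (e.g. the resensitization threshold must
#' lie below the desensitization threshold). An empty file yields the
#' reference scenario.
#'
#' @param path Path to a YAML file.
#' @return Validated configuration list of class `gc_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  cfg <- merge_config(gc_defaults(), raw)
  validate_config(cfg)
  structure(cfg, class = c("gc_config", "list"))
}

#' @export
print.gc_config <- function(x, ...) {
  cat("germinal-center simulation configuration\n")
  for (sec in names(x)) {
    vals <- x[[sec]]
    show <- vapply(vals, function(v)
      paste0(format(unlist(v), trim = TRUE), collapse = ","), character(1))
    cat("  ", sec, ": ", paste0(names(vals), "=", show, collapse = " "),
        "\n", sep = "")
  }
  invisible(x)
}
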