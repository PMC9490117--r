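# Run configuration: nested list with a fixed schema, YAML round-trip.

default_config_tree <- function() {
  list(
    scale = "desk",
    geometry = list(
      scaffold = list(outer_radius = 10, inner_radius = 5, height = 40,
                      n_vertical_channels = 12, n_pore_rows_half = 5,
                      horizontal_center_pitch = 2.2, strut_min = 0),
      defect = list(cortical_outer_radius = 10, cortical_inner_radius = 7.5,
                    defect_length = 40, callus_max_width = 10,
                    callus_overlap = 10),
      design_scale = 1
    ),
    materials = list(scaffold_material = "titanium"),
    loads = list(axial_force = 1372, bending_moment = 17.125, load_scale = 1,
                 fixation_axial = 2000, fixation_lateral = 500, dt = 1),
    mechanoregulation = list(a = 0.0375, b = 0.03, resorption_upper = 0.01,
                             mature_upper = 0.53, immature_upper = 1,
                             cartilage_upper = 3, scheme = "darcy"),
    cells = list(migration_speed = 30,
                 proliferation_progenitor = 0.60,
                 proliferation_fibroblast = 0.55,
                 proliferation_chondrocyte = 0.20,
                 proliferation_osteoblast = 0.30,
                 apoptosis_progenitor = 0.05, apoptosis_fibroblast = 0.05,
                 apoptosis_chondrocyte = 0.10, apoptosis_osteoblast = 0.16,
                 differentiation_rate = 0.3, seeding_occupancy = 0.30,
                 graft_factor = 2, resorption_rate = 1),
    abm = list(n_days = 168, site_edge = 0.1, element_edge = 1.2),
    optimizer = list(algorithm = "particle_swarm",
                     pattern_start = c(2.05, 2.05, 1.65),
                     lhs_multiplier = 20, loop1_tolerance = 0.05,
                     loop2_max_extra = 30, loop1_max_extra = 30,
                     pso_pop = 30, pso_iter = 100,
                     ga_pop = 50, ga_gen = 50),
    seeds = list(run = 1)
  )
}

apply_scale_preset <- function(cfg, scale) {
  if (scale == "full") return(cfg)
  # desk: half linear scale, coarser sites/elements, stress-preserving loads
  g <- cfg$geometry
  g$scaffold$outer_radius <- 5; g$scaffold$inner_radius <- 2.5
  g$scaffold$height <- 20
  g$scaffold$horizontal_center_pitch <- 1.1
  g$defect <- list(cortical_outer_radius = 5, cortical_inner_radius = 3.75,
                   defect_length = 20, callus_max_width = 5,
                   callus_overlap = 5)
  g$design_scale <- 0.5
  cfg$geometry <- g
  cfg$loads$axial_force <- 1372 / 4       # area scales with 1/4
  cfg$loads$bending_moment <- 17.125 / 8  # section modulus scales with 1/8
  if (scale == "desk") {
    cfg$abm$site_edge <- 0.2
    cfg$abm$element_edge <- 2
  } else if (scale == "micro") {
    cfg$abm$site_edge <- 0.4
    cfg$abm$element_edge <- 2.4
    cfg$abm$n_days <- 28
  }
  cfg
}

#' Build a run configuration
#'
#' Returns the full nested configuration for a run at one of the built-in
#' scale presets: `"full"` (the 40 mm defect at 0.1 mm agent sites),
#' `"desk"` (a geometrically similar domain at half linear scale with 0.2 mm
#' sites and 2 mm mechanics elements) or `"micro"` (desk geometry at 0.4 mm
#' sites, 2.4 mm elements and 28-day runs, for optimization-in-the-loop
#' tests). Overrides are named nested values, e.g.
#' `scaffopt_config("desk", loads = list(load_scale = 1.5))`.
#'
#' @param scale Scale preset.
#' @param ... Named overrides merged over the preset; unknown keys are
#'   rejected.
#' @return An object of class `scaffopt_config`.
#' @export
scaffopt_config <- function(scale = c("desk", "full", "micro"), ...) {
  scale <- match.arg(scale)
  cfg <- default_config_tree()
  cfg$scale <- scale
  cfg <- apply_scale_preset(cfg, scale)
  dots <- list(...)
  if (length(dots) > 0) cfg <- merge_config(cfg, dots, path = "")
  validate_config(cfg)
  structure(cfg, class = "scaffopt_config")
}

merge_config <- function(base, override, path = "") {
  for (nm in names(override)) {
    here <- paste0(path, "$", nm)
    if (!nm %in% names(base)) {
      stop("unknown configuration key: ", here, call. = FALSE)
    }
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], here)
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  template <- default_config_tree()
  check <- function(tmpl, val, path) {
    extra <- setdiff(names(val), names(tmpl))
    if (length(extra) > 0) {
      stop("unknown configuration key(s): ",
           paste0(path, "$", extra, collapse = ", "), call. = FALSE)
    }
    for (nm in names(val)) {
      if (is.list(tmpl[[nm]])) check(tmpl[[nm]], val[[nm]], paste0(path, "$", nm))
    }
  }
  check(template, unclass(cfg), "config")
  stopifnot(cfg$loads$load_scale > 0, cfg$abm$n_days >= 0,
            cfg$abm$site_edge > 0, cfg$abm$element_edge > 0)
  invisible(cfg)
}

#' Read / write a configuration as YAML
#'
#' The full configuration round-trips through serialization unchanged;
#' unknown keys in a file are rejected on read.
#'
#' @param path File path.
#' @param config A [scaffopt_config()].
#' @return `read_config()` returns a `scaffopt_config`.
#' @export
read_config <- function(path) {
  raw_cfg <- yaml::read_yaml(path)
  scale <- raw_cfg$scale %||% "desk"
  raw_cfg$scale <- NULL
  do.call(scaffopt_config, c(list(scale = scale), raw_cfg))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- accessors used by the simulator ------------------------------------

scale_design <- function(design, design_scale) {
  if (design_scale == 1) return(design)
  scaffold_design(design$x1 * design_scale, design$x2 * design_scale,
                  design$x3 * design_scale, check_bounds = FALSE)
}

config_geometry <- function(cfg) {
  list(scaffold = do.call(scaffold_spec, cfg$geometry$scaffold),
       defect = do.call(defect_spec, cfg$geometry$defect))
}

config_rates <- function(cfg) {
  cc <- cfg$cells
  cell_rates(
    migration_speed = cc$migration_speed,
    proliferation = c(progenitor = cc$proliferation_progenitor,
                      fibroblast = cc$proliferation_fibroblast,
                      chondrocyte = cc$proliferation_chondrocyte,
                      osteoblast = cc$proliferation_osteoblast),
    apoptosis = c(progenitor = cc$apoptosis_progenitor,
                  fibroblast = cc$apoptosis_fibroblast,
                  chondrocyte = cc$apoptosis_chondrocyte,
                  osteoblast = cc$apoptosis_osteoblast),
    differentiation_rate = cc$differentiation_rate,
    seeding_occupancy = cc$seeding_occupancy,
    graft_factor = cc$graft_factor,
    resorption_rate = cc$resorption_rate)
}

config_thresholds <- function(cfg) {
  m <- cfg$mechanoregulation
  tissue_thresholds(m$resorption_upper, m$mature_upper, m$immature_upper,
                    m$cartilage_upper)
}

config_load <- function(cfg) {
  l <- cfg$loads
  fixation <- if (is.null(l$fixation_axial) || l$fixation_axial <= 0) NULL
  else list(axial = l$fixation_axial, lateral = l$fixation_lateral)
  load_case(axial_force = l$axial_force, bending_moment = l$bending_moment,
            load_scale = l$load_scale, fixation = fixation, dt = l$dt)
}
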