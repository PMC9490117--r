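# Scaled-down fixtures so every stage is testable without a full-scale run.

#' Build a test fixture
#'
#' Presets:
#' * `"desk_domain"` — a geometrically similar regeneration domain at half
#'   linear scale with 0.2 mm agent sites and 2 mm mechanics elements, built
#'   for a mid-range design; fewer than a million agent sites.
#' * `"toy_oracles"` — the analytic objectives of [toy_oracles()] with known
#'   optima.
#' * `"strain_override"` — frozen stimulus fields for ABM-only tests: a
#'   bone-favoring level (S = 0.3) and a fibrous-tissue level (S = 5).
#'
#' @param preset Fixture name.
#' @param design Design used by `"desk_domain"` (full-scale mm; scaled with
#'   the preset's geometry).
#' @param dir Optional directory: fixture files (stimulus fields, domain
#'   export) are written there.
#' @return A list whose content depends on the preset.
#' @export
make_fixture <- function(preset = c("desk_domain", "toy_oracles",
                                    "strain_override"),
                         design = scaffold_design(2.05, 2.05, 1.65),
                         dir = NULL) {
  preset <- match.arg(preset)
  if (preset == "toy_oracles") return(toy_oracles())
  if (preset == "strain_override") {
    out <- list(S_bone = 0.3, S_fibrous = 5)
    if (!is.null(dir)) {
      for (nm in names(out)) {
        utils::write.csv(data.frame(S = out[[nm]]),
                         file.path(dir, paste0(nm, ".csv")),
                         row.names = FALSE)
      }
    }
    return(out)
  }
  config <- scaffopt_config("desk")
  geo <- config_geometry(config)
  scaled <- scale_design(design, config$geometry$design_scale)
  domain <- build_defect_domain(scaled, geo$defect, geo$scaffold,
                                voxel_edge = config$abm$site_edge)
  egrid <- element_grid(domain, config$abm$element_edge)
  stopifnot(prod(domain$dims) < 1e6)
  if (!is.null(dir)) write_voxel_grid(domain, file.path(dir, "desk_domain.gz"))
  list(config = config, design = design, domain = domain, egrid = egrid)
}
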