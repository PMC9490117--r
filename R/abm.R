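# Agent-based regeneration model on the 100 um cell lattice (site = domain
# voxel), coupled daily to the voxel FE mechanics.

#' Agent phenotype codes
#'
#' Integer codes of the per-site phenotype: EMPTY = 0, PROGENITOR = 1,
#' FIBROBLAST = 2, CHONDROCYTE = 3, IMMATURE_OSTEOBLAST = 4,
#' MATURE_OSTEOBLAST = 5.
#'
#' @format A named integer vector.
#' @export
AGENT_PHENOTYPES <- c(
  EMPTY = 0L, PROGENITOR = 1L, FIBROBLAST = 2L, CHONDROCYTE = 3L,
  IMMATURE_OSTEOBLAST = 4L, MATURE_OSTEOBLAST = 5L
)

#' Cell behaviour rates
#'
#' Daily stochastic rates of the cell agents: random-walk migration speed of
#' progenitors, per-phenotype proliferation and apoptosis probabilities,
#' progenitor differentiation rate, initial seeding occupancy, the graft
#' stimulation factor applied inside scaffold pores, and the daily resorption
#' probability of osteoblasts under a resorption-level stimulus.
#'
#' @param migration_speed Progenitor migration speed in um/h.
#' @param proliferation Named per-day probabilities for `progenitor`,
#'   `fibroblast`, `chondrocyte`, `osteoblast`.
#' @param apoptosis Same structure as `proliferation`.
#' @param differentiation_rate Progenitor differentiation probability per day.
#' @param seeding_occupancy Initial occupancy of marrow/periosteal sites.
#' @param graft_factor Multiplier on proliferation and differentiation
#'   probabilities inside pores (capped at probability 1).
#' @param resorption_rate Daily removal probability of osteoblasts in the
#'   resorption stimulus bin.
#' @return An object of class `cell_rates`.
#' @export
cell_rates <- function(migration_speed = 30,
                       proliferation = c(progenitor = 0.60, fibroblast = 0.55,
                                         chondrocyte = 0.20, osteoblast = 0.30),
                       apoptosis = c(progenitor = 0.05, fibroblast = 0.05,
                                     chondrocyte = 0.10, osteoblast = 0.16),
                       differentiation_rate = 0.3,
                       seeding_occupancy = 0.30,
                       graft_factor = 2,
                       resorption_rate = 1) {
  stopifnot(migration_speed >= 0,
            all(proliferation >= 0 & proliferation <= 1),
            all(apoptosis >= 0 & apoptosis <= 1),
            differentiation_rate >= 0, differentiation_rate <= 1,
            seeding_occupancy >= 0, seeding_occupancy <= 1,
            graft_factor >= 1, resorption_rate >= 0, resorption_rate <= 1)
  structure(list(migration_speed = migration_speed,
                 proliferation = proliferation, apoptosis = apoptosis,
                 differentiation_rate = differentiation_rate,
                 seeding_occupancy = seeding_occupancy,
                 graft_factor = graft_factor,
                 resorption_rate = resorption_rate),
            class = "cell_rates")
}

new_agent_lattice <- function(domain, phenotype) {
  region <- as.integer(domain$labels)
  structure(list(dims = domain$dims, site_edge = domain$voxel_edge,
                 origin = domain$origin,
                 phenotype = phenotype, region = region,
                 graft = region == VOXEL_LABELS[["PORE"]],
                 elem_id = NULL),
            class = "agent_lattice")
}

#' @export
print.agent_lattice <- function(x, ...) {
  cat(sprintf("<agent_lattice> %d x %d x %d sites at %.3g mm\n",
              x$dims[1], x$dims[2], x$dims[3], x$site_edge))
  counts <- tabulate(x$phenotype + 1L, nbins = 6)
  names(counts) <- names(AGENT_PHENOTYPES)
  print(counts)
  invisible(x)
}

#' Seed the initial progenitor population
#'
#' Marrow sites and periosteal sites (callus sites within one site layer of
#' the cortical surface of the intact extremities) each become a progenitor
#' independently with probability `seeding_occupancy`; everything else starts
#' empty.
#'
#' @param domain A `voxel_grid` from [build_defect_domain()].
#' @param rates A [cell_rates()].
#' @param seed Optional RNG seed (uses the current RNG state when `NULL`).
#' @return An `agent_lattice`.
#' @export
seed_initial <- function(domain, rates = cell_rates(), seed = NULL) {
  stopifnot(inherits(domain, "voxel_grid"))
  if (!is.null(seed)) set.seed(seed)
  region <- as.integer(domain$labels)
  if (!any(region == VOXEL_LABELS[["MARROW"]]) ||
      !any(region == VOXEL_LABELS[["CORTICAL"]])) {
    stop("domain lacks MARROW or CORTICAL regions needed for seeding",
         call. = FALSE)
  }
  eligible <- region == VOXEL_LABELS[["MARROW"]] |
    cpp_periosteal(region, as.integer(domain$dims))
  phen <- integer(length(region))
  n_el <- sum(eligible)
  phen[eligible] <- stats::rbinom(n_el, 1L, rates$seeding_occupancy)
  new_agent_lattice(domain, phen)
}

# per-site probability vectors for the daily kernels
site_prolif_prob <- function(lattice, rates) {
  map <- c(0, rates$proliferation[["progenitor"]],
           rates$proliferation[["fibroblast"]],
           rates$proliferation[["chondrocyte"]],
           rates$proliferation[["osteoblast"]],
           rates$proliferation[["osteoblast"]])
  p <- map[lattice$phenotype + 1L]
  pmin(1, p * ifelse(lattice$graft, rates$graft_factor, 1))
}

site_apopt_prob <- function(lattice, rates) {
  map <- c(0, rates$apoptosis[["progenitor"]],
           rates$apoptosis[["fibroblast"]],
           rates$apoptosis[["chondrocyte"]],
           rates$apoptosis[["osteoblast"]],
           rates$apoptosis[["osteoblast"]])
  map[lattice$phenotype + 1L]
}

stimulus_class_codes <- function(S, thresholds = tissue_thresholds()) {
  findInterval(S, c(thresholds$resorption_upper, thresholds$mature_upper,
                    thresholds$immature_upper, thresholds$cartilage_upper))
}

#' Daily progenitor migration
#'
#' Each progenitor performs `migration_speed * 24 / site_edge` lattice steps
#' per day in expectation (the fractional part realized by stochastic
#' rounding), each step moving to a uniformly chosen empty 6-neighbour inside
#' occupiable regions, or staying when fully blocked.
#'
#' @param lattice An `agent_lattice`.
#' @param rates A [cell_rates()].
#' @return The updated lattice.
#' @export
migrate <- function(lattice, rates = cell_rates()) {
  n_exp <- rates$migration_speed * 24 / (lattice$site_edge * 1000)
  base <- floor(n_exp)
  lattice$phenotype <- cpp_migrate(lattice$phenotype, lattice$region,
                                   as.integer(lattice$dims),
                                   as.integer(base), n_exp - base)
  lattice
}

#' Surface-guided progenitor differentiation
#'
#' Progenitors 26-adjacent to an existing surface (scaffold, cortical bone or
#' non-progenitor tissue) convert with the differentiation probability
#' (graft-stimulated inside pores) to the phenotype favored by the local
#' stimulus; a resorption-level stimulus triggers no differentiation.
#'
#' @param lattice An `agent_lattice`.
#' @param S Per-site stimulus values.
#' @param rates A [cell_rates()].
#' @param thresholds A [tissue_thresholds()].
#' @return The updated lattice.
#' @export
differentiate <- function(lattice, S, rates = cell_rates(),
                          thresholds = tissue_thresholds()) {
  p <- pmin(1, rates$differentiation_rate *
              ifelse(lattice$graft, rates$graft_factor, 1))
  lattice$phenotype <- cpp_differentiate(lattice$phenotype, lattice$region,
                                         stimulus_class_codes(S, thresholds),
                                         p, as.integer(lattice$dims))
  lattice
}

#' Stimulus-gated proliferation or apoptosis
#'
#' Cells in their favorable stimulus bin duplicate into a uniformly chosen
#' empty neighbour with their proliferation probability (graft-stimulated in
#' pores); cells outside it undergo apoptosis with their apoptosis
#' probability. Progenitors are favorable in any non-resorption bin,
#' osteoblasts in either bone bin, chondrocytes in the cartilage bin and
#' fibroblasts in the fibrous bin.
#'
#' @inheritParams differentiate
#' @return The updated lattice.
#' @export
proliferate_and_apoptose <- function(lattice, S, rates = cell_rates(),
                                     thresholds = tissue_thresholds()) {
  lattice$phenotype <- cpp_proliferate_apoptose(
    lattice$phenotype, lattice$region,
    stimulus_class_codes(S, thresholds),
    site_prolif_prob(lattice, rates),
    site_apopt_prob(lattice, rates),
    as.integer(lattice$dims))
  lattice
}

#' Bone resorption
#'
#' Osteoblast-occupied sites whose stimulus is below the resorption threshold
#' are cleared with the configured daily probability.
#'
#' @inheritParams differentiate
#' @return The updated lattice.
#' @export
resorb <- function(lattice, S, rates = cell_rates(),
                   thresholds = tissue_thresholds()) {
  lattice$phenotype <- cpp_resorb(lattice$phenotype, S,
                                  thresholds$resorption_upper,
                                  rates$resorption_rate)
  lattice
}

## ---- rule of mixtures with maturation ring buffer -----------------------

# material-library row index per site
site_material_row <- function(lattice, scaffold_material,
                              lib_names = names(material_library())) {
  row_i <- function(nm) match(nm, lib_names)
  region <- lattice$region
  phen <- lattice$phenotype
  out <- integer(length(region))
  out[region == VOXEL_LABELS[["SCAFFOLD"]]] <- row_i(scaffold_material)
  out[region == VOXEL_LABELS[["CORTICAL"]]] <- row_i("cortical_bone")
  tissue <- region %in% VOXEL_LABELS[c("PORE", "CALLUS", "MARROW")]
  phen_row <- c(NA, row_i("granulation"), row_i("fibrous"), row_i("cartilage"),
                row_i("immature_bone"), row_i("mature_bone"))
  out[tissue & phen > 0] <- phen_row[phen[tissue & phen > 0] + 1L]
  empty_callus <- tissue & phen == 0 & region != VOXEL_LABELS[["MARROW"]]
  out[empty_callus] <- row_i("granulation")
  empty_marrow <- region == VOXEL_LABELS[["MARROW"]] & phen == 0
  out[empty_marrow] <- row_i("bone_marrow")
  out
}

#' Instantaneous rule-of-mixtures element materials
#'
#' Element properties are the arithmetic mean of the material cards of the
#' sites the element contains: scaffold and cortical sites contribute their
#' fixed cards, occupied tissue sites the card of their phenotype's matrix,
#' empty callus/pore sites granulation tissue and empty marrow sites the
#' marrow card.
#'
#' @param lattice An `agent_lattice` with its element map attached.
#' @param egrid The [element_grid()] the lattice maps to.
#' @param scaffold_material Name of the scaffold material card.
#' @return Matrix (active elements x properties `E`, `nu`, `k`, `Kf`).
#' @export
element_mixture <- function(lattice, egrid, scaffold_material = "titanium") {
  M <- material_matrix()
  rows <- site_material_row(lattice, scaffold_material)
  sel <- rows > 0 & egrid$vox_elem_active > 0
  eid <- egrid$vox_elem_active[sel]
  nele <- max(egrid$elem_id)
  cnt <- tabulate(eid, nbins = nele)
  if (any(cnt == 0)) stop("element with no mapped sites", call. = FALSE)
  props <- matrix(0, nele, ncol(M), dimnames = list(NULL, colnames(M)))
  for (j in seq_len(ncol(M))) {
    v <- M[rows[sel], j]
    agg <- rowsum(v, eid)
    props[as.integer(rownames(agg)), j] <- agg[, 1]
  }
  props / cnt
}

new_material_ring <- function(props, depth = 10) {
  ring <- array(NA_real_, c(nrow(props), ncol(props), depth),
                dimnames = list(NULL, colnames(props), NULL))
  ring[, , 1] <- props
  structure(list(arr = ring, pos = 1L, count = 1L, depth = depth),
            class = "material_ring")
}

push_material_ring <- function(ring, props) {
  ring$pos <- ring$pos %% ring$depth + 1L
  ring$arr[, , ring$pos] <- props
  ring$count <- min(ring$count + 1L, ring$depth)
  ring
}

mean_material_ring <- function(ring) {
  if (ring$count == ring$depth) {
    out <- rowMeans(ring$arr, dims = 2)
  } else {
    idx <- seq_len(ring$count)
    out <- rowMeans(ring$arr[, , idx, drop = FALSE], dims = 2)
  }
  colnames(out) <- colnames(ring$arr)
  out
}

#' Element materials averaged over the maturation window
#'
#' The instantaneous rule-of-mixtures properties are pushed into a ring
#' buffer and averaged over up to the last ten iterations, representing the
#' time needed for tissue deposition and maturation.
#'
#' @param lattice,egrid,scaffold_material See [element_mixture()].
#' @param ring A ring buffer from a previous call, or `NULL` to start one.
#' @return List with `materials` (the averaged property matrix) and `ring`.
#' @export
update_element_materials <- function(lattice, egrid,
                                     scaffold_material = "titanium",
                                     ring = NULL) {
  props <- element_mixture(lattice, egrid, scaffold_material)
  ring <- if (is.null(ring)) new_material_ring(props)
  else push_material_ring(ring, props)
  list(materials = mean_material_ring(ring), ring = ring)
}

## ---- full regeneration run ----------------------------------------------

pore_bone_fraction <- function(lattice) {
  pore <- lattice$region == VOXEL_LABELS[["PORE"]]
  if (!any(pore)) stop("domain has no pore sites", call. = FALSE)
  sum(lattice$phenotype[pore] >= 4L) / sum(pore)
}

daily_tally <- function(lattice, day) {
  reg_names <- c(PORE = 2L, CALLUS = 3L, MARROW = 5L)
  out <- vector("list", length(reg_names))
  for (i in seq_along(reg_names)) {
    sel <- lattice$region == reg_names[[i]]
    cnt <- tabulate(lattice$phenotype[sel] + 1L, nbins = 6L)
    out[[i]] <- tibble::tibble(day = day, region = names(reg_names)[i],
                               phenotype = names(AGENT_PHENOTYPES),
                               count = cnt)
  }
  dplyr::bind_rows(out)
}

#' Simulate the full regeneration process for a scaffold design
#'
#' Runs the daily loop for `n_days` (168 days = 24 weeks by default): voxel
#' FE mechanics of the evolving composite, mechanoregulation stimulus per
#' element, then resorption, progenitor migration, surface-guided
#' differentiation, stimulus-gated proliferation/apoptosis, and the
#' rule-of-mixtures material update with its ten-day maturation window. Fully
#' reproducible from `(config, seed)`.
#'
#' @param design A [scaffold_design()].
#' @param scaffold_material `"titanium"`, `"soft_scaffold"` or another card
#'   name from [material_library()].
#' @param config A [scaffopt_config()]; its `scale` preset fixes geometry,
#'   lattice and element resolutions and the load case.
#' @param n_days Number of daily iterations (defaults to the config value).
#' @param seed RNG seed for the run.
#' @param stimulus_override Optional frozen stimulus: a single value or
#'   per-site vector used instead of the mechanics-derived stimulus (used by
#'   rule-level tests and fixtures).
#' @param record_every Record the composition tally every this many days.
#' @return An object of class `regeneration_outcome` with the final pore bone
#'   fraction, per-day composition tallies and the final lattice snapshot.
#' @export
run_regeneration <- function(design, scaffold_material = "titanium",
                             config = scaffopt_config(),
                             n_days = NULL, seed = 1,
                             stimulus_override = NULL,
                             record_every = 7) {
  stopifnot(inherits(design, "scaffold_design"))
  if (is.null(n_days)) n_days <- config$abm$n_days
  set.seed(seed)
  geo <- config_geometry(config)
  scaled <- scale_design(design, config$geometry$design_scale)
  domain <- build_defect_domain(scaled, geo$defect, geo$scaffold,
                                voxel_edge = config$abm$site_edge)
  egrid <- element_grid(domain, config$abm$element_edge)
  rates <- config_rates(config)
  params <- stimulus_params(config$mechanoregulation$a,
                            config$mechanoregulation$b)
  thr <- config_thresholds(config)
  load <- config_load(config)

  lattice <- seed_initial(domain, rates, seed = NULL)
  lattice$elem_id <- egrid$vox_elem_active

  upd <- update_element_materials(lattice, egrid, scaffold_material, NULL)
  ring <- upd$ring
  tallies <- list(daily_tally(lattice, 0L))
  frozen <- !is.null(stimulus_override)
  if (frozen) {
    S_site <- rep(stimulus_override, length.out = length(lattice$phenotype))
  }

  day <- 0L
  while (day < n_days) {
    day <- day + 1L
    if (!frozen) {
      ms <- mechanical_state(egrid, upd$materials, load,
                             scheme = config$mechanoregulation$scheme)
      if (any(!is.finite(ms$elements$gamma)) ||
          any(!is.finite(ms$elements$nu))) {
        stop("non-finite mechanical state at day ", day, call. = FALSE)
      }
      S_elem <- stimulus(ms$elements$gamma, ms$elements$nu, params)
      S_site <- rep(0, length(lattice$phenotype))
      has_elem <- lattice$elem_id > 0
      S_site[has_elem] <- S_elem[lattice$elem_id[has_elem]]
    }
    lattice <- resorb(lattice, S_site, rates, thr)
    lattice <- migrate(lattice, rates)
    lattice <- differentiate(lattice, S_site, rates, thr)
    lattice <- proliferate_and_apoptose(lattice, S_site, rates, thr)
    upd <- update_element_materials(lattice, egrid, scaffold_material, ring)
    ring <- upd$ring
    if (day %% record_every == 0 || day == n_days) {
      tallies[[length(tallies) + 1L]] <- daily_tally(lattice, day)
    }
  }

  daily <- dplyr::bind_rows(tallies)
  pore_daily <- dplyr::summarize(
    dplyr::group_by(dplyr::filter(daily, .data$region == "PORE"), .data$day),
    bone_fraction = sum(.data$count[.data$phenotype %in%
      c("IMMATURE_OSTEOBLAST", "MATURE_OSTEOBLAST")]) / sum(.data$count),
    .groups = "drop")
  structure(list(
    bone_fraction = pore_bone_fraction(lattice),
    daily = daily, pore_daily = pore_daily,
    lattice = lattice, design = design,
    scaffold_material = scaffold_material,
    n_days = n_days, seed = seed,
    config_hash = rlang::hash(config)),
    class = "regeneration_outcome")
}

#' @export
print.regeneration_outcome <- function(x, ...) {
  cat(sprintf(
    "<regeneration_outcome> %s scaffold, %d days, seed %d\n  pore bone fraction: %.3f\n",
    x$scaffold_material, x$n_days, x$seed, x$bone_fraction))
  invisible(x)
}

#' Regenerated bone volume fraction in the scaffold pores
#'
#' Osteoblast-occupied pore sites (both osteoblast phenotypes) divided by the
#' total number of agent positions within the scaffold pores.
#'
#' @param outcome A `regeneration_outcome` (or an `agent_lattice`).
#' @return Fraction in `[0, 1]`.
#' @export
bone_fraction <- function(outcome) {
  if (inherits(outcome, "agent_lattice")) return(pore_bone_fraction(outcome))
  stopifnot(inherits(outcome, "regeneration_outcome"))
  outcome$bone_fraction
}
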