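# Material cards for the composite scaffold-tissue domain.

#' Create a material card
#'
#' @param name Material name.
#' @param young_modulus Young's modulus in MPa.
#' @param poisson_ratio Poisson's ratio (0 <= nu < 0.5).
#' @param permeability Permeability in units of 1e-14 m^4 N^-1 s^-1, or `NA`
#'   for impermeable (solid) materials.
#' @param bulk_modulus_grain,bulk_modulus_fluid Bulk moduli in MPa (`NA` for
#'   non-poroelastic materials).
#' @return An object of class `material_card`.
#' @export
material_card <- function(name, young_modulus, poisson_ratio,
                          permeability = NA_real_,
                          bulk_modulus_grain = NA_real_,
                          bulk_modulus_fluid = NA_real_) {
  stopifnot(young_modulus > 0, poisson_ratio >= 0, poisson_ratio < 0.5)
  structure(list(name = name, young_modulus = young_modulus,
                 poisson_ratio = poisson_ratio, permeability = permeability,
                 bulk_modulus_grain = bulk_modulus_grain,
                 bulk_modulus_fluid = bulk_modulus_fluid),
            class = "material_card")
}

#' Built-in material library
#'
#' Linear-elastic and poroelastic properties of the scaffold materials and the
#' tissue phases: Young's modulus (MPa), Poisson's ratio, permeability
#' (1e-14 m^4 N^-1 s^-1) and grain/fluid bulk moduli (MPa).
#'
#' @return A named list of [material_card()] objects with entries
#'   `stainless_steel`, `titanium`, `soft_scaffold`, `cortical_bone`,
#'   `bone_marrow`, `granulation`, `fibrous`, `cartilage`, `immature_bone`,
#'   `mature_bone`.
#' @export
material_library <- function() {
  list(
    stainless_steel = material_card("stainless_steel", 210000, 0.3),
    titanium        = material_card("titanium",        104000, 0.3),
    soft_scaffold   = material_card("soft_scaffold",   0.2,    0.3),
    cortical_bone   = material_card("cortical_bone", 17000, 0.3, 0.001, 13920, 2300),
    bone_marrow     = material_card("bone_marrow",   2,     0.167, 1,    2300,  2300),
    granulation     = material_card("granulation",   0.2,   0.167, 1,    2300,  2300),
    fibrous         = material_card("fibrous",       2,     0.167, 1,    2300,  2300),
    cartilage       = material_card("cartilage",     10,    0.3,   0.5,  3700,  2300),
    immature_bone   = material_card("immature_bone", 1000,  0.3,   10,   13940, 2300),
    mature_bone     = material_card("mature_bone",   17000, 0.3,   37,   13940, 2300)
  )
}

# numeric property matrix (rows = materials) used by the mixture rule
material_matrix <- function(lib = material_library()) {
  m <- t(vapply(lib, function(cc) c(E = cc$young_modulus, nu = cc$poisson_ratio,
                                    k = ifelse(is.na(cc$permeability), 0,
                                               cc$permeability),
                                    Kf = ifelse(is.na(cc$bulk_modulus_fluid), 0,
                                                cc$bulk_modulus_fluid)),
                numeric(4)))
  rownames(m) <- names(lib)
  m
}
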