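# Parametric scaffold / defect geometry as labeled voxel models.
#
# All lengths are millimetres. Voxel grids are cell-centered, 0-based in the
# sense that voxel i spans [origin + (i-1)*h, origin + i*h]; the z axis is the
# bone long axis.

#' Voxel region labels
#'
#' Integer codes used in the `labels` array of a `voxel_grid`: OUTSIDE = 0,
#' SCAFFOLD = 1, PORE = 2, CALLUS = 3, CORTICAL = 4, MARROW = 5.
#'
#' @format A named integer vector.
#' @export
VOXEL_LABELS <- c(
  OUTSIDE  = 0L,
  SCAFFOLD = 1L,
  PORE     = 2L,
  CALLUS   = 3L,
  CORTICAL = 4L,
  MARROW   = 5L
)

#' Scaffold pore-size design vector
#'
#' The three design variables of the graded cylindrical scaffold: `x1` is the
#' horizontal pore size nearest the bone extremities, `x2` the horizontal pore
#' size at scaffold mid-height (sizes of the rows between follow a linear
#' gradient), and `x3` the side of the square vertical channels seen in the
#' radial plane. Bounds are 0.3--3.8 mm for `x1`, `x2` and 0.3--3.0 mm for
#' `x3`; the lower bound reflects the minimal pore size for vascularization,
#' the upper bounds keep neighbouring pores from merging completely.
#'
#' @param x1,x2,x3 Pore sizes in mm.
#' @param check_bounds If `FALSE`, skip the bound check (used by degenerate
#'   test geometries such as a scaffold with no pores).
#' @return An object of class `scaffold_design`.
#' @examples
#' scaffold_design(3.12, 3.26, 2.64)
#' @export
scaffold_design <- function(x1, x2, x3, check_bounds = TRUE) {
  stopifnot(is.numeric(x1), is.numeric(x2), is.numeric(x3),
            length(x1) == 1, length(x2) == 1, length(x3) == 1,
            is.finite(x1), is.finite(x2), is.finite(x3))
  if (check_bounds) {
    b <- design_bounds()
    x <- c(x1, x2, x3)
    if (any(x < b$lower - 1e-12) || any(x > b$upper + 1e-12)) {
      stop("scaffold design (", paste(signif(x, 4), collapse = ", "),
           ") outside bounds [", paste(b$lower, collapse = ", "), "] .. [",
           paste(b$upper, collapse = ", "), "] mm", call. = FALSE)
    }
  }
  structure(list(x1 = x1, x2 = x2, x3 = x3), class = "scaffold_design")
}

#' @export
print.scaffold_design <- function(x, ...) {
  cat(sprintf("<scaffold_design> x1 = %.3g, x2 = %.3g, x3 = %.3g mm\n",
              x$x1, x$x2, x$x3))
  invisible(x)
}

#' Design-space bounds of the scaffold pore sizes
#'
#' @return A list with numeric vectors `lower` and `upper` (mm), one entry per
#'   design variable (x1, x2, x3).
#' @export
design_bounds <- function() {
  list(lower = c(0.3, 0.3, 0.3), upper = c(3.8, 3.8, 3.0))
}

#' Scaffold macro-geometry specification
#'
#' Constants of the annular scaffold: a hollow cylinder of outer radius 10 mm,
#' inner radius 5 mm and height 40 mm (the defect length), with 12 square
#' vertical channels placed regularly on the mid-wall circle and horizontal
#' square channels running radially through the wall, arranged in
#' `n_pore_rows_half` rows per half scaffold (mirrored about mid-height) and
#' around the circumference on a fixed center pitch.
#'
#' @param outer_radius,inner_radius,height Scaffold envelope in mm.
#' @param n_vertical_channels Number of vertical square channels.
#' @param n_pore_rows_half Horizontal pore rows per half scaffold (extremity
#'   row, rows between, mid-height row).
#' @param horizontal_center_pitch Center-to-center distance (mm) of horizontal
#'   pores measured at the mid-wall radius; the default 2.2 mm is the value
#'   calibrated against the porosities of the printed reference designs.
#' @param strut_min Minimal wall thickness check (mm); 0 disables it.
#' @return An object of class `scaffold_spec`.
#' @export
scaffold_spec <- function(outer_radius = 10, inner_radius = 5, height = 40,
                          n_vertical_channels = 12, n_pore_rows_half = 5,
                          horizontal_center_pitch = 2.2, strut_min = 0) {
  stopifnot(outer_radius > inner_radius, inner_radius > 0, height > 0,
            n_vertical_channels >= 1, n_pore_rows_half >= 1,
            horizontal_center_pitch > 0)
  structure(list(outer_radius = outer_radius, inner_radius = inner_radius,
                 height = height, n_vertical_channels = n_vertical_channels,
                 n_pore_rows_half = n_pore_rows_half,
                 horizontal_center_pitch = horizontal_center_pitch,
                 strut_min = strut_min),
            class = "scaffold_spec")
}

#' Defect and callus geometry specification
#'
#' The segmental defect: an intact cortical tube (outer radius 10 mm, inner
#' radius 7.5 mm) containing marrow, interrupted by a defect of
#' `defect_length` mm that hosts the scaffold, with a regenerating callus
#' modelled as an arc of revolution of maximum width `callus_max_width` at
#' mid-height that overlaps the intact bone by `callus_overlap`.
#'
#' @param cortical_outer_radius,cortical_inner_radius Intact bone radii (mm).
#' @param defect_length Defect (and scaffold) length in mm.
#' @param callus_max_width Maximal radial callus width at mid-height (mm).
#' @param callus_overlap Axial overlap of the callus over intact bone (mm).
#' @return An object of class `defect_spec`.
#' @export
defect_spec <- function(cortical_outer_radius = 10,
                        cortical_inner_radius = 7.5,
                        defect_length = 40, callus_max_width = 10,
                        callus_overlap = 10) {
  stopifnot(cortical_outer_radius > cortical_inner_radius,
            cortical_inner_radius > 0, defect_length >= 0,
            callus_max_width > 0, callus_overlap > 0)
  structure(list(cortical_outer_radius = cortical_outer_radius,
                 cortical_inner_radius = cortical_inner_radius,
                 defect_length = defect_length,
                 callus_max_width = callus_max_width,
                 callus_overlap = callus_overlap),
            class = "defect_spec")
}

#' Horizontal pore size of a given row
#'
#' Row 0 (nearest the bone extremity) has size `x1`, the mid-height row has
#' size `x2`, and rows between follow a linear gradient; the layout is
#' mirrored about mid-height.
#'
#' @param row_index 0-based row index counted from the extremity.
#' @param n_rows_half Number of rows per half scaffold.
#' @param x1,x2 Extremity and mid-height pore sizes (mm).
#' @return Pore size in mm.
#' @examples
#' horizontal_pore_size(0, 5, 1.84, 3.45) # 1.84
#' horizontal_pore_size(2, 5, 1.0, 3.0)   # 2.0
#' @export
horizontal_pore_size <- function(row_index, n_rows_half, x1, x2) {
  if (any(row_index < 0) || any(row_index >= n_rows_half)) {
    stop("row_index must lie in [0, n_rows_half)", call. = FALSE)
  }
  if (n_rows_half == 1) return(rep(x2, length(row_index)))
  x1 + (x2 - x1) * row_index / (n_rows_half - 1)
}

## ---- internal geometry helpers ------------------------------------------

# cell-center coordinates for n cells starting at `origin` with edge h
cell_centers <- function(origin, n, h) origin + (seq_len(n) - 0.5) * h

# logical in-plane mask (length nx*ny) of the 12 vertical square channels
vertical_channel_mask <- function(X, Y, spec, x3) {
  if (x3 <= 0) return(rep(FALSE, length(X)))
  rc <- (spec$outer_radius + spec$inner_radius) / 2
  m <- rep(FALSE, length(X))
  for (j in seq_len(spec$n_vertical_channels)) {
    phi <- 2 * pi * (j - 1) / spec$n_vertical_channels
    er <- c(cos(phi), sin(phi))
    u <- (X - rc * er[1]) * er[1] + (Y - rc * er[2]) * er[2]
    v <- -(X - rc * er[1]) * er[2] + (Y - rc * er[2]) * er[1]
    m <- m | (abs(u) <= x3 / 2 & abs(v) <= x3 / 2)
  }
  m
}

# logical in-plane mask of one row of radial horizontal channels of size s
horizontal_row_mask <- function(X, Y, spec, s) {
  if (s <= 0) return(rep(FALSE, length(X)))
  rc <- (spec$outer_radius + spec$inner_radius) / 2
  n_circ <- max(1L, floor(2 * pi * rc / spec$horizontal_center_pitch))
  m <- rep(FALSE, length(X))
  for (k in seq_len(n_circ)) {
    psi <- 2 * pi * (k - 1) / n_circ
    rad <- X * cos(psi) + Y * sin(psi)
    tan_ <- -X * sin(psi) + Y * cos(psi)
    m <- m | (abs(tan_) <= s / 2 & rad >= 0)
  }
  m
}

# z positions (mm, measured from the bottom extremity) and sizes of all
# horizontal pore rows over the full scaffold height: rows per half are
# centered on equal vertical bands and mirrored about mid-height
pore_rows <- function(design, spec) {
  n <- spec$n_pore_rows_half
  H <- spec$height
  i <- seq_len(n) - 1
  z_half <- (i + 0.5) * (H / 2) / n
  s <- horizontal_pore_size(i, n, design$x1, design$x2)
  list(z = c(z_half, H - z_half), size = c(s, s))
}

new_voxel_grid <- function(labels, voxel_edge, origin, meta = list()) {
  structure(list(voxel_edge = voxel_edge, dims = dim(labels), origin = origin,
                 labels = labels, legend = VOXEL_LABELS, meta = meta),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels at %.3g mm\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_edge))
  counts <- tabulate(as.integer(x$labels) + 1L, nbins = length(VOXEL_LABELS))
  names(counts) <- names(VOXEL_LABELS)
  print(counts[counts > 0])
  invisible(x)
}

#' Build the parametric scaffold as a labeled voxel grid
#'
#' Voxelizes the annular scaffold minus the union of its pore channels:
#' horizontal square-section channels running radially through the wall, row
#' sizes given by [horizontal_pore_size()], placed circumferentially on the
#' configured pitch, plus `n_vertical_channels` square channels of side `x3`
#' extruded along z on the mid-wall circle. A voxel is `PORE` if its center
#' lies inside any channel, `SCAFFOLD` if inside the annulus but no channel,
#' `OUTSIDE` otherwise.
#'
#' @param design A [scaffold_design()].
#' @param spec A [scaffold_spec()].
#' @param voxel_edge Voxel edge in mm (0.05 for production-accuracy porosity,
#'   coarser for fast tests).
#' @return A `voxel_grid`.
#' @export
build_scaffold <- function(design, spec = scaffold_spec(), voxel_edge = 0.05) {
  stopifnot(inherits(design, "scaffold_design"), inherits(spec, "scaffold_spec"),
            voxel_edge > 0)
  Ro <- spec$outer_radius
  nx <- as.integer(round(2 * Ro / voxel_edge))
  nz <- as.integer(round(spec$height / voxel_edge))
  origin <- c(-Ro, -Ro, 0)
  xs <- cell_centers(-Ro, nx, voxel_edge)
  X <- rep(xs, times = nx)
  Y <- rep(xs, each = nx)
  r <- sqrt(X^2 + Y^2)
  annulus <- r >= spec$inner_radius & r <= Ro

  vert <- vertical_channel_mask(X, Y, spec, design$x3) & annulus
  rows <- pore_rows(design, spec)

  rc <- (Ro + spec$inner_radius) / 2
  n_circ <- max(1L, floor(2 * pi * rc / spec$horizontal_center_pitch))
  if (any(rows$size * n_circ >= 2 * pi * Ro)) {
    warning("horizontal pores merge over a full angular sector of the wall",
            call. = FALSE, immediate. = FALSE)
  }

  # per-slice label patterns: base (no row) plus one per unique row size;
  # rows never overlap axially because band width < row pitch
  base <- raw(nx * nx)
  base[annulus] <- as.raw(VOXEL_LABELS[["SCAFFOLD"]])
  base[vert] <- as.raw(VOXEL_LABELS[["PORE"]])
  patt <- list()
  for (s in unique(rows$size)) {
    p <- base
    p[horizontal_row_mask(X, Y, spec, s) & annulus] <-
      as.raw(VOXEL_LABELS[["PORE"]])
    patt[[sprintf("%.12g", s)]] <- p
  }

  labels <- raw(nx * nx * nz)
  zc <- cell_centers(0, nz, voxel_edge)
  plane <- nx * nx
  for (iz in seq_len(nz)) {
    act <- which(abs(zc[iz] - rows$z) <= rows$size / 2)
    slice <- if (length(act) == 0) base else patt[[sprintf("%.12g", rows$size[act[1]])]]
    labels[((iz - 1) * plane + 1):(iz * plane)] <- slice
  }
  dim(labels) <- c(nx, nx, nz)
  new_voxel_grid(labels, voxel_edge, origin,
                 meta = list(design = design, scaffold_spec = spec,
                             scaffold_z = c(0, spec$height)))
}

#' Macroscopic scaffold porosity
#'
#' Pore volume inside the hollow-cylinder envelope divided by the analytic
#' hollow-cylinder volume `pi * (Ro^2 - Ri^2) * height`. Deterministic for a
#' fixed voxel edge.
#'
#' @param grid A `voxel_grid` built by [build_scaffold()] or
#'   [build_defect_domain()] (the scaffold spec is taken from its metadata).
#' @return Porosity fraction in `[0, 1]`.
#' @export
compute_porosity <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  spec <- grid$meta$scaffold_spec
  if (is.null(spec)) stop("grid carries no scaffold geometry", call. = FALSE)
  n_pore <- sum(grid$labels == as.raw(VOXEL_LABELS[["PORE"]]))
  if (length(grid$labels) == 0) stop("empty grid", call. = FALSE)
  height <- if (isTRUE(grid$meta$half_domain)) spec$height / 2 else spec$height
  v_env <- pi * (spec$outer_radius^2 - spec$inner_radius^2) * height
  n_pore * grid$voxel_edge^3 / v_env
}

#' Convenience: porosity of a design without keeping the grid
#'
#' @inheritParams build_scaffold
#' @return Porosity fraction in `[0, 1]`.
#' @export
scaffold_porosity <- function(design, spec = scaffold_spec(),
                              voxel_edge = 0.05) {
  compute_porosity(build_scaffold(design, spec, voxel_edge))
}

# callus envelope radius at axial distance z from the mid-height plane;
# circular arc in the (r, z) plane, vertical tangent at mid-height, through
# (Ro + width, 0) and (cortical outer radius, defect/2 + overlap)
callus_radius <- function(z, defect, scaffold_outer) {
  A <- scaffold_outer + defect$callus_max_width
  B <- defect$cortical_outer_radius
  L <- defect$defect_length / 2 + defect$callus_overlap
  if (A <= B) return(rep(B, length(z)))
  r0 <- (A^2 - B^2 - L^2) / (2 * (A - B))
  rho <- A - r0
  r0 + sqrt(pmax(0, rho^2 - z^2))
}

#' Build the full regeneration half-domain
#'
#' Assembles the half model (mid-height symmetry plane at z = 0): the scaffold
#' annulus with its pores in the defect, the intact cortical tube and marrow
#' beyond the defect, and the callus envelope (arc of revolution, maximal
#' width at mid-height, overlapping intact bone) filling all non-scaffold
#' space in and around the defect. The callus space is initially granulation
#' tissue.
#'
#' @param design A [scaffold_design()].
#' @param defect A [defect_spec()].
#' @param spec A [scaffold_spec()]; its height must equal the defect length.
#' @param voxel_edge Voxel edge in mm.
#' @return A `voxel_grid` with z measured from the mid-height plane.
#' @export
build_defect_domain <- function(design, defect = defect_spec(),
                                spec = scaffold_spec(), voxel_edge = 0.2) {
  stopifnot(inherits(design, "scaffold_design"), inherits(defect, "defect_spec"),
            inherits(spec, "scaffold_spec"), voxel_edge > 0)
  half_defect <- defect$defect_length / 2
  z_max <- half_defect + defect$callus_overlap
  R_max <- if (defect$defect_length > 0)
    max(spec$outer_radius + defect$callus_max_width,
        defect$cortical_outer_radius)
  else defect$cortical_outer_radius
  if (defect$defect_length > 0 &&
      callus_radius(half_defect, defect, spec$outer_radius) < spec$outer_radius) {
    stop("scaffold is not contained in the callus envelope", call. = FALSE)
  }

  nx <- as.integer(round(2 * R_max / voxel_edge))
  nz <- as.integer(round(z_max / voxel_edge))
  origin <- c(-R_max, -R_max, 0)
  xs <- cell_centers(-R_max, nx, voxel_edge)
  X <- rep(xs, times = nx)
  Y <- rep(xs, each = nx)
  r <- sqrt(X^2 + Y^2)

  lab <- VOXEL_LABELS
  in_scaffold_band <- defect$defect_length > 0
  if (in_scaffold_band) {
    annulus <- r >= spec$inner_radius & r <= spec$outer_radius
    vert <- vertical_channel_mask(X, Y, spec, design$x3) & annulus
    rows <- pore_rows(design, spec)
    row_patterns <- lapply(stats::setNames(unique(rows$size),
                                           sprintf("%.12g", unique(rows$size))),
                           function(s) horizontal_row_mask(X, Y, spec, s) & annulus)
  }
  cortical <- r >= defect$cortical_inner_radius &
    r <= defect$cortical_outer_radius
  marrow <- r < defect$cortical_inner_radius

  labels <- raw(nx * nx * nz)
  zc <- cell_centers(0, nz, voxel_edge)
  plane <- nx * nx
  for (iz in seq_len(nz)) {
    z <- zc[iz]
    slice <- raw(plane)
    if (defect$defect_length > 0) {
      rc_env <- callus_radius(z, defect, spec$outer_radius)
      in_callus <- r <= rc_env
    } else in_callus <- rep(FALSE, plane)
    if (z < half_defect && in_scaffold_band) {
      slice[in_callus] <- as.raw(lab[["CALLUS"]])
      slice[annulus] <- as.raw(lab[["SCAFFOLD"]])
      # scaffold z coordinate measured from the extremity (mirror symmetric)
      z_s <- spec$height / 2 + z
      pore <- vert
      act <- which(abs(z_s - rows$z) <= rows$size / 2)
      if (length(act) > 0) {
        pore <- pore | row_patterns[[sprintf("%.12g", rows$size[act[1]])]]
      }
      slice[pore] <- as.raw(lab[["PORE"]])
    } else if (z >= half_defect) {
      slice[in_callus] <- as.raw(lab[["CALLUS"]])
      slice[cortical] <- as.raw(lab[["CORTICAL"]])
      slice[marrow] <- as.raw(lab[["MARROW"]])
    }
    labels[((iz - 1) * plane + 1):(iz * plane)] <- slice
  }
  dim(labels) <- c(nx, nx, nz)
  new_voxel_grid(labels, voxel_edge, origin,
                 meta = list(design = design, scaffold_spec = spec,
                             defect_spec = defect,
                             scaffold_z = c(0, half_defect),
                             half_domain = TRUE))
}
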