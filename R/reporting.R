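# Histology-style rendering, porosity/outcome reports, manifests, voxel IO.

#' Histology palette
#'
#' Colors used by the histology-like tissue maps, mirroring Safranin
#' Orange/von Kossa staining conventions: bone in black, fibrous tissue in
#' light red, cartilage in dark red, granulation/empty in white, scaffold in
#' gray.
#'
#' @return Named character vector of hex colors.
#' @export
histology_palette <- function() {
  c(bone = "#000000", fibrous = "#FF9E9E", cartilage = "#8B0000",
    granulation = "#FFFFFF", scaffold = "#808080", background = "#FFFFFF")
}

#' Render a histology-like tissue map
#'
#' Pixel-per-agent-site image of the mid-sagittal plane (the x-z plane
#' through the bone axis): osteoblast sites and cortical bone in black,
#' fibroblasts in light red, chondrocytes in dark red, granulation/empty in
#' white and scaffold in gray. Deterministic.
#'
#' @param outcome A `regeneration_outcome` or `agent_lattice`.
#' @param plane Only `"mid-sagittal"` is supported.
#' @param path Optional PNG output path.
#' @return An object of class `histology_image` with the color matrix
#'   (rows = z, columns = x) and palette legend.
#' @export
render_histology <- function(outcome, plane = "mid-sagittal", path = NULL) {
  lattice <- if (inherits(outcome, "regeneration_outcome")) outcome$lattice
  else outcome
  if (!inherits(lattice, "agent_lattice")) {
    stop("no lattice snapshot available", call. = FALSE)
  }
  if (!identical(plane, "mid-sagittal")) {
    stop("unsupported plane: ", plane, call. = FALSE)
  }
  d <- lattice$dims
  iy <- as.integer(ceiling(d[2] / 2))
  idx <- function(ix, iz) ix + d[1] * (iy - 1L) + d[1] * d[2] * (iz - 1L)
  ix <- rep(seq_len(d[1]), times = d[3])
  iz <- rep(seq_len(d[3]), each = d[1])
  ids <- idx(ix, iz)
  region <- lattice$region[ids]
  phen <- lattice$phenotype[ids]
  pal <- histology_palette()
  col <- rep(pal[["background"]], length(ids))
  tissue <- region %in% VOXEL_LABELS[c("PORE", "CALLUS", "MARROW")]
  col[tissue] <- pal[["granulation"]]
  col[tissue & phen == AGENT_PHENOTYPES[["FIBROBLAST"]]] <- pal[["fibrous"]]
  col[tissue & phen == AGENT_PHENOTYPES[["CHONDROCYTE"]]] <- pal[["cartilage"]]
  col[tissue & phen >= AGENT_PHENOTYPES[["IMMATURE_OSTEOBLAST"]]] <- pal[["bone"]]
  col[region == VOXEL_LABELS[["SCAFFOLD"]]] <- pal[["scaffold"]]
  col[region == VOXEL_LABELS[["CORTICAL"]]] <- pal[["bone"]]
  m <- matrix(col, nrow = d[3], ncol = d[1], byrow = TRUE)  # rows = z
  img <- structure(list(colors = m, palette = pal, plane = plane,
                        site_edge = lattice$site_edge),
                   class = "histology_image")
  if (!is.null(path)) {
    rgb <- grDevices::col2rgb(t(m)) / 255
    arr <- array(0, c(nrow(m), ncol(m), 3))
    arr[, , 1] <- matrix(rgb[1, ], nrow(m), byrow = TRUE)
    arr[, , 2] <- matrix(rgb[2, ], nrow(m), byrow = TRUE)
    arr[, , 3] <- matrix(rgb[3, ], nrow(m), byrow = TRUE)
    png::writePNG(arr[rev(seq_len(nrow(m))), , , drop = FALSE], path)
  }
  img
}

#' @export
print.histology_image <- function(x, ...) {
  cat(sprintf("<histology_image> %s plane, %d x %d sites\n", x$plane,
              ncol(x$colors), nrow(x$colors)))
  invisible(x)
}

#' Autoplot a histology image
#'
#' @param object A `histology_image`.
#' @param ... Unused.
#' @return A ggplot raster of the tissue map.
#' @export
autoplot.histology_image <- function(object, ...) {
  m <- object$colors
  df <- tidyr::expand_grid(z = seq_len(nrow(m)), x = seq_len(ncol(m)))
  df$color <- as.vector(t(m))[(df$z - 1) * ncol(m) + df$x]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z)) +
    ggplot2::geom_raster(fill = df$color) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (sites)", y = "z (sites)") +
    ggplot2::theme_void()
}

#' Porosity vs regenerated-bone scatter report
#'
#' Recomputes the macroscopic porosity of every design in an evaluation
#' ledger and relates it to the simulated bone fraction.
#'
#' @param ledger Tibble with design columns `x1`, `x2`, `x3` and an
#'   `objective` column (as produced by [run_framework()]).
#' @param spec A [scaffold_spec()] for the porosity computation.
#' @param voxel_edge Voxel edge (mm) for the porosity computation.
#' @param design_scale Multiplier applied to designs before building (use the
#'   config's `design_scale` for desk-scale ledgers).
#' @param csv Optional CSV output path.
#' @return List with `data` (tibble: design, porosity, bone fraction) and
#'   `plot` (ggplot).
#' @export
porosity_bone_scatter <- function(ledger, spec = scaffold_spec(),
                                  voxel_edge = 0.2, design_scale = 1,
                                  csv = NULL) {
  stopifnot(nrow(ledger) >= 1)
  dup <- duplicated(round(as.matrix(ledger[c("x1", "x2", "x3")]), 9))
  if (any(dup)) {
    warning(sum(dup), " duplicated design(s) removed from the report",
            call. = FALSE)
    ledger <- ledger[!dup, ]
  }
  por <- purrr::pmap_dbl(ledger[c("x1", "x2", "x3")], function(x1, x2, x3) {
    d <- scale_design(scaffold_design(x1, x2, x3), design_scale)
    suppressWarnings(scaffold_porosity(d, spec, voxel_edge))
  })
  data <- dplyr::mutate(ledger, porosity = por)
  if (!is.null(csv)) utils::write.csv(data, csv, row.names = FALSE)
  plot <- ggplot2::ggplot(data,
                          ggplot2::aes(x = .data$porosity,
                                       y = .data$objective)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "scaffold porosity",
                  y = "regenerated bone volume fraction in pores") +
    ggplot2::lims(x = c(0, 1), y = c(0, 1)) +
    ggplot2::theme_minimal()
  list(data = data, plot = plot)
}

#' Run manifest
#'
#' Deterministic record that makes an output regenerable: configuration
#' hash, seed and package version (no wall-clock fields).
#'
#' @param config A [scaffopt_config()].
#' @param seed The run seed.
#' @param extra Named list of additional fields.
#' @param path Optional YAML output path.
#' @return The manifest as a named list.
#' @export
run_manifest <- function(config, seed, extra = list(), path = NULL) {
  m <- c(list(config_hash = rlang::hash(config), seed = seed,
              scale = config$scale,
              version = as.character(utils::packageVersion("scaffopt"))),
         extra)
  if (!is.null(path)) yaml::write_yaml(m, path)
  m
}

#' Write / read a voxel grid as a gzipped label array with sidecar metadata
#'
#' @param grid A `voxel_grid`.
#' @param path Output path for the gzipped label bytes; the sidecar metadata
#'   (voxel edge, dims, origin, label legend) is written to `<path>.yml`.
#' @return `read_voxel_grid()` returns the `voxel_grid` (without build
#'   metadata).
#' @export
write_voxel_grid <- function(grid, path) {
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(grid$labels), con)
  yaml::write_yaml(list(voxel_edge = grid$voxel_edge,
                        dims = as.integer(grid$dims),
                        origin = as.numeric(grid$origin),
                        legend = as.list(VOXEL_LABELS)),
                   paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_voxel_grid
#' @export
read_voxel_grid <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  con <- gzfile(path, "rb")
  on.exit(close(con))
  labels <- readBin(con, "raw", n = prod(meta$dims))
  dim(labels) <- meta$dims
  new_voxel_grid(labels, meta$voxel_edge, meta$origin)
}
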