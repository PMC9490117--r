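# Shared fixtures: small synthetic domains and lattices built in code.

# homogeneous box domain with a single region label
box_domain <- function(dims, voxel_edge = 1, label = "CALLUS",
                       half_domain = FALSE) {
  lab <- rep(as.raw(scaffopt::VOXEL_LABELS[[label]]), prod(dims))
  dim(lab) <- dims
  scaffopt:::new_voxel_grid(lab, voxel_edge, c(0, 0, 0),
                            meta = list(half_domain = half_domain))
}

# solid cylinder domain (single material region) for mechanics patch tests
cylinder_domain <- function(R = 3, H = 6, voxel_edge = 0.5, label = "CALLUS") {
  nx <- as.integer(round(2 * R / voxel_edge))
  nz <- as.integer(round(H / voxel_edge))
  xs <- scaffopt:::cell_centers(-R, nx, voxel_edge)
  X <- rep(xs, nx); Y <- rep(xs, each = nx)
  inside <- sqrt(X^2 + Y^2) <= R
  lab <- raw(nx * nx * nz)
  for (iz in seq_len(nz)) {
    lab[(iz - 1) * nx * nx + which(inside)] <-
      as.raw(scaffopt::VOXEL_LABELS[[label]])
  }
  dim(lab) <- c(nx, nx, nz)
  scaffopt:::new_voxel_grid(lab, voxel_edge, c(-R, -R, 0),
                            meta = list(half_domain = TRUE))
}

# free-standing agent lattice over a single-region box (no domain build)
box_lattice <- function(dims, region = "CALLUS", site_edge = 0.1) {
  dom <- box_domain(dims, voxel_edge = site_edge, label = region)
  scaffopt:::new_agent_lattice(dom, integer(prod(dims)))
}

# cached desk-scale defect domain + element grid (built once per test run)
.fixture_env <- new.env(parent = emptyenv())
desk_fixture <- function() {
  if (is.null(.fixture_env$desk)) {
    .fixture_env$desk <- make_fixture("desk_domain")
  }
  .fixture_env$desk
}

# small mid-range design used across tests
mid_design <- function() scaffold_design(2.05, 2.05, 1.65)
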