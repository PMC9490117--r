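# Structured-grid finite-element mechanics of the scaffold-tissue composite.
#
# Trilinear hexahedral elements on a regular grid of aggregated voxels;
# material per element by a rule of mixtures over the fine grid. The linear
# system is solved by a sparse Cholesky factorization (exact, deterministic).

#' Load case for the defect model
#'
#' Compression plus anterior-posterior bending on the proximal cortical face,
#' a mid-height symmetry plane (zero normal displacement), drained outer
#' poroelastic surfaces, and the internal fixation hardware abstracted as
#' grounded springs on the proximal face (the plate's load path towards the
#' mirrored half of the model).
#'
#' @param axial_force Compressive axial force in N (default 1372, two body
#'   weights).
#' @param bending_moment Anterior-posterior bending moment in N*m
#'   (default 17.125).
#' @param load_scale Multiplier on both load components (0.5 / 1.5 reproduce
#'   load-sensitivity variants).
#' @param fixation `NULL` to disable, or a list with `axial` and `lateral`
#'   spring stiffness totals in N/mm distributed over the proximal face.
#' @param dt Consolidation time step in s for the fluid-speed estimate.
#' @return An object of class `load_case`.
#' @export
load_case <- function(axial_force = 1372, bending_moment = 17.125,
                      load_scale = 1,
                      fixation = list(axial = 2000, lateral = 500),
                      dt = 1) {
  stopifnot(load_scale > 0, dt > 0)
  structure(list(axial_force = axial_force, bending_moment = bending_moment,
                 load_scale = load_scale, fixation = fixation, dt = dt),
            class = "load_case")
}

#' Aggregate a voxel domain into a mechanics element grid
#'
#' Elements are cubic blocks of fine voxels; an element is active when at
#' least half of its voxels lie inside the domain. Per-element label counts
#' are retained for the rule-of-mixtures material assignment and for mapping
#' agent sites to elements.
#'
#' @param domain A `voxel_grid` (typically from [build_defect_domain()]).
#' @param element_edge Element edge in mm; must be an integer multiple of the
#'   domain voxel edge.
#' @return An object of class `element_grid`.
#' @export
element_grid <- function(domain, element_edge = 2) {
  stopifnot(inherits(domain, "voxel_grid"))
  f <- element_edge / domain$voxel_edge
  if (abs(f - round(f)) > 1e-8) {
    stop("element_edge must be an integer multiple of the voxel edge",
         call. = FALSE)
  }
  f <- as.integer(round(f))
  dims <- domain$dims
  ne <- as.integer(ceiling(dims / f))
  # voxel -> element index
  ex <- (seq_len(dims[1]) - 1L) %/% f
  ey <- (seq_len(dims[2]) - 1L) %/% f
  ez <- (seq_len(dims[3]) - 1L) %/% f
  vox_elem <- 1L + rep(ex, times = dims[2] * dims[3]) +
    ne[1] * rep(rep(ey, each = dims[1]), times = dims[3]) +
    ne[1] * ne[2] * rep(ez, each = dims[1] * dims[2])

  lab <- as.integer(domain$labels)
  n_lab <- length(VOXEL_LABELS)
  counts <- matrix(0L, prod(ne), n_lab,
                   dimnames = list(NULL, names(VOXEL_LABELS)))
  for (l in seq_len(n_lab)) {
    sel <- lab == (l - 1L)
    if (any(sel)) counts[, l] <- tabulate(vox_elem[sel], nbins = prod(ne))
  }
  inside <- rowSums(counts[, -1, drop = FALSE])
  total <- rowSums(counts)
  active <- inside >= pmax(1, total / 2) & inside > 0
  elem_id <- integer(prod(ne))            # full-grid -> active index
  elem_id[active] <- seq_len(sum(active))
  # centroids of full-grid elements
  cx <- domain$origin[1] + (rep(seq_len(ne[1]), times = ne[2] * ne[3]) - 0.5) * element_edge
  cy <- domain$origin[2] + (rep(rep(seq_len(ne[2]), each = ne[1]), times = ne[3]) - 0.5) * element_edge
  cz <- domain$origin[3] + (rep(seq_len(ne[3]), each = ne[1] * ne[2]) - 0.5) * element_edge
  structure(list(dims = ne, element_edge = element_edge, factor = f,
                 counts = counts, active = active, elem_id = elem_id,
                 centroid = cbind(x = cx, y = cy, z = cz)[active, , drop = FALSE],
                 vox_elem_active = elem_id[vox_elem],
                 domain_dims = dims, voxel_edge = domain$voxel_edge,
                 origin = domain$origin,
                 half_domain = isTRUE(domain$meta$half_domain)),
            class = "element_grid")
}

# initial rule-of-mixtures materials from region labels alone
initial_element_materials <- function(egrid, scaffold_material = "titanium",
                                      lib = material_library()) {
  M <- material_matrix(lib)
  row_of <- c(OUTSIDE = NA, SCAFFOLD = scaffold_material,
              PORE = "granulation", CALLUS = "granulation",
              CORTICAL = "cortical_bone", MARROW = "bone_marrow")
  cnt <- egrid$counts[egrid$active, , drop = FALSE]
  w <- cnt[, -1, drop = FALSE]            # drop OUTSIDE
  props <- matrix(0, nrow(w), ncol(M), dimnames = list(NULL, colnames(M)))
  for (j in colnames(w)) {
    props <- props + w[, j] %o% M[row_of[[j]], ]
  }
  props / rowSums(w)
}

## ---- hex element matrices ------------------------------------------------

# B matrix (6 x 24, Voigt exx eyy ezz gxy gyz gzx) of the trilinear hex at
# natural point xi for edge length h; node order: x fastest, then y, then z
hex_B <- function(xi, h) {
  sg <- as.matrix(expand.grid(sx = c(-1, 1), sy = c(-1, 1), sz = c(-1, 1)))
  dN <- matrix(0, 8, 3)
  for (i in 1:8) {
    s <- sg[i, ]
    dN[i, 1] <- s[1] * (1 + s[2] * xi[2]) * (1 + s[3] * xi[3]) / 8
    dN[i, 2] <- s[2] * (1 + s[1] * xi[1]) * (1 + s[3] * xi[3]) / 8
    dN[i, 3] <- s[3] * (1 + s[1] * xi[1]) * (1 + s[2] * xi[2]) / 8
  }
  dN <- dN * 2 / h                         # d(xi)/dx = 2/h
  B <- matrix(0, 6, 24)
  for (i in 1:8) {
    c0 <- 3 * (i - 1)
    B[1, c0 + 1] <- dN[i, 1]
    B[2, c0 + 2] <- dN[i, 2]
    B[3, c0 + 3] <- dN[i, 3]
    B[4, c0 + 1] <- dN[i, 2]; B[4, c0 + 2] <- dN[i, 1]
    B[5, c0 + 2] <- dN[i, 3]; B[5, c0 + 3] <- dN[i, 2]
    B[6, c0 + 1] <- dN[i, 3]; B[6, c0 + 3] <- dN[i, 1]
  }
  B
}

# geometry-only 24x24 stiffness blocks: K_e = lambda * KL + mu * KM
hex_stiffness_blocks <- function(h) {
  g <- 1 / sqrt(3)
  pts <- as.matrix(expand.grid(c(-g, g), c(-g, g), c(-g, g)))
  w <- (h / 2)^3
  mm <- matrix(0, 6, 6); mm[1:3, 1:3] <- 1
  dshear <- diag(c(2, 2, 2, 1, 1, 1))
  KL <- matrix(0, 24, 24); KM <- matrix(0, 24, 24)
  for (q in seq_len(nrow(pts))) {
    B <- hex_B(pts[q, ], h)
    KL <- KL + t(B) %*% mm %*% B * w
    KM <- KM + t(B) %*% dshear %*% B * w
  }
  list(KL = KL, KM = KM)
}

# active-element -> 8 node ids (nodes numbered over the full lattice)
element_nodes <- function(egrid) {
  ne <- egrid$dims
  nn <- ne + 1L
  act <- which(egrid$active)
  iz <- (act - 1L) %/% (ne[1] * ne[2])
  iy <- ((act - 1L) %/% ne[1]) %% ne[2]
  ix <- (act - 1L) %% ne[1]
  n0 <- 1L + ix + nn[1] * iy + nn[1] * nn[2] * iz
  offs <- c(0L, 1L, nn[1], nn[1] + 1L,
            nn[1] * nn[2], nn[1] * nn[2] + 1L,
            nn[1] * nn[2] + nn[1], nn[1] * nn[2] + nn[1] + 1L)
  # reorder to match hex_B node order (x fastest, then y, then z)
  outer(n0, offs, `+`)
}

node_coords <- function(egrid) {
  nn <- egrid$dims + 1L
  h <- egrid$element_edge
  x <- egrid$origin[1] + (seq_len(nn[1]) - 1L) * h
  y <- egrid$origin[2] + (seq_len(nn[2]) - 1L) * h
  z <- egrid$origin[3] + (seq_len(nn[3]) - 1L) * h
  cbind(x = rep(x, times = nn[2] * nn[3]),
        y = rep(rep(y, each = nn[1]), times = nn[3]),
        z = rep(z, each = nn[1] * nn[2]))
}

# connectivity check: all active elements must form one 6-connected component
check_connected <- function(egrid) {
  ne <- egrid$dims
  act <- egrid$active
  id <- integer(length(act)); id[act] <- 0L
  comp <- 0L
  strides <- c(1L, ne[1], ne[1] * ne[2])
  idx_all <- which(act)
  visited <- logical(length(act))
  for (start in idx_all) {
    if (visited[start]) next
    comp <- comp + 1L
    frontier <- start
    visited[start] <- TRUE
    while (length(frontier) > 0) {
      nb <- integer(0)
      for (d in 1:3) {
        i <- (frontier - 1L) %/% strides[d] %% ne[d]
        up <- frontier[i < ne[d] - 1L] + strides[d]
        dn <- frontier[i > 0L] - strides[d]
        nb <- c(nb, up, dn)
      }
      nb <- unique(nb[nb >= 1 & nb <= length(act)])
      nb <- nb[act[nb] & !visited[nb]]
      visited[nb] <- TRUE
      frontier <- nb
    }
    if (comp > 1L) {
      stop("domain contains a disconnected (floating) element component ",
           "starting at full-grid element ", start, call. = FALSE)
    }
  }
  invisible(TRUE)
}

# proximal (z = max) face elements used for load application
proximal_face_elements <- function(egrid) {
  ne <- egrid$dims
  act <- which(egrid$active)
  iz <- (act - 1L) %/% (ne[1] * ne[2])
  top <- act[iz == max(iz)]
  cort <- egrid$counts[top, "CORTICAL"]
  if (any(cort > 0)) {
    # restrict to cortical-majority elements when intact bone is present
    inside <- rowSums(egrid$counts[top, -1, drop = FALSE])
    top <- top[cort >= inside / 2]
  }
  top
}

#' Solve the linear-elastic voxel FE problem
#'
#' Assembles trilinear hexahedral stiffness on the active elements with the
#' given per-element materials, applies the mid-height symmetry condition
#' (zero normal displacement at z = min), distributes the axial force and
#' bending moment as statically-equivalent nodal forces on the proximal face,
#' adds the fixation springs, and solves by sparse Cholesky.
#'
#' @param egrid An [element_grid()].
#' @param materials Matrix with columns `E` (MPa) and `nu`, one row per
#'   active element.
#' @param load A [load_case()].
#' @return List with `u` (n_nodes x 3 displacement, mm), `nodes`, element
#'   node incidence, and the applied force vector.
#' @export
solve_elastic <- function(egrid, materials, load = load_case()) {
  stopifnot(inherits(egrid, "element_grid"))
  check_connected(egrid)
  h <- egrid$element_edge
  en <- element_nodes(egrid)
  nele <- nrow(en)
  stopifnot(nrow(materials) == nele)
  nodes <- node_coords(egrid)
  used <- sort(unique(as.vector(en)))
  remap <- integer(nrow(nodes)); remap[used] <- seq_along(used)
  en_u <- matrix(remap[en], nrow = nele)
  nodes_u <- nodes[used, , drop = FALSE]
  n_nodes <- nrow(nodes_u)

  E <- materials[, "E"]; nu <- materials[, "nu"]
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  blocks <- hex_stiffness_blocks(h)

  # element dof indices (24 per element)
  edof <- matrix(0L, nele, 24)
  for (i in 1:8) {
    edof[, 3 * i - 2] <- 3L * en_u[, i] - 2L
    edof[, 3 * i - 1] <- 3L * en_u[, i] - 1L
    edof[, 3 * i]     <- 3L * en_u[, i]
  }
  ii <- matrix(0L, nele, 576); jj <- matrix(0L, nele, 576)
  for (a in 1:24) {
    ii[, (a - 1) * 24 + (1:24)] <- edof[, a]
    jj[, (a - 1) * 24 + (1:24)] <- edof
  }
  vals <- lam %o% as.vector(blocks$KL) + mu %o% as.vector(blocks$KM)
  K <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                            x = as.vector(vals),
                            dims = c(3 * n_nodes, 3 * n_nodes))

  # loads on the proximal face
  ls <- load$load_scale
  top <- proximal_face_elements(egrid)
  top_active <- egrid$elem_id[top]
  face_nodes <- en_u[top_active, 5:8, drop = FALSE]   # +z face of each element
  A_face <- length(top) * h^2
  fvec <- numeric(3 * n_nodes)
  sigma_ax <- -load$axial_force * ls / A_face          # compressive
  yc <- egrid$centroid[top_active, "y"]
  ybar <- mean(yc)
  I_face <- sum(h^2 * (yc - ybar)^2) + length(top) * h^4 / 12
  M <- load$bending_moment * 1000 * ls                  # N*m -> N*mm
  sigma_bend <- if (I_face > 0) M * (yc - ybar) / I_face else rep(0, length(yc))
  f_elem <- (sigma_ax + sigma_bend) * h^2 / 4
  for (corner in 1:4) {
    dz <- 3L * face_nodes[, corner]
    agg <- rowsum(f_elem, dz)
    fvec[as.integer(rownames(agg))] <- fvec[as.integer(rownames(agg))] + agg[, 1]
  }

  # fixation springs on proximal face nodes
  if (!is.null(load$fixation)) {
    fn <- sort(unique(as.vector(face_nodes)))
    kax <- load$fixation$axial / length(fn)
    klat <- load$fixation$lateral / length(fn)
    diag_add <- numeric(3 * n_nodes)
    diag_add[3 * fn] <- kax
    diag_add[3 * fn - 1] <- klat
    diag_add[3 * fn - 2] <- klat
    K <- K + Matrix::Diagonal(3 * n_nodes, diag_add)
  }

  # constraints: symmetry plane uz = 0 at z = min; minimal in-plane pins if
  # no lateral springs are present
  zmin <- min(nodes_u[, "z"])
  sym_nodes <- which(abs(nodes_u[, "z"] - zmin) < 1e-9)
  fixed <- 3L * sym_nodes
  if (is.null(load$fixation)) {
    cx <- mean(nodes_u[sym_nodes, "x"]); cy <- mean(nodes_u[sym_nodes, "y"])
    d2 <- (nodes_u[sym_nodes, "x"] - cx)^2 + (nodes_u[sym_nodes, "y"] - cy)^2
    nA <- sym_nodes[which.min(d2)]
    same_y <- sym_nodes[abs(nodes_u[sym_nodes, "y"] - nodes_u[nA, "y"]) < 1e-9]
    nB <- same_y[which.max(abs(nodes_u[same_y, "x"] - nodes_u[nA, "x"]))]
    fixed <- c(fixed, 3L * nA - 2L, 3L * nA - 1L, 3L * nB - 1L)
  }
  keep <- setdiff(seq_len(3 * n_nodes), fixed)
  Kr <- Matrix::forceSymmetric(K[keep, keep, drop = FALSE])
  ur <- tryCatch(
    as.numeric(Matrix::solve(Kr, fvec[keep])),
    error = function(e) stop("singular stiffness system: ", conditionMessage(e),
                             call. = FALSE))
  u <- numeric(3 * n_nodes)
  u[keep] <- ur
  list(u = matrix(u, ncol = 3, byrow = TRUE), nodes = nodes_u, en = en_u,
       f = fvec, fixed_dofs = fixed)
}

#' Octahedral shear strain of a small-strain tensor
#'
#' `gamma = (2/3) * sqrt((e1-e2)^2 + (e2-e3)^2 + (e3-e1)^2)` over the
#' principal strains, evaluated invariantly from the strain deviator.
#'
#' @param eps Either a symmetric 3x3 strain tensor or a matrix of Voigt rows
#'   `(exx, eyy, ezz, gxy, gyz, gzx)` with engineering shear.
#' @return Non-negative octahedral shear strain(s).
#' @examples
#' octahedral_shear_strain(diag(c(0.01, -0.003, -0.003)))
#' @export
octahedral_shear_strain <- function(eps) {
  if (is.matrix(eps) && nrow(eps) == 3 && ncol(eps) == 3) {
    if (max(abs(eps - t(eps))) > 1e-12 * max(1, max(abs(eps)))) {
      stop("strain tensor must be symmetric", call. = FALSE)
    }
    eps <- matrix(c(eps[1, 1], eps[2, 2], eps[3, 3],
                    2 * eps[1, 2], 2 * eps[2, 3], 2 * eps[1, 3]), nrow = 1)
  }
  if (is.null(dim(eps))) eps <- matrix(eps, nrow = 1)
  tr <- rowSums(eps[, 1:3, drop = FALSE])
  d <- eps[, 1:3, drop = FALSE] - tr / 3
  tr_e2 <- rowSums(d^2) + rowSums(eps[, 4:6, drop = FALSE]^2) / 2
  (2 / 3) * sqrt(3 * tr_e2)
}

# per-element centroid strains (Voigt rows) from a solve_elastic() result
element_strains <- function(sol, h) {
  B0 <- hex_B(c(0, 0, 0), h)
  nele <- nrow(sol$en)
  U <- matrix(0, nele, 24)
  for (i in 1:8) {
    U[, 3 * i - 2] <- sol$u[sol$en[, i], 1]
    U[, 3 * i - 1] <- sol$u[sol$en[, i], 2]
    U[, 3 * i]     <- sol$u[sol$en[, i], 3]
  }
  U %*% t(B0)
}

#' Interstitial fluid speed estimate
#'
#' Single-step consolidation estimate: element pore pressure from volumetric
#' strain via the fluid bulk modulus (`p = -Kf * tr(eps)`), Darcy flux
#' `nu = k * |grad p|` with drained (p = 0) outer boundaries and no-flow
#' mirrors at the symmetry plane and at impermeable neighbours. The
#' alternative `"strain_rate"` scheme uses `nu = |tr(eps)| * L / dt`.
#'
#' @param egrid An [element_grid()].
#' @param materials Matrix with columns `k` (1e-14 m^4/N/s) and `Kf` (MPa).
#' @param strains Voigt strain rows from the elastic solve.
#' @param load A [load_case()] (supplies `dt`).
#' @param scheme `"darcy"` (default) or `"strain_rate"`.
#' @return Fluid speed per active element in mm/s.
#' @export
fluid_speed <- function(egrid, materials, strains, load = load_case(),
                        scheme = c("darcy", "strain_rate")) {
  scheme <- match.arg(scheme)
  if (load$dt <= 0) stop("dt must be positive", call. = FALSE)
  vol <- rowSums(strains[, 1:3, drop = FALSE])
  k <- materials[, "k"]
  permeable <- k > 0
  if (scheme == "strain_rate") {
    nu <- abs(vol) * egrid$element_edge / load$dt
    nu[!permeable] <- 0
    return(nu)
  }
  ne <- egrid$dims
  h <- egrid$element_edge
  act_idx <- which(egrid$active)
  p_act <- -materials[, "Kf"] * vol
  p_act[!permeable] <- 0
  # full-grid fields: NA outside the active domain
  p_full <- rep(NA_real_, prod(ne)); p_full[act_idx] <- p_act
  imp_full <- rep(FALSE, prod(ne)); imp_full[act_idx] <- !permeable
  strides <- c(1L, ne[1], ne[1] * ne[2])
  pos <- list((act_idx - 1L) %% ne[1],
              ((act_idx - 1L) %/% ne[1]) %% ne[2],
              (act_idx - 1L) %/% (ne[1] * ne[2]))
  grad2 <- numeric(length(act_idx))
  neighbor_p <- function(d, step) {
    in_range <- if (step > 0) pos[[d]] < ne[d] - 1L else pos[[d]] > 0L
    nb <- act_idx + step * strides[d]
    val <- rep(0, length(act_idx))            # drained outer boundary p = 0
    val[in_range] <- p_full[nb[in_range]]
    # impermeable neighbour: no-flow, mirror own pressure
    imp <- in_range; imp[in_range] <- imp_full[nb[in_range]]
    val[imp] <- p_act[imp]
    val[is.na(val)] <- 0                      # inactive neighbour: drained
    # symmetry plane: mirror own pressure across z = min
    if (d == 3 && step < 0 && egrid$half_domain) {
      at_sym <- pos[[d]] == 0L
      val[at_sym] <- p_act[at_sym]
    }
    val
  }
  for (d in 1:3) {
    up <- neighbor_p(d, 1L)
    dn <- neighbor_p(d, -1L)
    grad2 <- grad2 + ((up - dn) / (2 * h))^2
  }
  # unit conversion: k [1e-14 m^4/N/s] * gradp [MPa/mm] -> 0.01 * k * |grad p| mm/s
  nu <- 0.01 * k * sqrt(grad2)
  nu[!permeable] <- 0
  nu
}

#' Mechanical state of the composite domain
#'
#' Runs the elastic solve and derives the per-element octahedral shear strain
#' and fluid speed feeding the mechanoregulation stimulus.
#'
#' @inheritParams solve_elastic
#' @param scheme Fluid-speed scheme, see [fluid_speed()].
#' @return An object of class `mechanical_state`: a list with tibble `elements`
#'   (centroid, gamma, nu), the displacement field and scheme metadata.
#' @export
mechanical_state <- function(egrid, materials, load = load_case(),
                             scheme = "darcy") {
  sol <- solve_elastic(egrid, materials, load)
  strains <- element_strains(sol, egrid$element_edge)
  gamma <- octahedral_shear_strain(strains)
  nu <- fluid_speed(egrid, materials, strains, load, scheme)
  structure(list(
    elements = tibble::tibble(
      element = seq_len(nrow(strains)),
      x = egrid$centroid[, "x"], y = egrid$centroid[, "y"],
      z = egrid$centroid[, "z"],
      gamma = gamma, nu = nu),
    strains = strains, u = sol$u, scheme = scheme, load = load),
    class = "mechanical_state")
}
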