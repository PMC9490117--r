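test_that("octahedral shear strain matches the principal-strain formula", {
  # hydrostatic: no shear
  expect_equal(octahedral_shear_strain(diag(c(2e-3, 2e-3, 2e-3))), 0)
  # oracle: direct evaluation over principal strains
  oct_oracle <- function(e) {
    p <- eigen(e, symmetric = TRUE, only.values = TRUE)$values
    (2 / 3) * sqrt((p[1] - p[2])^2 + (p[2] - p[3])^2 + (p[3] - p[1])^2)
  }
  expect_equal(octahedral_shear_strain(diag(c(0.01, -0.003, -0.003))),
               oct_oracle(diag(c(0.01, -0.003, -0.003))))
  expect_equal(octahedral_shear_strain(diag(c(0.01, -0.003, -0.003))),
               (2 / 3) * sqrt(2) * 0.013, tolerance = 1e-10)
  expect_equal(octahedral_shear_strain(diag(c(0.01, -0.01, 0))),
               (2 / 3) * sqrt(6) * 0.01, tolerance = 1e-10)
  # random symmetric tensors: invariant form agrees with the eigen route
  set.seed(42)
  for (i in 1:20) {
    A <- matrix(rnorm(9, sd = 0.01), 3)
    E <- (A + t(A)) / 2
    expect_equal(octahedral_shear_strain(E), oct_oracle(E), tolerance = 1e-12)
  }
  expect_error(octahedral_shear_strain(matrix(1:9 / 100, 3)), "symmetric")
})

test_that("homogeneous cylinder under axial load reproduces the closed form", {
  dom <- cylinder_domain(R = 3, H = 6, voxel_edge = 0.5)
  eg <- element_grid(dom, 1)
  n <- sum(eg$active)
  mats <- cbind(E = rep(17000, n), nu = rep(0.3, n), k = rep(0.001, n),
                Kf = rep(2300, n))
  lc <- load_case(axial_force = 500, bending_moment = 0, fixation = NULL)
  sol <- solve_elastic(eg, mats, lc)
  st <- scaffopt:::element_strains(sol, 1)
  ne <- eg$dims
  top <- which((which(eg$active) - 1) %/% (ne[1] * ne[2]) == 0)
  A <- sum((which(eg$active) - 1) %/% (ne[1] * ne[2]) == 0) * 1^2
  eps_ref <- -500 / (17000 * A)
  expect_lt(max(abs(st[, 3] - eps_ref)) / abs(eps_ref), 1e-6)
  expect_lt(max(abs(st[, 1] - (-0.3 * eps_ref))) / abs(eps_ref), 1e-6)
  expect_lt(max(abs(st[, 4:6])), 1e-12)

  # zero load: zero displacement
  lc0 <- load_case(axial_force = 0, bending_moment = 0, fixation = NULL)
  sol0 <- solve_elastic(eg, mats, lc0)
  expect_equal(max(abs(sol0$u)), 0)

  # linearity: doubling every modulus halves the displacement
  sol2 <- solve_elastic(eg, cbind(E = mats[, "E"] * 2, mats[, -1]), lc)
  expect_equal(sol2$u, sol$u / 2, tolerance = 1e-9)
})

test_that("floating element components are rejected by name", {
  dims <- c(4, 4, 8)
  lab <- raw(prod(dims))
  dim(lab) <- dims
  lab[, , 1:3] <- as.raw(VOXEL_LABELS[["CALLUS"]])
  lab[, , 6:8] <- as.raw(VOXEL_LABELS[["CALLUS"]])   # gap at z = 4:5
  dom <- scaffopt:::new_voxel_grid(lab, 1, c(0, 0, 0))
  eg <- element_grid(dom, 1)
  n <- sum(eg$active)
  mats <- cbind(E = rep(1, n), nu = rep(0.3, n))
  expect_error(solve_elastic(eg, mats, load_case(fixation = NULL)),
               "disconnected")
})

test_that("Darcy flux matches a hand-computed consolidation column", {
  # 1 x 1 x 10 element column (laterally symmetric, so the transverse
  # pressure gradient vanishes), volumetric strain linear in z
  dom <- box_domain(c(1, 1, 10), voxel_edge = 1)
  eg <- element_grid(dom, 1)
  n <- sum(eg$active)
  iz <- which(eg$active) - 1                  # 0..9
  strains <- matrix(0, n, 6)
  strains[, 3] <- -1e-4 * (iz + 1)            # ezz, tr(eps) linear in z
  k_col <- ifelse(iz < 5, 1, 0.5)             # two materials
  mats <- cbind(E = 1, nu = 0.3, k = k_col, Kf = 2300)
  nu_pkg <- fluid_speed(eg, mats, strains, load_case(fixation = NULL))
  # hand oracle: p = -Kf * tr(eps) per layer, central differences with
  # drained (p = 0) boundaries; lateral gradient zero by symmetry of layers
  p <- 2300 * 1e-4 * (0:9 + 1)
  grad <- numeric(10)
  for (i in 1:10) {
    up <- if (i < 10) p[i + 1] else 0
    dn <- if (i > 1) p[i - 1] else 0
    grad[i] <- abs(up - dn) / 2
  }
  nu_hand <- 0.01 * k_col * grad[iz + 1]
  expect_equal(nu_pkg, nu_hand, tolerance = 1e-6)
  # zero strain: no flux; uniform pressure: interior flux vanishes
  expect_equal(fluid_speed(eg, mats, matrix(0, n, 6), load_case()),
               rep(0, n))
  strains_u <- matrix(0, n, 6); strains_u[, 1] <- -1e-4
  nu_u <- fluid_speed(eg, mats, strains_u, load_case(fixation = NULL))
  interior <- iz %in% 2:7   # away from the drained column ends
  expect_equal(nu_u[interior], rep(0, sum(interior)), tolerance = 1e-12)
  expect_error(load_case(dt = 0))
})

test_that("stimulus extremes of stiff and soft domains bracket the bins", {
  fx <- desk_fixture()
  eg <- fx$egrid
  n <- sum(eg$active)
  # closed-form bounds apply to the bulk field without the load-sharing
  # fixation springs and away from the load-introduction face
  lc <- load_case(axial_force = 343, bending_moment = 17.125 / 8,
                  fixation = NULL)
  # all-cortical (stiff) domain: octahedral strain well below 0.1%
  stiff <- cbind(E = rep(17000, n), nu = rep(0.3, n), k = rep(0.001, n),
                 Kf = rep(2300, n))
  ms <- mechanical_state(eg, stiff, lc)
  bulk <- ms$elements$z < 13
  expect_lt(max(ms$elements$gamma[bulk]), 0.001)
  # all-granulation domain: mid-defect stimulus deep in the fibrous bin
  soft <- cbind(E = rep(0.2, n), nu = rep(0.167, n), k = rep(1, n),
                Kf = rep(2300, n))
  ms2 <- mechanical_state(eg, soft, lc)
  S <- stimulus(ms2$elements$gamma, ms2$elements$nu)
  mid <- ms2$elements$z < 2
  expect_gt(stats::median(S[mid]), 3)
  # zero load downstream: S identically zero
  lc0 <- load_case(axial_force = 0, bending_moment = 0)
  ms0 <- mechanical_state(eg, soft, lc0)
  expect_equal(max(stimulus(ms0$elements$gamma, ms0$elements$nu)), 0)
})

test_that("a stiffer scaffold does not raise strain in pore-adjacent callus", {
  fx <- desk_fixture()
  eg <- fx$egrid
  lc <- scaffopt:::config_load(fx$config)
  m_ti <- scaffopt:::initial_element_materials(eg, "titanium")
  m_soft <- scaffopt:::initial_element_materials(eg, "soft_scaffold")
  g_ti <- mechanical_state(eg, m_ti, lc)$elements$gamma
  g_soft <- mechanical_state(eg, m_soft, lc)$elements$gamma
  cnt <- eg$counts[eg$active, ]
  near_pore <- cnt[, "PORE"] > 0 & (cnt[, "CALLUS"] + cnt[, "PORE"]) > 0
  expect_lte(stats::median(g_ti[near_pore]),
             stats::median(g_soft[near_pore]))
})

test_that("median strain is stable under element refinement", {
  dom <- box_domain(c(16, 16, 32), voxel_edge = 0.5)
  eg1 <- element_grid(dom, 2)
  eg2 <- element_grid(dom, 1)
  lc <- load_case(axial_force = 1000, bending_moment = 1, fixation = NULL)
  g1 <- with(list(n = sum(eg1$active)), {
    mechanical_state(eg1, cbind(E = rep(1000, n), nu = rep(0.3, n),
                                k = rep(1, n), Kf = rep(2300, n)),
                     lc)$elements$gamma
  })
  g2 <- with(list(n = sum(eg2$active)), {
    mechanical_state(eg2, cbind(E = rep(1000, n), nu = rep(0.3, n),
                                k = rep(1, n), Kf = rep(2300, n)),
                     lc)$elements$gamma
  })
  expect_lt(abs(stats::median(g1) - stats::median(g2)) / stats::median(g2),
            0.05)
})
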