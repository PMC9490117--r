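test_that("horizontal pore sizes follow the linear gradient", {
  expect_equal(horizontal_pore_size(0, 5, 1.84, 3.45), 1.84)
  expect_equal(horizontal_pore_size(4, 5, 1.84, 3.45), 3.45)
  expect_equal(horizontal_pore_size(2, 5, 1.0, 3.0), 2.0)
  # symmetric about mid-height by construction of the row layout
  rows <- scaffopt:::pore_rows(scaffold_design(1, 3, 1), scaffold_spec())
  expect_equal(rows$size[6:10], rows$size[1:5])
  expect_equal(rows$z[6:10], 40 - rows$z[1:5])
  expect_error(horizontal_pore_size(5, 5, 1, 3), "row_index")
  expect_error(horizontal_pore_size(-1, 5, 1, 3), "row_index")
})

test_that("design bounds are enforced at construction", {
  expect_error(scaffold_design(0.2, 1, 1), "outside bounds")
  expect_error(scaffold_design(1, 3.9, 1), "outside bounds")
  expect_error(scaffold_design(1, 1, 3.1), "outside bounds")
  expect_silent(scaffold_design(0.3, 3.8, 3.0))
  # test-only bypass: a scaffold without pores has porosity exactly zero
  solid <- scaffold_design(0, 0, 0, check_bounds = FALSE)
  expect_equal(scaffold_porosity(solid, voxel_edge = 0.25), 0)
})

test_that("porosity is voxel-converged and deterministic", {
  d <- scaffold_design(1.9, 0.77, 0.70)
  p1 <- scaffold_porosity(d, voxel_edge = 0.2)
  p2 <- scaffold_porosity(d, voxel_edge = 0.1)
  expect_lt(abs(p1 - p2), 0.01)
  expect_identical(p1, scaffold_porosity(d, voxel_edge = 0.2))
  expect_gt(p1, 0); expect_lt(p1, 1)
})

test_that("porosity is monotone in each design variable", {
  vals <- list(x1 = c(0.5, 1.5, 2.5, 3.5), x2 = c(0.5, 1.5, 2.5, 3.5),
               x3 = c(0.5, 1.3, 2.1, 2.9))
  base <- c(1.5, 1.5, 1.5)
  for (k in 1:3) {
    p <- vapply(vals[[k]], function(v) {
      x <- base; x[k] <- v
      suppressWarnings(scaffold_porosity(scaffold_design(x[1], x[2], x[3]),
                                         voxel_edge = 0.2))
    }, numeric(1))
    expect_true(all(diff(p) > -1e-9),
                info = paste("porosity not monotone in", names(vals)[k]))
  }
  p_lo <- scaffold_porosity(scaffold_design(0.3, 0.3, 0.3), voxel_edge = 0.2)
  p_hi <- suppressWarnings(
    scaffold_porosity(scaffold_design(3.8, 3.8, 3.0), voxel_edge = 0.2))
  expect_lt(p_lo, p_hi)
  expect_gt(p_lo, 0); expect_lt(p_hi, 1)
  expect_lt(p_lo, 0.2)  # lower-bound design is mostly solid
})

test_that("scaffold labels mirror about the mid-height plane", {
  g <- build_scaffold(scaffold_design(1.2, 2.4, 1.0), voxel_edge = 0.25)
  nz <- g$dims[3]
  for (k in c(1, 5, 17, nz %/% 2)) {
    expect_identical(g$labels[, , k], g$labels[, , nz + 1 - k])
  }
})

test_that("defect domain carries all regions and degenerates cleanly", {
  fx <- desk_fixture()
  lab <- as.integer(fx$domain$labels)
  expect_setequal(sort(unique(lab)), unname(VOXEL_LABELS))
  # scaffold annulus is inside the callus envelope
  expect_gte(scaffopt:::callus_radius(10, defect_spec(), 10), 10)

  empty <- build_defect_domain(mid_design(),
                               defect_spec(defect_length = 0),
                               scaffold_spec(height = 20), voxel_edge = 0.5)
  lab0 <- as.integer(empty$labels)
  expect_false(any(lab0 == VOXEL_LABELS[["SCAFFOLD"]]))
  expect_false(any(lab0 == VOXEL_LABELS[["CALLUS"]]))

  expect_error(
    build_defect_domain(mid_design(),
                        defect_spec(callus_max_width = 0.1,
                                    cortical_outer_radius = 6,
                                    cortical_inner_radius = 4),
                        scaffold_spec(), voxel_edge = 0.5),
    "callus envelope")
})

test_that("porosity of the embedded scaffold converges under refinement", {
  d <- scaffold_design(1.9, 0.77, 0.70)
  p1 <- compute_porosity(build_defect_domain(d, voxel_edge = 0.2))
  p2 <- compute_porosity(build_defect_domain(d, voxel_edge = 0.1))
  expect_lt(abs(p1 - p2), 0.01)
  # and the embedded scaffold agrees with the free-standing build
  expect_equal(p1, scaffold_porosity(d, voxel_edge = 0.2), tolerance = 1e-12)
})
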