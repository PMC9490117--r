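test_that("seeding follows the binomial occupancy law deterministically", {
  fx <- desk_fixture()
  lat1 <- seed_initial(fx$domain, cell_rates(), seed = 7)
  lat2 <- seed_initial(fx$domain, cell_rates(), seed = 7)
  expect_identical(lat1$phenotype, lat2$phenotype)

  region <- lat1$region
  eligible <- region == VOXEL_LABELS[["MARROW"]] |
    scaffopt:::cpp_periosteal(region, as.integer(fx$domain$dims))
  n <- sum(eligible)
  occ <- sum(lat1$phenotype == AGENT_PHENOTYPES[["PROGENITOR"]])
  expect_lt(abs(occ - 0.3 * n), 3 * sqrt(n * 0.3 * 0.7))
  # progenitors appear only on eligible sites
  expect_true(all(eligible[lat1$phenotype > 0]))

  empty <- seed_initial(fx$domain, cell_rates(seeding_occupancy = 0), seed = 1)
  expect_equal(sum(empty$phenotype), 0)

  box <- box_domain(c(4, 4, 4), label = "CALLUS")
  expect_error(seed_initial(box, cell_rates()), "MARROW")
})

test_that("migration is a conservative lattice random walk", {
  # single progenitor in an open box: mean squared displacement after one
  # day matches the random-walk prediction n * edge^2 (n = 7.2 at 0.1 mm)
  dims <- c(21, 21, 21)
  center <- 11 + 21 * 10 + 441 * 10
  set.seed(1)
  disp2 <- replicate(400, {
    lat <- box_lattice(dims, site_edge = 0.1)
    lat$phenotype[center] <- 1L
    lat <- migrate(lat, cell_rates())
    pos <- which(lat$phenotype == 1L) - 1L
    xyz <- c(pos %% 21, (pos %/% 21) %% 21, pos %/% 441) - 10
    sum(xyz^2) * 0.1^2
  })
  n_steps <- 30 * 24 / 100
  expect_equal(mean(disp2), n_steps * 0.1^2, tolerance = 0.12)

  # cell number is conserved and zero speed freezes the lattice
  lat <- box_lattice(c(8, 8, 8))
  set.seed(2)
  lat$phenotype[sample(512, 100)] <- 1L
  before <- sum(lat$phenotype)
  moved <- migrate(lat, cell_rates())
  expect_equal(sum(moved$phenotype), before)
  frozen <- migrate(lat, cell_rates(migration_speed = 0))
  expect_identical(frozen$phenotype, lat$phenotype)

  # a fully packed region cannot move
  full <- box_lattice(c(4, 4, 4))
  full$phenotype[] <- 1L
  expect_identical(migrate(full, cell_rates())$phenotype, full$phenotype)
})

test_that("differentiation is surface-guided and rate-correct", {
  # progenitor adjacent to scaffold, bone-favoring stimulus: ~30% convert
  mk <- function() {
    lat <- box_lattice(c(3, 3, 3))
    lat$region[1] <- VOXEL_LABELS[["SCAFFOLD"]]   # a scaffold surface corner
    lat$phenotype[14] <- 1L                        # center site
    lat
  }
  set.seed(3)
  hits <- replicate(1000, {
    lat <- differentiate(mk(), S = rep(0.3, 27), cell_rates())
    lat$phenotype[14] == AGENT_PHENOTYPES[["MATURE_OSTEOBLAST"]]
  })
  expect_lt(abs(mean(hits) - 0.3), 3 * sqrt(0.3 * 0.7 / 1000))

  # fibrous-level stimulus converts towards fibroblast
  set.seed(4)
  lat <- mk()
  for (i in 1:50) {
    out <- differentiate(lat, S = rep(5, 27), cell_rates())
    if (out$phenotype[14] != 1L) break
  }
  expect_equal(out$phenotype[14], AGENT_PHENOTYPES[["FIBROBLAST"]])

  # an isolated progenitor (no surface anywhere) never differentiates
  iso <- box_lattice(c(5, 5, 5))
  iso$phenotype[63] <- 1L
  set.seed(5)
  for (i in 1:50) {
    iso2 <- differentiate(iso, S = rep(0.3, 125), cell_rates())
    expect_equal(iso2$phenotype[63], 1L)
  }

  # resorption-level stimulus: no differentiation even at a surface
  set.seed(6)
  for (i in 1:50) {
    out <- differentiate(mk(), S = rep(0.005, 27), cell_rates())
    expect_equal(out$phenotype[14], 1L)
  }

  # graft stimulation doubles the rate inside pores (capped at 1)
  mkp <- function() {
    lat <- mk()
    lat$region[] <- VOXEL_LABELS[["PORE"]]
    lat$region[1] <- VOXEL_LABELS[["SCAFFOLD"]]
    lat$graft <- lat$region == VOXEL_LABELS[["PORE"]]
    lat
  }
  set.seed(7)
  hits <- replicate(1000, {
    lat <- differentiate(mkp(), S = rep(0.3, 27), cell_rates())
    lat$phenotype[14] != 1L
  })
  expect_lt(abs(mean(hits) - 0.6), 3 * sqrt(0.6 * 0.4 / 1000))
})

test_that("proliferation and apoptosis follow the printed rates", {
  # chondrocyte in the cartilage bin duplicates with p = 0.20
  set.seed(8)
  dup <- replicate(1000, {
    lat <- box_lattice(c(3, 3, 3))
    lat$phenotype[14] <- AGENT_PHENOTYPES[["CHONDROCYTE"]]
    out <- proliferate_and_apoptose(lat, S = rep(2, 27), cell_rates())
    sum(out$phenotype > 0) == 2
  })
  expect_lt(abs(mean(dup) - 0.20), 3 * sqrt(0.2 * 0.8 / 1000))

  # osteoblast at fibrous-level stimulus undergoes apoptosis with p = 0.16
  set.seed(9)
  gone <- replicate(1000, {
    lat <- box_lattice(c(3, 3, 3))
    lat$phenotype[14] <- AGENT_PHENOTYPES[["MATURE_OSTEOBLAST"]]
    out <- proliferate_and_apoptose(lat, S = rep(5, 27), cell_rates())
    out$phenotype[14] == 0L
  })
  expect_lt(abs(mean(gone) - 0.16), 3 * sqrt(0.16 * 0.84 / 1000))

  # exclusion: no empty neighbour, no proliferation
  full <- box_lattice(c(3, 3, 3))
  full$phenotype[] <- AGENT_PHENOTYPES[["CHONDROCYTE"]]
  set.seed(10)
  out <- proliferate_and_apoptose(full, S = rep(2, 27), cell_rates())
  expect_identical(out$phenotype, full$phenotype)
})

test_that("resorption clears osteoblasts below the threshold", {
  lat <- box_lattice(c(2, 2, 2))
  lat$phenotype[1] <- AGENT_PHENOTYPES[["MATURE_OSTEOBLAST"]]
  lat$phenotype[2] <- AGENT_PHENOTYPES[["IMMATURE_OSTEOBLAST"]]
  lat$phenotype[3] <- AGENT_PHENOTYPES[["CHONDROCYTE"]]
  S <- c(0.005, 0.005, 0.005, rep(0.02, 5))
  out <- resorb(lat, S, cell_rates())
  expect_equal(out$phenotype[1:3], c(0L, 0L, AGENT_PHENOTYPES[["CHONDROCYTE"]]))
  lat2 <- box_lattice(c(2, 2, 2))
  lat2$phenotype[1] <- AGENT_PHENOTYPES[["MATURE_OSTEOBLAST"]]
  out2 <- resorb(lat2, rep(0.02, 8), cell_rates())
  expect_equal(out2$phenotype[1], AGENT_PHENOTYPES[["MATURE_OSTEOBLAST"]])
  empty <- box_lattice(c(2, 2, 2))
  expect_identical(resorb(empty, rep(0.005, 8), cell_rates())$phenotype,
                   empty$phenotype)
})

test_that("rule-of-mixtures properties average over the maturation window", {
  lat <- box_lattice(c(4, 4, 4), region = "CALLUS", site_edge = 1)
  dom <- box_domain(c(4, 4, 4), voxel_edge = 1, label = "CALLUS")
  eg <- element_grid(dom, 4)     # a single element containing all sites
  lat$elem_id <- eg$vox_elem_active

  # all mature bone, steady for >= 10 days: E reaches 17,000 exactly
  lat$phenotype[] <- AGENT_PHENOTYPES[["MATURE_OSTEOBLAST"]]
  upd <- update_element_materials(lat, eg, "titanium", NULL)
  for (i in 1:12) upd <- update_element_materials(lat, eg, "titanium", upd$ring)
  expect_equal(unname(upd$materials[1, "E"]), 17000)

  # half granulation / half mature bone: arithmetic mean 8500.1 MPa
  lat$phenotype[] <- 0L
  lat$phenotype[1:32] <- AGENT_PHENOTYPES[["MATURE_OSTEOBLAST"]]
  upd <- update_element_materials(lat, eg, "titanium", NULL)
  for (i in 1:12) upd <- update_element_materials(lat, eg, "titanium", upd$ring)
  expect_equal(unname(upd$materials[1, "E"]), 8500.1)

  # moving-average window: after a composition switch the element modulus
  # reaches the new steady value exactly 10 iterations later
  lat$phenotype[] <- 0L
  upd <- update_element_materials(lat, eg, "titanium", NULL)
  for (i in 1:11) upd <- update_element_materials(lat, eg, "titanium", upd$ring)
  expect_equal(unname(upd$materials[1, "E"]), 0.2)
  lat$phenotype[] <- AGENT_PHENOTYPES[["MATURE_OSTEOBLAST"]]
  E_path <- numeric(11)
  for (i in 1:11) {
    upd <- update_element_materials(lat, eg, "titanium", upd$ring)
    E_path[i] <- upd$materials[1, "E"]
  }
  expect_lt(E_path[9], 17000)
  expect_equal(E_path[10], 17000)
  expect_equal(E_path[11], 17000)
  # linear ramp of the running mean while the window refills
  expect_equal(E_path[1], (0.2 * 9 + 17000) / 10)

  # an element whose sites carry no material (mismatched lattice) errors
  lat_out <- box_lattice(c(4, 4, 4), region = "OUTSIDE", site_edge = 1)
  lat_out$elem_id <- eg$vox_elem_active
  expect_error(element_mixture(lat_out, eg), "sites")
})

test_that("bone fraction counts osteoblast-occupied pore sites", {
  lat <- box_lattice(c(4, 4, 4), region = "PORE")
  expect_equal(bone_fraction(lat), 0)
  lat$phenotype[] <- AGENT_PHENOTYPES[["MATURE_OSTEOBLAST"]]
  expect_equal(bone_fraction(lat), 1)
  lat$phenotype[] <- 0L
  lat$phenotype[1:32] <- AGENT_PHENOTYPES[["MATURE_OSTEOBLAST"]]
  lat$phenotype[33:48] <- AGENT_PHENOTYPES[["IMMATURE_OSTEOBLAST"]]
  expect_equal(bone_fraction(lat), 0.75)
  none <- box_lattice(c(2, 2, 2), region = "CALLUS")
  expect_error(bone_fraction(none), "pore")
})

test_that("regeneration runs are bit-identical for identical (config, seed)", {
  cfg <- scaffopt_config("micro")
  a <- run_regeneration(mid_design(), "titanium", cfg, n_days = 3, seed = 11)
  b <- run_regeneration(mid_design(), "titanium", cfg, n_days = 3, seed = 11)
  expect_identical(a$lattice$phenotype, b$lattice$phenotype)
  expect_identical(a$bone_fraction, b$bone_fraction)
  expect_identical(a$daily, b$daily)
  c <- run_regeneration(mid_design(), "titanium", cfg, n_days = 3, seed = 12)
  expect_false(identical(a$lattice$phenotype, c$lattice$phenotype))
})

test_that("frozen stimulus drives the expected saturation directions", {
  cfg <- scaffopt_config("micro")
  up <- run_regeneration(mid_design(), "titanium", cfg, n_days = 21, seed = 1,
                         stimulus_override = 0.3, record_every = 7)
  expect_gt(up$bone_fraction, 0.2)
  bf <- up$pore_daily$bone_fraction
  expect_true(all(diff(bf) >= -0.02))        # grows up to noise
  down <- run_regeneration(mid_design(), "titanium", cfg, n_days = 14, seed = 1,
                           stimulus_override = 5)
  expect_equal(down$bone_fraction, 0)
  none <- run_regeneration(mid_design(), "titanium", cfg, n_days = 0, seed = 1)
  expect_equal(none$bone_fraction, 0)
})

test_that("bone fraction is stable across seeds on the scaled-down fixture", {
  cfg <- scaffopt_config("micro")
  bf <- vapply(1:10, function(s) {
    run_regeneration(mid_design(), "titanium", cfg, n_days = 14,
                     seed = s, record_every = 100)$bone_fraction
  }, numeric(1))
  expect_lt(stats::sd(bf), 0.05)
})
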