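test_that("histology rendering counts sites exactly", {
  # checkerboard of bone and cartilage in a pore box: pixel counts must
  # match the site counts of the rendered plane
  lat <- box_lattice(c(6, 5, 8), region = "PORE")
  idx <- seq_len(6 * 5 * 8)
  chk <- (idx %% 2) == 0
  lat$phenotype[chk] <- AGENT_PHENOTYPES[["MATURE_OSTEOBLAST"]]
  lat$phenotype[!chk] <- AGENT_PHENOTYPES[["CHONDROCYTE"]]
  img <- render_histology(lat)
  pal <- histology_palette()
  iy <- ceiling(5 / 2)
  plane_ids <- as.vector(outer(seq_len(6), seq_len(8), function(ix, iz)
    ix + 6 * (iy - 1) + 30 * (iz - 1)))
  expect_equal(sum(img$colors == pal[["bone"]]), sum(chk[plane_ids]))
  expect_equal(sum(img$colors == pal[["cartilage"]]), sum(!chk[plane_ids]))

  # all-bone slice renders black over the whole tissue region
  lat$phenotype[] <- AGENT_PHENOTYPES[["IMMATURE_OSTEOBLAST"]]
  img2 <- render_histology(lat)
  expect_true(all(img2$colors == pal[["bone"]]))

  # empty lattice: background/granulation only
  lat$phenotype[] <- 0L
  img3 <- render_histology(lat)
  expect_true(all(img3$colors == pal[["granulation"]]))

  expect_error(render_histology(lat, plane = "coronal"), "plane")
  # PNG write round-trip
  f <- tempfile(fileext = ".png")
  render_histology(lat, path = f)
  expect_true(file.exists(f))
  expect_equal(dim(png::readPNG(f))[1:2], c(8, 6))
})

test_that("porosity/bone scatter recomputes porosity from the designs", {
  led <- tibble::tibble(x1 = c(1.9, 1.62, 1.84, 3.12, 1.9),
                        x2 = c(0.77, 1.44, 3.45, 3.26, 0.50),
                        x3 = c(0.70, 0.98, 2.26, 2.64, 0.70),
                        objective = c(0.67, 0.51, 0.93, 0.96, 0.65))
  rep5 <- suppressWarnings(porosity_bone_scatter(led, voxel_edge = 0.25))
  expect_equal(nrow(rep5$data), 5)
  direct <- suppressWarnings(
    scaffold_porosity(scaffold_design(1.84, 3.45, 2.26), voxel_edge = 0.25))
  expect_equal(rep5$data$porosity[3], direct)
  expect_s3_class(rep5$plot, "ggplot")

  one <- suppressWarnings(porosity_bone_scatter(led[1, ], voxel_edge = 0.25))
  expect_equal(nrow(one$data), 1)
  expect_warning(porosity_bone_scatter(led[c(1, 1), ], voxel_edge = 0.25),
                 "duplicated")
})

test_that("configuration round-trips and rejects unknown keys", {
  cfg <- scaffopt_config("desk", loads = list(load_scale = 1.5))
  f <- tempfile(fileext = ".yml")
  write_config(cfg, f)
  back <- read_config(f)
  expect_equal(unclass(back), unclass(cfg))
  expect_error(scaffopt_config("desk", loads = list(bogus_key = 1)),
               "unknown configuration key")
  expect_error(scaffopt_config("desk", not_a_section = list(a = 1)),
               "unknown configuration key")
  # manifest is deterministic and timestamp-free
  m1 <- run_manifest(cfg, 3)
  m2 <- run_manifest(cfg, 3)
  expect_identical(m1, m2)
  expect_false(any(grepl("time|date", names(m1), ignore.case = TRUE)))
  expect_false(identical(run_manifest(scaffopt_config("desk"), 3)$config_hash,
                         m1$config_hash))
})

test_that("voxel grids round-trip through the gzipped export", {
  g <- build_scaffold(mid_design(), scaffold_spec(height = 10),
                      voxel_edge = 0.5)
  f <- tempfile(fileext = ".gz")
  write_voxel_grid(g, f)
  back <- read_voxel_grid(f)
  expect_identical(back$labels, g$labels)
  expect_equal(back$voxel_edge, g$voxel_edge)
  expect_equal(back$dims, g$dims)
})

test_that("the CLI reports porosity and fails cleanly on bad input", {
  out <- tempfile()
  msgs <- capture.output(
    status <- scaffopt_cli(c("geometry", "--design", "1.9,0.77,0.70",
                             "--voxel", "0.25", "--out", out)))
  expect_equal(status, 0L)
  expect_true(any(grepl("porosity", msgs)))
  expect_true(file.exists(file.path(out, "porosity.csv")))
  expect_true(file.exists(file.path(out, "manifest.yml")))
  p <- utils::read.csv(file.path(out, "porosity.csv"))$porosity
  expect_equal(p, suppressWarnings(
    scaffold_porosity(scaffold_design(1.9, 0.77, 0.7), voxel_edge = 0.25)))

  expect_equal(suppressMessages(scaffopt_cli(character())), 1L)
  expect_equal(suppressMessages(scaffopt_cli(c("geometry"))), 1L)
  expect_equal(suppressMessages(scaffopt_cli(c("nonsense"))), 1L)
  expect_equal(suppressMessages(
    scaffopt_cli(c("geometry", "--design", "9,9,9"))), 1L)
})

test_that("fixtures expose the documented presets", {
  fx <- desk_fixture()
  expect_lt(prod(fx$domain$dims), 1e6)
  expect_s3_class(fx$config, "scaffopt_config")
  toys <- make_fixture("toy_oracles")
  expect_equal(toys$toy_quadratic(attr(toys$toy_quadratic, "optimum")), 0.9)
  ov <- make_fixture("strain_override")
  expect_equal(ov$S_bone, 0.3)
  expect_equal(ov$S_fibrous, 5)
  d <- tempfile(); dir.create(d)
  make_fixture("strain_override", dir = d)
  expect_true(file.exists(file.path(d, "S_bone.csv")))
})
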