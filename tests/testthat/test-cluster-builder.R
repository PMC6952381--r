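# Stoichiometric sucrose cluster generation and fixtures.

test_that("a single molecule has 45 atoms and 182 bound electrons", {
  cl <- build_cluster(1, seed = 1)
  expect_equal(nrow(cl$atoms), 45L)
  expect_equal(bound_electron_count(cl), 182)
  counts <- table(cl$atoms$element)
  expect_equal(unname(counts[c("C", "H", "O")]), c(12L, 22L, 11L),
               ignore_attr = TRUE)
})

test_that("particle bookkeeping: 227 tracked particles per molecule", {
  for (n in c(1, 7)) {
    cl <- build_cluster(n, seed = 2)
    expect_equal(nrow(cl$atoms) + bound_electron_count(cl), 227 * n)
  }
  # the production-scale configuration: ~42 million particles, ~50 nm
  expect_equal(227 * 185193, 42038811)
  expect_equal(2 * cluster_radius_nm(185193), 50, tolerance = 0.01)
})

test_that("generated density tracks the nominal sucrose density within 2%", {
  for (n in c(100, 300)) {
    cl <- build_cluster(n, seed = 4)
    d <- cluster_diameter(cl)
    mass_g <- n * dynscat:::sucrose_molar_mass() /
      dynscat_constants$avogadro
    dens <- mass_g / ((4 / 3) * pi * (d / 2 * 1e-7)^3) * 1000
    expect_equal(dens, 1581, tolerance = 0.02)
  }
})

test_that("cluster builds are seed-deterministic", {
  a <- build_cluster(20, seed = 9)
  b <- build_cluster(20, seed = 9)
  expect_identical(a$atoms$x_nm, b$atoms$x_nm)
  c2 <- build_cluster(20, seed = 10)
  expect_false(identical(a$atoms$x_nm, c2$atoms$x_nm))
})

test_that("impossible packings raise an error suggesting relaxation", {
  expect_error(build_cluster(50, seed = 1, density_kg_m3 = 1581,
                             min_distance_nm = 2,
                             max_attempts_per_molecule = 20),
               "relaxation")
})

test_that("XYZ and PDB exports round-trip coordinates", {
  cl <- build_cluster(2, seed = 3)
  xyz <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(cl, xyz)
  back <- read_xyz(xyz)
  expect_equal(back$atoms$element, cl$atoms$element)
  expect_equal(back$atoms$x_nm, cl$atoms$x_nm, tolerance = 1e-5)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(cl, pdb)
  lines <- readLines(pdb)
  expect_equal(sum(grepl("^HETATM", lines)), 90L)
  expect_equal(lines[length(lines)], "END")
})

test_that("ensemble generator is deterministic and honours a zero size spread", {
  geom <- detector_geometry(binning = 16)
  dn <- sucrose_dn_1483()$abs
  a <- synthetic_shot_ensemble(4, geom, 1483, dn, size_sd_nm = 0,
                               seed = 5)
  b <- synthetic_shot_ensemble(4, geom, 1483, dn, size_sd_nm = 0,
                               seed = 5)
  expect_identical(a$images, b$images)
  expect_true(all(a$truth$d_nm == 45))
})
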