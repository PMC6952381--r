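# Homogeneous-sphere forward model, image fitting and experimental DSE.

test_that("sphere envelope has the Taylor limit and zeros at tan s = s", {
  expect_equal(dynscat:::.sphere_envelope2(1e-9), 1 / 9)
  # roots of tan s = s located independently by root finding
  g <- function(s) sin(s) - s * cos(s)
  roots <- vapply(list(c(pi, 1.5 * pi), c(2 * pi, 2.5 * pi),
                       c(3 * pi, 3.5 * pi)), function(iv) {
    stats::uniroot(g, iv, tol = 1e-12)$root
  }, numeric(1))
  expect_equal(roots[1], 4.4934, tolerance = 1e-4)
  expect_equal(roots[2], 7.7253, tolerance = 1e-4)
  expect_true(all(dynscat:::.sphere_envelope2(roots) < 1e-20))
})

test_that("sphere image: central intensity, fluence linearity, isotropy", {
  geom <- test_geometry()
  lam <- 1239.842 / 1483
  dn <- sucrose_dn_1483()$abs
  m1 <- sphere_model(45, lam, dn, 1000)
  img1 <- sphere_image(m1, geom)
  # innermost pixel agrees with the small-s Taylor limit |...|^2 -> 1/9
  i0 <- which.min(geom$theta)
  s0 <- (2 * pi * 45 / lam) * sin(geom$theta[i0])
  expect_equal(img1[i0],
               1000 * geom$d_qegeo[i0] * (6 * pi * m1$volume_nm3 * dn /
                                            lam^2)^2 *
                 dynscat:::.sphere_envelope2(s0),
               tolerance = 1e-10)
  expect_lt(abs(dynscat:::.sphere_envelope2(s0 / 50) - 1 / 9), 1e-4)
  m2 <- sphere_model(45, lam, dn, 2000)
  expect_equal(sphere_image(m2, geom), 2 * img1, tolerance = 1e-12)
  # azimuthal isotropy: exact mirror symmetry plus a narrow ring at a
  # fringe maximum (where the profile is locally flat in theta)
  expect_equal(img1, img1[, rev(seq_len(ncol(img1)))], tolerance = 1e-12)
  expect_equal(img1, img1[rev(seq_len(nrow(img1))), ], tolerance = 1e-12)
  s_all <- (2 * pi * 45 / lam) * sin(geom$theta)
  ring <- abs(s_all - 5.76) < 0.02   # first side-lobe crest
  expect_gt(sum(ring), 20)
  expect_lt(stats::sd(img1[ring]) / mean(img1[ring]), 0.05)
})

test_that("noiseless synthetic images are recovered exactly", {
  geom <- test_geometry()
  lam <- 1239.842 / 1483
  dn <- sucrose_dn_1483()$abs
  i0 <- fluence_to_photons_nm2(25, 1483)
  img <- sphere_image(sphere_model(45, lam, dn, i0), geom)
  f <- fit_sphere(img, geom, dn, lam)
  expect_equal(f$d_nm, 45, tolerance = 0.005)
  expect_equal(f$i0_photons_nm2, i0, tolerance = 0.02)
  expect_false(f$low_confidence)
})

test_that("Poisson-noised fits recover the fluence within 10% (median)", {
  geom <- test_geometry()
  lam <- 1239.842 / 1483
  dn <- sucrose_dn_1483()$abs
  i0 <- fluence_to_photons_nm2(25, 1483)
  mu <- sphere_image(sphere_model(45, lam, dn, i0), geom)
  set.seed(100)
  rel_err <- replicate(100, {
    img <- matrix(stats::rpois(length(mu), mu), nrow(mu))
    f <- fit_sphere(img, geom, dn, lam)
    abs(f$i0_photons_nm2 - i0) / i0
  })
  expect_lt(stats::median(rel_err), 0.10)
})

test_that("visible fringes increase with photon energy at fixed size", {
  geom <- test_geometry()
  n_min <- vapply(c(530, 1000, 1483), function(om) {
    lam <- 1239.842 / om
    dn <- refractive_decrement(c(C = 12, H = 22, O = 11), 1581, om)$abs
    img <- sphere_image(sphere_model(45, lam, dn,
                                     fluence_to_photons_nm2(25, om)),
                        geom)
    prof <- radial_profile(img, geom, 150)
    sum(diff(sign(diff(log(prof$mean_counts + 1e-12)))) > 0)
  }, numeric(1))
  expect_true(all(diff(n_min) > 0))
})

test_that("refractive decrement: zero density, mixture linearity, 1483 eV value", {
  expect_equal(refractive_decrement(c(O = 1), 0, 1000)$abs, 0)
  # additivity over components at fixed partitioning of number density
  full <- refractive_decrement(c(C = 12, H = 22, O = 11), 1581, 1000)
  # doubling density doubles delta
  half <- refractive_decrement(c(C = 12, H = 22, O = 11), 1581 / 2, 1000)
  expect_equal(full$delta, 2 * half$delta, tolerance = 1e-10)
  expect_equal(full$beta, 2 * half$beta, tolerance = 1e-10)
  # cross-check against an independently computed optical-constant value:
  # delta = r_e lambda^2 / (2 pi) x n x sum(f1), with sum(f1) ~ 181.1 for
  # sucrose at 1483 eV (Z sum 182 with small negative dispersion terms)
  rd <- sucrose_dn_1483()
  lam <- 1239.842 / 1483
  n_nm3 <- 1581 * 1000 / 342.297 * 6.02214076e23 / 1e27
  delta_ref <- 2.8179403e-6 * lam^2 / (2 * pi) * n_nm3 * 181.1
  expect_equal(rd$delta, delta_ref, tolerance = 0.05)
})

test_that("experimental DSE: identity, top-fraction ordering, size filter", {
  # all fitted fluences equal to F0 -> DSE = 1
  fits <- tibble::tibble(d_nm = rnorm(50, 45, 1),
                         i0_photons_nm2 = rep(7.5, 50))
  expect_equal(dse_experimental(fits, 7.5)$dse, 1)
  # heavy-tailed fluences: top 5% beats the full average
  set.seed(2)
  fits2 <- tibble::tibble(d_nm = rnorm(200, 45, 0.5),
                          i0_photons_nm2 = exp(rnorm(200, 0, 1)))
  d5 <- dse_experimental(fits2, 1, top_fraction = 0.05)$dse
  d100 <- dse_experimental(fits2, 1, top_fraction = 1)$dse
  expect_gt(d5, d100)
  # zero size spread: filter keeps everything
  fits3 <- tibble::tibble(d_nm = rep(45, 20),
                          i0_photons_nm2 = seq_len(20))
  expect_equal(dse_experimental(fits3, 1,
                                top_fraction = 1)$n_after_size_filter, 20L)
  expect_error(dse_experimental(fits3[0, ], 1), "no shots|non-empty|NA")
})

test_that("synthetic ensemble pipeline recovers an injected damage factor", {
  geom <- test_geometry()
  dn <- sucrose_dn_1483()$abs
  ens <- synthetic_shot_ensemble(40, geom, 1483, dn, size_mean_nm = 45,
                                 size_sd_nm = 4, focal = 25,
                                 damage_factor = 0.3, seed = 3)
  fits <- fit_shot_ensemble(ens, geom, dn, 1483)
  f0 <- fluence_to_photons_nm2(25, 1483)
  # undamaged reference: same pipeline with damage 1
  ens1 <- synthetic_shot_ensemble(40, geom, 1483, dn, size_mean_nm = 45,
                                  size_sd_nm = 4, focal = 25,
                                  damage_factor = 1, seed = 4)
  fits1 <- fit_shot_ensemble(ens1, geom, dn, 1483)
  d03 <- dse_experimental(fits, f0, top_fraction = 0.05)$dse
  d1 <- dse_experimental(fits1, f0, top_fraction = 0.05)$dse
  expect_equal(d03, 0.3, tolerance = 0.05)
  expect_equal(d1, 1, tolerance = 0.05)
})

test_that("ensemble containers round-trip through the text layout", {
  geom <- detector_geometry(binning = 16)
  dn <- sucrose_dn_1483()$abs
  ens <- synthetic_shot_ensemble(3, geom, 1483, dn, seed = 6)
  dir <- withr::local_tempdir()
  write_shot_ensemble(ens, dir, geom)
  back <- read_shot_ensemble(dir)
  expect_equal(length(back$images), 3)
  expect_equal(back$images[[2]], unname(ens$images[[2]]),
               ignore_attr = TRUE)
  expect_equal(back$truth$d_nm, ens$truth$d_nm, tolerance = 1e-8)
  expect_equal(back$meta$detector$distance_mm, 370)
})
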