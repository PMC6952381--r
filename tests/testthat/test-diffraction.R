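# Coherent scattering: instantaneous form factors, dynamic and undamaged
# cross sections, DSE.

test_that("single neutral atom at the origin scatters with no phase", {
  st <- cluster_state(tibble::tibble(element = "O", x_nm = 0, y_nm = 0,
                                     z_nm = 0))
  q <- cbind(c(1e-9, 5, 20), 0, 0)
  Fq <- instantaneous_form_factor(st, q, omega_ev = 2000)
  ad <- oxygen_ground()
  fa <- form_factor(ad, sqrt(rowSums(q^2)), 2000)
  expect_equal(Fq, fa, tolerance = 1e-10)
  expect_equal(Re(Fq[1]), 8, tolerance = 0.1)
})

test_that("two-atom interference follows the closed form", {
  d <- 0.5
  st <- cluster_state(tibble::tibble(element = c("O", "O"),
                                     x_nm = c(0, d), y_nm = 0, z_nm = 0))
  q <- seq(0.5, 30, length.out = 40)
  Fq <- instantaneous_form_factor(st, cbind(q, 0, 0), omega_ev = 1000)
  f1 <- form_factor(oxygen_ground(), q, 1000)
  expect_equal(Mod(Fq)^2, 2 * Mod(f1)^2 * (1 + cos(q * d)),
               tolerance = 1e-8)
  # fringe period 2 pi / d: intensity minima at q = pi/d, 3 pi/d
  qmin <- c(pi / d, 3 * pi / d)
  expect_lt(max(Mod(instantaneous_form_factor(
    st, cbind(qmin, 0, 0), 1000))^2), 1e-10 * max(Mod(Fq)^2))
})

test_that("q = 0 amplitude counts all bound electrons, Friedel symmetry holds", {
  cl <- build_cluster(2, seed = 5)
  F0 <- instantaneous_form_factor(cl, c(1e-12, 0, 0), 2000)
  expect_equal(Re(F0), 2 * 182, tolerance = 0.5)
  qs <- rbind(c(3, 2, 1), c(-3, -2, -1), c(0.5, -8, 2),
              c(-0.5, 8, -2))
  # exact Friedel symmetry for a real (single-phase) scattering density:
  # a one-species cluster has a common complex prefactor that drops out
  one <- cluster_state(dplyr::mutate(cl$atoms[1:45, ], element = "C",
                                     config = NULL))
  F1 <- instantaneous_form_factor(one, qs, 2000)
  expect_equal(Mod(F1[1])^2, Mod(F1[2])^2, tolerance = 1e-10)
  expect_equal(Mod(F1[3])^2, Mod(F1[4])^2, tolerance = 1e-10)
  # mixed species: anomalous dispersion breaks Friedel symmetry only at
  # the level of the (small) phase difference between f_C, f_H, f_O
  Fq <- instantaneous_form_factor(cl, qs, 8000)
  expect_equal(Mod(Fq[1])^2, Mod(Fq[2])^2, tolerance = 0.02)
  expect_equal(Mod(Fq[3])^2, Mod(Fq[4])^2, tolerance = 0.02)
})

test_that("missing atomic data for a configuration fails loudly", {
  st <- cluster_state(tibble::tibble(element = "O", x_nm = 0, y_nm = 0,
                                     z_nm = 0))
  st$atoms$config <- list(electronic_configuration("O", c(2, 2, 4)))
  # force an invalid photon energy instead: outside tabulated grid
  expect_error(instantaneous_form_factor(st, c(1, 0, 0), 0.5),
               "refusing to extrapolate|positive")
})

test_that("frozen dynamics give sigma_dam = sigma_nodam and DSE = 1 exactly", {
  cl <- build_cluster(3, seed = 2)
  p <- pulse_spec(530, 2, 25)
  ctl <- dynamics_control(dt_fs = 0.02, snapshot_every_fs = 0.5,
                          damage = FALSE, motion = FALSE,
                          ei = FALSE, rc = FALSE)
  r <- theoretical_dse(cl, p, seed = 1, control = ctl, n_theta = 16,
                       n_dir = 8, n_bandwidth_nodes = 3)
  expect_equal(r$dse, 1, tolerance = 1e-12)
})

test_that("pure delocalized electrons scatter incoherently: sigma = N_e sigma_th", {
  # hand-built trajectory: no atoms, five delocalized electrons
  reg <- config_registry(1000, 10)
  snap <- list(t_fs = 0, pos_nm = matrix(0, 0, 3), cfg = integer(0),
               n_e = 5L, escaped = 0L)
  traj <- structure(list(snapshots = list(snap),
                         pulse = pulse_spec(1000, 5, 25),
                         registry = reg,
                         events = tibble::tibble()),
                    class = "cluster_trajectory")
  res <- dynamic_cross_section(traj, n_theta = 96, n_dir = 4,
                               n_bandwidth_nodes = 1)
  sigma_thomson_barn <- 0.6652458                 # full Thomson
  expect_equal(res$sigma_barn, 5 * sigma_thomson_barn, tolerance = 1e-3)
})

test_that("patterns are non-negative and fluence-linear in expected counts", {
  r <- dse_run("d530_5")
  expect_true(all(r$damaged$pattern$dsdo_barn_sr >= 0))
  expect_true(all(r$undamaged$pattern$dsdo_barn_sr >= 0))
  expect_gt(r$sigma_nodam_barn, 0)
  expect_gt(r$dse, 0)
  expect_lte(r$dse, 1.05)
})

test_that("cross sections are stable under quadrature refinement", {
  cl <- build_cluster(2, seed = 7)
  p <- pulse_spec(530, 2, 25)
  reg <- config_registry(530, 5.3)
  traj <- simulate_cluster(cl, p, seed = 9,
                           control = dynamics_control(
                             snapshot_every_fs = 0.25),
                           registry = reg)
  coarse <- dynamic_cross_section(traj, n_theta = 24, n_dir = 8,
                                  n_bandwidth_nodes = 3,
                                  snapshot_stride = 4)
  fine <- dynamic_cross_section(traj, n_theta = 48, n_dir = 16,
                                n_bandwidth_nodes = 7,
                                snapshot_stride = 1)
  expect_equal(coarse$sigma_barn, fine$sigma_barn, tolerance = 0.1)
})

test_that("aperture errors are explicit and DSE guards its denominator", {
  cl <- build_cluster(1, seed = 1)
  p <- pulse_spec(530, 2, 25)
  expect_error(undamaged_cross_section(cl, p, q_max_nm_inv = 1e5),
               "exceeds the physical maximum")
  expect_error(dse_theory(1, 0), "positive")
  expect_equal(dse_theory(0, 10), 0)
  expect_equal(dse_theory(3, 3), 1)
})

test_that("empty cluster has zero undamaged cross section", {
  empty <- cluster_state(tibble::tibble(element = character(),
                                        x_nm = numeric(),
                                        y_nm = numeric(),
                                        z_nm = numeric()))
  p <- pulse_spec(530, 2, 25)
  expect_equal(undamaged_cross_section(empty, p)$sigma_barn, 0)
})
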