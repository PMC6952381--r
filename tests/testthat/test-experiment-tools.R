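# Beamline arithmetic, focal-volume fluence distribution, two-level Rabi
# estimate.

test_that("peak fluence arithmetic is exact and linear", {
  bl <- beamline_spec(1.55, 0.10, 5, 530)
  expect_equal(peak_fluence(bl)$uj_um2, 31)
  expect_equal(peak_fluence(beamline_spec(0, 0.10, 5, 530))$uj_um2, 0)
  expect_equal(peak_fluence(beamline_spec(1.55, 0.20, 5, 530))$uj_um2,
               2 * 31)
  expect_equal(peak_fluence(beamline_spec(3.10, 0.10, 5, 530))$uj_um2,
               2 * 31)
  # photon-number conversion consistent
  expect_equal(peak_fluence(bl)$photons_um2,
               fluence_to_photons_nm2(31, 530) * 1e6)
})

test_that("focal fluence distribution: flat is a delta, Gaussian is 1/F", {
  bl <- beamline_spec(1.55, 0.10, 5, 530)
  flat <- focal_fluence_distribution(bl, "flat")
  expect_equal(nrow(flat), 1L)
  expect_equal(flat$fluence_uj_um2, 31)
  expect_equal(flat$weight, 1)

  g <- focal_fluence_distribution(bl, "gaussian", n_bins = 40)
  expect_equal(sum(g$weight), 1, tolerance = 1e-12)
  expect_equal(attr(g, "support_max_uj_um2"), 31)
  expect_lte(max(g$fluence_uj_um2), 31)
  expect_gt(max(g$fluence_uj_um2), 0.9 * 31)
  # p(F) ~ 1/F: equal mass per log bin
  expect_lt(diff(range(g$weight)) / mean(g$weight), 1e-9)
})

test_that("two-level norm never exceeds one and decays without field", {
  p <- pulse_spec(530, 5, 25)
  r <- rabi_two_level(p, dipole_au = 0.15, auger_rate_per_fs = 0.25)
  expect_true(all(r$trace$norm <= 1 + 1e-8))
  # no field: excited population decays exponentially at the Auger rate
  p0 <- pulse_spec(530, 5, 0)
  r0 <- rabi_two_level(p0, dipole_au = 0.15, auger_rate_per_fs = 0.25,
                       initial = c(0, 1))
  t_rel <- r0$trace$t_fs - r0$trace$t_fs[1]
  expect_equal(r0$trace$pop_e, exp(-0.25 * t_rel), tolerance = 1e-4)
  expect_equal(r0$trace$pop_g, rep(0, length(t_rel)), tolerance = 1e-10)
})

test_that("peak Rabi frequency scales as one over sqrt(duration) at fixed fluence", {
  d <- 0.12
  r1 <- rabi_two_level(pulse_spec(530, 8, 25), d, 0.25)
  r2 <- rabi_two_level(pulse_spec(530, 2, 25), d, 0.25)
  expect_equal(r2$peak_rabi_per_fs / r1$peak_rabi_per_fs, 2,
               tolerance = 1e-10)
  # closed-form envelope maximum: Omega = d sqrt(2 I_peak / (eps0 c))
  p <- pulse_spec(530, 5, 25)
  ipk <- 25 * 100 * 2 * sqrt(log(2) / pi) / 5e-15   # W/cm^2
  expect_equal(pulse_peak_field_au(p), sqrt(ipk / 3.50944758e16),
               tolerance = 1e-12)
})

test_that("pulse profiles integrate to their nominal fluence and unity", {
  p <- pulse_spec(530, 30, 25)
  tt <- seq(-1.4 * 30, 1.4 * 30, by = 0.01)
  fl <- sum(pulse_flux(p, tt)) * 0.01
  expect_equal(fl / p$fluence_photons_nm2, 1, tolerance = 1e-3)
  om <- seq(480, 580, by = 0.01)
  expect_equal(sum(pulse_bandwidth_profile(p, om)) * 0.01, 1,
               tolerance = 1e-6)
  nodes <- bandwidth_nodes(p, 7)
  expect_equal(sum(nodes$weight), 1, tolerance = 1e-12)
  expect_equal(sum(nodes$weight * nodes$omega_ev), 530, tolerance = 1e-8)
})
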