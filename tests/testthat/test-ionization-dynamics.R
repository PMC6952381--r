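# Monte-Carlo rate-equation sampling of electronic-configuration
# transitions.

test_that("rate tables: field off means Auger only, at the configured rate", {
  p <- pulse_spec(530, 30, 25)
  # far outside the pulse: no field
  tb0 <- build_rate_table(ground_configuration("O"), p, t_fs = -1e4)
  expect_equal(attr(tb0, "total_rate_per_fs"), 0)
  # 1s core hole decays at 1/tau with the 4-fs oxygen preset
  tb <- build_rate_table(electronic_configuration("O", c(1, 2, 4)), p,
                         t_fs = -1e4)
  expect_equal(attr(tb, "total_rate_per_fs"), 1 / 4, tolerance = 1e-10)
  expect_equal(unique(tb$channel[tb$rate_per_fs > 0]), "A")
  # the 5-fs preset is selectable
  reg5 <- config_registry(530, 5.3,
                          hfs_control(lifetimes = list(C = 10, N = 7,
                                                       O = 5)))
  tb5 <- build_rate_table(electronic_configuration("O", c(1, 2, 4)), p,
                          t_fs = -1e4, registry = reg5)
  expect_equal(attr(tb5, "total_rate_per_fs"), 1 / 5, tolerance = 1e-10)
})

test_that("branching probabilities sum to one whenever the rate is positive", {
  p <- pulse_spec(530, 30, 25)
  reg <- config_registry(530, 5.3)
  for (occ in list(c(2, 2, 4), c(1, 2, 4), c(2, 2, 3), c(1, 2, 5))) {
    tb <- build_rate_table(electronic_configuration("O", occ), p,
                           t_fs = 0, registry = reg)
    tot <- attr(tb, "total_rate_per_fs")
    if (tot > 0) {
      expect_equal(sum(tb$rate_per_fs) / tot, 1, tolerance = 1e-12)
      expect_true(all(tb$rate_per_fs >= 0))
    }
  }
})

test_that("resonant channels require a matching line inside the bandwidth", {
  p800 <- pulse_spec(800, 30, 25)
  tb <- build_rate_table(ground_configuration("O"), p800, t_fs = 0)
  expect_false("RE" %in% tb$channel)   # no O line near 800 eV
  p530 <- pulse_spec(530, 30, 25)
  tb2 <- build_rate_table(ground_configuration("O"), p530, t_fs = 0)
  expect_true("RE" %in% tb2$channel)   # ground O 1s->2p sits in band
})

test_that("zero-fluence evolution leaves every atom in its ground state", {
  run <- evolve_configurations(rep("O", 20), pulse_spec(530, 5, 0),
                               seed = 1, dt_fs = 0.05)
  expect_equal(run$n_electrons_freed, 0L)
  expect_true(all(run$final_charge == 0))
  expect_equal(nrow(run$events), 0L)
})

test_that("single-photon ionized fraction follows the Poisson closed form", {
  p <- pulse_spec(800, 5, 2)
  run <- evolve_configurations(rep("O", 300), p, seed = 4, dt_fs = 0.02)
  frac <- mean(run$final_charge > 0)
  ad <- oxygen_ground()
  sig_nm2 <- total_photoionization_cs(ad, 800) * 1e-10
  expected <- 1 - exp(-sig_nm2 * p$fluence_photons_nm2)
  se <- sqrt(expected * (1 - expected) / 300)
  expect_lt(abs(frac - expected), 3 * se + 0.01)
})

test_that("core-hole survival decays exponentially at the Auger rate", {
  start <- replicate(400, electronic_configuration("O", c(1, 2, 4)),
                     simplify = FALSE)
  run <- evolve_configurations(start, pulse_spec(530, 5, 0), seed = 5,
                               dt_fs = 0.01, t_range_fs = c(0, 4))
  surv <- mean(vapply(run$final, function(cf) {
    identical(cf$occupations, c(1L, 2L, 4L))
  }, logical(1)))
  expected <- exp(-1)   # 4 fs at 1/(4 fs)
  se <- sqrt(expected * (1 - expected) / 400)
  expect_lt(abs(surv - expected), 3 * se + 0.01)
})

test_that("evolution is reproducible bit-for-bit for a fixed seed", {
  p <- pulse_spec(530, 5, 10)
  reg <- config_registry(530, 5.3)
  a <- evolve_configurations(rep("O", 30), p, seed = 42, registry = reg,
                             dt_fs = 0.02)
  b <- evolve_configurations(rep("O", 30), p, seed = 42, registry = reg,
                             dt_fs = 0.02)
  expect_identical(a$events, b$events)
  c2 <- evolve_configurations(rep("O", 30), p, seed = 43, registry = reg,
                              dt_fs = 0.02)
  expect_false(identical(a$events, c2$events))
})

test_that("too-coarse steps are rejected with guidance", {
  p <- pulse_spec(530, 1, 5000)   # absurd intensity
  expect_error(evolve_configurations("O", p, dt_fs = 0.05),
               "smaller dt")
})

test_that("electron bookkeeping balances over an isolated-atom run", {
  p <- pulse_spec(530, 5, 25)
  run <- evolve_configurations(rep("O", 40), p, seed = 8, dt_fs = 0.01)
  freed <- run$n_electrons_freed
  bound <- sum(vapply(run$final, function(cf) cf$n_electrons, numeric(1)))
  expect_equal(bound + freed, 40L * 8L)
  expect_equal(sum(run$final_charge), freed)
})

test_that("argon benchmark: zero fluence all neutral; flat focus equals single run", {
  p0 <- pulse_spec(530, 5, 0)
  d0 <- argon_benchmark(p0, n_atoms = 5, seed = 2, dt_fs = 0.05)
  expect_equal(d0$charge, 0L)
  expect_equal(d0$probability, 1)

  p <- pulse_spec(530, 5, 10)
  flat <- tibble::tibble(fluence_uj_um2 = 10, weight = 1)
  a <- argon_benchmark(p, focal = flat, n_atoms = 30, seed = 3,
                       dt_fs = 0.02)
  b <- argon_benchmark(p, focal = NULL, n_atoms = 30, seed = 3,
                       dt_fs = 0.02)
  expect_equal(a, b)
  expect_equal(sum(a$probability), 1, tolerance = 1e-12)
  expect_true(any(a$charge > 0))   # 2p ionization is open at 530 eV
})
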