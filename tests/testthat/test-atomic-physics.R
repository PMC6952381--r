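# Hartree-Fock-Slater engine: configurations, SCF, cross sections and
# complex form factors.

test_that("electronic configurations enforce capacities and charge", {
  cf <- electronic_configuration("O", c(2, 2, 4))
  expect_equal(cf$n_electrons, 8L)
  expect_equal(cf$charge, 0L)
  expect_error(electronic_configuration("O", c(3, 2, 4)), "capacity")
  expect_error(electronic_configuration("O", c(2, 2, 7)), "capacity")
  expect_error(electronic_configuration("O", c(2, 2, 6)), "exceeds Z")
  expect_error(electronic_configuration("O", c(-1, 2, 4)), "negative")
})

test_that("radial solver reproduces the analytic hydrogen eigenvalue", {
  ad <- hydrogen_bare()
  expect_equal(-ad$energies_ev[1], -13.6057, tolerance = 0.01)
})

test_that("SCF density integrates to the bound-electron count", {
  ad <- oxygen_ground()
  expect_equal(sum(ad$rho_rad * ad$r * ad$h), 8, tolerance = 1e-4)
  ad_ion <- solve_hfs("O", c(1, 2, 4), with_transitions = FALSE)
  expect_equal(sum(ad_ion$rho_rad * ad_ion$r * ad_ion$h), 7,
               tolerance = 1e-4)
})

test_that("the core-excited oxygen configuration carries a 1s-2p line", {
  ad <- solve_hfs("O", c(1, 2, 5))
  expect_s3_class(ad$transitions, "tbl_df")
  # absorption 1s -> 2p still possible (one 2p vacancy left)
  expect_true(any(ad$transitions$from == "1s" & ad$transitions$to == "2p"))
  expect_true(all(ad$transitions$gamma_ev > 0))
})

test_that("photoionization vanishes below threshold and is non-negative", {
  ad <- oxygen_ground()
  expect_equal(photoionization_cs(ad, "2p", 5), 0)
  expect_equal(photoionization_cs(ad, "1s", 400), 0)
  om <- c(20, 50, 200, 530, 1000)
  expect_true(all(total_photoionization_cs(ad, om) >= 0))
  expect_error(photoionization_cs(ad, "7q", 530), "unknown subshell")
})

test_that("hydrogenic photo cross section matches the closed form", {
  ad <- hydrogen_bare()
  for (om in c(20, 40, 136, 400)) {
    expect_equal(photoionization_cs(ad, "1s", om), stobbe_cs_barn(om),
                 tolerance = 0.05)
  }
})

test_that("resonant cross section follows the bandwidth dilution limit", {
  ad <- oxygen_ground()
  tr <- ad$transitions[ad$transitions$from == "1s" &
                         ad$transitions$to == "2p", ]
  s_narrow <- resonant_cs(ad, "1s", "2p", tr$omega_ev, 5.3)
  s_wide <- resonant_cs(ad, "1s", "2p", tr$omega_ev, 530)
  expect_gt(s_narrow, 10 * s_wide)
  expect_lt(resonant_cs(ad, "1s", "2p", tr$omega_ev, 1e6), 1e4)
  # transition into a full subshell is rejected
  ad_full <- solve_hfs("O", c(2, 2, 6) - c(0, 2, 0))  # 2s holes, 2p full
  expect_error(resonant_cs(ad_full, "1s", "2p", 530, 5.3), "full subshell")
})

test_that("form factor limits: electron count at q = 0, zero for bare ions", {
  ad <- oxygen_ground()
  expect_equal(form_factor_f0(ad, 0), 8, tolerance = 1e-4)
  f_high <- form_factor(ad, 0, 8000)
  expect_equal(Re(f_high), 8, tolerance = 0.15)
  expect_lt(Im(f_high), 0.2)
  stripped <- solve_hfs("O", c(0, 0, 0), with_transitions = FALSE)
  expect_equal(form_factor(stripped, c(0, 5, 50), 530),
               complex(real = c(0, 0, 0)))
})

test_that("f0 decays within a monotone envelope at large q", {
  ad <- oxygen_ground()
  q <- seq(0, 400, length.out = 200)
  f0 <- form_factor_f0(ad, q)
  # windowed maxima of |f0| decrease
  win <- split(abs(f0), cut(q, 8))
  env <- vapply(win, max, numeric(1))
  expect_true(all(diff(env) < 1e-6))
  expect_lt(abs(f0[length(f0)]), 0.35)
})

test_that("f'' is non-negative across the tabulated range", {
  ad <- oxygen_ground()
  for (om in c(30, 100, 300, 530, 560, 1000, 5000)) {
    expect_gte(anomalous_terms(ad, om)$f2, 0)
  }
  expect_error(anomalous_terms(ad, 1), "refusing to extrapolate")
})

test_that("Kramers-Kronig transform matches the analytic Lorentzian pair", {
  om0 <- 500; gam <- 8
  grid <- seq(5, 5000, by = 2.5)
  f2 <- (gam / 2) / ((grid - om0)^2 + gam^2 / 4)
  eval_at <- c(420, 470, 490, 510, 530, 600)
  f1 <- kramers_kronig(grid, f2, eval_at)
  f1_exact <- (eval_at - om0) / ((eval_at - om0)^2 + gam^2 / 4)
  expect_equal(f1, f1_exact, tolerance = 0.05)
})

test_that("SCF failure and invalid occupations raise explicit errors", {
  expect_error(solve_hfs("O", ground_configuration("O"),
                         control = hfs_control(alpha = 0.6811,
                                               max_iter = 2)),
               "did not converge")
  expect_error(solve_hfs("O", c(2, 2, 7)), "capacity")
})

test_that("atomic data export/import round-trips the tables", {
  ad <- oxygen_ground()
  dir <- withr::local_tempdir()
  export_atomic_data(ad, dir)
  back <- import_atomic_data(dir)
  expect_equal(back$meta$element, "O")
  expect_equal(back$levels$binding_ev, tidy(ad)$binding_ev,
               tolerance = 1e-6)
  expect_equal(nrow(back$transitions), nrow(ad$transitions))
  expect_true(all(back$sigma_pi$`2p` >= 0))
})
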