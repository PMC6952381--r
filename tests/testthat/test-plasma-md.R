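# Classical nanoplasma propagation: symplectic Coulomb dynamics,
# continuum processes, delocalization census.

bohr_nm <- dynscat_constants$bohr_nm
fs_au <- dynscat_constants$fs_au

test_that("neutral atoms evolve ballistically (no forces)", {
  st <- cluster_state(tibble::tibble(
    element = c("O", "C"), x_nm = c(0, 1), y_nm = 0, z_nm = 0,
    vx = c(0.1, -0.05), vy = 0, vz = 0))
  out <- md_propagate(st, t_fs = 2, dt_fs = 0.01)
  expect_equal(out$atoms$x_nm, c(0 + 0.1 * 2, 1 - 0.05 * 2),
               tolerance = 1e-9)
  expect_equal(out$atoms$vx, c(0.1, -0.05), tolerance = 1e-12)
})

test_that("bound two-body Coulomb orbit conserves energy and momentum", {
  # electron on a circular orbit around a bare proton (Kepler oracle)
  st <- cluster_state(
    tibble::tibble(element = "H", x_nm = 0, y_nm = 0, z_nm = 0,
                   config = list(electronic_configuration("H", c(0)))),
    electrons = tibble::tibble(x_nm = bohr_nm, y_nm = 0, z_nm = 0,
                               vx = 0, vy = bohr_nm * fs_au, vz = 0))
  ctl <- dynamics_control(dt_fs = 0.001, snapshot_every_fs = 10,
                          softening_nm = 1e-5, damage = FALSE,
                          ei = FALSE, rc = FALSE)
  out <- md_propagate(st, t_fs = 10, dt_fs = 0.001, control = ctl)
  energy <- function(s) {
    mp <- 1.008 * dynscat_constants$amu_au
    d <- sqrt((s$electrons$x_nm - s$atoms$x_nm)^2 +
                (s$electrons$y_nm - s$atoms$y_nm)^2 +
                (s$electrons$z_nm - s$atoms$z_nm)^2) / bohr_nm
    ke_e <- 0.5 * (s$electrons$vx^2 + s$electrons$vy^2 +
                     s$electrons$vz^2) / (bohr_nm * fs_au)^2
    ke_p <- 0.5 * mp * (s$atoms$vx^2 + s$atoms$vy^2 + s$atoms$vz^2) /
      (bohr_nm * fs_au)^2
    ke_e + ke_p - 1 / d
  }
  expect_equal(energy(st), -0.5, tolerance = 1e-6)
  expect_lt(abs(energy(out) - energy(st)) / abs(energy(st)), 1e-4)
  # total momentum conserved to round-off
  mp <- 1.008 * dynscat_constants$amu_au
  px <- out$electrons$vx + mp * out$atoms$vx
  py <- out$electrons$vy + mp * out$atoms$vy
  expect_lt(abs(px) / (bohr_nm * fs_au), 1e-8)
  expect_equal(py / (bohr_nm * fs_au), 1, tolerance = 1e-8)
})

test_that("impact-ionization probability reproduces the Lotz cross section", {
  # electrons fired past a ground-state O atom on straight lines with
  # impact parameters uniform over a disc: the hit fraction must equal
  # sigma_Lotz / disc area
  ad <- oxygen_ground()
  ke_ev <- 150
  bind <- ad$energies_ev
  occ <- ad$configuration$occupations
  sig_nm2 <- lotz_cross_section(bind, occ, ke_ev)
  b_hit <- sqrt(sig_nm2 / pi)
  v_nm_fs <- sqrt(2 * ke_ev / 27.211386) * bohr_nm * fs_au
  n <- 40
  b_disc <- 3 * b_hit
  set.seed(31)
  bb <- b_disc * sqrt(runif(n))
  # one isolated atom per projectile, well separated: every encounter
  # sees a pristine ground-state target
  zoff <- (seq_len(n) - 1) * 5
  st <- cluster_state(
    tibble::tibble(element = "O", x_nm = 0, y_nm = 0, z_nm = zoff),
    electrons = tibble::tibble(x_nm = -0.35, y_nm = bb,
                               z_nm = zoff, vx = v_nm_fs, vy = 0,
                               vz = 0))
  ctl <- dynamics_control(dt_fs = 0.002, snapshot_every_fs = 10,
                          softening_nm = 0.01, damage = TRUE,
                          ei = TRUE, rc = FALSE)
  pulse <- pulse_spec(530, 0.25, 0)
  reg <- config_registry(530, 5.3)
  traj <- simulate_cluster(st, pulse, seed = 3, control = ctl,
                           registry = reg)
  n_ei <- sum(traj$events$channel == "EI")
  expect_equal(n_ei, sum(bb < b_hit))
})

test_that("recombination only captures electrons bound to an ion", {
  ev <- dse_run("d530_5")$trajectory$events
  rc <- ev[ev$channel == "RC", ]
  if (nrow(rc) > 0) {
    # every capture lands in a configuration with one more electron
    nb <- function(key) sum(as.integer(strsplit(
      strsplit(key, ":")[[1]][2], ",")[[1]]))
    expect_true(all(vapply(seq_len(nrow(rc)), function(i) {
      nb(rc$to[i]) == nb(rc$from[i]) + 1
    }, logical(1))))
  }
  expect_gte(nrow(rc), 0)
})

test_that("delocalization census classifies the trivial cases", {
  cl <- build_cluster(2, seed = 3)
  cen <- delocalization_census(cl)
  expect_equal(cen$n_delocalized, 0L)
  expect_equal(cen$escaped, 0L)
  expect_gt(cen$diameter_nm, 0)
  expect_equal(cen$bound_electrons, 2 * 182)

  # all electrons far away and unbound -> escaped
  far <- cluster_state(
    cl$atoms[1:45, ],
    electrons = tibble::tibble(x_nm = c(500, -700), y_nm = 0, z_nm = 0,
                               vx = c(50, 60), vy = 0, vz = 0))
  cen2 <- delocalization_census(far)
  expect_equal(cen2$n_delocalized, 0L)
  expect_equal(cen2$escaped, 2L)
})

test_that("charge is conserved through a damaging run", {
  r <- dse_run("d530_5")
  traj <- r$trajectory
  final <- traj$final
  expect_equal(sum(final$atoms$charge),
               nrow(final$electrons) + final$escaped)
  # and per snapshot: bound + delocalized + escaped = initial electrons
  cen <- trajectory_census(traj)
  tot <- cen$bound_electrons + cen$n_delocalized + cen$escaped
  expect_true(all(tot == bound_electron_count(traj$cluster)))
})

test_that("classical energy audit balances injection and removal", {
  # a gentle photoemission regime (no dense-plasma churn): fast
  # photoelectrons leave ballistically and every audited term is
  # integrator-resolved, so the books must close:
  # E1 - E0 = injected - removed
  cl <- build_cluster(2, seed = 8)
  p <- pulse_spec(800, 5, 1.5)
  r <- simulate_cluster(cl, p, seed = 21,
                        registry = config_registry(800, 8))
  a <- r$audit
  expect_gt(nrow(r$events), 3)   # something actually happened
  scale <- max(abs(a$injected), abs(a$removed), 1)
  expect_lt(abs((a$E1 - a$E0) - (a$injected - a$removed)) / scale, 0.05)
})
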