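# Shared, lazily computed fixtures. Atomic-structure results are memoised
# inside the package; the expensive dynamics runs are memoised here so
# several test files can share one trajectory.

.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  hit <- .fx[[name]]
  if (!is.null(hit)) return(hit)
  val <- builder()
  .fx[[name]] <- val
  val
}

oxygen_ground <- function() {
  fx("oxygen_ground", function() {
    solve_hfs("O", ground_configuration("O"))
  })
}

hydrogen_bare <- function() {
  fx("hydrogen_bare", function() {
    solve_hfs("H", c(1), control = hfs_control(exchange = "none"),
              with_transitions = FALSE)
  })
}

small_cluster <- function() {
  fx("small_cluster", function() build_cluster(10, seed = 1))
}

# the scaled-down study conditions, all at 25 uJ/um^2 on a 10-molecule
# cluster: the pulse-duration sweep {5, 30, 180} fs at 530 eV, and the
# photon-energy comparison {500, 530, 800} eV at 30 fs (the resonant
# 530-eV minimum is a fixed-duration ordering; 30 fs keeps the
# long-pulse mechanism active at desk-scale cost)
dse_conditions <- list(
  d530_5 = c(530, 5), d530_30 = c(530, 30), d530_180 = c(530, 180),
  d500_30 = c(500, 30), d800_30 = c(800, 30))

registry_for <- function(omega_ev) {
  fx(paste0("registry_", omega_ev), function() {
    config_registry(omega_ev, 0.01 * omega_ev)
  })
}

# the sweeps integrate at 20 as (cross-checked against the default
# 10-as step: DSE values agree to ~10% and every ordering is unchanged)
dse_run <- function(name) {
  fx(paste0("dse_", name), function() {
    cond <- dse_conditions[[name]]
    pulse <- pulse_spec(cond[1], cond[2], 25)
    theoretical_dse(small_cluster(), pulse, seed = 11,
                    control = dynamics_control(dt_fs = 0.02),
                    registry = registry_for(cond[1]))
  })
}

# hydrogenic (Stobbe) 1s photoionization cross section, barn
stobbe_cs_barn <- function(omega_ev, z = 1) {
  ion_ev <- 13.605693 * z^2
  if (omega_ev <= ion_ev) return(0)
  k <- sqrt(2 * (omega_ev - ion_ev) / 27.211386) / z
  nu <- 1 / k
  s_au <- (2^9 * pi^2 / 3) * 7.2973525693e-3 / z^2 *
    (ion_ev / omega_ev)^4 *
    exp(-4 * nu * atan2(1, nu)) / (1 - exp(-2 * pi * nu))
  s_au * 2.80028520539e7
}

sucrose_dn_1483 <- function() {
  fx("dn1483", function() {
    refractive_decrement(c(C = 12, H = 22, O = 11), 1581, 1483)
  })
}

test_geometry <- function() {
  fx("geom", function() detector_geometry(binning = 4))
}
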