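## Time- and bandwidth-resolved coherent scattering.
##
## The damaged differential cross section is the pulse-intensity- and
## bandwidth-weighted average of instantaneous patterns,
##   dsigma_dam/dOmega(q) = dsigma_th/dOmega x (1/F) int domega int dt
##        g(omega, omega_x) j_X(tau, t) [ |F_c(q,t)|^2 + N_e(t) ],
## with F_c(q,t) the coherent sum over atomic form factors and N_e(t) the
## delocalized electrons contributing incoherently. Total cross sections
## integrate over the full scattering sphere (or a configured aperture).

#' Quasi-uniform directions on the sphere (Fibonacci lattice)
#' @param n number of directions.
#' @return n x 3 matrix of unit vectors.
#' @keywords internal
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' @keywords internal
xray_wavelength_nm <- function(photon_energy_ev) {
  1239.8419843320026 / photon_energy_ev  # hc in eV nm
}

# unpolarized Thomson differential cross section, barn/sr
.thomson_dsdo_barn <- function(theta) {
  re2_barn <- dynscat_constants$r_e_nm^2 * 1e10   # nm^2 -> barn
  re2_barn * (1 + cos(theta)^2) / 2
}

# per-configuration complex form factors at the q grid and bandwidth nodes
.config_ff_matrix <- function(reg, cfg_idx, q_abs, omega_nodes,
                              resonance_broadening_ev = 0) {
  f0 <- matrix(0, length(q_abs), length(cfg_idx))
  an <- matrix(0 + 0i, length(cfg_idx), length(omega_nodes))
  for (g in seq_along(cfg_idx)) {
    config <- reg$configs[[cfg_idx[g]]]
    if (config$n_electrons == 0L) next
    ad <- solve_hfs(config, control = reg$control)
    f0[, g] <- form_factor_f0(ad, q_abs)
    for (m in seq_along(omega_nodes)) {
      a <- anomalous_terms(ad, omega_nodes[m], resonance_broadening_ev)
      an[g, m] <- complex(real = a$f1, imaginary = a$f2)
    }
  }
  list(f0 = f0, anomalous = an)
}

#' Instantaneous cluster form factor F_c(q, t)
#'
#' Exact coherent sum of complex atomic form factors over all nuclei/ions
#' (free electrons enter the cross section incoherently, not here).
#'
#' @param state a `cluster_state`.
#' @param q_nm_inv n x 3 matrix of momentum-transfer vectors (nm^-1), or a
#'   length-3 vector.
#' @param omega_ev photon energy (eV).
#' @param control an [hfs_control()] for the atomic data.
#' @return complex vector of amplitudes, one per q vector.
#' @export
instantaneous_form_factor <- function(state, q_nm_inv, omega_ev,
                                      control = hfs_control()) {
  if (is.null(dim(q_nm_inv))) q_nm_inv <- matrix(q_nm_inv, 1)
  keys <- vapply(state$atoms$config, config_key, character(1))
  ukeys <- unique(keys)
  group <- match(keys, ukeys)
  pos <- as.matrix(state$atoms[, c("x_nm", "y_nm", "z_nm")])
  S <- cpp_phase_sum(pos, group, length(ukeys), q_nm_inv)
  qa <- sqrt(rowSums(q_nm_inv^2))
  out <- complex(real = rep(0, nrow(q_nm_inv)))
  for (g in seq_along(ukeys)) {
    cf <- state$atoms$config[[match(ukeys[g], keys)]]
    if (cf$n_electrons == 0L) next
    ad <- solve_hfs(cf, control = control)
    fq <- form_factor_f0(ad, qa)
    an <- anomalous_terms(ad, omega_ev)
    out <- out + (fq + complex(real = an$f1, imaginary = an$f2)) * S[, g]
  }
  out
}

#' @keywords internal
scattering_theta_grid <- function(lambda_nm, n_theta, q_max_nm_inv = NULL) {
  q_phys <- 4 * pi / lambda_nm
  theta_max <- pi
  if (!is.null(q_max_nm_inv)) {
    if (q_max_nm_inv > q_phys + 1e-9) {
      stop("requested aperture q_max = ", q_max_nm_inv,
           " nm^-1 exceeds the physical maximum 4 pi / lambda = ",
           signif(q_phys, 4), " nm^-1 at this wavelength")
    }
    theta_max <- 2 * asin(min(1, q_max_nm_inv * lambda_nm / (4 * pi)))
  }
  dth <- theta_max / n_theta
  theta <- (seq_len(n_theta) - 0.5) * dth
  list(theta = theta, dtheta = dth,
       q = (4 * pi / lambda_nm) * sin(theta / 2))
}

#' Damage-inclusive dynamic scattering cross section
#'
#' Double quadrature of the instantaneous patterns over the pulse
#' (snapshot weights j_X(t)) and the Gaussian bandwidth (Gauss-Hermite
#' nodes), normalised per incident photon. Orientation structure is
#' sampled with a fixed Fibonacci direction set; the bandwidth enters
#' through the anomalous form factors (the sub-percent geometric spread of
#' the momentum-transfer mapping across the bandwidth is neglected).
#'
#' @param trajectory a `cluster_trajectory` from [simulate_cluster()].
#' @param n_theta polar quadrature points over the aperture.
#' @param n_dir orientation-sampling directions.
#' @param n_bandwidth_nodes Gauss-Hermite nodes over the bandwidth.
#' @param q_max_nm_inv aperture limit (default: full sphere).
#' @param snapshot_stride use every k-th stored snapshot.
#' @return object of class `cross_section_result`: `sigma_barn`, the
#'   radial `pattern` tibble, and quadrature metadata.
#' @export
dynamic_cross_section <- function(trajectory, n_theta = 32, n_dir = 12,
                                  n_bandwidth_nodes = 5,
                                  q_max_nm_inv = NULL,
                                  snapshot_stride = 1) {
  pulse <- trajectory$pulse
  reg <- trajectory$registry
  lam <- xray_wavelength_nm(pulse$photon_energy_ev)
  gr <- scattering_theta_grid(lam, n_theta, q_max_nm_inv)
  dirs <- fibonacci_directions(n_dir)
  qmat <- do.call(rbind, lapply(seq_along(gr$q), function(i) dirs * gr$q[i]))
  nodes <- bandwidth_nodes(pulse, n_bandwidth_nodes)

  snaps <- trajectory$snapshots[seq(1, length(trajectory$snapshots),
                                    by = snapshot_stride)]
  all_cfg <- sort(unique(unlist(lapply(snaps, function(s) unique(s$cfg)))))
  ffm <- .config_ff_matrix(reg, all_cfg, gr$q, nodes$omega_ev,
                           pulse$bandwidth_fwhm_ev)

  acc <- matrix(0, n_theta, n_bandwidth_nodes)  # <|F|^2> accumulators
  acc_ne <- 0
  wsum <- 0
  for (s in snaps) {
    w <- pulse_flux(pulse, s$t_fs)
    if (w <= 0) next
    gidx <- match(s$cfg, all_cfg)
    S <- cpp_phase_sum(s$pos_nm, gidx, length(all_cfg), qmat)
    for (m in seq_len(n_bandwidth_nodes)) {
      fg <- ffm$f0 + matrix(ffm$anomalous[, m], n_theta,
                            length(all_cfg), byrow = TRUE)
      # S rows are theta-major blocks of n_dir directions
      frow <- fg[rep(seq_len(n_theta), each = n_dir), , drop = FALSE]
      Fv <- rowSums(frow * S)
      I_dir <- Mod(Fv)^2
      I_theta <- colMeans(matrix(I_dir, n_dir, n_theta))
      acc[, m] <- acc[, m] + w * I_theta
    }
    acc_ne <- acc_ne + w * s$n_e
    wsum <- wsum + w
  }
  if (wsum <= 0) stop("pulse carries no fluence inside the window")
  mean_F2 <- as.vector((acc %*% nodes$weight) / wsum)
  mean_ne <- acc_ne / wsum
  dsdo <- .thomson_dsdo_barn(gr$theta) * (mean_F2 + mean_ne)
  sigma <- sum(dsdo * 2 * pi * sin(gr$theta) * gr$dtheta)
  structure(list(
    sigma_barn = sigma,
    pattern = tibble::tibble(theta = gr$theta, q_nm_inv = gr$q,
                             mean_F2 = mean_F2,
                             dsdo_barn_sr = dsdo),
    mean_ne = mean_ne, damaged = TRUE,
    pulse = pulse, n_snapshots = length(snaps)),
    class = "cross_section_result")
}

#' Undamaged reference scattering cross section
#'
#' Static evaluation for the ground-state cluster (exact orientation
#' average through the Debye formula), bandwidth-averaged.
#'
#' @param cluster a `cluster_state` (ground-state configurations).
#' @param pulse a [pulse_spec()].
#' @inheritParams dynamic_cross_section
#' @param control an [hfs_control()].
#' @return a `cross_section_result` with `sigma_barn`.
#' @export
undamaged_cross_section <- function(cluster, pulse, n_theta = 32,
                                    n_bandwidth_nodes = 5,
                                    q_max_nm_inv = NULL,
                                    control = hfs_control(),
                                    method = c("debye", "directions"),
                                    n_dir = 12) {
  method <- match.arg(method)
  lam <- xray_wavelength_nm(pulse$photon_energy_ev)
  gr <- scattering_theta_grid(lam, n_theta, q_max_nm_inv)
  if (nrow(cluster$atoms) == 0) {
    return(structure(list(sigma_barn = 0,
                          pattern = tibble::tibble(), damaged = FALSE),
                     class = "cross_section_result"))
  }
  keys <- vapply(cluster$atoms$config, config_key, character(1))
  ukeys <- unique(keys)
  group <- match(keys, ukeys)
  pos <- as.matrix(cluster$atoms[, c("x_nm", "y_nm", "z_nm")])
  G <- length(ukeys)
  nodes <- bandwidth_nodes(pulse, n_bandwidth_nodes)
  fmat <- matrix(0 + 0i, G, n_bandwidth_nodes)
  f0 <- matrix(0, length(gr$q), G)
  for (g in seq_len(G)) {
    cf <- cluster$atoms$config[[match(ukeys[g], keys)]]
    if (cf$n_electrons == 0L) next
    ad <- solve_hfs(cf, control = control)
    f0[, g] <- form_factor_f0(ad, gr$q)
    for (m in seq_len(n_bandwidth_nodes)) {
      a <- anomalous_terms(ad, nodes$omega_ev[m], pulse$bandwidth_fwhm_ev)
      fmat[g, m] <- complex(real = a$f1, imaginary = a$f2)
    }
  }
  mean_F2 <- numeric(length(gr$q))
  if (method == "debye") {
    D <- cpp_debye(pos, group, G, gr$q)
    D <- array(D, dim = c(length(gr$q), G, G))
    for (m in seq_len(n_bandwidth_nodes)) {
      fg <- f0 + matrix(fmat[, m], length(gr$q), G, byrow = TRUE)
      for (g1 in seq_len(G)) {
        for (g2 in seq_len(G)) {
          mean_F2 <- mean_F2 + nodes$weight[m] *
            Re(fg[, g1] * Conj(fg[, g2])) * D[, g1, g2]
        }
      }
    }
  } else {
    dirs <- fibonacci_directions(n_dir)
    qmat <- do.call(rbind,
                    lapply(seq_along(gr$q), function(i) dirs * gr$q[i]))
    S <- cpp_phase_sum(pos, group, G, qmat)
    for (m in seq_len(n_bandwidth_nodes)) {
      fg <- f0 + matrix(fmat[, m], length(gr$q), G, byrow = TRUE)
      frow <- fg[rep(seq_len(n_theta), each = n_dir), , drop = FALSE]
      Fv <- rowSums(frow * S)
      I_theta <- colMeans(matrix(Mod(Fv)^2, n_dir, n_theta))
      mean_F2 <- mean_F2 + nodes$weight[m] * I_theta
    }
  }
  dsdo <- .thomson_dsdo_barn(gr$theta) * mean_F2
  sigma <- sum(dsdo * 2 * pi * sin(gr$theta) * gr$dtheta)
  structure(list(
    sigma_barn = sigma,
    pattern = tibble::tibble(theta = gr$theta, q_nm_inv = gr$q,
                             mean_F2 = mean_F2, dsdo_barn_sr = dsdo),
    mean_ne = 0, damaged = FALSE, pulse = pulse),
    class = "cross_section_result")
}

#' @export
print.cross_section_result <- function(x, ...) {
  cat(sprintf("<%s scattering cross section: %.4g barn>\n",
              if (isTRUE(x$damaged)) "damaged" else "undamaged",
              x$sigma_barn))
  invisible(x)
}

#' Theoretical dynamic scattering efficiency
#'
#' DSE = sigma_dam / sigma_nodam, the ratio of the damage-inclusive to the
#' undamaged scattering cross section.
#'
#' @param sigma_dam damaged cross section (barn), or a
#'   `cross_section_result`.
#' @param sigma_nodam undamaged cross section (> 0), or a
#'   `cross_section_result`.
#' @return dimensionless DSE.
#' @export
dse_theory <- function(sigma_dam, sigma_nodam) {
  if (inherits(sigma_dam, "cross_section_result")) {
    sigma_dam <- sigma_dam$sigma_barn
  }
  if (inherits(sigma_nodam, "cross_section_result")) {
    sigma_nodam <- sigma_nodam$sigma_barn
  }
  stopifnot(sigma_dam >= 0)
  if (!is.finite(sigma_nodam) || sigma_nodam <= 0) {
    stop("undamaged cross section must be positive")
  }
  sigma_dam / sigma_nodam
}

#' End-to-end theoretical DSE for a cluster and pulse
#'
#' Runs the MC/MD dynamics, evaluates the damaged and undamaged cross
#' sections with matched quadrature, and returns their ratio.
#'
#' @inheritParams simulate_cluster
#' @inheritParams dynamic_cross_section
#' @return list with `dse`, `sigma_dam_barn`, `sigma_nodam_barn`,
#'   `trajectory`.
#' @export
theoretical_dse <- function(cluster, pulse, seed = 1,
                            control = dynamics_control(),
                            registry = NULL, hfs = hfs_control(),
                            n_theta = 32, n_dir = 12,
                            n_bandwidth_nodes = 5,
                            q_max_nm_inv = NULL, snapshot_stride = 1) {
  traj <- simulate_cluster(cluster, pulse, seed = seed, control = control,
                           registry = registry, hfs = hfs)
  dam <- dynamic_cross_section(traj, n_theta = n_theta, n_dir = n_dir,
                               n_bandwidth_nodes = n_bandwidth_nodes,
                               q_max_nm_inv = q_max_nm_inv,
                               snapshot_stride = snapshot_stride)
  nodam <- undamaged_cross_section(
    cluster, pulse, n_theta = n_theta,
    n_bandwidth_nodes = n_bandwidth_nodes, q_max_nm_inv = q_max_nm_inv,
    control = if (is.null(registry)) hfs else registry$control,
    method = "directions", n_dir = n_dir)
  list(dse = dse_theory(dam, nodam),
       sigma_dam_barn = dam$sigma_barn,
       sigma_nodam_barn = nodam$sigma_barn,
       damaged = dam, undamaged = nodam,
       trajectory = traj)
}
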