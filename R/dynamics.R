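## Coupled MC/MD cluster dynamics: R driver around the compiled engine.

#' Control parameters for the cluster dynamics
#'
#' @param dt_fs MD/MC time step (default 0.01 fs = 10 as).
#' @param snapshot_every_fs cadence at which cluster snapshots are stored
#'   for the scattering integrals (default 0.5 fs).
#' @param softening_nm Coulomb softening length (default 0.05 nm),
#'   chosen so a 10-as step resolves the closest classical electron-ion
#'   encounters (the classical energy audit quantifies the heating that
#'   under-resolved flybys would otherwise inject; smaller values are
#'   configurable).
#' @param interaction_radius_factor electrons beyond this multiple of the
#'   initial cluster radius (minimum 2 nm) with positive total energy
#'   count as escaped (default 3).
#' @param capture_radius_nm recombination capture radius (default 0.02 nm).
#' @param ei,rc enable electron-impact ionization / recombination.
#' @param motion propagate nuclei and electrons (disable for frozen-nuclei
#'   checks).
#' @param damage enable the Monte-Carlo electronic transitions (disable
#'   for the undamaged reference).
#' @return list of class `dynamics_control`.
#' @export
dynamics_control <- function(dt_fs = 0.01, snapshot_every_fs = 0.5,
                             softening_nm = 0.05,
                             interaction_radius_factor = 3,
                             capture_radius_nm = 0.02,
                             ei = TRUE, rc = TRUE,
                             motion = TRUE, damage = TRUE) {
  stopifnot(dt_fs > 0, snapshot_every_fs >= dt_fs)
  structure(list(dt_fs = dt_fs, snapshot_every_fs = snapshot_every_fs,
                 softening_nm = softening_nm,
                 interaction_radius_factor = interaction_radius_factor,
                 capture_radius_nm = capture_radius_nm,
                 ei = ei, rc = rc, motion = motion, damage = damage),
            class = "dynamics_control")
}

# flatten the registry into the matrix tables the engine consumes
#' @keywords internal
reg_tables <- function(reg) {
  n <- length(reg$keys)
  NPH <- 5L; NRES <- 8L; NSUB <- 5L
  ready <- logical(n)
  charge <- vapply(reg$configs, function(cf) cf$charge, numeric(1))
  nbound <- vapply(reg$configs, function(cf) cf$n_electrons, numeric(1))
  photo_sig <- matrix(0, n, NPH); photo_ke <- matrix(0, n, NPH)
  photo_tgt <- matrix(0L, n, NPH)
  res_sig <- matrix(0, n, NRES); res_tgt <- matrix(0L, n, NRES)
  aug_rate <- numeric(n); aug_ke <- numeric(n); aug_tgt <- integer(n)
  fl_rate <- numeric(n); fl_tgt <- integer(n)
  ei_tgt <- integer(n); ei_bind <- numeric(n)
  bind_ev <- matrix(0, n, NSUB); occm <- matrix(0L, n, NSUB)
  rc_tgt <- integer(n)
  for (i in seq_len(n)) {
    row <- reg$rows[[i]]
    if (is.null(row)) next
    ready[i] <- TRUE
    if (!is.null(row$photo) && nrow(row$photo) > 0) {
      k <- seq_len(min(nrow(row$photo), NPH))
      photo_sig[i, k] <- row$photo$sigma_nm2[k]
      photo_ke[i, k] <- row$photo$ke_ev[k]
      photo_tgt[i, k] <- row$photo$target[k]
    }
    if (!is.null(row$res) && nrow(row$res) > 0) {
      k <- seq_len(min(nrow(row$res), NRES))
      res_sig[i, k] <- row$res$sigma_nm2[k]
      res_tgt[i, k] <- row$res$target[k]
    }
    if (!is.null(row$auger)) {
      aug_rate[i] <- row$auger$rate_per_fs
      aug_ke[i] <- row$auger$ke_ev
      aug_tgt[i] <- row$auger$target
      fy <- reg$control$fluorescence_yield
      if (fy > 0) {
        # fluorescence: core hole filled radiatively, no electron out
        fl_rate[i] <- fy * row$auger$rate_per_fs
        fl_tgt[i] <- row$auger$target
      }
    }
    ns <- length(row$bind_ev)
    bind_ev[i, seq_len(ns)] <- ifelse(is.finite(row$bind_ev), row$bind_ev, 0)
    occm[i, seq_len(ns)] <- row$occ
    if (!is.null(row$ei_target) && !is.na(row$ei_target)) {
      ei_tgt[i] <- row$ei_target
      ei_bind[i] <- row$ei_bind_ev
    }
    if (!is.na(row$rc_target)) rc_tgt[i] <- row$rc_target
  }
  list(ready = ready, charge = as.integer(round(charge)),
       nbound = nbound,
       photo_sig = photo_sig, photo_ke = photo_ke, photo_tgt = photo_tgt,
       res_sig = res_sig, res_tgt = res_tgt,
       aug_rate = aug_rate, aug_ke = aug_ke, aug_tgt = aug_tgt,
       fl_rate = fl_rate, fl_tgt = fl_tgt,
       ei_tgt = ei_tgt, ei_bind = ei_bind,
       bind_ev = bind_ev, occ = occm, rc_tgt = rc_tgt)
}

#' Simulate the full MC/MD dynamics of a cluster in an XFEL pulse
#'
#' Propagates all nuclei/ions and delocalized electrons classically in
#' 10-as steps while sampling the six electronic transition channels
#' against the instantaneous pulse intensity, over the window
#' +/- `window_fwhm` x FWHM around the pulse centre. Snapshots of
#' positions and configurations are stored every
#' `control$snapshot_every_fs` for the scattering integrals.
#' Deterministic for a fixed seed, step size and snapshot cadence.
#'
#' @param cluster a `cluster_state` (t = 0, typically from
#'   [build_cluster()]).
#' @param pulse a [pulse_spec()].
#' @param seed RNG seed.
#' @param control a [dynamics_control()].
#' @param registry optional prebuilt [config_registry()] (shared across
#'   runs at the same photon energy to reuse atomic data).
#' @param hfs an [hfs_control()] used when `registry` is NULL.
#' @return object of class `cluster_trajectory`: snapshot list (times,
#'   positions, per-atom configuration indices, delocalized/escaped
#'   counts), event log, registry, and an energy audit.
#' @export
simulate_cluster <- function(cluster, pulse, seed = 1,
                             control = dynamics_control(),
                             registry = NULL, hfs = hfs_control()) {
  reg <- if (is.null(registry)) {
    config_registry(pulse$photon_energy_ev, pulse$bandwidth_fwhm_ev, hfs)
  } else registry
  atoms <- cluster$atoms
  N <- nrow(atoms)
  cfg <- integer(N)
  for (i in seq_len(N)) cfg[i] <- reg_index(reg, atoms$config[[i]])
  for (ci in unique(cfg)) reg_build(reg, ci)

  b <- dynscat_constants$bohr_nm
  apos <- as.matrix(atoms[, c("x_nm", "y_nm", "z_nm")]) / b
  avel <- as.matrix(atoms[, c("vx", "vy", "vz")]) / b / dynscat_constants$fs_au
  amass <- vapply(atoms$element,
                  function(e) element_info(e)$mass_amu, numeric(1)) *
    dynscat_constants$amu_au
  epos <- as.matrix(cluster$electrons[, c("x_nm", "y_nm", "z_nm")]) / b
  evel <- as.matrix(cluster$electrons[, c("vx", "vy", "vz")]) / b /
    dynscat_constants$fs_au
  if (nrow(epos) == 0) { epos <- matrix(0, 0, 3); evel <- matrix(0, 0, 3) }

  r0 <- max(sqrt(rowSums(apos^2)))
  r_int <- max(control$interaction_radius_factor * r0, 2 / b)
  cpp_ctrl <- list(soft2 = (control$softening_nm / b)^2,
                   r_int = r_int,
                   r_cap = control$capture_radius_nm / b,
                   ei = control$ei, rc = control$rc,
                   motion = control$motion, damage = control$damage,
                   snap_every = fs_to_au(control$snapshot_every_fs))
  pl <- list(fluence_photons_nm2 = pulse$fluence_photons_nm2,
             fwhm_fs = pulse$fwhm_fs)

  t0 <- -pulse$window_fwhm * pulse$fwhm_fs
  t_end <- fs_to_au(-t0)
  t_now <- fs_to_au(t0)
  next_snap <- t_now
  escaped <- cluster$escaped
  injected <- 0; removed <- 0
  last_ei <- rep(-1L, nrow(epos))

  set.seed(seed)
  snaps <- list()
  ev <- list()
  e0 <- cpp_state_energy(apos, avel, amass,
                         as.integer(reg_tables(reg)$charge[cfg]),
                         epos, evel, cpp_ctrl$soft2)
  repeat {
    tabs <- reg_tables(reg)
    res <- cpp_run_dynamics(apos, avel, amass, cfg, epos, evel,
                            t_now, t_end, fs_to_au(control$dt_fs),
                            tabs, pl, cpp_ctrl, escaped, injected,
                            removed, next_snap, last_ei)
    apos <- res$apos; avel <- res$avel; cfg <- res$acfg
    epos <- res$epos; evel <- res$evel
    last_ei <- res$last_ei
    t_now <- res$t_now; next_snap <- res$next_snap
    escaped <- res$escaped
    injected <- res$injected; removed <- res$removed
    if (length(res$snap_t) > 0) snaps[[length(snaps) + 1]] <- res
    if (length(res$ev_t) > 0) ev[[length(ev) + 1]] <- res
    if (res$status == 0) break
    for (ci in unique(res$need)) reg_build(reg, ci)
  }
  e1 <- cpp_state_energy(apos, avel, amass,
                         as.integer(reg_tables(reg)$charge[cfg]),
                         epos, evel, cpp_ctrl$soft2)

  # unpack snapshots
  snapshots <- list()
  for (blk in snaps) {
    ns <- length(blk$snap_t)
    for (k in seq_len(ns)) {
      idx <- ((k - 1) * N + 1):(k * N)
      snapshots[[length(snapshots) + 1]] <- list(
        t_fs = blk$snap_t[k],
        pos_nm = blk$snap_pos[idx, , drop = FALSE] * b,
        cfg = blk$snap_cfg[idx],
        n_e = blk$snap_ne[k],
        escaped = blk$snap_esc[k])
    }
  }
  events <- if (length(ev)) {
    dplyr::bind_rows(lapply(ev, function(blk) {
      tibble::tibble(t_fs = blk$ev_t, atom = blk$ev_atom,
                     channel = c("P", "A", "F", "RE", "EI", "RC",
                                 "ESC")[blk$ev_type],
                     from = ifelse(blk$ev_from > 0,
                                   reg$keys[pmax(blk$ev_from, 1)], NA),
                     to = ifelse(blk$ev_to > 0,
                                 reg$keys[pmax(blk$ev_to, 1)], NA))
    }))
  } else {
    tibble::tibble(t_fs = numeric(), atom = integer(),
                   channel = character(), from = character(),
                   to = character())
  }

  final <- cluster
  final$atoms$x_nm <- apos[, 1] * b
  final$atoms$y_nm <- apos[, 2] * b
  final$atoms$z_nm <- apos[, 3] * b
  final$atoms$vx <- avel[, 1] * b * dynscat_constants$fs_au
  final$atoms$vy <- avel[, 2] * b * dynscat_constants$fs_au
  final$atoms$vz <- avel[, 3] * b * dynscat_constants$fs_au
  final$atoms$config <- lapply(cfg, function(i) reg$configs[[i]])
  final$atoms$charge <- vapply(final$atoms$config, function(cf) cf$charge,
                               numeric(1))
  final$electrons <- tibble::tibble(
    x_nm = epos[, 1] * b, y_nm = epos[, 2] * b, z_nm = epos[, 3] * b,
    vx = evel[, 1] * b * dynscat_constants$fs_au,
    vy = evel[, 2] * b * dynscat_constants$fs_au,
    vz = evel[, 3] * b * dynscat_constants$fs_au)
  final$escaped <- escaped
  final$time_fs <- au_to_fs(t_now)

  structure(list(snapshots = snapshots, events = events,
                 final = final, cluster = cluster, pulse = pulse,
                 registry = reg, control = control,
                 interaction_radius_nm = r_int * b,
                 audit = list(E0 = e0$total, E1 = e1$total,
                              injected = injected, removed = removed)),
            class = "cluster_trajectory")
}

#' @export
print.cluster_trajectory <- function(x, ...) {
  cat(sprintf(
    "<cluster trajectory: %d snapshots over [%.1f, %.1f] fs, %d events, %d escaped e->\n",
    length(x$snapshots),
    if (length(x$snapshots)) x$snapshots[[1]]$t_fs else NA,
    if (length(x$snapshots)) x$snapshots[[length(x$snapshots)]]$t_fs else NA,
    nrow(x$events), x$final$escaped))
  invisible(x)
}

#' Propagate a cluster state by plain molecular dynamics
#'
#' Pure symplectic (velocity Verlet) propagation under softened pairwise
#' Coulomb forces, with all electronic transition channels disabled: the
#' MD reduces to classical Coulomb dynamics.
#'
#' @param state a `cluster_state`.
#' @param t_fs propagation time (fs).
#' @param dt_fs step size (default 0.01 fs).
#' @param control a [dynamics_control()].
#' @return the propagated `cluster_state`.
#' @export
md_propagate <- function(state, t_fs, dt_fs = 0.01,
                         control = dynamics_control(dt_fs = dt_fs,
                                                    damage = FALSE,
                                                    ei = FALSE, rc = FALSE)) {
  control$damage <- FALSE; control$ei <- FALSE; control$rc <- FALSE
  control$dt_fs <- dt_fs
  # run through simulate_cluster with a zero-fluence pulse over [0, t_fs]
  pulse <- pulse_spec(500, t_fs / 2.8, 0)   # fluence 0: window = t span
  pulse$window_fwhm <- 1.4
  reg <- config_registry(500, 5, hfs_control())
  # huge interaction radius: no escapes during plain MD
  control$interaction_radius_factor <- 1e6
  traj <- simulate_cluster(state, pulse, seed = 1, control = control,
                           registry = reg)
  out <- traj$final
  out$time_fs <- state$time_fs + t_fs
  out
}

#' Delocalization census of a cluster state
#'
#' Classifies each tracked electron as delocalized (inside the
#' interaction radius, or outside but still bound in the cluster monopole
#' field) or escaped, and reports the sphere-equivalent diameter of the
#' nuclei.
#'
#' @param state a `cluster_state`.
#' @param interaction_radius_nm boundary of the interaction region
#'   (default 3 x the current nuclear extent, minimum 2 nm).
#' @return tibble with `n_delocalized`, `escaped`, `diameter_nm`,
#'   `bound_electrons` and `total_charge`.
#' @export
delocalization_census <- function(state, interaction_radius_nm = NULL) {
  a <- state$atoms
  e <- state$electrons
  if (is.null(interaction_radius_nm)) {
    r0 <- max(sqrt(a$x_nm^2 + a$y_nm^2 + a$z_nm^2), 0.1)
    interaction_radius_nm <- max(3 * max(r0), 2)
  }
  esc_extra <- 0L
  n_in <- 0L
  if (nrow(e) > 0) {
    qtot <- sum(a$charge) - nrow(e) + 1
    r <- sqrt(e$x_nm^2 + e$y_nm^2 + e$z_nm^2)
    ke_au <- 0.5 * ((e$vx^2 + e$vy^2 + e$vz^2) /
                      (dynscat_constants$bohr_nm *
                         dynscat_constants$fs_au)^2)
    pot_au <- ifelse(qtot > 0,
                     -qtot / (r / dynscat_constants$bohr_nm), 0)
    out <- r > interaction_radius_nm & (ke_au + pot_au) > 0
    esc_extra <- sum(out)
    n_in <- nrow(e) - esc_extra
  }
  tibble::tibble(
    n_delocalized = n_in,
    escaped = state$escaped + esc_extra,
    diameter_nm = cluster_diameter(state),
    bound_electrons = bound_electron_count(state),
    total_charge = sum(a$charge))
}

#' Per-snapshot census of a trajectory
#'
#' @param trajectory a `cluster_trajectory`.
#' @return tibble with one row per snapshot: time, delocalized and
#'   escaped electron counts, bound electrons, mean ion charge and
#'   sphere-equivalent diameter.
#' @export
trajectory_census <- function(trajectory) {
  reg <- trajectory$registry
  nb <- vapply(reg$configs, function(cf) cf$n_electrons, numeric(1))
  qq <- vapply(reg$configs, function(cf) cf$charge, numeric(1))
  purrr::map_dfr(trajectory$snapshots, function(s) {
    p <- s$pos_nm
    cx <- colMeans(p)
    rg2 <- mean((p[, 1] - cx[1])^2 + (p[, 2] - cx[2])^2 +
                  (p[, 3] - cx[3])^2)
    tibble::tibble(
      t_fs = s$t_fs,
      n_delocalized = s$n_e,
      escaped = s$escaped,
      bound_electrons = sum(nb[s$cfg]),
      mean_charge = mean(qq[s$cfg]),
      diameter_nm = 2 * sqrt(5 / 3) * sqrt(rg2))
  })
}
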