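## Monte-Carlo rate-equation machinery.
##
## Transitions between electronic configurations I -> J proceed through six
## channels: photoionization (P), Auger decay (A), fluorescence (F),
## resonant excitation (RE), electron-impact ionization (EI) and
## recombination (RC). Field-driven channels scale linearly with the
## instantaneous pulse intensity; Auger/fluorescence are field-free; EI/RC
## are mediated by the surrounding nanoplasma.
##
## A configuration registry memoises, per photon energy, the per-channel
## cross sections and target configurations so that both the isolated-atom
## sampler and the compiled cluster engine draw from the same tables.

.lotz_a_nm2_ev2 <- 4.5  # Lotz constant: 4.5e-14 cm^2 eV^2

#' Lotz electron-impact ionization cross section
#'
#' Classic Lotz formula over the HFS subshell binding energies:
#' sigma = a sum_i N_i ln(E/B_i)/(E B_i) for E > B_i.
#'
#' @param binding_ev vector of subshell binding energies (eV).
#' @param occupations vector of subshell occupations.
#' @param ke_ev projectile electron kinetic energy (eV).
#' @return cross section in nm^2.
#' @export
lotz_cross_section <- function(binding_ev, occupations, ke_ev) {
  ok <- is.finite(binding_ev) & binding_ev > 0 & occupations > 0 &
    ke_ev > binding_ev
  if (!any(ok)) return(0)
  sum(.lotz_a_nm2_ev2 * occupations[ok] * log(ke_ev / binding_ev[ok]) /
        (ke_ev * binding_ev[ok]))
}

#' Create a configuration registry for a photon energy
#'
#' @param omega_x_ev central photon energy (eV).
#' @param bandwidth_fwhm_ev Gaussian bandwidth FWHM (eV).
#' @param control an [hfs_control()].
#' @param resonance_window_sigmas resonant channels are retained when the
#'   line lies within this many bandwidth sigmas of the carrier.
#' @return a registry environment.
#' @export
config_registry <- function(omega_x_ev, bandwidth_fwhm_ev,
                            control = hfs_control(),
                            resonance_window_sigmas = 4) {
  reg <- new.env(parent = emptyenv())
  reg$omega_x_ev <- omega_x_ev
  reg$bandwidth_fwhm_ev <- bandwidth_fwhm_ev
  reg$control <- control
  reg$res_window <- resonance_window_sigmas
  reg$idx <- new.env(parent = emptyenv())  # key -> integer index
  reg$rows <- list()                       # index -> row (or NULL if only allocated)
  reg$keys <- character()
  reg$configs <- list()
  reg$rate_cache <- new.env(parent = emptyenv())
  reg
}

#' @keywords internal
reg_index <- function(reg, config) {
  key <- config_key(config)
  i <- reg$idx[[key]]
  if (!is.null(i)) return(i)
  i <- length(reg$keys) + 1L
  reg$idx[[key]] <- i
  reg$keys[i] <- key
  reg$configs[[i]] <- config
  reg$rows[i] <- list(NULL)
  i
}

#' @keywords internal
reg_build <- function(reg, i) {
  if (!is.null(reg$rows[[i]])) return(reg$rows[[i]])
  config <- reg$configs[[i]]
  ctl <- reg$control
  nsub <- element_info(config$element)$n_subshells
  caps <- .subshell_cap[seq_len(nsub)]
  occ <- config$occupations

  if (config$n_electrons == 0L) {
    row <- list(key = reg$keys[i], nbound = 0L, charge = config$charge,
                photo = NULL, res = NULL, auger = NULL,
                bind_ev = rep(NA_real_, nsub), occ = occ,
                rc_target = NA_integer_)
    reg$rows[[i]] <- row
    return(row)
  }
  ad <- solve_hfs(config, control = ctl)

  # photoionization channels, one per occupied subshell above threshold
  photo <- NULL
  for (s in seq_len(nsub)) {
    if (occ[s] == 0L) next
    B <- ionization_threshold_ev(ad, s)
    if (!is.finite(B) || reg$omega_x_ev <= B) next
    sig <- photoionization_cs(ad, .subshell_names[s], reg$omega_x_ev)
    if (sig <= 0) next
    occ_f <- occ; occ_f[s] <- occ_f[s] - 1L
    tgt <- reg_index(reg, electronic_configuration(config$element, occ_f))
    photo <- rbind(photo, data.frame(
      subshell = s, sigma_nm2 = sig * 1e-10,   # barn -> nm^2
      ke_ev = reg$omega_x_ev - B, target = tgt))
  }

  # resonant excitation channels within the bandwidth window
  res <- NULL
  tr <- ad$transitions
  if (!is.null(tr) && nrow(tr) > 0) {
    sg <- reg$bandwidth_fwhm_ev / (2 * sqrt(2 * log(2)))
    keep <- abs(tr$omega_ev - reg$omega_x_ev) < reg$res_window * sg
    for (k in which(keep)) {
      sig <- resonant_cs(ad, tr$from[k], tr$to[k], reg$omega_x_ev,
                         reg$bandwidth_fwhm_ev)
      if (sig < 1) next   # < 1 barn: negligible
      occ_f <- occ
      vi <- match(tr$from[k], .subshell_names)
      ui <- match(tr$to[k], .subshell_names)
      occ_f[vi] <- occ_f[vi] - 1L; occ_f[ui] <- occ_f[ui] + 1L
      tgt <- reg_index(reg, electronic_configuration(config$element, occ_f))
      res <- rbind(res, data.frame(
        from = tr$from[k], to = tr$to[k],
        sigma_nm2 = sig * 1e-10, target = tgt))
    }
    if (!is.null(res) && nrow(res) > 8) {
      res <- res[order(-res$sigma_nm2)[1:8], ]
    }
  }

  auger <- NULL
  if (!is.null(ad$auger)) {
    tgt <- reg_index(reg, ad$auger$final)
    auger <- list(rate_per_fs = ad$auger$rate_per_fs,
                  ke_ev = ad$auger$electron_ke_ev, target = tgt)
  }

  vac <- which(occ < caps)
  rc_target <- NA_integer_
  if (length(vac) > 0 && config$charge > 0L) {
    d <- max(vac)   # outermost subshell with a vacancy
    occ_f <- occ; occ_f[d] <- occ_f[d] + 1L
    rc_target <- reg_index(reg, electronic_configuration(config$element, occ_f))
  }

  # EI removal from the outermost occupied subshell
  ei_target <- NA_integer_
  occd <- which(occ > 0L)
  if (length(occd) > 0) {
    t <- max(occd)
    occ_f <- occ; occ_f[t] <- occ_f[t] - 1L
    ei_target <- reg_index(reg, electronic_configuration(config$element, occ_f))
  }

  row <- list(key = reg$keys[i], nbound = config$n_electrons,
              charge = config$charge,
              photo = photo, res = res, auger = auger,
              bind_ev = ad$energies_ev[seq_len(nsub)], occ = occ,
              rc_target = rc_target, ei_target = ei_target,
              ei_bind_ev = if (length(occd) > 0) ad$energies_ev[max(occd)] else NA_real_)
  reg$rows[[i]] <- row
  row
}

#' Channel-resolved transition rate table for a configuration
#'
#' Rates out of configuration I at time `t_fs` of the pulse, over the six
#' channels. Photoionization and resonant excitation scale linearly with
#' the instantaneous intensity; Auger decay and fluorescence are
#' field-free; impact ionization and recombination come from the supplied
#' local plasma environment (zero for isolated atoms). Tables are memoised
#' per (configuration, intensity bin), 64 logarithmic bins per decade.
#'
#' @param configuration an `electronic_configuration`.
#' @param pulse a [pulse_spec()].
#' @param t_fs time relative to pulse centre (fs).
#' @param local_environment list with `electron_density_nm3` and
#'   `electron_ke_ev` describing the surrounding nanoplasma (defaults 0).
#' @param registry optionally, a prebuilt [config_registry()].
#' @return tibble with `channel`, `target` (configuration key),
#'   `rate_per_fs`, plus attribute `total_rate_per_fs`.
#' @export
build_rate_table <- function(configuration, pulse, t_fs = 0,
                             local_environment = list(
                               electron_density_nm3 = 0,
                               electron_ke_ev = 0),
                             registry = NULL) {
  if (is.null(registry)) {
    registry <- config_registry(pulse$photon_energy_ev,
                                pulse$bandwidth_fwhm_ev)
  }
  reg <- registry
  i <- reg_index(reg, configuration)
  flux <- pulse_flux(pulse, t_fs)   # photons / nm^2 / fs

  ne <- local_environment$electron_density_nm3
  kee <- local_environment$electron_ke_ev
  cache_ok <- (is.null(ne) || ne == 0)
  bin <- if (flux > 0) round(64 * log10(flux)) else -Inf
  ckey <- paste0(reg$keys[i], "@", bin)
  if (cache_ok) {
    hit <- reg$rate_cache[[ckey]]
    if (!is.null(hit)) return(hit)
  }

  row <- reg_build(reg, i)
  out <- list()
  if (!is.null(row$photo)) {
    out[[length(out) + 1]] <- tibble::tibble(
      channel = "P", target = reg$keys[row$photo$target],
      rate_per_fs = row$photo$sigma_nm2 * flux)
  }
  if (!is.null(row$res)) {
    out[[length(out) + 1]] <- tibble::tibble(
      channel = "RE", target = reg$keys[row$res$target],
      rate_per_fs = row$res$sigma_nm2 * flux)
  }
  if (!is.null(row$auger)) {
    out[[length(out) + 1]] <- tibble::tibble(
      channel = "A", target = reg$keys[row$auger$target],
      rate_per_fs = row$auger$rate_per_fs)
    fy <- reg$control$fluorescence_yield
    if (fy > 0) {
      out[[length(out) + 1]] <- tibble::tibble(
        channel = "F", target = reg$keys[row$auger$target],
        rate_per_fs = fy * row$auger$rate_per_fs)
    }
  }
  if (!is.null(ne) && ne > 0 && !is.na(row$ei_target)) {
    sig <- lotz_cross_section(row$bind_ev, row$occ, kee)
    if (sig > 0) {
      v_nm_fs <- sqrt(2 * ev_to_au(kee)) *
        dynscat_constants$bohr_nm * dynscat_constants$fs_au
      out[[length(out) + 1]] <- tibble::tibble(
        channel = "EI", target = reg$keys[row$ei_target],
        rate_per_fs = ne * sig * v_nm_fs)
    }
  }
  tab <- if (length(out)) dplyr::bind_rows(out) else {
    tibble::tibble(channel = character(), target = character(),
                   rate_per_fs = numeric())
  }
  attr(tab, "total_rate_per_fs") <- sum(tab$rate_per_fs)
  if (cache_ok) reg$rate_cache[[ckey]] <- tab
  tab
}

#' Monte-Carlo evolution of isolated-atom configurations
#'
#' Per-step Bernoulli sampling of configuration transitions for an
#' ensemble of isolated atoms (no plasma environment, no nuclear motion):
#' the photoionization, resonant-excitation, Auger and fluorescence
#' channels of the full model, driven by the instantaneous pulse
#' intensity. Event times are reproducible bit-for-bit for a fixed seed.
#'
#' @param atoms character vector of element symbols, or a list of starting
#'   `electronic_configuration`s.
#' @param pulse a [pulse_spec()].
#' @param seed RNG seed.
#' @param dt_fs Monte-Carlo step (default 0.01 fs = 10 as).
#' @param t_range_fs simulation window (default +/- `window_fwhm` x FWHM).
#' @param registry optional prebuilt [config_registry()].
#' @param max_p_step error bound on per-step transition probability;
#'   exceeding it raises an error instructing a smaller step.
#' @return list with `final` (list of configurations), `events` tibble
#'   (`t_fs`, `atom`, `channel`, `from`, `to`) and `n_electrons_freed`.
#' @export
evolve_configurations <- function(atoms, pulse, seed = 1, dt_fs = 0.01,
                                  t_range_fs = NULL, registry = NULL,
                                  max_p_step = 0.1) {
  if (is.character(atoms)) {
    atoms <- lapply(atoms, ground_configuration)
  }
  if (is.null(registry)) {
    registry <- config_registry(pulse$photon_energy_ev,
                                pulse$bandwidth_fwhm_ev)
  }
  reg <- registry
  if (is.null(t_range_fs)) {
    t_range_fs <- c(-1, 1) * pulse$window_fwhm * pulse$fwhm_fs
  }
  set.seed(seed)
  n <- length(atoms)
  cfg <- vapply(atoms, function(cf) reg_index(reg, cf), integer(1))
  times <- seq(t_range_fs[1], t_range_fs[2], by = dt_fs)

  # per-configuration channel arrays, built once and memoised locally
  chans <- new.env(parent = emptyenv())
  get_chans <- function(ci) {
    key <- as.character(ci)
    hit <- chans[[key]]
    if (!is.null(hit)) return(hit)
    row <- reg_build(reg, ci)
    sig <- numeric(0); tgt_f <- integer(0); ch_f <- character(0)
    if (!is.null(row$photo)) {
      sig <- c(sig, row$photo$sigma_nm2); tgt_f <- c(tgt_f, row$photo$target)
      ch_f <- c(ch_f, rep("P", nrow(row$photo)))
    }
    if (!is.null(row$res)) {
      sig <- c(sig, row$res$sigma_nm2); tgt_f <- c(tgt_f, row$res$target)
      ch_f <- c(ch_f, rep("RE", nrow(row$res)))
    }
    const <- numeric(0); tgt_c <- integer(0); ch_c <- character(0)
    if (!is.null(row$auger)) {
      const <- c(const, row$auger$rate_per_fs)
      tgt_c <- c(tgt_c, row$auger$target); ch_c <- c(ch_c, "A")
      fy <- reg$control$fluorescence_yield
      if (fy > 0) {
        const <- c(const, fy * row$auger$rate_per_fs)
        tgt_c <- c(tgt_c, row$auger$target); ch_c <- c(ch_c, "F")
      }
    }
    val <- list(sig = sig, tgt = c(tgt_f, tgt_c), chan = c(ch_f, ch_c),
                const = const, nf = length(sig))
    chans[[key]] <- val
    val
  }

  ev_t <- numeric(0); ev_a <- integer(0); ev_c <- character(0)
  ev_from <- integer(0); ev_to <- integer(0)
  freed <- 0L
  for (t in times) {
    flux <- pulse_flux(pulse, t)
    for (ci in unique(cfg)) {
      cc <- get_chans(ci)
      rates <- c(cc$sig * flux, cc$const)
      tot <- sum(rates)
      if (tot == 0) next
      p <- tot * dt_fs
      if (p > max_p_step) {
        stop("per-step transition probability ", signif(p, 3),
             " exceeds ", max_p_step,
             "; use a smaller dt_fs for this intensity")
      }
      members <- which(cfg == ci)
      hit <- members[stats::runif(length(members)) < p]
      for (a in hit) {
        k <- if (length(rates) == 1L) 1L else {
          sample.int(length(rates), 1, prob = rates)
        }
        ev_t <- c(ev_t, t); ev_a <- c(ev_a, a); ev_c <- c(ev_c, cc$chan[k])
        ev_from <- c(ev_from, ci); ev_to <- c(ev_to, cc$tgt[k])
        if (cc$chan[k] %in% c("P", "A")) freed <- freed + 1L
        cfg[a] <- cc$tgt[k]
      }
    }
  }
  events <- data.frame(t_fs = ev_t, atom = ev_a, channel = ev_c,
                       from = reg$keys[ev_from], to = reg$keys[ev_to],
                       stringsAsFactors = FALSE)
  list(final = lapply(cfg, function(i) reg$configs[[i]]),
       final_charge = vapply(cfg, function(i) reg$configs[[i]]$charge,
                             numeric(1)),
       events = tibble::as_tibble(events),
       n_electrons_freed = freed)
}

#' Focal-volume-averaged argon charge-state distribution
#'
#' Monte-Carlo rate-equation benchmark for the argon fluence calibration:
#' isolated Ar atoms are evolved at each fluence of the focal-volume
#' distribution and the final charge-state histograms are combined with
#' the focal weights.
#'
#' @param pulse a [pulse_spec()] at the calibration photon energy; its
#'   fluence is taken as the peak fluence F0.
#' @param focal tibble from [focal_fluence_distribution()] (or NULL for a
#'   flat, single-fluence profile).
#' @param n_atoms Monte-Carlo ensemble size per fluence bin.
#' @param seed RNG seed.
#' @param dt_fs Monte-Carlo step.
#' @return tibble with `charge` and `probability` (sums to 1).
#' @export
argon_benchmark <- function(pulse, focal = NULL, n_atoms = 50, seed = 1,
                            dt_fs = 0.01) {
  if (is.null(focal)) {
    focal <- tibble::tibble(fluence_uj_um2 = pulse$fluence_uj_um2,
                            weight = 1)
  }
  reg <- config_registry(pulse$photon_energy_ev, pulse$bandwidth_fwhm_ev)
  probs <- list()
  for (b in seq_len(nrow(focal))) {
    pb <- pulse_spec(pulse$photon_energy_ev, pulse$fwhm_fs,
                     focal$fluence_uj_um2[b],
                     pulse$bandwidth_fwhm_fraction, pulse$window_fwhm)
    run <- evolve_configurations(rep("Ar", n_atoms), pb,
                                 seed = seed + b, dt_fs = dt_fs,
                                 registry = reg)
    probs[[b]] <- tibble::tibble(charge = run$final_charge,
                                 weight = focal$weight[b] / n_atoms)
  }
  dplyr::bind_rows(probs) |>
    dplyr::group_by(charge = as.integer(charge)) |>
    dplyr::summarise(probability = sum(weight), .groups = "drop") |>
    dplyr::arrange(charge)
}
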