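## Photoionization and resonant-excitation cross sections from HFS data.
##
## Continuum waves are energy-normalised partial waves computed in the same
## self-consistent potential as the bound orbitals (frozen-potential,
## length-gauge dipole approximation).

#' @keywords internal
subshell_index <- function(ad, subshell) {
  k <- length(ad$eigen_au)
  idx <- match(subshell, .subshell_names[seq_len(k)])
  if (is.na(idx)) {
    stop("unknown subshell '", subshell, "' for ",
         ad$configuration$element, "; valid: ",
         paste(.subshell_names[seq_len(k)], collapse = ", "))
  }
  idx
}

# pick the amplitude-matching radius for the continuum wave: fine enough
# grid resolution (k * dr < 0.45) and outside the centrifugal barrier
.continuum_norm_index <- function(r, h, eps_au, l) {
  n <- length(r)
  k_inf <- sqrt(2 * max(eps_au, 1e-8))
  r_res <- 0.45 / (h * k_inf)
  r_norm <- min(r_res, r[n - 8])
  if (l > 0) {
    r_t <- sqrt(l * (l + 1) / (2 * max(eps_au, 1e-8)))
    if (r_norm < 3 * r_t + 1) r_norm <- min(3 * r_t + 1, r[n - 8])
  }
  max(20L, which.min(abs(r - r_norm)))
}

# radial dipole integral between bound orbital i and the energy-normalised
# continuum wave with angular momentum lp at photoelectron energy eps_au
.dipole_to_continuum <- function(ad, i, lp, eps_au) {
  Pc <- cpp_continuum_wave(ad$r, ad$potential, lp, eps_au,
                           .continuum_norm_index(ad$r, ad$h, eps_au, lp) - 1L)
  sum(Pc * ad$r * ad$orbitals[, i] * ad$r * ad$h)
}

#' @keywords internal
#' Ionization threshold of a subshell: relaxed (delta-SCF) difference of
#' total energies by default, orbital eigenvalue otherwise.
ionization_threshold_ev <- function(atomic_data, i) {
  ad <- atomic_data
  if (ad$control$transition_energy == "eigen") return(ad$energies_ev[i])
  occ <- ad$configuration$occupations
  if (occ[i] == 0L) return(NA_real_)
  occ_f <- occ; occ_f[i] <- occ_f[i] - 1L
  ion <- electronic_configuration(ad$configuration$element, occ_f)
  ad_f <- solve_hfs(ion, control = ad$control, with_transitions = FALSE)
  au_to_ev(ad_f$total_energy_au - ad$total_energy_au)
}

#' Photoionization cross section of a subshell
#'
#' Length-gauge dipole photoionization cross section of one subshell,
#' computed with energy-normalised continuum partial waves in the
#' self-consistent HFS potential:
#' \deqn{\sigma_{nl}(\omega) = \frac{4\pi^2\alpha}{3}\,\omega\,
#'   \frac{N_{nl}}{2l+1}\left[l\,R_{l-1}^2 + (l+1)\,R_{l+1}^2\right]}
#' It is exactly zero below the subshell binding energy.
#'
#' @param atomic_data an `atomic_data` object from [solve_hfs()].
#' @param subshell subshell name, e.g. `"2p"`.
#' @param omega_ev photon energy in eV (scalar or vector).
#' @return cross section in barn (1 Mbarn = 1e6 barn).
#' @export
photoionization_cs <- function(atomic_data, subshell, omega_ev) {
  ad <- atomic_data
  i <- subshell_index(ad, subshell)
  occ <- ad$configuration$occupations[i]
  if (occ == 0L) return(rep(0, length(omega_ev)))
  B <- ionization_threshold_ev(ad, i)
  l <- .subshell_l[i]
  vapply(omega_ev, function(om) {
    if (!is.finite(om) || om <= 0) stop("photon energy must be positive")
    if (om <= B) return(0)
    eps <- ev_to_au(om - B)
    s <- 0
    if (l > 0) s <- s + l * .dipole_to_continuum(ad, i, l - 1L, eps)^2
    s <- s + (l + 1) * .dipole_to_continuum(ad, i, l + 1L, eps)^2
    sig_au <- (4 * pi^2 * dynscat_constants$alpha / 3) * ev_to_au(om) *
      occ / (2 * l + 1) * s
    sig_au * dynscat_constants$au_area_barn
  }, numeric(1))
}

#' Total photoionization cross section summed over subshells
#'
#' @inheritParams photoionization_cs
#' @param subshells subshell names to include (default: all).
#' @return cross section in barn.
#' @export
total_photoionization_cs <- function(atomic_data, omega_ev,
                                     subshells = NULL) {
  k <- length(atomic_data$eigen_au)
  if (is.null(subshells)) subshells <- .subshell_names[seq_len(k)]
  m <- matrix(0, length(omega_ev), length(subshells))
  for (j in seq_along(subshells)) {
    m[, j] <- photoionization_cs(atomic_data, subshells[j], omega_ev)
  }
  rowSums(m)
}

#' @keywords internal
find_transition <- function(ad, from, to) {
  if (is.null(ad$transitions)) {
    stop("atomic data was built without transitions")
  }
  tr <- ad$transitions[ad$transitions$from == from & ad$transitions$to == to, ]
  if (nrow(tr) == 0) {
    i <- subshell_index(ad, to)
    if (ad$configuration$occupations[i] >= .subshell_cap[i]) {
      stop("transition ", from, " -> ", to, " targets a full subshell in ",
           format(ad$configuration))
    }
    stop("transition ", from, " -> ", to, " not available for ",
         format(ad$configuration))
  }
  tr[1, ]
}

#' Resonant bound-bound absorption cross section
#'
#' Cross section for resonant excitation v -> u at photon energy
#' `omega_x_ev`, for an XFEL pulse with a Gaussian bandwidth profile: the
#' natural Lorentzian line (width `gamma_vu`) is convolved with the
#' unit-normalised Gaussian bandwidth and evaluated at the carrier energy.
#' The frequency-integrated cross section is \eqn{2\pi^2\alpha f_{vu}}
#' (109.76 Mbarn eV per unit oscillator strength).
#'
#' @inheritParams photoionization_cs
#' @param from,to subshell names of the occupied lower and vacant upper
#'   level, e.g. `"1s"`, `"2p"`.
#' @param omega_x_ev central photon energy of the pulse, eV.
#' @param bandwidth_fwhm_ev FWHM of the Gaussian bandwidth in eV (e.g. a 1
#'   percent bandwidth at 530 eV is 5.3 eV).
#' @return cross section in barn.
#' @export
resonant_cs <- function(atomic_data, from = "1s", to = "2p",
                        omega_x_ev, bandwidth_fwhm_ev) {
  stopifnot(bandwidth_fwhm_ev > 0)
  tr <- find_transition(atomic_data, from, to)
  # integrated line cross section 2 pi^2 alpha [bohr^2 Ha] = 109.76e6 barn eV
  S_ev_barn <- 2 * pi^2 * dynscat_constants$alpha *
    dynscat_constants$au_area_barn * dynscat_constants$hartree_ev
  sg <- bandwidth_fwhm_ev / (2 * sqrt(2 * log(2)))
  gam <- tr$gamma_ev
  vapply(omega_x_ev, function(om) {
    delta <- om - tr$omega_ev
    voigt <- stats::integrate(function(w) {
      stats::dnorm(w, 0, sg) * stats::dcauchy(delta - w, 0, gam / 2)
    }, -Inf, Inf, rel.tol = 1e-8)$value
    S_ev_barn * tr$f_osc * voigt
  }, numeric(1))
}
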