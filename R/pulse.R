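## PulseSpec: Gaussian XFEL pulse in time (FWHM duration tau) and photon
## energy (Gaussian bandwidth profile g(omega, omega_x), unit-normalised).

#' Specify an XFEL pulse
#'
#' @param photon_energy_ev central photon energy omega_x (eV).
#' @param fwhm_fs FWHM pulse duration tau (fs).
#' @param fluence_uj_um2 fluence in uJ/um^2 (use
#'   [photons_nm2_to_fluence()] to convert from photon units).
#' @param bandwidth_fwhm_fraction Gaussian bandwidth FWHM as a fraction of
#'   the photon energy (default 0.01, i.e. 1 percent).
#' @param window_fwhm half-width of the simulation window in units of the
#'   FWHM duration (default 1.4: the window captures > 99.9 percent of the
#'   pulse fluence).
#' @return object of class `pulse_spec`.
#' @export
pulse_spec <- function(photon_energy_ev, fwhm_fs, fluence_uj_um2,
                       bandwidth_fwhm_fraction = 0.01,
                       window_fwhm = 1.4) {
  stopifnot(photon_energy_ev > 0, fwhm_fs > 0, fluence_uj_um2 >= 0,
            bandwidth_fwhm_fraction > 0)
  structure(list(
    photon_energy_ev = photon_energy_ev,
    fwhm_fs = fwhm_fs,
    fluence_uj_um2 = fluence_uj_um2,
    fluence_photons_nm2 = fluence_to_photons_nm2(fluence_uj_um2,
                                                 photon_energy_ev),
    bandwidth_fwhm_fraction = bandwidth_fwhm_fraction,
    bandwidth_fwhm_ev = bandwidth_fwhm_fraction * photon_energy_ev,
    window_fwhm = window_fwhm
  ), class = "pulse_spec")
}

#' @export
print.pulse_spec <- function(x, ...) {
  cat(sprintf(
    "<XFEL pulse: %.1f eV, %.1f fs FWHM, %.3g uJ/um^2 (%.3g ph/nm^2), %.2g%% bandwidth>\n",
    x$photon_energy_ev, x$fwhm_fs, x$fluence_uj_um2,
    x$fluence_photons_nm2, 100 * x$bandwidth_fwhm_fraction))
  invisible(x)
}

#' Instantaneous photon flux j_X(tau, t)
#'
#' Gaussian temporal profile normalised so that the time integral equals
#' the pulse fluence.
#'
#' @param pulse a [pulse_spec()].
#' @param t_fs time relative to the pulse centre (fs).
#' @return photons per nm^2 per fs.
#' @export
pulse_flux <- function(pulse, t_fs) {
  tau <- pulse$fwhm_fs
  pulse$fluence_photons_nm2 * (2 / tau) * sqrt(log(2) / pi) *
    exp(-4 * log(2) * t_fs^2 / tau^2)
}

#' Spectral bandwidth profile g(omega, omega_x)
#'
#' Unit-normalised Gaussian in photon energy.
#'
#' @inheritParams pulse_flux
#' @param omega_ev photon energy (eV).
#' @return density per eV; integrates to 1.
#' @export
pulse_bandwidth_profile <- function(pulse, omega_ev) {
  sg <- pulse$bandwidth_fwhm_ev / (2 * sqrt(2 * log(2)))
  stats::dnorm(omega_ev, pulse$photon_energy_ev, sg)
}

#' Gauss-Hermite quadrature nodes over the pulse bandwidth
#'
#' Nodes and weights for integrals of the form
#' int g(omega, omega_x) F(omega) d omega; weights sum to 1.
#'
#' @inheritParams pulse_flux
#' @param n number of nodes (default 7).
#' @return tibble with `omega_ev` and `weight`.
#' @export
bandwidth_nodes <- function(pulse, n = 7) {
  gh <- .gauss_hermite(n)
  sg <- pulse$bandwidth_fwhm_ev / (2 * sqrt(2 * log(2)))
  tibble::tibble(omega_ev = pulse$photon_energy_ev + sqrt(2) * sg * gh$x,
                 weight = gh$w / sqrt(pi))
}

# Gauss-Hermite nodes/weights via the Golub-Welsch eigenvalue method
.gauss_hermite <- function(n) {
  if (n == 1) return(list(x = 0, w = sqrt(pi)))
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  J <- diag(0, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- sqrt(pi) * e$vectors[1, ]^2
  ord <- order(x)
  list(x = x[ord], w = w[ord])
}

#' Peak electric field of the pulse
#'
#' Peak field of the Gaussian envelope, from the peak intensity
#' I_peak = F * 2 sqrt(ln 2 / pi) / tau.
#'
#' @inheritParams pulse_flux
#' @return field amplitude in atomic units.
#' @export
pulse_peak_field_au <- function(pulse) {
  fl_j_cm2 <- pulse$fluence_uj_um2 * 1e-6 / 1e-8   # J/cm^2
  ipk_w_cm2 <- fl_j_cm2 * 2 * sqrt(log(2) / pi) / (pulse$fwhm_fs * 1e-15)
  sqrt(ipk_w_cm2 / dynscat_constants$I_au_w_cm2)
}
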