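## Physical constants and unit conversions (CODATA 2018 values).
## Internal computations use Hartree atomic units; user-facing interfaces
## use eV, fs, nm, barn and uJ/um^2 as customary in the XFEL literature.

#' Physical constants used throughout the package
#'
#' A named list of physical constants and unit conversion factors. All
#' internal atomic-structure and dynamics computations are carried out in
#' Hartree atomic units; these factors convert to the experimental units
#' used at the interfaces (eV, fs, nm, barn, uJ/um^2).
#'
#' @format Named list with elements such as `hartree_ev` (eV per Hartree),
#'   `bohr_nm` (nm per bohr), `fs_au` (atomic time units per fs),
#'   `alpha` (fine-structure constant), `au_area_barn` (barn per bohr^2),
#'   `r_e_nm` (classical electron radius, nm), `ev_joule` (J per eV),
#'   `hbar_ev_fs` (eV fs), `amu_au` (electron masses per unified amu),
#'   `avogadro`.
#' @export
dynscat_constants <- list(
  hartree_ev   = 27.211386245988,
  bohr_nm      = 0.052917721067,
  fs_au        = 41.341373335,      # 1 fs in atomic time units
  alpha        = 7.2973525693e-3,   # fine-structure constant
  au_area_barn = 2.80028520539e7,   # bohr^2 in barn (1 barn = 1e-24 cm^2)
  au_area_mbarn = 28.0028520539,    # bohr^2 in Mbarn
  r_e_nm       = 2.8179403262e-6,   # classical electron radius in nm
  ev_joule     = 1.602176634e-19,
  hbar_ev_fs   = 0.6582119569,      # hbar in eV fs
  amu_au       = 1822.888486209,    # electron masses per amu
  avogadro     = 6.02214076e23,
  # intensity of 1 atomic unit of field, W/cm^2
  I_au_w_cm2   = 3.50944758e16
)

#' @keywords internal
ev_to_au <- function(ev) ev / dynscat_constants$hartree_ev

#' @keywords internal
au_to_ev <- function(au) au * dynscat_constants$hartree_ev

#' @keywords internal
nm_to_au <- function(nm) nm / dynscat_constants$bohr_nm

#' @keywords internal
au_to_nm <- function(au) au * dynscat_constants$bohr_nm

#' @keywords internal
fs_to_au <- function(fs) fs * dynscat_constants$fs_au

#' @keywords internal
au_to_fs <- function(au) au / dynscat_constants$fs_au

#' Convert pulse fluence between uJ/um^2 and photons/nm^2
#'
#' @param fluence_uj_um2 fluence in micro-Joule per square micrometre.
#' @param photon_energy_ev photon energy in eV.
#' @return photons per square nanometre.
#' @export
fluence_to_photons_nm2 <- function(fluence_uj_um2, photon_energy_ev) {
  stopifnot(photon_energy_ev > 0)
  joule_per_um2 <- fluence_uj_um2 * 1e-6
  photons_per_um2 <- joule_per_um2 / (photon_energy_ev * dynscat_constants$ev_joule)
  photons_per_um2 / 1e6
}

#' @rdname fluence_to_photons_nm2
#' @param photons_nm2 photons per square nanometre.
#' @export
photons_nm2_to_fluence <- function(photons_nm2, photon_energy_ev) {
  photons_nm2 * 1e6 * photon_energy_ev * dynscat_constants$ev_joule * 1e6
}
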