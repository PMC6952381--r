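## broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an HFS atomic-data object
#'
#' @param x an `atomic_data` object.
#' @param ... unused.
#' @return tibble with one row per subshell: occupation, binding energy.
#' @method tidy atomic_data
#' @export
tidy.atomic_data <- function(x, ...) {
  k <- length(x$eigen_au)
  tibble::tibble(
    element = x$configuration$element,
    subshell = .subshell_names[seq_len(k)],
    occupation = x$configuration$occupations,
    binding_ev = x$energies_ev,
    eigenvalue_au = x$eigen_au)
}

#' @rdname tidy.atomic_data
#' @method glance atomic_data
#' @export
glance.atomic_data <- function(x, ...) {
  tibble::tibble(
    element = x$configuration$element,
    configuration = config_key(x$configuration),
    n_bound = x$n_bound,
    charge = x$configuration$charge,
    total_energy_au = x$total_energy_au,
    scf_iterations = x$scf_iterations,
    n_transitions = if (is.null(x$transitions)) 0L else nrow(x$transitions),
    auger_lifetime_fs = if (is.null(x$auger)) NA_real_ else x$auger$lifetime_fs)
}

#' Tidy a scattering cross-section result
#'
#' @param x a `cross_section_result`.
#' @param ... unused.
#' @return the radial pattern tibble.
#' @method tidy cross_section_result
#' @export
tidy.cross_section_result <- function(x, ...) x$pattern

#' @rdname tidy.cross_section_result
#' @method glance cross_section_result
#' @export
glance.cross_section_result <- function(x, ...) {
  tibble::tibble(sigma_barn = x$sigma_barn,
                 damaged = isTRUE(x$damaged),
                 mean_ne = x$mean_ne %||% 0,
                 photon_energy_ev = if (!is.null(x$pulse)) {
                   x$pulse$photon_energy_ev
                 } else NA_real_)
}

#' Tidy a cluster trajectory (per-snapshot census)
#'
#' @param x a `cluster_trajectory`.
#' @param ... unused.
#' @return the [trajectory_census()] tibble.
#' @method tidy cluster_trajectory
#' @export
tidy.cluster_trajectory <- function(x, ...) trajectory_census(x)

#' @rdname tidy.cluster_trajectory
#' @method glance cluster_trajectory
#' @export
glance.cluster_trajectory <- function(x, ...) {
  cen <- trajectory_census(x)
  n0 <- bound_electron_count(x$cluster)
  tibble::tibble(
    n_atoms = nrow(x$cluster$atoms),
    n_snapshots = length(x$snapshots),
    n_events = nrow(x$events),
    escaped = x$final$escaped,
    electron_loss_fraction = 1 - (cen$bound_electrons[nrow(cen)] +
                                    cen$n_delocalized[nrow(cen)]) / n0,
    diameter_initial_nm = cen$diameter_nm[1],
    diameter_final_nm = cen$diameter_nm[nrow(cen)],
    photon_energy_ev = x$pulse$photon_energy_ev,
    fwhm_fs = x$pulse$fwhm_fs,
    fluence_uj_um2 = x$pulse$fluence_uj_um2)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
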