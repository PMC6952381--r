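## Homogeneous-sphere diffraction model and single-shot image analysis.
##
## Expected photons per pixel for a sphere of diameter d and refractive
## index 1 - dn at incident fluence I0:
##   I_i = I0 D_QEgeo (6 pi V |dn| / lambda^2)^2
##         | (sin s_i - s_i cos s_i) / s_i^3 |^2 ,   s_i = (2 pi d/lambda) sin(theta_i)
## The (6 pi V |dn| / lambda^2)^2 |...|^2 term is the differential cross
## section (area/sr); D_QEgeo folds quantum efficiency and the per-pixel
## solid angle.

#' pnCCD-style detector geometry
#'
#' Two panels of 512 x 1024 pixels (rows split symmetrically about the
#' beam with a central gap), mapped per pixel to scattering angle theta,
#' momentum transfer and solid angle.
#'
#' @param distance_mm sample-detector distance (default 370).
#' @param pixel_mm pixel pitch (default 0.075, i.e. 75 um).
#' @param gap_mm width of the central gap between the two panels.
#' @param n_rows,n_cols pixels per panel (rows) and along the panel.
#' @param binning integer pixel binning factor (coarser grids for fast
#'   synthetic studies).
#' @param qe quantum efficiency folded into D_QE,geo.
#' @return object of class `detector_geometry` with per-pixel matrices
#'   `theta`, `solid_angle_sr`, `d_qegeo` and the panel `mask`.
#' @export
detector_geometry <- function(distance_mm = 370, pixel_mm = 0.075,
                              gap_mm = 1.5, n_rows = 512, n_cols = 1024,
                              binning = 1, qe = 1) {
  stopifnot(binning >= 1)
  px <- pixel_mm * binning
  nr <- as.integer(n_rows / binning)
  nc <- as.integer(n_cols / binning)
  # columns span symmetric about beam; rows: two panels above/below gap
  x <- (seq_len(nc) - (nc + 1) / 2) * px
  y_top <- gap_mm / 2 + (seq_len(nr) - 0.5) * px
  y <- c(rev(-y_top), y_top)
  xm <- matrix(x, 2 * nr, nc, byrow = TRUE)
  ym <- matrix(y, 2 * nr, nc)
  r2 <- xm^2 + ym^2
  theta <- atan(sqrt(r2) / distance_mm)
  # pixel solid angle: A cos^3(theta) / L^2
  sa <- (px^2) * cos(theta)^3 / distance_mm^2
  structure(list(distance_mm = distance_mm, pixel_mm = px,
                 gap_mm = gap_mm, nx = nc, ny = 2 * nr,
                 x_mm = xm, y_mm = ym, theta = theta,
                 solid_angle_sr = sa, d_qegeo = qe * sa,
                 mask = matrix(TRUE, 2 * nr, nc)),
            class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf(
    "<detector: 2 x %d x %d px (pitch %.3f mm, gap %.1f mm) at %.0f mm; theta up to %.2f rad>\n",
    x$ny / 2, x$nx, x$pixel_mm, x$gap_mm, x$distance_mm, max(x$theta)))
  invisible(x)
}

#' Momentum transfer map of a geometry at a wavelength
#'
#' Uses the sphere-model convention |q| = (2/lambda) sin(theta), the one
#' that makes s = pi d |q|.
#'
#' @param geometry a [detector_geometry()].
#' @param wavelength_nm photon wavelength (nm).
#' @return matrix of |q| in nm^-1.
#' @export
detector_q_map <- function(geometry, wavelength_nm) {
  (2 / wavelength_nm) * sin(geometry$theta)
}

#' Homogeneous-sphere model parameters
#'
#' @param diameter_nm sphere diameter d.
#' @param wavelength_nm photon wavelength lambda.
#' @param delta_n_abs refractive decrement magnitude |dn| (from
#'   [refractive_decrement()]).
#' @param fluence_photons_nm2 incident fluence I0 on the particle
#'   (photons/nm^2).
#' @return object of class `sphere_model`.
#' @export
sphere_model <- function(diameter_nm, wavelength_nm, delta_n_abs,
                         fluence_photons_nm2) {
  stopifnot(diameter_nm > 0, wavelength_nm > 0, delta_n_abs > 0,
            fluence_photons_nm2 >= 0)
  structure(list(diameter_nm = diameter_nm,
                 volume_nm3 = pi * diameter_nm^3 / 6,
                 wavelength_nm = wavelength_nm,
                 delta_n_abs = delta_n_abs,
                 fluence_photons_nm2 = fluence_photons_nm2),
            class = "sphere_model")
}

# |(sin s - s cos s)/s^3|^2 with the s -> 0 series limit 1/9
.sphere_envelope2 <- function(s) {
  out <- rep(1 / 9, length(s))
  big <- s > 1e-4
  out[big] <- ((sin(s[big]) - s[big] * cos(s[big])) / s[big]^3)^2
  out
}

#' Expected photons per pixel from the sphere model
#'
#' @param model a [sphere_model()].
#' @param geometry a [detector_geometry()].
#' @return matrix of expected photon counts (same shape as the detector).
#' @export
sphere_image <- function(model, geometry) {
  s <- (2 * pi * model$diameter_nm / model$wavelength_nm) *
    sin(geometry$theta)
  amp2 <- (6 * pi * model$volume_nm3 * model$delta_n_abs /
             model$wavelength_nm^2)^2          # nm^2 / sr scale
  model$fluence_photons_nm2 * geometry$d_qegeo * amp2 *
    .sphere_envelope2(s)
}

#' Refractive decrement of a material from its atomic form factors
#'
#' Standard dispersion relation n = 1 - (r_e lambda^2 / 2 pi) sum_i n_i
#' f_i(0, omega), with number densities from the stoichiometry and mass
#' density. Returns the complex decrement dn = delta + i beta and its
#' magnitude.
#'
#' @param stoichiometry named integer vector of atoms per formula unit,
#'   e.g. `c(C = 12, H = 22, O = 11)` for sucrose.
#' @param mass_density_kg_m3 mass density (1581 for sucrose).
#' @param omega_ev photon energy (eV).
#' @param control an [hfs_control()].
#' @return list with `delta`, `beta`, `abs`, `n_formula_nm3`.
#' @export
refractive_decrement <- function(stoichiometry, mass_density_kg_m3,
                                 omega_ev, control = hfs_control()) {
  stopifnot(all(names(stoichiometry) %in% names(.elements)))
  if (mass_density_kg_m3 == 0) {
    return(list(delta = 0, beta = 0, abs = 0, n_formula_nm3 = 0))
  }
  m_formula_g <- sum(vapply(seq_along(stoichiometry), function(i) {
    element_info(names(stoichiometry)[i])$mass_amu * stoichiometry[[i]]
  }, numeric(1)))
  n_formula_nm3 <- mass_density_kg_m3 * 1000 / m_formula_g *
    dynscat_constants$avogadro / 1e27   # g/m^3 / (g/mol) * Na -> per nm^3
  lam <- xray_wavelength_nm(omega_ev)
  fsum <- 0 + 0i
  for (i in seq_along(stoichiometry)) {
    el <- names(stoichiometry)[i]
    ad <- solve_hfs(el, ground_configuration(el), control = control)
    an <- anomalous_terms(ad, omega_ev,
                          resonance_broadening_ev = 0.01 * omega_ev)
    fsum <- fsum + stoichiometry[[i]] *
      complex(real = ad$n_bound + an$f1, imaginary = an$f2)
  }
  pref <- dynscat_constants$r_e_nm * lam^2 / (2 * pi) * n_formula_nm3
  delta <- pref * Re(fsum)
  beta <- pref * Im(fsum)
  list(delta = delta, beta = beta, abs = sqrt(delta^2 + beta^2),
       n_formula_nm3 = n_formula_nm3)
}
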