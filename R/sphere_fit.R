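## Fitting single-shot sphere-diffraction images: diameter from the fringe
## structure, incident fluence from the amplitude, and the experimental
## dynamic scattering efficiency from an ensemble of fits.

#' Azimuthally averaged radial profile of an image
#'
#' @param image photon-count matrix (detector shape).
#' @param geometry a [detector_geometry()].
#' @param n_bins number of polar-angle bins.
#' @return tibble with `theta`, `mean_counts`, `n_pixels`,
#'   `sum_counts`, `mean_d_qegeo`.
#' @export
radial_profile <- function(image, geometry, n_bins = 180) {
  ok <- geometry$mask & is.finite(image)
  th <- geometry$theta[ok]
  bins <- cut(th, breaks = seq(0, max(th) + 1e-9, length.out = n_bins + 1),
              labels = FALSE)
  tibble::tibble(bin = bins, counts = image[ok],
                 dq = geometry$d_qegeo[ok], theta = th) |>
    dplyr::group_by(bin) |>
    dplyr::summarise(theta = mean(theta),
                     mean_counts = mean(counts),
                     sum_counts = sum(counts),
                     n_pixels = dplyr::n(),
                     mean_d_qegeo = mean(dq), .groups = "drop")
}

# expected mean counts in a radial bin for unit fluence
.profile_shape <- function(d_nm, lambda_nm, delta_n_abs, prof) {
  v <- pi * d_nm^3 / 6
  amp2 <- (6 * pi * v * delta_n_abs / lambda_nm^2)^2
  s <- (2 * pi * d_nm / lambda_nm) * sin(prof$theta)
  amp2 * .sphere_envelope2(s) * prof$mean_d_qegeo
}

#' Fit sphere diameter and incident fluence to a diffraction image
#'
#' Poisson maximum likelihood on the azimuthally averaged radial profile:
#' the diameter shapes the fringe pattern, the incident fluence is the
#' (analytically profiled-out) amplitude. Initialisation takes the
#' diameter from the first radial minimum; a multi-start over +/- 20
#' percent guards against fringe-order aliasing. Deterministic given
#' inputs.
#'
#' @param image photon-count matrix.
#' @param geometry a [detector_geometry()].
#' @param delta_n_abs refractive decrement magnitude |dn|.
#' @param wavelength_nm photon wavelength.
#' @param d_range_nm diameter search range.
#' @param n_bins radial bins.
#' @return tibble (one row) with `d_nm`, `i0_photons_nm2`, `i0_uj_um2`,
#'   `deviance`, `low_confidence` (no fringe minimum inside the q range)
#'   and fit metadata; class `sphere_fit`.
#' @export
fit_sphere <- function(image, geometry, delta_n_abs, wavelength_nm,
                       d_range_nm = c(10, 200), n_bins = 180) {
  prof <- radial_profile(image, geometry, n_bins)
  prof <- prof[prof$n_pixels > 0 & prof$theta > 0, ]

  # initial diameter from the first fringe minimum: s_min1 = 4.4934
  sm <- stats::supsmu(prof$theta, log(prof$mean_counts + 1e-6))
  dips <- which(diff(sign(diff(sm$y))) > 0) + 1
  low_confidence <- length(dips) == 0
  d_init <- if (!low_confidence) {
    4.4934 / ((2 * pi / wavelength_nm) * sin(sm$x[dips[1]]))
  } else {
    mean(d_range_nm)
  }
  d_init <- min(max(d_init, d_range_nm[1]), d_range_nm[2])

  obs <- prof$sum_counts
  npix <- prof$n_pixels
  nll <- function(d) {
    mu1 <- .profile_shape(d, wavelength_nm, delta_n_abs, prof) * npix
    tot <- sum(mu1)
    if (tot <= 0) return(Inf)
    i0 <- sum(obs) / tot              # Poisson ML amplitude, profiled out
    mu <- pmax(i0 * mu1, 1e-12)
    -sum(stats::dpois(round(obs), mu, log = TRUE))
  }
  # global coarse scan (guards against fringe-order aliasing), then local
  # refinement around the best candidates including the fringe-based start
  grid <- exp(seq(log(d_range_nm[1]), log(d_range_nm[2]),
                  length.out = 60))
  gv <- vapply(grid, nll, numeric(1))
  starts <- unique(c(grid[order(gv)[1:3]], d_init * c(0.9, 1, 1.1)))
  best <- NULL
  for (s0 in starts) {
    o <- stats::optimize(nll, interval = c(0.85 * s0, 1.18 * s0))
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  d_hat <- best$minimum
  mu1 <- .profile_shape(d_hat, wavelength_nm, delta_n_abs, prof) * npix
  i0 <- sum(obs) / sum(mu1)
  omega_ev <- 1239.8419843320026 / wavelength_nm
  out <- tibble::tibble(
    d_nm = d_hat,
    i0_photons_nm2 = i0,
    i0_uj_um2 = photons_nm2_to_fluence(i0, omega_ev),
    deviance = 2 * (best$objective +
                      sum(stats::dpois(round(obs), pmax(round(obs), 1e-12),
                                       log = TRUE))),
    n_bins = nrow(prof),
    low_confidence = low_confidence,
    wavelength_nm = wavelength_nm,
    delta_n_abs = delta_n_abs)
  class(out) <- c("sphere_fit", class(out))
  out
}

#' Experimental dynamic scattering efficiency from fitted shots
#'
#' Filters the fitted shots to sizes within one standard deviation of the
#' mean cluster size, takes the most intense `top_fraction` of fitted
#' incident fluences, and reports their mean relative to the beamline
#' peak fluence: DSE = mean(top I0) / F0.
#'
#' @param fits tibble with columns `d_nm` and `i0_photons_nm2` (or
#'   `i0_uj_um2`), e.g. rows of [fit_sphere()] results.
#' @param f0 beamline peak fluence, same units as the chosen `i0` column.
#' @param i0_column which fitted-fluence column to compare with `f0`.
#' @param size_filter_sd half-width of the size filter in standard
#'   deviations (default 1; `Inf` disables).
#' @param top_fraction fraction of most intense hits averaged (default
#'   0.05).
#' @return tibble with `dse`, `n_used`, `n_after_size_filter`,
#'   `mean_top_i0`.
#' @export
dse_experimental <- function(fits, f0, i0_column = "i0_photons_nm2",
                             size_filter_sd = 1, top_fraction = 0.05) {
  stopifnot(f0 > 0, top_fraction > 0, top_fraction <= 1)
  d <- fits$d_nm
  keep <- abs(d - mean(d)) <= size_filter_sd * stats::sd(d) |
    !is.finite(stats::sd(d))
  keep[is.na(keep)] <- TRUE
  sel <- fits[keep, ]
  if (nrow(sel) == 0) stop("no shots left after the size filter")
  i0 <- sel[[i0_column]]
  n_top <- max(1L, ceiling(top_fraction * length(i0)))
  top <- sort(i0, decreasing = TRUE)[seq_len(n_top)]
  tibble::tibble(dse = mean(top) / f0,
                 n_used = n_top,
                 n_after_size_filter = nrow(sel),
                 mean_top_i0 = mean(top))
}

#' Generate a synthetic single-shot ensemble with known ground truth
#'
#' Draws particle sizes and incident fluences, renders each expected
#' sphere image scaled by a known damage factor, adds Poisson noise, and
#' returns the images with their ground truth - the stand-in for an
#' experimental hit ensemble used in recovery studies.
#'
#' @param n_shots number of shots.
#' @param geometry a [detector_geometry()].
#' @param omega_ev photon energy.
#' @param delta_n_abs refractive decrement magnitude.
#' @param size_mean_nm,size_sd_nm Gaussian size distribution.
#' @param focal tibble from [focal_fluence_distribution()], or a single
#'   fluence in uJ/um^2.
#' @param damage_factor multiplies every expected image (the injected
#'   "DSE" the recovery study should find).
#' @param seed RNG seed.
#' @param noise add Poisson noise (TRUE).
#' @return list with `images` (list of matrices) and `truth` tibble
#'   (`d_nm`, `i0_uj_um2`, `i0_photons_nm2`, `damage_factor`).
#' @export
synthetic_shot_ensemble <- function(n_shots, geometry, omega_ev,
                                    delta_n_abs,
                                    size_mean_nm = 45, size_sd_nm = 5,
                                    focal = 25, damage_factor = 1,
                                    seed = 1, noise = TRUE) {
  set.seed(seed)
  lam <- xray_wavelength_nm(omega_ev)
  if (is.numeric(focal)) {
    focal <- tibble::tibble(fluence_uj_um2 = focal, weight = 1)
  }
  d <- pmax(stats::rnorm(n_shots, size_mean_nm, size_sd_nm),
            size_mean_nm / 4)
  fl_uj <- focal$fluence_uj_um2[sample.int(nrow(focal), n_shots,
                                           replace = TRUE,
                                           prob = focal$weight)]
  images <- vector("list", n_shots)
  for (k in seq_len(n_shots)) {
    i0 <- fluence_to_photons_nm2(fl_uj[k], omega_ev)
    m <- sphere_model(d[k], lam, delta_n_abs, i0)
    mu <- sphere_image(m, geometry) * damage_factor
    images[[k]] <- if (noise) {
      matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
    } else mu
  }
  list(images = images,
       truth = tibble::tibble(
         d_nm = d, i0_uj_um2 = fl_uj,
         i0_photons_nm2 = fluence_to_photons_nm2(fl_uj, omega_ev),
         damage_factor = damage_factor, omega_ev = omega_ev))
}

#' Fit every image of a shot ensemble
#'
#' @param ensemble result of [synthetic_shot_ensemble()] (or a list with
#'   `images`).
#' @param geometry a [detector_geometry()].
#' @param delta_n_abs refractive decrement magnitude.
#' @param omega_ev photon energy.
#' @param ... passed to [fit_sphere()].
#' @return tibble of per-shot fits.
#' @export
fit_shot_ensemble <- function(ensemble, geometry, delta_n_abs, omega_ev,
                              ...) {
  lam <- xray_wavelength_nm(omega_ev)
  purrr::map_dfr(seq_along(ensemble$images), function(k) {
    f <- fit_sphere(ensemble$images[[k]], geometry, delta_n_abs, lam, ...)
    f$shot <- k
    f
  })
}
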