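## Plain-text container I/O.
##
## Atomic data and diffraction-image ensembles are stored in a documented
## directory layout of TSV tables with a JSON metadata sidecar (one
## directory per object, mirroring the group structure of the CXI/HDF5
## convention in portable text form).

#' Export HFS atomic data as a plain-text directory
#'
#' Layout: `meta.json` (element, configuration, control), `levels.tsv`
#' (subshell energies/occupations), `transitions.tsv`, `sigma_pi.tsv`
#' (photoionization grid per subshell) and `density.tsv` (radial grid and
#' electron density).
#'
#' @param atomic_data an `atomic_data` object.
#' @param dir output directory (created).
#' @param omega_grid_ev photon-energy grid for the exported cross-section
#'   table.
#' @return `dir`, invisibly.
#' @export
export_atomic_data <- function(atomic_data, dir,
                               omega_grid_ev = exp(seq(log(10), log(5000),
                                                       length.out = 60))) {
  ad <- atomic_data
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(element = ad$configuration$element,
               occupations = ad$configuration$occupations,
               n_bound = ad$n_bound,
               charge = ad$configuration$charge,
               total_energy_au = ad$total_energy_au,
               alpha = ad$control$alpha,
               transition_energy = ad$control$transition_energy)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(tidy(ad), file.path(dir, "levels.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(ad$transitions)) {
    utils::write.table(as.data.frame(ad$transitions),
                       file.path(dir, "transitions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  k <- length(ad$eigen_au)
  sig <- data.frame(omega_ev = omega_grid_ev)
  for (s in seq_len(k)) {
    if (ad$configuration$occupations[s] == 0) next
    sig[[.subshell_names[s]]] <-
      photoionization_cs(ad, .subshell_names[s], omega_grid_ev)
  }
  utils::write.table(sig, file.path(dir, "sigma_pi.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(r_bohr = ad$r, rho_radial = ad$rho_rad),
    file.path(dir, "density.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  invisible(dir)
}

#' Import an exported atomic-data directory
#'
#' Returns the tabulated form (not a live solver object): level table,
#' transitions, cross-section grid, density and metadata.
#'
#' @param dir directory written by [export_atomic_data()].
#' @return list with `meta`, `levels`, `transitions`, `sigma_pi`,
#'   `density`.
#' @export
import_atomic_data <- function(dir) {
  read1 <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) return(NULL)
    tibble::as_tibble(utils::read.table(p, header = TRUE, sep = "\t",
                                        check.names = FALSE))
  }
  list(meta = jsonlite::read_json(file.path(dir, "meta.json"),
                                  simplifyVector = TRUE),
       levels = read1("levels.tsv"),
       transitions = read1("transitions.tsv"),
       sigma_pi = read1("sigma_pi.tsv"),
       density = read1("density.tsv"))
}

#' Write a shot ensemble as a plain-text directory
#'
#' Layout: `meta.json` (geometry and beam), `truth.tsv` (ground-truth
#' sidecar) and `shot_###.tsv` (one TSV matrix of photon counts per
#' image).
#'
#' @param ensemble result of [synthetic_shot_ensemble()].
#' @param dir output directory.
#' @param geometry the [detector_geometry()] used.
#' @return `dir`, invisibly.
#' @export
write_shot_ensemble <- function(ensemble, dir, geometry = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(n_shots = length(ensemble$images))
  if (!is.null(geometry)) {
    meta$detector <- list(distance_mm = geometry$distance_mm,
                          pixel_mm = geometry$pixel_mm,
                          gap_mm = geometry$gap_mm,
                          nx = geometry$nx, ny = geometry$ny)
  }
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(as.data.frame(ensemble$truth),
                     file.path(dir, "truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (k in seq_along(ensemble$images)) {
    utils::write.table(ensemble$images[[k]],
                       file.path(dir, sprintf("shot_%03d.tsv", k)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Read a shot ensemble directory
#'
#' @param dir directory written by [write_shot_ensemble()].
#' @return list with `images`, `truth`, `meta`.
#' @export
read_shot_ensemble <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  truth <- tibble::as_tibble(
    utils::read.table(file.path(dir, "truth.tsv"), header = TRUE,
                      sep = "\t"))
  files <- sort(list.files(dir, pattern = "^shot_\\d+\\.tsv$",
                           full.names = TRUE))
  images <- lapply(files, function(f) {
    as.matrix(utils::read.table(f, header = FALSE, sep = "\t"))
  })
  list(images = images, truth = truth, meta = meta)
}
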