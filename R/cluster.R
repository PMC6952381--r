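## Cluster construction and the ClusterState container.
##
## A cluster state holds, at one instant, all nuclei (element, position,
## velocity, electronic configuration, charge) and all delocalized
## electrons, plus escaped-electron bookkeeping. Positions in nm,
## velocities in nm/fs, time in fs.

#' Construct a cluster state from an atom table
#'
#' @param atoms tibble/data.frame with columns `element`, `x_nm`, `y_nm`,
#'   `z_nm`; optional `config` (list of `electronic_configuration`,
#'   default ground state) and velocities `vx`, `vy`, `vz` (nm/fs,
#'   default 0).
#' @param time_fs simulation time stamp.
#' @param electrons tibble with `x_nm, y_nm, z_nm, vx, vy, vz` for
#'   delocalized electrons (default none).
#' @param escaped number of electrons that have left the interaction
#'   region.
#' @return object of class `cluster_state`.
#' @export
cluster_state <- function(atoms, time_fs = 0, electrons = NULL,
                          escaped = 0L) {
  atoms <- tibble::as_tibble(atoms)
  stopifnot(all(c("element", "x_nm", "y_nm", "z_nm") %in% names(atoms)))
  if (!("config" %in% names(atoms))) {
    atoms$config <- lapply(atoms$element, ground_configuration)
  }
  for (v in c("vx", "vy", "vz")) if (is.null(atoms[[v]])) atoms[[v]] <- 0
  atoms$charge <- vapply(atoms$config, function(cf) cf$charge, numeric(1))
  if (is.null(electrons)) {
    electrons <- tibble::tibble(x_nm = numeric(), y_nm = numeric(),
                                z_nm = numeric(), vx = numeric(),
                                vy = numeric(), vz = numeric())
  }
  structure(list(atoms = atoms, electrons = tibble::as_tibble(electrons),
                 time_fs = time_fs, escaped = as.integer(escaped)),
            class = "cluster_state")
}

#' @export
print.cluster_state <- function(x, ...) {
  cat(sprintf(
    "<cluster state t = %.3f fs: %d nuclei, %d delocalized e-, %d escaped, diameter %.2f nm>\n",
    x$time_fs, nrow(x$atoms), nrow(x$electrons), x$escaped,
    cluster_diameter(x)))
  invisible(x)
}

#' Sphere-equivalent diameter of the nuclear distribution
#'
#' Defined as 2 sqrt(5/3) times the radius of gyration of the nuclei (the
#' exact relation for a homogeneous sphere).
#'
#' @param state a `cluster_state`.
#' @return diameter in nm.
#' @export
cluster_diameter <- function(state) {
  a <- state$atoms
  if (nrow(a) < 2) return(0)
  cx <- c(mean(a$x_nm), mean(a$y_nm), mean(a$z_nm))
  rg2 <- mean((a$x_nm - cx[1])^2 + (a$y_nm - cx[2])^2 + (a$z_nm - cx[3])^2)
  2 * sqrt(5 / 3) * sqrt(rg2)
}

#' Total bound-electron count of a cluster state
#' @param state a `cluster_state`.
#' @export
bound_electron_count <- function(state) {
  sum(vapply(state$atoms$config, function(cf) cf$n_electrons, numeric(1)))
}

# uniform random rotation matrix (Arvo / quaternion method)
.random_rotation <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
           2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
           2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Build a stoichiometric sucrose cluster
#'
#' Places `n_molecules` sucrose molecules with random orientations inside
#' a sphere whose radius follows from the sucrose mass density (default
#' 1581 kg/m^3), using Poisson-disk rejection sampling of the molecular
#' centres. Stoichiometry is exact (45 atoms, 182 electrons per molecule);
#' the build is deterministic for a given seed. For 185,193 molecules the
#' sphere diameter is about 50 nm and the dynamics would track about 42
#' million particles; desk-scale runs use tens to thousands of molecules.
#'
#' @param n_molecules number of sucrose units (>= 1).
#' @param seed RNG seed (placement and orientations).
#' @param density_kg_m3 target mass density.
#' @param min_distance_nm minimum centre-centre distance between molecules.
#' @param max_attempts_per_molecule rejection-sampling budget; exceeded
#'   packing raises an error suggesting a density relaxation factor.
#' @return a `cluster_state` at t = 0 with all atoms in their ground
#'   state.
#' @export
build_cluster <- function(n_molecules, seed = 1, density_kg_m3 = 1581,
                          min_distance_nm = 0.60,
                          max_attempts_per_molecule = 2000) {
  stopifnot(n_molecules >= 1)
  set.seed(seed)
  R <- cluster_radius_nm(n_molecules, density_kg_m3)
  mol <- sucrose_molecule()
  xyz_mol <- as.matrix(mol[, c("x_nm", "y_nm", "z_nm")])
  if (n_molecules == 1) {
    centers <- matrix(0, 1, 3)
  } else {
    # centre-placement radius chosen so the atomic radius of gyration
    # reproduces the nominal homogeneous-sphere radius R:
    # (3/5) R_c^2 + Rg_mol^2 = (3/5) R^2
    rg2_mol <- mean(rowSums(xyz_mol^2))
    r_center <- sqrt(max(R^2 - (5 / 3) * rg2_mol, 1e-4))
    # tiny clusters: the nominal spacing cannot exceed the placement
    # sphere itself
    min_distance_nm <- min(min_distance_nm, r_center)
    centers <- matrix(NA_real_, n_molecules, 3)
    placed <- 0L
    attempts <- 0L
    budget <- max_attempts_per_molecule * n_molecules
    while (placed < n_molecules) {
      attempts <- attempts + 1L
      if (attempts > budget) {
        stop("could not pack ", n_molecules, " molecules at ",
             density_kg_m3, " kg/m^3 after ", budget, " attempts; ",
             "consider a density relaxation factor (lower density or ",
             "smaller min_distance_nm)")
      }
      p <- stats::runif(3, -1, 1)
      while (sum(p^2) > 1) p <- stats::runif(3, -1, 1)
      cand <- p * r_center
      if (placed > 0L) {
        d2 <- (centers[seq_len(placed), 1] - cand[1])^2 +
          (centers[seq_len(placed), 2] - cand[2])^2 +
          (centers[seq_len(placed), 3] - cand[3])^2
        if (min(d2) < min_distance_nm^2) next
      }
      placed <- placed + 1L
      centers[placed, ] <- cand
    }
    # radial rescale so the atomic radius of gyration matches the nominal
    # homogeneous sphere exactly (removes residual edge-layering bias of
    # the rejection sampling; the generated density then tracks the target)
    rg2c <- mean(rowSums(centers^2))
    target <- (3 / 5) * R^2 - rg2_mol
    if (rg2c > 0 && target > 0) centers <- centers * sqrt(target / rg2c)
  }
  parts <- vector("list", n_molecules)
  for (m in seq_len(n_molecules)) {
    rot <- .random_rotation()
    xyz <- xyz_mol %*% t(rot)
    parts[[m]] <- tibble::tibble(
      element = mol$element,
      x_nm = xyz[, 1] + centers[m, 1],
      y_nm = xyz[, 2] + centers[m, 2],
      z_nm = xyz[, 3] + centers[m, 3],
      molecule = m)
  }
  atoms <- dplyr::bind_rows(parts)
  st <- cluster_state(atoms)
  st$meta <- list(n_molecules = n_molecules, seed = seed,
                  density_kg_m3 = density_kg_m3, nominal_radius_nm = R)
  st
}

#' Nominal cluster radius from molecule count and mass density
#'
#' @inheritParams build_cluster
#' @return radius in nm.
#' @export
cluster_radius_nm <- function(n_molecules, density_kg_m3 = 1581) {
  mass_g <- n_molecules * sucrose_molar_mass() / dynscat_constants$avogadro
  vol_cm3 <- mass_g / (density_kg_m3 / 1000)
  (3 * vol_cm3 / (4 * pi))^(1 / 3) * 1e7
}

#' Write a cluster as an XYZ file
#'
#' @param state a `cluster_state`.
#' @param path output file (coordinates in Angstrom, XYZ convention).
#' @export
write_xyz <- function(state, path) {
  a <- state$atoms
  lines <- c(nrow(a), sprintf("dynscat cluster t=%.3f fs", state$time_fs),
             sprintf("%-2s %12.5f %12.5f %12.5f", a$element,
                     a$x_nm * 10, a$y_nm * 10, a$z_nm * 10))
  writeLines(lines, path)
  invisible(path)
}

#' Read an XYZ file into a cluster state
#' @param path XYZ file (Angstrom).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  rec <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  cluster_state(tibble::tibble(
    element = vapply(rec, `[[`, "", 1),
    x_nm = as.numeric(vapply(rec, `[[`, "", 2)) / 10,
    y_nm = as.numeric(vapply(rec, `[[`, "", 3)) / 10,
    z_nm = as.numeric(vapply(rec, `[[`, "", 4)) / 10))
}

#' Write a cluster as a minimal PDB file
#'
#' @inheritParams write_xyz
#' @export
write_pdb <- function(state, path) {
  a <- state$atoms
  n <- nrow(a)
  resno <- if (!is.null(a$molecule)) a$molecule else rep(1L, n)
  lines <- sprintf(
    "HETATM%5d %-4s SUC A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(n) %% 100000, substr(a$element, 1, 2), resno %% 10000,
    a$x_nm * 10, a$y_nm * 10, a$z_nm * 10, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
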