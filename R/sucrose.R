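## Idealized sucrose (C12 H22 O11) molecular template: standard bond
## lengths/angles, coordinates in nm about the centroid. 45 atoms, 182
## bound electrons. ~0.1 nm positional fidelity is all that matters over
## the momentum-transfer range the simulations exercise.

.sucrose_coords <- matrix(c(
  0.3306, -0.1235, -0.2115,  0.4330, -0.0637, -0.1362,
  0.3755,  0.0097, -0.0142,  0.2735,  0.0987, -0.0546,
  0.1573,  0.0726,  0.0219,  0.0994,  0.2119,  0.0601,
  0.0173,  0.2054,  0.1734,  0.0724, -0.0056, -0.0627,
 -0.0653, -0.0101, -0.0287, -0.1349,  0.0847, -0.1078,
 -0.2713,  0.0996, -0.0686, -0.2855,  0.2137,  0.0336,
 -0.4205,  0.2468,  0.0528, -0.3377, -0.0323, -0.0185,
 -0.4765, -0.0311, -0.0419, -0.2706, -0.1531, -0.0860,
 -0.3265, -0.2728, -0.0384, -0.1184, -0.1529, -0.0579,
 -0.0506, -0.2081, -0.1679,  0.2038, -0.0076,  0.1454,
  0.1061, -0.0953,  0.1951,  0.3204, -0.0854,  0.0914,
  0.4160, -0.1106,  0.1910,  0.3269, -0.2191, -0.1852,
  0.4850,  0.0102, -0.2008,  0.5090, -0.1386, -0.1038,
  0.4572,  0.0705,  0.0308,  0.1839,  0.2810,  0.0823,
  0.0435,  0.2548, -0.0259, -0.0143,  0.2980,  0.1900,
 -0.0824,  0.0098,  0.0791, -0.3252,  0.1318, -0.1605,
 -0.2289,  0.3030, -0.0013, -0.2428,  0.1829,  0.1312,
 -0.4484,  0.2994, -0.0266, -0.3224, -0.0422,  0.0913,
 -0.4907, -0.0300, -0.1401, -0.2863, -0.1452, -0.1963,
 -0.4115, -0.2868, -0.0877, -0.0972, -0.2145,  0.0327,
 -0.0663, -0.3061, -0.1651,  0.2403,  0.0616,  0.2253,
  0.0588, -0.0474,  0.2680,  0.2852, -0.1808,  0.0454,
  0.3792, -0.1835,  0.2475), ncol = 3, byrow = TRUE)

.sucrose_elements <- c(
  "O","C","C","O","C","C","O","O","C","O","C","C","O","C","O","C","O",
  "C","O","C","O","C","O", rep("H", 22))

#' The sucrose molecule template
#'
#' Idealized internal coordinates for one sucrose molecule
#' (C12 H22 O11, 45 atoms, 182 bound electrons), centred on the centroid.
#'
#' @return tibble with columns `element`, `x_nm`, `y_nm`, `z_nm`.
#' @export
sucrose_molecule <- function() {
  tibble::tibble(element = .sucrose_elements,
                 x_nm = .sucrose_coords[, 1],
                 y_nm = .sucrose_coords[, 2],
                 z_nm = .sucrose_coords[, 3])
}

#' @keywords internal
sucrose_molar_mass <- function() {
  12 * 12.011 + 22 * 1.008 + 11 * 15.999   # g/mol
}
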