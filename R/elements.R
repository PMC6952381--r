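## Element registry: the four species the simulation engine supports
## (hydrogen, carbon, oxygen for sucrose; nitrogen for completeness of the
## light-element set; argon for the fluence-calibration benchmark).

.subshell_names <- c("1s", "2s", "2p", "3s", "3p")
.subshell_n     <- c(1L, 2L, 2L, 3L, 3L)
.subshell_l     <- c(0L, 0L, 1L, 0L, 1L)
.subshell_cap   <- c(2L, 2L, 6L, 2L, 6L)

.elements <- list(
  H  = list(symbol = "H",  Z = 1L,  mass_amu = 1.008,
            n_subshells = 1L, ground = c(1L)),
  C  = list(symbol = "C",  Z = 6L,  mass_amu = 12.011,
            n_subshells = 3L, ground = c(2L, 2L, 2L)),
  N  = list(symbol = "N",  Z = 7L,  mass_amu = 14.007,
            n_subshells = 3L, ground = c(2L, 2L, 3L)),
  O  = list(symbol = "O",  Z = 8L,  mass_amu = 15.999,
            n_subshells = 3L, ground = c(2L, 2L, 4L)),
  Ar = list(symbol = "Ar", Z = 18L, mass_amu = 39.948,
            n_subshells = 5L, ground = c(2L, 2L, 6L, 2L, 6L))
)

#' @keywords internal
element_info <- function(element) {
  el <- .elements[[as.character(element)]]
  if (is.null(el)) {
    stop("unknown element '", element, "'; supported: ",
         paste(names(.elements), collapse = ", "))
  }
  el
}

#' Subshell bookkeeping table for an element
#'
#' @param element element symbol ("H", "C", "N", "O" or "Ar").
#' @return tibble with columns `subshell`, `n`, `l`, `capacity` and the
#'   ground-state occupation.
#' @export
subshell_table <- function(element) {
  el <- element_info(element)
  k <- el$n_subshells
  tibble::tibble(
    subshell = .subshell_names[seq_len(k)],
    n = .subshell_n[seq_len(k)],
    l = .subshell_l[seq_len(k)],
    capacity = .subshell_cap[seq_len(k)],
    ground = el$ground
  )
}
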