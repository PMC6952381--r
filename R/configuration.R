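## ElectronicConfiguration: per-atom subshell occupation vector C_j(t).
## Every ionisation/decay channel in the Monte-Carlo dynamics is a move
## between two of these objects.

#' Create an electronic configuration
#'
#' An electronic configuration is an ordered vector of integer occupation
#' numbers over the subshells 1s, 2s, 2p, (3s, 3p for argon). Occupations
#' must respect subshell capacities (2, 2, 6, 2, 6) and cannot exceed the
#' atomic number, so the ion charge `Z - sum(occupations)` is non-negative.
#'
#' @param element element symbol ("H", "C", "N", "O", "Ar").
#' @param occupations integer vector of per-subshell occupations, one entry
#'   per subshell of the element (shorter vectors are zero-padded).
#' @return an object of class `electronic_configuration`.
#' @examples
#' electronic_configuration("O", c(2, 2, 4))   # ground-state oxygen
#' electronic_configuration("O", c(1, 2, 5))   # core-excited 1s -> 2p state
#' @export
electronic_configuration <- function(element, occupations) {
  el <- element_info(element)
  occ <- as.integer(round(occupations))
  if (length(occ) > el$n_subshells) {
    if (any(occ[-seq_len(el$n_subshells)] != 0L)) {
      stop("occupations extend beyond the subshells of ", el$symbol)
    }
    occ <- occ[seq_len(el$n_subshells)]
  }
  occ <- c(occ, integer(el$n_subshells - length(occ)))
  caps <- .subshell_cap[seq_len(el$n_subshells)]
  if (any(occ < 0L)) stop("negative occupation number")
  if (any(occ > caps)) {
    stop("occupation exceeds subshell capacity for ", el$symbol, ": ",
         paste(occ, collapse = " "))
  }
  if (sum(occ) > el$Z) {
    stop("total occupation ", sum(occ), " exceeds Z = ", el$Z)
  }
  structure(
    list(element = el$symbol, Z = el$Z, occupations = occ,
         n_electrons = sum(occ), charge = el$Z - sum(occ)),
    class = "electronic_configuration"
  )
}

#' Ground-state configuration of an element
#' @inheritParams electronic_configuration
#' @export
ground_configuration <- function(element) {
  el <- element_info(element)
  electronic_configuration(el$symbol, el$ground)
}

#' @export
format.electronic_configuration <- function(x, ...) {
  k <- length(x$occupations)
  occ <- paste0(.subshell_names[seq_len(k)], x$occupations, collapse = " ")
  sprintf("<%s %s (q=%+d)>", x$element, occ, x$charge)
}

#' @export
print.electronic_configuration <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @keywords internal
config_key <- function(config) {
  paste0(config$element, ":", paste(config$occupations, collapse = ","))
}
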