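#' State labels for the laser-tissue interface
#'
#' The warning system distinguishes three laser irradiance states: `Idle`
#' (laser not firing), `Stone` (laser fragmenting a stone) and `Tissue`
#' (laser striking soft tissue -- the hazard). States are encoded as the
#' integers 0, 1 and 2 in that order, and that bijection is fixed throughout
#' the package: label columns in files, simulator output, classifier classes
#' and confusion-matrix axes all use it.
#'
#' @return `state_labels()` returns the named integer vector
#'   `c(Idle = 0L, Stone = 1L, Tissue = 2L)`.
#' @examples
#' state_labels()
#' state_code("Stone")
#' state_name(2)
#' @export
state_labels <- function() {
  c(Idle = 0L, Stone = 1L, Tissue = 2L)
}

#' @rdname state_labels
#' @param name State name, one of `"Idle"`, `"Stone"`, `"Tissue"`
#'   (case-insensitive).
#' @return `state_code()` returns the integer code of a state name.
#' @export
state_code <- function(name) {
  codes <- state_labels()
  idx <- match(tolower(name), tolower(names(codes)))
  if (anyNA(idx)) {
    stop("unknown state name(s): ", paste(name[is.na(idx)], collapse = ", "),
         "; expected one of ", paste(names(codes), collapse = ", "))
  }
  unname(codes[idx])
}

#' @rdname state_labels
#' @param code Integer state code in `{0, 1, 2}`.
#' @return `state_name()` returns the state name of an integer code.
#' @export
state_name <- function(code) {
  check_label_codes(code)
  names(state_labels())[as.integer(code) + 1L]
}

# Validate a vector of label codes; `where` names the offending input in the
# error message, and the first bad row index is reported.
check_label_codes <- function(codes, where = "label") {
  bad <- which(!(codes %in% c(0L, 1L, 2L)))
  if (length(bad) > 0L) {
    stop(sprintf("invalid %s code %s at row %d: must be 0 (Idle), 1 (Stone) or 2 (Tissue)",
                 where, format(codes[bad[1L]]), bad[1L]))
  }
  invisible(TRUE)
}
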