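#' Gait phase codes
#'
#' Integer codes for the five raw gait sub-phases: swing (SW), heel strike
#' (HS), full contact (FC), heel off (HO), and toe off (TO). After the
#' class-merge step ([merge_phases()]) only the four classes SW, HS, FC and HO
#' remain. The numeric assignment is a package convention, not a biomechanical
#' fact; all user-facing functions accept and return these codes.
#'
#' @format Named integer vector of length 5.
#' @export
#' @examples
#' PHASES[["TO"]]
#' phase_name(c(1L, 3L))
PHASES <- c(SW = 1L, HS = 2L, FC = 3L, HO = 4L, TO = 5L)

#' @rdname PHASES
#' @param code integer vector of phase codes.
#' @return `phase_name()` returns the character names for integer codes.
#' @export
phase_name <- function(code) {
  stopifnot(all(code %in% PHASES))
  names(PHASES)[match(code, PHASES)]
}

#' @rdname PHASES
#' @param name character vector of phase names.
#' @return `phase_code()` returns integer codes for phase names.
#' @export
phase_code <- function(name) {
  out <- PHASES[toupper(name)]
  if (anyNA(out)) {
    stop("unknown phase name(s): ",
         paste(name[is.na(out)], collapse = ", "), call. = FALSE)
  }
  unname(out)
}

# internal: stop() with a consistent prefix for argument validation
check_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop(..., call. = FALSE)
  invisible(TRUE)
}

# round-half-up, used wherever a count is derived from a ratio so that
# 0.5 * 14 -> 7 regardless of the platform's banker's rounding
round_half_up <- function(x) floor(x + 0.5)
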