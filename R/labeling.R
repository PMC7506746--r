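#' Binarize FSR analog traces
#'
#' Converts analog force-sensitive-resistor (FSR) readings into on/off contact
#' states by thresholding. Activation uses `>=`, so a reading exactly at the
#' threshold counts as contact; binarization is monotone in the analog value.
#'
#' @param fsr numeric vector or n x 3 matrix of non-negative analog readings.
#'   Columns are heel, metatarsal, toe when a matrix.
#' @param threshold positive activation level (default 0.5 on a normalized
#'   0-1 analog scale). May be length 3 for per-channel thresholds.
#' @return logical object of the same shape as `fsr`.
#' @export
#' @examples
#' binarize_fsr(c(heel = 0.9, meta = 0.1, toe = 0.1))
binarize_fsr <- function(fsr, threshold = 0.5) {
  check_that(all(threshold > 0), "threshold must be positive")
  check_that(all(is.finite(fsr)) && all(fsr >= 0),
             "FSR analog values must be finite and non-negative")
  if (is.matrix(fsr) && length(threshold) == ncol(fsr)) {
    sweep(fsr, 2L, threshold, `>=`)
  } else {
    fsr >= threshold
  }
}

#' Default FSR contact to phase decision table
#'
#' Maps each of the 8 heel/meta/toe contact combinations to a phase code,
#' following the anatomical rollover order of the stance phase: no contact is
#' swing; heel only is heel strike; heel plus forefoot (metatarsal, toe, or
#' both) is full contact; forefoot with the heel lifted and the metatarsal
#' loaded is heel off; toe alone is toe off.
#'
#' @return integer vector of length 8 indexed by
#'   `heel*4 + meta*2 + toe + 1`.
#' @export
fsr_decision_table <- function() {
  tab <- integer(8)
  tab[0 + 0 + 0 + 1] <- PHASES[["SW"]] # (0,0,0)
  tab[0 + 0 + 1 + 1] <- PHASES[["TO"]] # (0,0,1)
  tab[0 + 2 + 0 + 1] <- PHASES[["HO"]] # (0,1,0)
  tab[0 + 2 + 1 + 1] <- PHASES[["HO"]] # (0,1,1)
  tab[4 + 0 + 0 + 1] <- PHASES[["HS"]] # (1,0,0)
  tab[4 + 0 + 1 + 1] <- PHASES[["FC"]] # (1,0,1)
  tab[4 + 2 + 0 + 1] <- PHASES[["FC"]] # (1,1,0)
  tab[4 + 2 + 1 + 1] <- PHASES[["FC"]] # (1,1,1)
  tab
}

#' Map FSR contact states to a gait phase
#'
#' Total mapping: every combination of the three boolean contact states yields
#' exactly one phase label. The decision table can be overridden for
#' alternative sensor layouts.
#'
#' @param heel_on,meta_on,toe_on logical vectors (recycled to common length).
#' @param table decision table as returned by [fsr_decision_table()].
#' @return integer phase codes (see [PHASES]).
#' @export
#' @examples
#' phase_name(fsr_to_phase(FALSE, FALSE, FALSE)) # "SW"
#' phase_name(fsr_to_phase(TRUE, TRUE, TRUE))    # "FC"
fsr_to_phase <- function(heel_on, meta_on, toe_on,
                         table = fsr_decision_table()) {
  check_that(length(table) == 8L && all(table %in% PHASES),
             "decision table must map all 8 combinations to phase codes")
  idx <- as.integer(heel_on) * 4L + as.integer(meta_on) * 2L +
    as.integer(toe_on) + 1L
  table[idx]
}

#' Label a motion recording from its FSR traces
#'
#' Applies [binarize_fsr()] and [fsr_to_phase()] samplewise to the left and
#' right analog insole traces of a recording, yielding one phase label per
#' sample per foot.
#'
#' @param recording a `motion_recording` (see [simulate_walk()]) or a list
#'   with elements `fsr_left` and `fsr_right`, each an n x 3 matrix.
#' @param threshold FSR activation threshold (see [binarize_fsr()]).
#' @param min_run optional minimum run length; runs of identical labels
#'   shorter than this are absorbed into the preceding run (off by default,
#'   mirroring the raw sensor-driven labeling).
#' @param table decision table (see [fsr_decision_table()]).
#' @return list with integer vectors `left` and `right`, one label per frame.
#' @export
label_stream <- function(recording, threshold = 0.5, min_run = 1L,
                         table = fsr_decision_table()) {
  check_that(is.matrix(recording$fsr_left) && is.matrix(recording$fsr_right),
             "recording must carry fsr_left and fsr_right matrices")
  n <- if (!is.null(recording$features)) nrow(recording$features) else
    nrow(recording$fsr_right)
  check_that(nrow(recording$fsr_left) == n && nrow(recording$fsr_right) == n,
             "FSR traces must be aligned with the frames: expected ", n,
             " rows")
  one_foot <- function(fsr) {
    on <- binarize_fsr(fsr, threshold)
    lab <- fsr_to_phase(on[, 1L], on[, 2L], on[, 3L], table = table)
    if (min_run > 1L) lab <- filter_min_run(lab, min_run)
    lab
  }
  list(left = one_foot(recording$fsr_left),
       right = one_foot(recording$fsr_right))
}

#' Absorb short label runs
#'
#' Replaces runs shorter than `min_run` with the label of the preceding run
#' (the first run is kept regardless). A simple debouncing filter; disabled by
#' default throughout the package.
#'
#' @param labels integer label vector.
#' @param min_run minimum run length to keep.
#' @return filtered integer label vector of the same length.
#' @export
filter_min_run <- function(labels, min_run = 2L) {
  r <- rle(labels)
  for (k in seq_along(r$lengths)[-1L]) {
    if (r$lengths[k] < min_run) r$values[k] <- r$values[k - 1L]
  }
  inverse.rle(r)
}
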