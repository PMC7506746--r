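# Delimited-text formats. The integrated message stream mirrors the on-wire
# layout of the acquisition console: one line per 10 ms sample holding the
# timestamp, the left- and right-foot labels, then the feature channels, in
# that order. Comma-separated, UTF-8, header row, '.' decimal, integer
# millisecond timestamps.

#' Write / read the integrated message stream
#'
#' `write_stream()` writes a recording (or any labeled frame set) as CSV with
#' columns `time_ms`, `left_label`, `right_label`, then one column per
#' feature channel. `read_stream()` parses it back, checking that the column
#' count is constant and timestamps strictly increase; the round trip is
#' lossless to full double precision.
#'
#' @param recording a `motion_recording`, or a list with `time_ms`,
#'   `features`, and either `left_label`/`right_label` or FSR traces from
#'   which labels are derived via [label_stream()].
#' @param path file path.
#' @param labels optional list with `left` and `right` integer label vectors;
#'   defaults to the recording's FSR-derived labels.
#' @return `read_stream()` returns a `labeled_stream`: list with `time_ms`,
#'   `left_label`, `right_label`, `features`. `write_stream()` returns
#'   `path` invisibly.
#' @export
write_stream <- function(recording, path, labels = NULL) {
  if (is.null(labels)) {
    labels <- if (!is.null(recording$left_label)) {
      list(left = recording$left_label, right = recording$right_label)
    } else {
      label_stream(recording)
    }
  }
  df <- data.frame(time_ms = recording$time_ms,
                   left_label = labels$left,
                   right_label = labels$right,
                   recording$features, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stream
#' @export
read_stream <- function(path) {
  check_that(file.exists(path), "no such file: ", path)
  nf <- utils::count.fields(path, sep = ",")
  if (length(nf) > 1L && any(nf != nf[1L])) {
    bad <- which(nf != nf[1L])[1L]
    stop("column count drifts at line ", bad, " of ", path,
         " (expected ", nf[1L], " fields, found ", nf[bad], ")",
         call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE)
  required <- c("time_ms", "left_label", "right_label")
  check_that(all(required %in% names(df)),
             "stream is missing column(s): ",
             paste(setdiff(required, names(df)), collapse = ", "))
  if (nrow(df) >= 2L) {
    bad <- which(diff(df$time_ms) <= 0)
    if (length(bad)) {
      stop("timestamps not strictly increasing at line ", bad[1L] + 2L,
           " of ", path, call. = FALSE)
    }
  }
  feats <- as.matrix(df[, setdiff(names(df), required), drop = FALSE])
  check_that(nrow(df) == 0L || is.numeric(feats),
             "non-numeric feature values in ", path)
  structure(list(time_ms = as.integer(df$time_ms),
                 left_label = as.integer(df$left_label),
                 right_label = as.integer(df$right_label),
                 features = feats),
            class = "labeled_stream")
}

#' Write / read the ground-truth sidecar
#'
#' Per-sample true phases of a synthetic recording, used as the oracle when
#' checking the FSR labeling chain.
#'
#' @param recording a `motion_recording`.
#' @param path file path.
#' @return `read_ground_truth()` returns a data.frame with `time_ms`,
#'   `truth_left`, `truth_right`.
#' @export
write_ground_truth <- function(recording, path) {
  utils::write.csv(data.frame(time_ms = recording$time_ms,
                              truth_left = recording$truth_left,
                              truth_right = recording$truth_right),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  utils::read.csv(path)
}

run_config_defaults <- function(preset = "desk") {
  list(
    preset = preset,
    seed = 1L,
    simulate = list(n_subjects = 5L, duration_s = 60,
                    speed_mps = c(0.8, 1.4)),
    window = list(width_samples = 14L, height_features = 22L,
                  stride_samples = 1L, slo_ratio = 0.3),
    augmentation = list(amplitude_factor = 0.1, n_copies = 0L,
                        noise_kind = "bounded-white"),
    cnn = list(filter_height = 3L, filter_width = 3L, preset = preset),
    train = list(preset = preset),
    split = list(train_frac = 0.6),
    max_windows = if (preset == "desk") 10000L else Inf
  )
}

#' Read a run configuration
#'
#' A single YAML (or JSON) document controlling a full pipeline run. Known
#' top-level keys: `preset` (`"desk"` or `"paper"`), `seed`, `simulate`,
#' `window`, `augmentation`, `cnn`, `train`, `split`, `max_windows`. Unknown
#' keys (at the top level or inside a section) are rejected rather than
#' silently ignored.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param preset preset applied before file overrides.
#' @return named list of validated configuration values.
#' @export
read_run_config <- function(path = NULL, preset = "desk") {
  cfg <- run_config_defaults(preset)
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  if (!is.null(user$preset)) cfg <- run_config_defaults(user$preset)
  bad <- setdiff(names(user), names(cfg))
  check_that(length(bad) == 0L,
             "unknown configuration key(s): ", paste(bad, collapse = ", "))
  for (k in names(user)) {
    if (is.list(cfg[[k]]) && is.list(user[[k]])) {
      inner_bad <- setdiff(names(user[[k]]), names(cfg[[k]]))
      check_that(length(inner_bad) == 0L, "unknown key(s) in '", k, "': ",
                 paste(inner_bad, collapse = ", "))
      cfg[[k]][names(user[[k]])] <- user[[k]]
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  cfg
}
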