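# Sliding-window label overlapping (SLO): fixed-width windows are cut from a
# labeled multichannel time series with stride 1 (10 ms at 100 Hz). A window
# that spans a label transition contains several labels; the SLO ratio decides
# which label the whole window receives. Windows holding three or more
# distinct labels are outliers and are dropped. Kept windows are rescaled to
# [0,1] grayscale images for the CNN.

#' Sliding-window configuration
#'
#' Holds the window geometry and the label-overlap ratio. The ratio is
#' converted to a sample count `r = round(slo_ratio * width_samples)`
#' (half-up), the minimum number of most-recent samples a newly appeared
#' label must occupy for the window to take that label: at width 14 the
#' ratios 0.3, 0.5 and 0.7 give r = 4, 7 and 10.
#'
#' @param width_samples window width in samples (default 14).
#' @param height_features number of feature rows per window (default 22).
#' @param stride_samples shift between consecutive windows (default 1, i.e.
#'   10 ms at 100 Hz).
#' @param slo_ratio label-overlap ratio in (0, 1] (default 0.3).
#' @param fs_hz sampling rate (default 100).
#' @return object of class `window_config` with the derived field `r`.
#' @export
#' @examples
#' window_config(slo_ratio = 0.7)$r  # 10
window_config <- function(width_samples = 14L, height_features = 22L,
                          stride_samples = 1L, slo_ratio = 0.3,
                          fs_hz = 100) {
  check_that(width_samples >= 1L, "width_samples must be >= 1")
  check_that(height_features >= 1L, "height_features must be >= 1")
  check_that(stride_samples >= 1L, "stride_samples must be >= 1")
  check_that(slo_ratio > 0 && slo_ratio <= 1,
             "slo_ratio must lie in (0, 1]")
  r <- as.integer(round_half_up(slo_ratio * width_samples))
  r <- min(max(r, 1L), as.integer(width_samples))
  structure(list(width_samples = as.integer(width_samples),
                 height_features = as.integer(height_features),
                 stride_samples = as.integer(stride_samples),
                 slo_ratio = slo_ratio, r = r, fs_hz = fs_hz),
            class = "window_config")
}

#' @export
print.window_config <- function(x, ...) {
  cat(sprintf(
    "<window_config> %dx%d (features x samples), stride %d, ratio %.2f (r = %d) @ %g Hz\n",
    x$height_features, x$width_samples, x$stride_samples, x$slo_ratio, x$r,
    x$fs_hz))
  invisible(x)
}

#' Merge the toe-off phase into heel off
#'
#' Toe off occupies only ~1.6% of a gait cycle, so nearly every window
#' containing it also touches its neighbours and would be discarded as an
#' outlier. The merge relabels every TO sample as HO, leaving the four final
#' classes SW, HS, FC, HO. The merge direction is configurable.
#'
#' @param labels integer phase-code vector.
#' @param from,to codes merged (default TO into HO).
#' @return relabeled integer vector; never contains `from`.
#' @export
#' @examples
#' phase_name(merge_phases(phase_code(c("FC", "HO", "TO", "TO", "SW"))))
merge_phases <- function(labels, from = PHASES[["TO"]], to = PHASES[["HO"]]) {
  labels[labels == from] <- to
  labels
}

#' Extract sliding windows from a labeled frame sequence
#'
#' Cuts every width-`w` window at the configured stride from a feature matrix
#' and its per-sample label vector. Each window carries the transposed feature
#' block (features x samples), its label subsequence, and its start timestamp.
#'
#' @param features n x height matrix (rows = samples, columns = channels).
#' @param labels integer label vector of length n.
#' @param config a [window_config()].
#' @param time_ms optional integer timestamps; defaults to
#'   `0, 1000/fs, 2000/fs, ...` ms.
#' @return list of `sliding_window` objects (fields `features`, `label_seq`,
#'   `start_ms`); length `floor((n - width) / stride) + 1`.
#' @export
extract_windows <- function(features, labels, config = window_config(),
                            time_ms = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  w <- config$width_samples
  check_that(n >= w, "stream too short: need at least ", w,
             " frames, got ", n)
  check_that(length(labels) == n, "labels must have one entry per frame")
  check_that(ncol(features) == config$height_features,
             "feature count ", ncol(features), " != configured height ",
             config$height_features)
  if (is.null(time_ms)) time_ms <- as.integer(round((seq_len(n) - 1L) *
                                                      1000 / config$fs_hz))
  starts <- seq.int(1L, n - w + 1L, by = config$stride_samples)
  lapply(starts, function(s) {
    idx <- s:(s + w - 1L)
    structure(list(features = t(features[idx, , drop = FALSE]),
                   label_seq = labels[idx],
                   start_ms = time_ms[s]),
              class = "sliding_window")
  })
}

#' Assign a class to a label-overlapped window
#'
#' Implements the overlap rule on one (already phase-merged) label sequence:
#' \itemize{
#'   \item three or more distinct labels: the window is an outlier (`NA`);
#'   \item one distinct label: that label;
#'   \item two distinct labels: the window takes the newest label (the one at
#'     the window's end) if the terminal contiguous run of that label is at
#'     least `r` samples long, otherwise it keeps the older label.
#' }
#' `r` is therefore the recency-evidence threshold: how many of the most
#' recent samples a newly appearing label must cover before it represents the
#' window.
#'
#' @param window a `sliding_window` or a plain integer label sequence.
#' @param r overlap sample count (see [window_config()]).
#' @return integer phase code, or `NA_integer_` for an outlier window.
#' @export
#' @examples
#' assign_window_label(rep(phase_code(c("FC", "HO")), c(10, 4)), r = 4)  # HO
#' assign_window_label(rep(phase_code(c("FC", "HO")), c(12, 2)), r = 4)  # FC
assign_window_label <- function(window, r) {
  seq <- if (inherits(window, "sliding_window")) window$label_seq else window
  w <- length(seq)
  check_that(r >= 1 && r <= w, "r must lie in [1, window width]")
  distinct <- unique(seq)
  if (length(distinct) >= 3L) return(NA_integer_)
  if (length(distinct) == 1L) return(distinct)
  newest <- seq[w]
  run <- rle(seq)
  terminal_run <- run$lengths[length(run$lengths)]
  if (terminal_run >= r) newest else distinct[distinct != newest]
}

# vectorized assignment over a label matrix (rows = windows); returns
# NA for outliers; identical rule to assign_window_label()
assign_labels_matrix <- function(labmat, r) {
  nw <- nrow(labmat)
  w <- ncol(labmat)
  classes <- sort(unique(as.vector(labmat)))
  present <- vapply(classes, function(cl) rowSums(labmat == cl) > 0L,
                    logical(nw))
  if (nw == 1L) present <- matrix(present, nrow = 1L)
  ndistinct <- rowSums(present)
  newest <- labmat[, w]
  # terminal run length of the newest label
  eq <- labmat == newest
  run <- eq[, w]
  terminal <- as.integer(run)
  if (w >= 2L) for (j in (w - 1L):1L) {
    run <- run & eq[, j]
    terminal <- terminal + run
  }
  out <- rep(NA_integer_, nw)
  uniform <- ndistinct == 1L
  out[uniform] <- newest[uniform]
  two <- ndistinct == 2L
  take_new <- two & terminal >= r
  out[take_new] <- newest[take_new]
  take_old <- two & terminal < r
  if (any(take_old)) {
    # the older label is the one just before the terminal run
    idx <- cbind(which(take_old), w - terminal[take_old])
    out[take_old] <- labmat[idx]
  }
  out
}

#' Convert a window to a grayscale image
#'
#' Linear min-max rescaling of the whole window to \[0, 1\] (the grayscale
#' conversion applied per window, not globally): the window minimum maps to 0
#' and the maximum to 1. A constant window, where the map is undefined, is
#' encoded as all zeros.
#'
#' @param window a `sliding_window` or a numeric matrix (features x samples).
#' @return numeric matrix of the same shape with values in \[0, 1\].
#' @export
#' @examples
#' window_to_image(matrix(c(-2, 0, 2), 1))  # 0, 0.5, 1
window_to_image <- function(window) {
  x <- if (inherits(window, "sliding_window")) window$features else window
  x <- as.matrix(x)
  check_that(all(is.finite(x)), "window contains non-finite values")
  rng <- range(x)
  if (rng[1L] == rng[2L]) return(array(0, dim(x)))
  (x - rng[1L]) / (rng[2L] - rng[1L])
}

#' Build a window-image dataset from a labeled stream
#'
#' Runs the full SLO pipeline: merge TO into HO, extract all sliding windows,
#' assign each window a class by the overlap rule, drop outlier windows
#' (three or more distinct labels), and rescale each kept window to a
#' \[0, 1\]
#' grayscale image. Implemented vectorized so that minute-scale recordings
#' (tens of thousands of windows) are processed in seconds.
#'
#' @param features n x height matrix of (standardized) feature channels.
#' @param labels integer phase-code vector of length n (raw five-phase labels;
#'   the merge is applied internally).
#' @param config a [window_config()].
#' @param merge apply the TO-to-HO merge first (default TRUE).
#' @return object of class `slo_dataset`: list with `images` (array
#'   height x width x kept), `labels` (integer codes), `start_ms`, `config`,
#'   and `counts` (`extracted`, `dropped`, `kept`).
#' @export
build_window_dataset <- function(features, labels, config = window_config(),
                                 merge = TRUE) {
  features <- as.matrix(features)
  n <- nrow(features)
  w <- config$width_samples
  h <- config$height_features
  check_that(n >= w, "stream too short: need at least ", w, " frames")
  check_that(length(labels) == n, "labels must have one entry per frame")
  check_that(ncol(features) == h, "feature count ", ncol(features),
             " != configured height ", h)
  check_that(all(is.finite(features)), "features contain non-finite values")
  if (merge) labels <- merge_phases(labels)

  starts <- seq.int(1L, n - w + 1L, by = config$stride_samples)
  nw <- length(starts)
  offs <- 0L:(w - 1L)
  labmat <- matrix(labels[rep(starts, times = w) + rep(offs, each = nw)],
                   nw, w)
  assigned <- assign_labels_matrix(labmat, config$r)
  keep <- which(!is.na(assigned))

  # windows as rows of a (kept x h*w) matrix, column-major within window:
  # entry (i, (j-1)*h + k) = channel k at sample j of window i
  ks <- starts[keep]
  nk <- length(ks)
  W <- matrix(0, nk, h * w)
  for (j in seq_len(w)) {
    W[, ((j - 1L) * h + 1L):(j * h)] <- features[ks + (j - 1L), , drop = FALSE]
  }
  # per-window min-max rescale to [0,1]; constant windows become zeros
  mn <- W[, 1L]; mx <- W[, 1L]
  if (ncol(W) > 1L) for (j in 2L:ncol(W)) {
    mn <- pmin(mn, W[, j]); mx <- pmax(mx, W[, j])
  }
  span <- mx - mn
  const <- span == 0
  span[const] <- 1
  W <- (W - mn) / span
  if (any(const)) W[const, ] <- 0

  images <- array(t(W), dim = c(h, w, nk))
  time_ms <- as.integer(round((starts - 1L) * 1000 / config$fs_hz))
  structure(list(images = images,
                 labels = assigned[keep],
                 start_ms = time_ms[keep],
                 config = config,
                 counts = list(extracted = nw, dropped = nw - nk, kept = nk)),
            class = "slo_dataset")
}

#' @export
print.slo_dataset <- function(x, ...) {
  cat(sprintf("<slo_dataset> %d images %dx%d (dropped %d/%d outlier windows)\n",
              x$counts$kept, dim(x$images)[1L], dim(x$images)[2L],
              x$counts$dropped, x$counts$extracted))
  tab <- table(factor(phase_name(x$labels), levels = names(PHASES)[1:4]))
  cat("  class histogram:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Save / load an SLO dataset as delimited text
#'
#' The dataset is written as a flat CSV: one row per window, columns
#' `label`, `start_ms`, then the `height x width` pixels in column-major
#' order (`px_0001`...), plus a JSON sidecar `<path>.meta.json` holding the
#' window configuration fingerprint. Ordering is deterministic.
#'
#' @param dataset an `slo_dataset`.
#' @param path CSV file path.
#' @return `read_slo_dataset()` returns the restored `slo_dataset`;
#'   `write_slo_dataset()` returns `path` invisibly.
#' @export
write_slo_dataset <- function(dataset, path) {
  check_that(inherits(dataset, "slo_dataset"), "not an slo_dataset")
  d <- dim(dataset$images)
  flat <- matrix(dataset$images, d[3L], d[1L] * d[2L], byrow = TRUE)
  colnames(flat) <- sprintf("px_%04d", seq_len(ncol(flat)))
  df <- data.frame(label = dataset$labels, start_ms = dataset$start_ms, flat,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- c(unclass(dataset$config), dataset$counts)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_slo_dataset
#' @export
read_slo_dataset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  cfg <- window_config(meta$width_samples, meta$height_features,
                       meta$stride_samples, meta$slo_ratio, meta$fs_hz)
  h <- cfg$height_features; w <- cfg$width_samples
  px <- as.matrix(df[, grep("^px_", names(df)), drop = FALSE])
  nk <- nrow(df)
  structure(list(images = array(t(px), dim = c(h, w, nk)),
                 labels = as.integer(df$label),
                 start_ms = as.integer(df$start_ms),
                 config = cfg,
                 counts = list(extracted = meta$extracted,
                               dropped = meta$dropped, kept = meta$kept)),
            class = "slo_dataset")
}
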