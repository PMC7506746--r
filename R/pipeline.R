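# End-to-end pipeline: synthetic recordings -> FSR labeling ->
# (optional augmentation) -> standardization -> SLO window images ->
# train/test split -> CNN -> metrics. One seed controls every stage.

#' Run the full gait-phase pipeline on synthetic walks
#'
#' Simulates several subjects walking at different speeds, labels each
#' recording from its FSR traces, standardizes the feature channels,
#' builds the SLO window-image dataset per recording (windows never span
#' recording boundaries), pools and optionally subsamples the windows,
#' splits them 60/40, trains the CNN, and evaluates the held-out part
#' together with the majority-class baseline.
#'
#' Standardization is fitted on the pooled simulated frames (the training
#' material) and would be reused, not refitted, for any later validation
#' stream. With `augment_copies > 0`, noisy copies of every recording are
#' added to the pool before windowing, mirroring an
#' augment-first / standardize-after ordering.
#'
#' @param seed integer master seed for generation, subsampling, splitting
#'   and model training.
#' @param n_subjects number of simulated subjects (default 5).
#' @param duration_s seconds of walking per subject (default 60).
#' @param speed_range speeds assigned evenly across subjects (m/s).
#' @param config a [window_config()] (default: width 14, ratio 0.3).
#' @param cnn a [cnn_config()] (default: desk preset, 3x3 filters).
#' @param spec a [train_spec()]; its seed is replaced by `seed`.
#' @param augment an [augmentation_spec()] or `NULL` (default) to skip
#'   augmentation.
#' @param augment_copies copies per recording when `augment` is given.
#' @param max_windows cap on pooled windows, applied by seeded subsampling
#'   to keep desk-scale runs fast (default 10000; `Inf` disables).
#' @param train_frac training fraction of the split (default 0.6).
#' @param verbose print per-stage progress.
#' @return list with `model` (a fitted `gait_cnn`), `metrics`
#'   (held-out [evaluate_model()] output), `baseline_accuracy` (majority
#'   class frequency in the held-out part), `counts` (frames, windows
#'   extracted/dropped/kept/used), `standardization`, and the configs.
#' @export
run_end_to_end <- function(seed = 1L, n_subjects = 5L, duration_s = 60,
                           speed_range = c(0.8, 1.4),
                           config = window_config(slo_ratio = 0.3),
                           cnn = cnn_config(3L, 3L),
                           spec = train_spec(),
                           augment = NULL, augment_copies = 0L,
                           max_windows = 10000L, train_frac = 0.6,
                           verbose = FALSE) {
  seed <- as.integer(seed)
  speeds <- seq(speed_range[1L], speed_range[2L], length.out = n_subjects)
  say <- function(...) if (verbose) message(sprintf(...))

  recs <- lapply(seq_len(n_subjects), function(i) {
    profile <- make_gait_profile(seed * 1000L + i, speed_mps = speeds[i])
    simulate_walk(profile, duration_s, fs_hz = config$fs_hz)
  })
  n_frames <- sum(vapply(recs, function(r) nrow(r$features), numeric(1)))
  say("simulated %d subjects, %d frames", n_subjects, n_frames)

  # labeled feature streams (FSR-derived labels for the right foot, whose
  # motion the feature panel follows)
  streams <- lapply(recs, function(rec) {
    list(features = rec$features, labels = label_stream(rec)$right)
  })
  if (!is.null(augment) && augment_copies > 0L) {
    aug <- list()
    for (k in seq_along(streams)) {
      sp <- augmentation_spec(augment$amplitude_factor, augment_copies,
                              augment$noise_kind, seed = seed + 17L * k)
      copies <- augment_series(streams[[k]]$features, sp)
      aug <- c(aug, lapply(copies, function(f)
        list(features = f, labels = streams[[k]]$labels)))
    }
    streams <- c(streams, aug)
    say("augmented to %d streams", length(streams))
  }

  params <- fit_standardization(do.call(rbind, lapply(streams, `[[`,
                                                      "features")))
  datasets <- lapply(streams, function(s)
    build_window_dataset(apply_standardization(s$features, params),
                         s$labels, config))
  images <- do.call(abind3, lapply(datasets, `[[`, "images"))
  labels <- unlist(lapply(datasets, `[[`, "labels"))
  counts <- list(
    frames = n_frames,
    extracted = sum(vapply(datasets, function(d) d$counts$extracted,
                           numeric(1))),
    dropped = sum(vapply(datasets, function(d) d$counts$dropped,
                         numeric(1))),
    kept = length(labels))
  say("windows: %d extracted, %d outliers dropped, %d kept",
      counts$extracted, counts$dropped, counts$kept)

  if (is.finite(max_windows) && counts$kept > max_windows) {
    sel <- with_seed(seed + 7L, sort(sample.int(counts$kept,
                                                as.integer(max_windows))))
    images <- images[, , sel, drop = FALSE]
    labels <- labels[sel]
  }
  counts$used <- length(labels)

  parts <- split_dataset(length(labels), train_frac = train_frac,
                         seed = seed + 11L)
  spec$seed <- seed + 13L
  model <- fit_gait_cnn(images[, , parts$train, drop = FALSE],
                        labels[parts$train],
                        test_x = images[, , parts$test, drop = FALSE],
                        test_y = labels[parts$test],
                        config = cnn, spec = spec, verbose = verbose)
  metrics <- evaluate_model(model, images[, , parts$test, drop = FALSE],
                            labels[parts$test])
  train_metrics <- evaluate_model(model, images[, , parts$train,
                                                drop = FALSE],
                                  labels[parts$train])
  baseline <- max(table(labels[parts$test])) / length(parts$test)
  say("held-out accuracy %.4f (majority baseline %.4f)",
      metrics$accuracy, baseline)

  list(model = model, metrics = metrics, train_metrics = train_metrics,
       baseline_accuracy = as.numeric(baseline),
       counts = counts, standardization = params,
       config = config, cnn = cnn, spec = spec,
       n_train = length(parts$train), n_test = length(parts$test))
}

# bind 3-d arrays along the third dimension
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1L]])
  n3 <- sum(vapply(arrs, function(a) dim(a)[3L], numeric(1)))
  array(unlist(arrs, use.names = FALSE), dim = c(d[1L], d[2L], n3))
}

#' Desk-scale Taguchi evaluator
#'
#' Returns an evaluator for [run_taguchi_experiments()] that, for each L9
#' run, rebuilds the SLO dataset at the run's ratio, trains the desk-preset
#' CNN with the run's filter size, and reports train/test accuracy on the
#' synthetic split plus "validation" accuracy on a freshly simulated subject
#' unseen during training (all in percent). A full L9 sweep trains nine
#' models; size the durations accordingly.
#'
#' @param duration_s seconds of walking per training subject.
#' @param n_subjects training subjects per run.
#' @param max_windows window cap per run.
#' @param val_duration_s seconds of validation walking.
#' @return `function(slo_ratio, filter_width, filter_height, seed)` giving
#'   `c(train=, test=, val=)` accuracies in percent.
#' @export
desk_evaluator <- function(duration_s = 20, n_subjects = 2L,
                           max_windows = 3000L, val_duration_s = 20) {
  function(slo_ratio, filter_width, filter_height, seed) {
    cfg <- window_config(slo_ratio = slo_ratio)
    res <- run_end_to_end(seed = seed, n_subjects = n_subjects,
                          duration_s = duration_s,
                          config = cfg,
                          cnn = cnn_config(filter_height, filter_width),
                          max_windows = max_windows)
    # validation: a subject (seed offset) never seen during training
    vp <- make_gait_profile(seed * 1000L + 999L, speed_mps = 1.3)
    vrec <- simulate_walk(vp, val_duration_s, fs_hz = cfg$fs_hz)
    vfeat <- apply_standardization(vrec$features, res$standardization)
    vds <- build_window_dataset(vfeat, label_stream(vrec)$right, cfg)
    vm <- evaluate_model(res$model, vds)
    c(train = 100 * res$train_metrics$accuracy,
      test = 100 * res$metrics$accuracy,
      val = 100 * vm$accuracy)
  }
}
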