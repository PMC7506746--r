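#' CNN architecture configuration
#'
#' Describes the window-image classifier: three convolution blocks, each a
#' same-padded stride-1 convolution with ReLU followed by 2x2 average
#' pooling, then a ReLU dense layer with dropout and a softmax output over
#' the four phase classes. Filter height/width are the Taguchi factors; the
#' remaining sizes come in two presets: `"desk"` (filters 8/16/32, dense 64)
#' sized for CPU-scale experiments, and `"paper"` (filters 32/64/128,
#' dense 128) matching a full-scale run.
#'
#' @param filter_height,filter_width convolution filter dims (default 3x3).
#' @param preset `"desk"` or `"paper"`.
#' @param n_conv_layers number of conv+pool blocks (default 3).
#' @param filters_per_layer integer vector, one entry per conv layer.
#' @param dense_units width of the fully connected hidden layer.
#' @param dropout_rate dropout on the dense hidden layer (default 0.3).
#' @param n_classes output classes (default 4: SW, HS, FC, HO).
#' @return object of class `cnn_config`.
#' @export
cnn_config <- function(filter_height = 3L, filter_width = 3L,
                       preset = c("desk", "paper"),
                       n_conv_layers = 3L,
                       filters_per_layer = NULL,
                       dense_units = NULL,
                       dropout_rate = 0.3,
                       n_classes = 4L) {
  preset <- match.arg(preset)
  filters_per_layer <- filters_per_layer %||%
    switch(preset, desk = c(8L, 16L, 32L), paper = c(32L, 64L, 128L))
  dense_units <- dense_units %||% switch(preset, desk = 64L, paper = 128L)
  check_that(filter_height >= 1L && filter_width >= 1L,
             "filter dims must be positive")
  check_that(filter_height %% 2L == 1L && filter_width %% 2L == 1L,
             "filter dims must be odd for symmetric same-padding")
  check_that(length(filters_per_layer) == n_conv_layers,
             "filters_per_layer must have one entry per conv layer")
  check_that(dropout_rate >= 0 && dropout_rate < 1,
             "dropout_rate must lie in [0, 1)")
  structure(list(n_conv_layers = as.integer(n_conv_layers),
                 filter_shape = c(as.integer(filter_height),
                                  as.integer(filter_width)),
                 filters_per_layer = as.integer(filters_per_layer),
                 dense_units = as.integer(dense_units),
                 dropout_rate = dropout_rate,
                 n_classes = as.integer(n_classes),
                 preset = preset),
            class = "cnn_config")
}

#' Training specification
#'
#' Optimization settings for [fit_gait_cnn()]: adaptive-moment (Adam)
#' optimizer on categorical cross-entropy, learning-rate reduction on plateau
#' of the monitored (test) loss, and early stopping. The `"paper"` preset
#' uses batch 4000 and up to 10,000 epochs; the `"desk"` preset (default)
#' uses batch 256 and up to 200 epochs with short patiences, sized for a
#' single CPU.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param learning_rate initial learning rate (default 0.001).
#' @param batch_size minibatch size.
#' @param max_epochs epoch cap.
#' @param plateau_factor multiplier applied to the learning rate after a
#'   plateau (default 0.5).
#' @param plateau_patience epochs without improvement before the reduction.
#' @param early_stop_patience epochs without improvement tolerated before
#'   stopping (0 stops at the first non-improving epoch).
#' @param min_delta minimum loss decrease counted as improvement.
#' @param seed integer seed controlling initialization, shuffling, dropout.
#' @return object of class `train_spec`.
#' @export
train_spec <- function(preset = c("desk", "paper"),
                       learning_rate = 0.001,
                       batch_size = NULL, max_epochs = NULL,
                       plateau_factor = 0.5, plateau_patience = NULL,
                       early_stop_patience = NULL,
                       min_delta = 1e-4, seed = 1L) {
  preset <- match.arg(preset)
  batch_size <- batch_size %||% switch(preset, desk = 256L, paper = 4000L)
  max_epochs <- max_epochs %||% switch(preset, desk = 200L, paper = 10000L)
  plateau_patience <- plateau_patience %||%
    switch(preset, desk = 3L, paper = 10L)
  early_stop_patience <- early_stop_patience %||%
    switch(preset, desk = 6L, paper = 50L)
  check_that(learning_rate > 0 && batch_size >= 1 && max_epochs >= 1,
             "learning_rate, batch_size and max_epochs must be positive")
  check_that(plateau_factor > 0 && plateau_factor < 1,
             "plateau_factor must lie in (0, 1)")
  check_that(early_stop_patience >= 0, "early_stop_patience must be >= 0")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 early_stop_patience = as.integer(early_stop_patience),
                 min_delta = min_delta, seed = as.integer(seed),
                 preset = preset),
            class = "train_spec")
}

#' Build (initialize) the window-image CNN
#'
#' Instantiates the architecture for a given input shape with seeded
#' He-normal weights, without training. Mostly useful to inspect layer shapes
#' and the parameter count; [fit_gait_cnn()] builds its network internally.
#'
#' @param config a [cnn_config()].
#' @param input_shape `c(height, width)` of the input images (default 22x14).
#' @param seed integer seed for weight initialization.
#' @return object of class `gait_cnn_net` with fields `net` (weights),
#'   `config`, `input_shape`, `n_params`, `shapes`.
#' @export
#' @examples
#' build_cnn(cnn_config())$n_params
build_cnn <- function(config = cnn_config(), input_shape = c(22L, 14L),
                      seed = 1L) {
  check_that(inherits(config, "cnn_config"), "config must be a cnn_config()")
  net <- init_network(config, input_shape, seed)
  structure(list(net = net, config = config,
                 input_shape = as.integer(input_shape),
                 n_params = net$n_params, shapes = net$shapes),
            class = "gait_cnn_net")
}

#' @export
print.gait_cnn_net <- function(x, ...) {
  cat(sprintf("<gait_cnn_net> input %dx%d, %d parameters\n",
              x$input_shape[1L], x$input_shape[2L], x$n_params))
  cat(paste0("  ", x$shapes, collapse = "\n"), "\n")
  cat(sprintf("  dense(%d, ReLU) -> dropout(%.1f) -> dense(%d, softmax)\n",
              x$config$dense_units, x$config$dropout_rate,
              x$config$n_classes))
  invisible(x)
}

# normalize x/y input: accepts an slo_dataset or (array, labels)
as_image_batch <- function(x, y = NULL) {
  if (inherits(x, "slo_dataset")) {
    list(X = x$images, y = x$labels)
  } else {
    x <- if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
    check_that(is.array(x) && length(dim(x)) == 3L,
               "images must be a height x width x n array or an slo_dataset")
    list(X = x, y = y)
  }
}

#' Fit the gait-phase CNN
#'
#' Trains the window-image classifier by minibatch Adam on categorical
#' cross-entropy, monitoring the test set (or the training loss when no test
#' set is given) for learning-rate reduction on plateau and early stopping.
#' The weights from the best monitored epoch are restored at the end. With a
#' fixed seed the whole run is reproducible.
#'
#' @param x training images: an `slo_dataset` or a height x width x n array.
#' @param y integer phase codes (ignored when `x` is an `slo_dataset`).
#' @param test_x,test_y held-out monitoring set, same forms as `x`/`y`.
#' @param config a [cnn_config()].
#' @param spec a [train_spec()].
#' @param verbose print one line per epoch.
#' @return object of class `gait_cnn` with the trained weights, the class
#'   code table, and a `history` data.frame (per-epoch learning rate,
#'   train/test loss and accuracy).
#' @export
fit_gait_cnn <- function(x, y = NULL, test_x = NULL, test_y = NULL,
                         config = cnn_config(), spec = train_spec(),
                         verbose = FALSE) {
  tr <- as_image_batch(x, y)
  X <- tr$X; ylab <- as.integer(tr$y)
  check_that(!is.null(ylab) && length(ylab) == dim(X)[3L],
             "need one label per training image")
  classes <- sort(unique(ylab))
  check_that(length(classes) == config$n_classes,
             "training set has ", length(classes), " classes, model expects ",
             config$n_classes, " (every class must be represented)")
  y_idx <- match(ylab, classes)
  h <- dim(X)[1L]; w <- dim(X)[2L]; n <- dim(X)[3L]
  dim(X) <- c(h, w, 1L, n)

  has_test <- !is.null(test_x)
  if (has_test) {
    te <- as_image_batch(test_x, test_y)
    Xt <- te$X
    yt <- match(as.integer(te$y), classes)
    check_that(!anyNA(yt), "test labels outside the training classes")
    check_that(length(yt) == dim(Xt)[3L], "need one label per test image")
    dim(Xt) <- c(h, w, 1L, dim(Xt)[3L])
  }

  net <- init_network(config, c(h, w), spec$seed)
  params <- net_param_list(net)
  opt <- adam_init(params)
  lr <- spec$learning_rate
  best <- Inf
  best_params <- params
  since_improve <- 0L
  since_plateau <- 0L
  hist <- vector("list", spec$max_epochs)
  stopped <- spec$max_epochs

  with_seed(spec$seed + 1L, {
    for (epoch in seq_len(spec$max_epochs)) {
      perm <- sample.int(n)
      bl <- 0; ba <- 0; nb <- 0L
      for (s in seq.int(1L, n, by = spec$batch_size)) {
        idx <- perm[s:min(s + spec$batch_size - 1L, n)]
        Xb <- X[, , , idx, drop = FALSE]
        yb <- y_idx[idx]
        net <- net_set_params(net, params)
        mask <- if (config$dropout_rate > 0) {
          matrix(stats::runif(config$dense_units * length(idx)) >=
                   config$dropout_rate, config$dense_units, length(idx))
        } else NULL
        fwd <- net_forward(net, config, Xb, training = TRUE,
                           dropout_mask = mask)
        la <- ce_loss_acc(fwd$probs, yb)
        g <- net_backward(net, config, fwd, yb, dropout_mask = mask)
        step <- adam_step(params, grad_param_list(g), opt, lr)
        params <- step$params; opt <- step$state
        bl <- bl + la$loss * length(idx); ba <- ba + la$acc * length(idx)
        nb <- nb + length(idx)
      }
      train_loss <- bl / nb; train_acc <- ba / nb
      net <- net_set_params(net, params)
      if (has_test) {
        Pt <- net_predict_probs(net, config, Xt)
        mt <- ce_loss_acc(Pt, yt)
        monitor <- mt$loss
      } else {
        mt <- list(loss = NA_real_, acc = NA_real_)
        monitor <- train_loss
      }
      hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                  train_loss = train_loss,
                                  train_acc = train_acc,
                                  test_loss = mt$loss, test_acc = mt$acc)
      if (verbose) {
        cat(sprintf(
          "epoch %3d lr %.2g train loss %.4f acc %.4f test loss %.4f acc %.4f\n",
          epoch, lr, train_loss, train_acc, mt$loss, mt$acc))
      }
      if (monitor < best - spec$min_delta) {
        best <- monitor
        best_params <- params
        since_improve <- 0L
        since_plateau <- 0L
      } else {
        since_improve <- since_improve + 1L
        since_plateau <- since_plateau + 1L
        if (since_improve > spec$early_stop_patience) {
          stopped <- epoch
          break
        }
        if (since_plateau >= spec$plateau_patience) {
          lr <- lr * spec$plateau_factor
          since_plateau <- 0L
        }
      }
      stopped <- epoch
    }
  })

  net <- net_set_params(net, best_params)
  structure(list(net = net, config = config, spec = spec,
                 classes = classes, input_shape = c(h, w),
                 n_params = net$n_params,
                 history = do.call(rbind, hist[!vapply(hist, is.null,
                                                       logical(1))]),
                 stopped_epoch = stopped),
            class = "gait_cnn")
}

#' @export
print.gait_cnn <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<gait_cnn> %d parameters, classes {%s}\n", x$n_params,
              paste(phase_name(x$classes), collapse = ", ")))
  cat(sprintf("  trained %d epoch(s); final train acc %.4f, test acc %s\n",
              x$stopped_epoch, last$train_acc,
              ifelse(is.na(last$test_acc), "-",
                     sprintf("%.4f", last$test_acc))))
  invisible(x)
}

#' @export
summary.gait_cnn <- function(object, ...) {
  print(object)
  cat(sprintf("  input %dx%d, filters %s, dense %d, dropout %.1f\n",
              object$input_shape[1L], object$input_shape[2L],
              paste(object$config$filters_per_layer, collapse = "/"),
              object$config$dense_units, object$config$dropout_rate))
  cat(sprintf("  lr schedule: %.2g -> %.2g (%d reduction(s))\n",
              object$history$lr[1L], object$history$lr[nrow(object$history)],
              length(unique(object$history$lr)) - 1L))
  invisible(object)
}

#' Predict gait phases for window images
#'
#' @param object a fitted [fit_gait_cnn()] model.
#' @param newdata an `slo_dataset`, a height x width x n array, or one
#'   height x width matrix.
#' @param type `"class"` for integer phase codes, `"prob"` for the n x K
#'   probability matrix. Ties are broken toward the lowest class code.
#' @param ... unused.
#' @return integer codes or a probability matrix with one row per image.
#' @importFrom stats predict
#' @export
predict.gait_cnn <- function(object, newdata, type = c("class", "prob"),
                             ...) {
  type <- match.arg(type)
  nb <- as_image_batch(newdata)
  X <- nb$X
  check_that(dim(X)[1L] == object$input_shape[1L] &&
               dim(X)[2L] == object$input_shape[2L],
             "image shape ", dim(X)[1L], "x", dim(X)[2L],
             " does not match model input ", object$input_shape[1L], "x",
             object$input_shape[2L])
  n <- dim(X)[3L]
  dim(X) <- c(dim(X)[1L], dim(X)[2L], 1L, n)
  P <- net_predict_probs(object$net, object$config, X)
  if (type == "prob") {
    out <- t(P)
    colnames(out) <- phase_name(object$classes)
    return(out)
  }
  object$classes[max.col(t(P), ties.method = "first")]
}

#' Evaluate a fitted model
#'
#' Computes the confusion matrix (rows = true class, columns = predicted),
#' per-class accuracies (diagonal over row sums), overall accuracy (trace
#' over total), and the macro mean of the per-class accuracies, which is the
#' headline "total" figure used for validation-set reporting.
#'
#' @param model a fitted `gait_cnn`.
#' @param x images (`slo_dataset` or array).
#' @param y integer phase codes (ignored when `x` is an `slo_dataset`).
#' @return list with `confusion`, `per_class_accuracy`, `accuracy`,
#'   `macro_accuracy`, `n`.
#' @export
evaluate_model <- function(model, x, y = NULL) {
  nb <- as_image_batch(x, y)
  ylab <- as.integer(nb$y)
  check_that(length(ylab) > 0, "evaluation set is empty")
  check_that(all(ylab %in% model$classes),
             "labels outside the model's classes: ",
             paste(setdiff(ylab, model$classes), collapse = ", "))
  pred <- predict(model, nb$X, type = "class")
  classification_metrics(ylab, pred, model$classes)
}

#' Classification metrics from label vectors
#'
#' @param true,pred integer class-code vectors.
#' @param classes class codes fixing the confusion-matrix order.
#' @return list with `confusion`, `per_class_accuracy`, `accuracy`,
#'   `macro_accuracy`, `n`.
#' @export
classification_metrics <- function(true, pred,
                                   classes = sort(unique(c(true, pred)))) {
  lv <- phase_name(classes)
  confusion <- table(true = factor(phase_name(true), levels = lv),
                     pred = factor(phase_name(pred), levels = lv))
  per_class <- diag(confusion) / pmax(rowSums(confusion), 1L)
  list(confusion = confusion,
       per_class_accuracy = per_class,
       accuracy = sum(diag(confusion)) / length(true),
       macro_accuracy = mean(per_class),
       n = length(true))
}

#' Predict the phase of a single window image
#'
#' @param model a fitted `gait_cnn`.
#' @param image one height x width matrix (a [window_to_image()] output).
#' @return list with `phase` (integer code), `name`, and `prob` (named
#'   probability vector).
#' @export
predict_phase <- function(model, image) {
  check_that(is.matrix(image), "image must be a single matrix")
  p <- predict(model, image, type = "prob")[1L, ]
  k <- which.max(p)   # which.max takes the first maximum: lowest class code
  list(phase = model$classes[k], name = phase_name(model$classes[k]),
       prob = p)
}

#' Plot training history
#'
#' Two panels: loss and accuracy per epoch for the training and monitoring
#' sets.
#'
#' @param x a fitted `gait_cnn`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.gait_cnn <- function(x, ...) {
  h <- x$history
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::matplot(h$epoch, cbind(h$train_loss, h$test_loss), type = "l",
                    lty = 1, col = c("black", "red3"), xlab = "epoch",
                    ylab = "cross-entropy loss", main = "model loss", ...)
  graphics::legend("topright", c("train", "test"), lty = 1,
                   col = c("black", "red3"), bty = "n")
  graphics::matplot(h$epoch, cbind(h$train_acc, h$test_acc), type = "l",
                    lty = 1, col = c("black", "red3"), xlab = "epoch",
                    ylab = "accuracy", main = "model accuracy", ...)
  graphics::legend("bottomright", c("train", "test"), lty = 1,
                   col = c("black", "red3"), bty = "n")
  invisible(x)
}

#' Serialize / restore a fitted model as JSON
#'
#' Weights, configuration, class table and history are written to one JSON
#' document (text, full precision), so a trained model can be reused on
#' later validation streams.
#'
#' @param model a fitted `gait_cnn`.
#' @param path file path.
#' @return `read_gait_cnn()` returns the restored model; `write_gait_cnn()`
#'   returns `path` invisibly.
#' @export
write_gait_cnn <- function(model, path) {
  check_that(inherits(model, "gait_cnn"), "not a gait_cnn model")
  params <- net_param_list(model$net)
  ser <- lapply(params, function(p)
    list(dim = dim(p) %||% length(p), values = as.numeric(p)))
  doc <- list(config = unclass(model$config), spec = unclass(model$spec),
              classes = model$classes, input_shape = model$input_shape,
              params = ser, history = model$history,
              stopped_epoch = model$stopped_epoch)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_gait_cnn
#' @export
read_gait_cnn <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(cnn_config, c(
    list(filter_height = doc$config$filter_shape[1L],
         filter_width = doc$config$filter_shape[2L],
         preset = doc$config$preset,
         n_conv_layers = doc$config$n_conv_layers,
         filters_per_layer = doc$config$filters_per_layer,
         dense_units = doc$config$dense_units,
         dropout_rate = doc$config$dropout_rate,
         n_classes = doc$config$n_classes)))
  spec <- train_spec(preset = doc$spec$preset,
                     learning_rate = doc$spec$learning_rate,
                     batch_size = doc$spec$batch_size,
                     max_epochs = doc$spec$max_epochs,
                     plateau_factor = doc$spec$plateau_factor,
                     plateau_patience = doc$spec$plateau_patience,
                     early_stop_patience = doc$spec$early_stop_patience,
                     min_delta = doc$spec$min_delta, seed = doc$spec$seed)
  net <- init_network(cfg, doc$input_shape, seed = 0L)
  params <- lapply(doc$params, function(p) {
    if (length(p$dim) > 1L) array(p$values, p$dim) else p$values
  })
  net <- net_set_params(net, params)
  structure(list(net = net, config = cfg, spec = spec,
                 classes = as.integer(doc$classes),
                 input_shape = as.integer(doc$input_shape),
                 n_params = net$n_params,
                 history = as.data.frame(doc$history),
                 stopped_epoch = doc$stopped_epoch),
            class = "gait_cnn")
}
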