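#' Noise-augmentation specification
#'
#' Parameters of the additive-noise augmentation. For a feature series
#' `S`, the noise amplitude is `a = (max(|S|) - |mean(S)|) * amplitude_factor`,
#' so a series whose extreme magnitude equals its mean magnitude (e.g. a
#' constant series) receives zero noise. Two noise kinds are supported:
#' `"bounded-white"` adds i.i.d. uniform noise on `[-a, a]` (white noise whose
#' excursion never exceeds the amplitude), and `"signed-offset"` adds exactly
#' `+a` or `-a` to the whole series, alternating sign across copies.
#'
#' @param amplitude_factor non-negative scale applied to the amplitude term
#'   (default 0.1).
#' @param n_copies number of augmented copies per input series (default 25,
#'   i.e. a ~26-fold dataset including the originals).
#' @param noise_kind `"bounded-white"` or `"signed-offset"`.
#' @param seed integer seed for the bounded-white draws.
#' @return object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(amplitude_factor = 0.1, n_copies = 25L,
                              noise_kind = c("bounded-white", "signed-offset"),
                              seed = 1L) {
  check_that(amplitude_factor >= 0, "amplitude_factor must be >= 0")
  check_that(n_copies >= 0, "n_copies must be >= 0")
  structure(list(amplitude_factor = amplitude_factor,
                 n_copies = as.integer(n_copies),
                 noise_kind = match.arg(noise_kind),
                 seed = as.integer(seed)),
            class = "augmentation_spec")
}

#' Augment a feature series with bounded noise
#'
#' Produces `n_copies` noisy copies of a series (vector) or of each column of
#' a matrix, with per-series amplitude
#' `a = (max(|S|) - |mean(S)|) * amplitude_factor`. Every copy satisfies
#' `|copy - S| <= a` elementwise.
#'
#' @param S numeric vector (one series) or matrix (one series per column).
#' @param spec an [augmentation_spec()].
#' @return list of `n_copies` objects shaped like `S`.
#' @export
#' @examples
#' augment_series(c(1, 2, 3),
#'   augmentation_spec(noise_kind = "signed-offset", n_copies = 1))
#' # [[1]] = c(1.1, 2.1, 3.1): amplitude (3 - 2) * 0.1 = 0.1
augment_series <- function(S, spec = augmentation_spec()) {
  check_that(length(S) > 0, "series must be non-empty")
  check_that(all(is.finite(S)), "series must be finite")
  X <- if (is.matrix(S)) S else matrix(S, ncol = 1L)
  a <- apply(X, 2L, function(col) max(abs(col)) - abs(mean(col))) *
    spec$amplitude_factor
  a <- pmax(a, 0)
  shape <- function(M) if (is.matrix(S)) M else drop(M)
  if (spec$n_copies == 0L) return(list())
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_copies), function(k) {
      noise <- switch(spec$noise_kind,
        "signed-offset" = matrix(rep(if (k %% 2L == 1L) a else -a,
                                     each = nrow(X)), nrow(X), ncol(X)),
        "bounded-white" = matrix(stats::runif(length(X), -1, 1), nrow(X),
                                 ncol(X)) * rep(a, each = nrow(X)))
      shape(X + noise)
    })
  })
}

#' Fit standardization parameters
#'
#' Computes per-column means and population standard deviations (divisor `N`,
#' not `N - 1`) of a feature matrix. Constant columns are rejected because a
#' zero standard deviation makes the rescaling undefined.
#'
#' @param X numeric matrix, rows = observations, columns = features.
#' @return object of class `standardization_params` with fields `mean`,
#'   `sigma`, `n_fit`.
#' @export
#' @examples
#' p <- fit_standardization(cbind(a = c(1, 2, 3)))
#' p$sigma  # sqrt(2/3) ~= 0.8165
fit_standardization <- function(X) {
  X <- as.matrix(X)
  check_that(nrow(X) >= 2L, "need at least 2 rows to fit standardization")
  check_that(all(is.finite(X)), "feature matrix must be finite")
  mu <- colMeans(X)
  sigma <- sqrt(colMeans(sweep(X, 2L, mu)^2))   # population form
  zero <- which(sigma <= 0)
  check_that(length(zero) == 0L,
             "constant feature column(s): ",
             paste(zero, collapse = ", "),
             " (zero variance cannot be standardized)")
  structure(list(mean = mu, sigma = sigma, n_fit = nrow(X)),
            class = "standardization_params")
}

#' Apply standardization
#'
#' Rescales each column to `(x - mean) / sigma` using parameters fitted with
#' [fit_standardization()]. Validation/test data must be transformed with the
#' training-set parameters, never refitted.
#'
#' @param X numeric matrix with the same column count as the fitted params.
#' @param params a `standardization_params` object.
#' @return standardized matrix of the same shape.
#' @export
apply_standardization <- function(X, params) {
  check_that(inherits(params, "standardization_params"),
             "params must come from fit_standardization()")
  X <- as.matrix(X)
  check_that(ncol(X) == length(params$mean),
             "dimension mismatch: matrix has ", ncol(X),
             " columns, params expect ", length(params$mean))
  sweep(sweep(X, 2L, params$mean), 2L, params$sigma, `/`)
}

#' Invert standardization
#'
#' @param Z standardized matrix.
#' @param params a `standardization_params` object.
#' @return matrix on the original scale.
#' @export
invert_standardization <- function(Z, params) {
  check_that(inherits(params, "standardization_params"),
             "params must come from fit_standardization()")
  sweep(sweep(as.matrix(Z), 2L, params$sigma, `*`), 2L, params$mean, `+`)
}

#' @export
print.standardization_params <- function(x, ...) {
  cat(sprintf("<standardization_params> %d features, fitted on %d rows\n",
              length(x$mean), x$n_fit))
  invisible(x)
}

#' Persist / restore standardization parameters as JSON
#'
#' @param params a `standardization_params` object.
#' @param path file path.
#' @return `read_standardization()` returns the restored object;
#'   `write_standardization()` returns `path` invisibly.
#' @export
write_standardization <- function(params, path) {
  check_that(inherits(params, "standardization_params"),
             "params must come from fit_standardization()")
  jsonlite::write_json(list(mean = params$mean, sigma = params$sigma,
                            n_fit = params$n_fit),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_standardization
#' @export
read_standardization <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = as.numeric(obj$mean), sigma = as.numeric(obj$sigma),
                 n_fit = as.integer(obj$n_fit)),
            class = "standardization_params")
}

#' Split a dataset into training and test parts
#'
#' Seeded uniform shuffle split into disjoint, exhaustive index sets. With
#' `stratify` supplied, the split is performed within each class so that class
#' proportions carry over.
#'
#' @param n number of items, or a vector/list of items whose length is used.
#' @param train_frac fraction assigned to training (default 0.6).
#' @param seed integer seed.
#' @param stratify optional vector of class labels of length `n`.
#' @return list with integer index vectors `train` and `test`.
#' @export
#' @examples
#' s <- split_dataset(100, train_frac = 0.6, seed = 7)
#' length(s$train)  # 60
split_dataset <- function(n, train_frac = 0.6, seed = 1L, stratify = NULL) {
  if (!is.numeric(n) || length(n) != 1L) n <- length(n)
  n <- as.integer(n)
  check_that(n >= 1L, "cannot split an empty dataset")
  check_that(train_frac > 0 && train_frac < 1,
             "train_frac must lie strictly between 0 and 1")
  with_seed(seed, {
    if (is.null(stratify)) {
      perm <- sample.int(n)
      k <- round_half_up(train_frac * n)
      k <- min(max(k, 1L), n - 1L)
      train <- sort(perm[seq_len(k)])
    } else {
      check_that(length(stratify) == n, "stratify must have length ", n)
      train <- sort(unlist(lapply(split(seq_len(n), stratify), function(idx) {
        perm <- sample(idx)
        k <- round_half_up(train_frac * length(idx))
        perm[seq_len(min(max(k, 1L), length(idx)))]
      }), use.names = FALSE))
    }
    list(train = train, test = setdiff(seq_len(n), train))
  })
}
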