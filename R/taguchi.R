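# L9(3^3) orthogonal-array sensitivity analysis over the three tunable
# factors of the pipeline: SLO ratio, convolution filter width, convolution
# filter height. Responses are larger-the-better accuracies (%); the primary
# statistic is the plain level average, with an optional larger-the-better
# signal-to-noise ratio.

#' L9(3^3) orthogonal design
#'
#' The standard 9-run array for three factors at three levels: each level
#' appears exactly three times per factor, and every ordered factor pair
#' covers all nine level combinations exactly once.
#'
#' @param slo_ratios,filter_widths,filter_heights the three level triples
#'   (defaults: ratios 0.3/0.5/0.7, filter dims 3/5/7).
#' @return object of class `taguchi_design`: list with `factors`, `levels`
#'   (named list of value triples) and `array` (9 x 3 level-index matrix).
#' @export
#' @examples
#' l9_design()$array[4, ]  # run 4: levels (2, 1, 2)
l9_design <- function(slo_ratios = c(0.3, 0.5, 0.7),
                      filter_widths = c(3L, 5L, 7L),
                      filter_heights = c(3L, 5L, 7L)) {
  check_that(length(slo_ratios) == 3L && length(filter_widths) == 3L &&
               length(filter_heights) == 3L,
             "each factor needs exactly three levels")
  arr <- matrix(c(1L, 1L, 1L,
                  1L, 2L, 2L,
                  1L, 3L, 3L,
                  2L, 1L, 2L,
                  2L, 2L, 3L,
                  2L, 3L, 1L,
                  3L, 1L, 3L,
                  3L, 2L, 1L,
                  3L, 3L, 2L), nrow = 9L, byrow = TRUE)
  colnames(arr) <- c("slo_ratio", "filter_width", "filter_height")
  structure(list(factors = colnames(arr),
                 levels = list(slo_ratio = slo_ratios,
                               filter_width = filter_widths,
                               filter_height = filter_heights),
                 array = arr),
            class = "taguchi_design")
}

#' @export
print.taguchi_design <- function(x, ...) {
  cat("<taguchi_design> L9(3^3)\n")
  for (f in x$factors) {
    cat(sprintf("  %s: %s\n", f, paste(x$levels[[f]], collapse = ", ")))
  }
  print(x$array)
  invisible(x)
}

#' Factor values for one design run
#'
#' @param design a [l9_design()].
#' @param run run index 1..9.
#' @return named list with the factor values of that run.
#' @export
design_run_values <- function(design, run) {
  check_that(run >= 1 && run <= nrow(design$array), "run out of range")
  lv <- design$array[run, ]
  stats::setNames(lapply(design$factors, function(f)
    design$levels[[f]][lv[[f]]]), design$factors)
}

#' Run the L9 experiments
#'
#' Calls `evaluator` once per design row, in array order, with the factor
#' values of that row and a per-run seed derived from `seed`. The evaluator
#' must return the three larger-the-better responses (train, test and
#' validation accuracy, in percent); a failing evaluator records `NA` for
#' that run and the analysis functions refuse incomplete tables.
#'
#' @param design a [l9_design()].
#' @param evaluator `function(slo_ratio, filter_width, filter_height, seed)`
#'   returning a numeric vector with elements `train`, `test`, `val`.
#' @param seed integer base seed; run `i` receives `seed + i`.
#' @return object of class `taguchi_response`: data.frame with columns `run`,
#'   the three level indices, `train`, `test`, `val`, carrying the design as
#'   attribute `"design"`.
#' @export
run_taguchi_experiments <- function(design, evaluator, seed = 1L) {
  check_that(inherits(design, "taguchi_design"), "design must be l9_design()")
  rows <- lapply(seq_len(nrow(design$array)), function(i) {
    vals <- design_run_values(design, i)
    resp <- tryCatch(
      evaluator(slo_ratio = vals$slo_ratio,
                filter_width = vals$filter_width,
                filter_height = vals$filter_height,
                seed = as.integer(seed) + i),
      error = function(e) {
        warning("run ", i, " failed: ", conditionMessage(e), call. = FALSE)
        c(train = NA_real_, test = NA_real_, val = NA_real_)
      })
    data.frame(run = i,
               slo_ratio = design$array[i, 1L],
               filter_width = design$array[i, 2L],
               filter_height = design$array[i, 3L],
               train = as.numeric(resp[["train"]]),
               test = as.numeric(resp[["test"]]),
               val = as.numeric(resp[["val"]]))
  })
  out <- do.call(rbind, rows)
  attr(out, "design") <- design
  class(out) <- c("taguchi_response", class(out))
  out
}

#' Assemble a response table from known values
#'
#' Builds a `taguchi_response` directly from response vectors, e.g. to
#' analyze a published table.
#'
#' @param train,test,val numeric vectors of length 9 (percent accuracies) in
#'   array order.
#' @param design a [l9_design()].
#' @return a `taguchi_response` data.frame.
#' @export
taguchi_response_table <- function(train, test, val, design = l9_design()) {
  check_that(length(train) == 9L && length(test) == 9L && length(val) == 9L,
             "responses must have one value per design run")
  out <- data.frame(run = 1:9,
                    slo_ratio = design$array[, 1L],
                    filter_width = design$array[, 2L],
                    filter_height = design$array[, 3L],
                    train = as.numeric(train), test = as.numeric(test),
                    val = as.numeric(val))
  attr(out, "design") <- design
  class(out) <- c("taguchi_response", class(out))
  out
}

#' Worked-example L9 response table
#'
#' The accuracies (percent) reported for the nine SLO-ratio x filter-size
#' combinations in a published gait-phase classification experiment at full
#' scale (window width 14 at 100 Hz, batch 4000). Distributed as a worked
#' example for the level-average analysis; these numbers are inputs, not
#' outputs of this package.
#'
#' @return a `taguchi_response` data.frame with 9 rows.
#' @export
#' @examples
#' level_averages(example_response_table(), "val")["slo_ratio", 1]
example_response_table <- function() {
  taguchi_response_table(
    train = c(99.97, 100, 99.99, 99.90, 99.87, 99.86, 99.99, 99.99, 99.90),
    test = c(99.84, 99.88, 99.86, 99.48, 99.33, 99.35, 99.49, 99.51, 99.32),
    val = c(84.80, 79.40, 79.29, 78.23, 76.96, 77.55, 78.77, 81.41, 74.92))
}

check_complete <- function(table, response) {
  check_that(inherits(table, "taguchi_response"),
             "table must be a taguchi_response")
  check_that(response %in% c("train", "test", "val"),
             "response must be one of train, test, val")
  check_that(!anyNA(table[[response]]),
             "incomplete response table: run(s) ",
             paste(which(is.na(table[[response]])), collapse = ", "),
             " missing")
  invisible(TRUE)
}

#' Level-average analysis
#'
#' Averages a larger-the-better response over the three runs at each level of
#' each factor. Because the design is balanced, each factor's level averages
#' share the same grand mean.
#'
#' @param table a `taguchi_response`.
#' @param response `"train"`, `"test"` or `"val"`.
#' @return 3 x 3 numeric matrix, rows = factors, columns = levels.
#' @export
level_averages <- function(table, response = "val") {
  check_complete(table, response)
  y <- table[[response]]
  design <- attr(table, "design")
  out <- t(vapply(design$factors, function(f)
    vapply(1:3, function(l) mean(y[table[[f]] == l]), numeric(1)),
    numeric(3)))
  dimnames(out) <- list(design$factors, paste0("level", 1:3))
  out
}

#' Select the best factor levels
#'
#' Picks, per factor, the level with the highest average response (ties go to
#' the lower level index) and reports the matching design run when the
#' selected triple appears in the array.
#'
#' @inheritParams level_averages
#' @return list with `best_levels` (named integer vector), `best_values`
#'   (factor values), `run` (matching array row or `NA`), and the
#'   `level_averages` matrix.
#' @export
select_best <- function(table, response = "val") {
  avg <- level_averages(table, response)
  best <- apply(avg, 1L, which.max)   # which.max: first max = lowest level
  design <- attr(table, "design")
  arr <- design$array
  hit <- which(arr[, 1L] == best[1L] & arr[, 2L] == best[2L] &
                 arr[, 3L] == best[3L])
  list(best_levels = best,
       best_values = stats::setNames(lapply(design$factors, function(f)
         design$levels[[f]][best[[f]]]), design$factors),
       run = if (length(hit)) hit[1L] else NA_integer_,
       level_averages = avg)
}

#' Larger-the-better signal-to-noise ratio
#'
#' `-10 log10(mean(1/y^2))`, the Taguchi S/N statistic for responses where
#' larger is better. Provided as a secondary statistic; the primary analysis
#' uses plain level averages.
#'
#' @param y positive numeric responses.
#' @return S/N ratio in dB.
#' @export
sn_larger_better <- function(y) {
  check_that(all(y > 0), "larger-the-better S/N needs positive responses")
  -10 * log10(mean(1 / y^2))
}

#' Plot level averages
#'
#' One panel per factor: mean response at each level, the standard
#' level-average sensitivity display.
#'
#' @param x a `taguchi_response`.
#' @param response response column to plot.
#' @param ... passed to [graphics::plot()].
#' @export
plot.taguchi_response <- function(x, response = "val", ...) {
  avg <- level_averages(x, response)
  design <- attr(x, "design")
  old <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(old))
  for (f in design$factors) {
    graphics::plot(1:3, avg[f, ], type = "b", pch = 19, xaxt = "n",
                   xlab = f, ylab = paste("mean", response, "[%]"),
                   main = f, ...)
    graphics::axis(1, at = 1:3, labels = design$levels[[f]])
  }
  invisible(x)
}

#' Read / write a response table as CSV
#'
#' Column layout: run, the three level indices, then the train/test/val
#' accuracies in percent.
#'
#' @param table a `taguchi_response`.
#' @param path file path.
#' @param design design used to re-attach levels on read.
#' @return `read_response_table()` returns a `taguchi_response`;
#'   `write_response_table()` returns `path` invisibly.
#' @export
write_response_table <- function(table, path) {
  check_that(inherits(table, "taguchi_response"),
             "table must be a taguchi_response")
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_response_table
#' @export
read_response_table <- function(path, design = l9_design()) {
  df <- utils::read.csv(path)
  out <- taguchi_response_table(df$train, df$test, df$val, design = design)
  check_that(all(out$slo_ratio == df$slo_ratio) &&
               all(out$filter_width == df$filter_width) &&
               all(out$filter_height == df$filter_height),
             "level columns in ", path, " do not match the L9 array")
  out
}
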