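#' Regression metrics for torque prediction
#'
#' `nrmse` is the root-mean-squared error normalized by the range of the true
#' series, in percent; `pearson_r` the sample Pearson correlation; and
#' `r_squared` the coefficient of determination `1 - SSE/SST` (which can be
#' negative for predictors worse than the mean). All three are invariant
#' under a common positive rescaling of both series, so they can be computed
#' on peak-normalized or physical-unit torque interchangeably.
#'
#' @param y True series.
#' @param yhat Predicted series, same length.
#' @return A single number: percent for `nrmse`, dimensionless otherwise.
#' @examples
#' y <- c(1, 2, 3, 4); yhat <- c(1.5, 2.5, 2.5, 3.5)
#' nrmse(y, yhat)      # 16.667
#' pearson_r(y, yhat)  # 0.94868
#' r_squared(y, yhat)  # 0.8
#' @name torque_metrics
NULL

check_series_pair <- function(y, yhat, min_len = 2L) {
  if (length(y) != length(yhat)) stop("length mismatch", call. = FALSE)
  if (length(y) < min_len) stop("series too short", call. = FALSE)
  stop_if_not_finite(y, "y"); stop_if_not_finite(yhat, "yhat")
}

#' @rdname torque_metrics
#' @export
nrmse <- function(y, yhat) {
  check_series_pair(y, yhat)
  rng <- max(y) - min(y)
  if (rng <= 0) stop("true series is constant (zero range)", call. = FALSE)
  100 * sqrt(mean((y - yhat)^2)) / rng
}

#' @rdname torque_metrics
#' @export
pearson_r <- function(y, yhat) {
  check_series_pair(y, yhat)
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0) {
    stop("zero variance in a series", call. = FALSE)
  }
  stats::cor(y, yhat)
}

#' @rdname torque_metrics
#' @export
r_squared <- function(y, yhat) {
  check_series_pair(y, yhat)
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) stop("true series is constant (zero SST)", call. = FALSE)
  1 - sum((y - yhat)^2) / sst
}

#' Cycle index of every row on the 100 Hz grid
#'
#' @param n_rows Number of rows.
#' @param boundaries 0-based cycle start indices including the end index.
#' @return Integer vector: 1-based cycle number per row.
#' @export
row_cycles <- function(n_rows, boundaries) {
  stopifnot(all(diff(boundaries) > 0))
  findInterval(seq_len(n_rows) - 1L, boundaries[-length(boundaries)])
}

#' Leave-one-cycle-out split of a supervised set
#'
#' Assigns every supervised sample to the training set (all of its input rows
#' and its target row lie in training cycles), the test set (all rows in the
#' held-out cycle), or drops it (the sample straddles the cycle cut). Dropping
#' from both sides guarantees that no test row leaks into any training
#' sample's window and vice versa.
#'
#' @param set A `supervised_set`.
#' @param cycles Cycle number per feature-matrix row (see [row_cycles()]).
#' @param test_cycle Cycle number held out for testing.
#' @return An object of class `cycle_split`: list with integer sample indices
#'   `train`, `test`, `dropped`, plus `train_cycles` and `test_cycle`.
#' @export
split_cycles <- function(set, cycles, test_cycle) {
  all_cycles <- sort(unique(cycles))
  if (!(test_cycle %in% all_cycles)) stop("test cycle out of range", call. = FALSE)
  if (length(all_cycles) < 2L) stop("need at least 2 cycles", call. = FALSE)
  n <- length(set$y)
  sample_cycles <- lapply(seq_len(n), function(k) {
    rows <- c(set$input_rows[k, "start"]:set$input_rows[k, "end"],
              set$target_row[k])
    unique(cycles[rows])
  })
  in_test <- vapply(sample_cycles, function(cl) all(cl == test_cycle), logical(1))
  in_train <- vapply(sample_cycles, function(cl) !(test_cycle %in% cl), logical(1))
  structure(
    list(train = which(in_train), test = which(in_test),
         dropped = which(!in_train & !in_test),
         train_cycles = setdiff(all_cycles, test_cycle),
         test_cycle = test_cycle),
    class = "cycle_split"
  )
}

#' @export
print.cycle_split <- function(x, ...) {
  cat(sprintf("Cycle split: test cycle %d; %d train / %d test / %d dropped samples\n",
              x$test_cycle, length(x$train), length(x$test), length(x$dropped)))
  invisible(x)
}

subset_supervised <- function(set, idx) {
  out <- set
  if (set$kind == "sequence") {
    out$x <- set$x[idx, , , drop = FALSE]
  } else {
    out$x <- set$x[idx, , drop = FALSE]
  }
  out$y <- set$y[idx]
  out$input_rows <- set$input_rows[idx, , drop = FALSE]
  out$target_row <- set$target_row[idx]
  out
}

#' Metrics table in the per-subject / average layout
#'
#' Appends an "average" row per joint x model, with each metric averaged
#' arithmetically over subjects.
#'
#' @param metrics Data frame with columns `subject`, `joint`, `model`,
#'   `nrmse`, `r`, `r2`.
#' @return The table with average rows appended.
#' @export
metrics_table <- function(metrics) {
  stopifnot(all(c("subject", "joint", "model", "nrmse", "r", "r2") %in%
                  names(metrics)))
  avg <- do.call(rbind, lapply(split(metrics, metrics[c("joint", "model")]),
    function(d) {
      data.frame(subject = "average", joint = d$joint[1], model = d$model[1],
                 nrmse = mean(d$nrmse), r = mean(d$r), r2 = mean(d$r2))
    }))
  metrics$subject <- as.character(metrics$subject)
  out <- rbind(metrics, avg)
  rownames(out) <- NULL
  out
}
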