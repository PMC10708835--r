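#' Zero-lag Butterworth band-pass filter
#'
#' Band-pass filters a raw sEMG channel with a Butterworth design applied
#' forward and backward (`signal::filtfilt`), cancelling the phase delay.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param low,high Band edges in Hz (0 < low < high < fs/2).
#' @param order Filter design order.
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_zero_lag <- function(x, fs, low = 20, high = 450, order = 4) {
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("need 0 < low < high < Nyquist", call. = FALSE)
  }
  if (length(x) < 6L * order) stop("signal too short to filter", call. = FALSE)
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

#' Analysis-window specification
#'
#' Time-domain features use a 150 ms (300-sample) window and frequency-domain
#' features a 128 ms (256-sample) window, both right-aligned (causal) and slid
#' with a hop of `fs / out_rate` samples so the feature series lands natively
#' on the output grid.
#'
#' @param td_len Time-domain window length in samples.
#' @param fd_len Frequency-domain window length in samples.
#' @param hop Hop between consecutive windows in samples.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(td_len = 300L, fd_len = 256L, hop = 20L) {
  if (hop < 1L) stop("hop must be >= 1", call. = FALSE)
  if (td_len < 3L || fd_len < 4L) stop("windows too short", call. = FALSE)
  structure(list(td_len = as.integer(td_len), fd_len = as.integer(fd_len),
                 hop = as.integer(hop)), class = "window_spec")
}

#' Overlapped-window feature extraction on one channel
#'
#' Slides the two analysis windows over a (filtered) sEMG channel and returns
#' the seven features per hop. Windows are right-aligned: the feature stamped
#' at time `t` uses only samples up to `t`, so a one-step-ahead prediction
#' from these features is causal. With the default hop of 20 samples at
#' 2000 Hz the output rate is 100 Hz, matching the kinematic grid.
#'
#' @param x Filtered channel samples.
#' @param fs Sampling rate in Hz.
#' @param spec A [window_spec()].
#' @return Data frame with `time` (s, end of each window) and columns
#'   `mav, rms, zc, ssc, wl, mnf, mdf`.
#' @export
extract_features <- function(x, fs = 2000, spec = window_spec()) {
  n <- length(x)
  wmax <- max(spec$td_len, spec$fd_len)
  if (n < wmax) stop("channel shorter than the largest window", call. = FALSE)
  # first window end aligned to the hop grid so timestamps land on the
  # output-rate grid
  e0 <- as.integer(ceiling(wmax / spec$hop) * spec$hop)
  ends <- seq.int(e0, n, by = spec$hop)
  out <- matrix(0, length(ends), 7L,
                dimnames = list(NULL, emg_feature_names()))
  for (i in seq_along(ends)) {
    e <- ends[i]
    out[i, ] <- emg_features(td = x[(e - spec$td_len + 1L):e],
                             fd = x[(e - spec$fd_len + 1L):e],
                             fs = fs)
  }
  data.frame(time = ends / fs, out)
}

#' Assemble the 38-dimensional input matrix
#'
#' Joins per-muscle feature series and the joint-angle series on their common
#' time stamps, muscle-major (`GMX_mav ... GMX_mdf, RF_mav, ..., GC_mdf, hip,
#' knee, ankle`). Assembly is keyed by channel name, so the order in which the
#' feature tables are supplied does not matter. Rows are trimmed to time
#' stamps present in every series.
#'
#' @param features Named list of per-muscle feature data frames from
#'   [extract_features()].
#' @param angles Matrix of joint angles (columns hip, knee, ankle).
#' @param angle_time Time stamps of the angle rows (s).
#' @param muscles Muscle order for the output columns.
#' @return An object of class `feature_matrix`: list with `time` and the
#'   numeric `values` matrix (rows = time, 38 named columns).
#' @export
assemble_inputs <- function(features, angles, angle_time,
                            muscles = c("GMX", "RF", "BF", "TA", "GC")) {
  if (!all(muscles %in% names(features))) {
    stop("missing feature tables for: ",
         paste(setdiff(muscles, names(features)), collapse = ", "),
         call. = FALSE)
  }
  keys <- lapply(features[muscles], function(f) round(f$time * 1e6))
  akey <- round(angle_time * 1e6)
  common <- Reduce(intersect, c(keys, list(akey)))
  if (length(common) == 0) stop("no overlapping time stamps", call. = FALSE)
  common <- sort(common)
  blocks <- lapply(muscles, function(m) {
    f <- features[[m]]
    idx <- match(common, round(f$time * 1e6))
    v <- as.matrix(f[idx, emg_feature_names()])
    colnames(v) <- paste(m, emg_feature_names(), sep = "_")
    v
  })
  aidx <- match(common, akey)
  ang <- as.matrix(angles)[aidx, , drop = FALSE]
  colnames(ang) <- joint_names()
  values <- do.call(cbind, c(blocks, list(ang)))
  rownames(values) <- NULL
  structure(list(time = common / 1e6, values = values),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d rows x %d columns, t = [%.3f, %.3f] s\n",
              nrow(x$values), ncol(x$values), min(x$time), max(x$time)))
  invisible(x)
}

#' Peak normalization by column
#'
#' Divides every column by its maximum absolute value over the reference rows
#' (the training rows, to avoid test-set leakage). Normalization never changes
#' the sign of a value; constants are returned for the inverse transform.
#'
#' @param x Numeric matrix (or vector, treated as one column).
#' @param reference Row indices over which the constants are computed.
#' @return List with `values` (normalized matrix) and `constants` (named
#'   per-column maxima of the absolute values).
#' @export
normalize_columns <- function(x, reference = seq_len(nrow(as.matrix(x)))) {
  x <- as.matrix(x)
  if (length(reference) == 0) stop("reference rows are empty", call. = FALSE)
  constants <- apply(abs(x[reference, , drop = FALSE]), 2, max)
  if (any(constants == 0)) {
    stop("zero normalization constant in column(s): ",
         paste(colnames(x)[constants == 0], collapse = ", "), call. = FALSE)
  }
  list(values = sweep(x, 2, constants, "/"), constants = constants)
}

#' Invert [normalize_columns()]
#'
#' @param x Normalized matrix.
#' @param constants Per-column constants from [normalize_columns()].
#' @return Matrix on the original scale.
#' @export
denormalize_columns <- function(x, constants) {
  sweep(as.matrix(x), 2, constants, "*")
}

#' Build sequence samples for the LSTM
#'
#' Sample `k` stacks feature rows `k .. k + time_step - 1` and is paired with
#' the torque at row `k + time_step + horizon - 1`: with the defaults
#' (`time_step = 5`, `horizon = 1`, 100 Hz grid) the model sees 50 ms of
#' features and predicts the torque 10 ms ahead of the last observed sample.
#'
#' @param values Feature matrix (rows = time, columns = features).
#' @param target Torque series aligned to the rows of `values`.
#' @param time_step Sequence length in rows.
#' @param horizon Prediction horizon in rows (>= 1).
#' @return An object of class `supervised_set`: `x` (array N x time_step x d),
#'   `y` (length N), `input_rows` (N x 2 first/last row), `target_row`
#'   (length N), `kind = "sequence"`.
#' @export
make_sequences <- function(values, target, time_step = 5L, horizon = 1L) {
  values <- as.matrix(values)
  T_len <- nrow(values)
  stopifnot(length(target) == T_len)
  if (horizon < 1L) stop("horizon must be >= 1", call. = FALSE)
  n <- T_len - time_step - horizon + 1L
  if (n < 1L) stop("series too short for time_step + horizon", call. = FALSE)
  x <- array(0, c(n, time_step, ncol(values)),
             dimnames = list(NULL, NULL, colnames(values)))
  tgt_row <- integer(n)
  for (k in seq_len(n)) {
    x[k, , ] <- values[k:(k + time_step - 1L), ]
    tgt_row[k] <- k + time_step + horizon - 1L
  }
  structure(list(x = x, y = target[tgt_row],
                 input_rows = cbind(start = seq_len(n),
                                    end = seq_len(n) + time_step - 1L),
                 target_row = tgt_row, kind = "sequence"),
            class = "supervised_set")
}

#' Build one-step samples for the GPR
#'
#' Sample `k` is feature row `k` paired with the torque at row `k + horizon`:
#' the torque at the current time point is predicted from the features of the
#' previous time point, 10 ms ahead on the 100 Hz grid.
#'
#' @inheritParams make_sequences
#' @return A `supervised_set` with `x` a matrix (N x d), `kind = "pointwise"`.
#' @export
make_pointwise <- function(values, target, horizon = 1L) {
  values <- as.matrix(values)
  T_len <- nrow(values)
  stopifnot(length(target) == T_len)
  if (horizon < 1L) stop("horizon must be >= 1 (0 would pair a row with itself)",
                         call. = FALSE)
  n <- T_len - horizon
  if (n < 1L) stop("series too short", call. = FALSE)
  structure(list(x = values[seq_len(n), , drop = FALSE],
                 y = target[seq_len(n) + horizon],
                 input_rows = cbind(start = seq_len(n), end = seq_len(n)),
                 target_row = seq_len(n) + horizon, kind = "pointwise"),
            class = "supervised_set")
}

#' @export
print.supervised_set <- function(x, ...) {
  n <- length(x$y)
  cat(sprintf("Supervised set (%s): %d samples\n", x$kind, n))
  invisible(x)
}

#' Filter raw sEMG and extract all muscle feature tables
#'
#' Convenience wrapper: band-pass filters every channel of a trial and runs
#' [extract_features()] on each.
#'
#' @param trial A `gait_trial`.
#' @param filter_low,filter_high,filter_order Band-pass settings.
#' @param spec A [window_spec()].
#' @return Named list of per-muscle feature data frames.
#' @export
trial_features <- function(trial, filter_low = 20, filter_high = 450,
                           filter_order = 4, spec = window_spec()) {
  fs <- trial$config$emg_rate
  out <- lapply(colnames(trial$emg), function(m) {
    filt <- bandpass_zero_lag(trial$emg[, m], fs, filter_low, filter_high,
                              filter_order)
    extract_features(filt, fs, spec)
  })
  names(out) <- colnames(trial$emg)
  out
}
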