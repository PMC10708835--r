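#' Window features for surface EMG
#'
#' Classical time-domain descriptors of an sEMG analysis window: mean absolute
#' value (`mav`), root mean square (`rms`), zero-crossing count
#' (`zero_crossings`), slope-sign-change count (`slope_sign_changes`) and
#' waveform length (`waveform_length`).
#'
#' Zero crossings are counted as strict sign changes between adjacent samples
#' (`x[i] * x[i + 1] < 0`); slope sign changes as strict interior extrema
#' (`(x[i] - x[i - 1]) * (x[i] - x[i + 1]) > 0`). No amplitude deadband is
#' applied.
#'
#' @param x Numeric vector, the samples of one analysis window (finite values,
#'   length at least 2; `slope_sign_changes` needs at least 3).
#' @return A single number: signal units for `mav`, `rms` and
#'   `waveform_length`; a nonnegative integer count for `zero_crossings` and
#'   `slope_sign_changes`.
#' @examples
#' mav(c(1, -1, 2, -2))          # 1.5
#' rms(c(3, 4))                  # sqrt(12.5)
#' zero_crossings(c(1, -1, 1))   # 2
#' waveform_length(0:5)          # 5
#' @name emg_time_features
NULL

check_window <- function(x, min_len = 2L) {
  if (!is.numeric(x) || length(x) < min_len) {
    stop("window must be numeric with at least ", min_len, " samples",
         call. = FALSE)
  }
  stop_if_not_finite(x, "window")
}

#' @rdname emg_time_features
#' @export
mav <- function(x) {
  check_window(x)
  mean(abs(x))
}

#' @rdname emg_time_features
#' @export
rms <- function(x) {
  check_window(x)
  sqrt(mean(x^2))
}

#' @rdname emg_time_features
#' @export
zero_crossings <- function(x) {
  check_window(x)
  sum(x[-length(x)] * x[-1] < 0)
}

#' @rdname emg_time_features
#' @export
slope_sign_changes <- function(x) {
  check_window(x, min_len = 3L)
  n <- length(x)
  d1 <- x[2:(n - 1)] - x[1:(n - 2)]
  d2 <- x[2:(n - 1)] - x[3:n]
  sum(d1 * d2 > 0)
}

#' @rdname emg_time_features
#' @export
waveform_length <- function(x) {
  check_window(x)
  sum(abs(diff(x)))
}

#' One-sided periodogram of a signal window
#'
#' Raw (rectangular-window) periodogram used by the spectral features. The DC
#' bin is excluded; frequencies run from `fs / n` up to the Nyquist frequency.
#'
#' @param x Numeric vector of samples.
#' @param fs Sampling rate in Hz.
#' @return An object of class `power_spectrum`: a list with `freq` (Hz,
#'   strictly increasing) and `power` (nonnegative, arbitrary scale).
#' @export
power_spectrum <- function(x, fs) {
  check_window(x)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive", call. = FALSE)
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  m <- n %/% 2L
  out <- list(freq = (1:m) * fs / n, power = p[2:(m + 1L)])
  class(out) <- "power_spectrum"
  out
}

#' Mean and median frequency of an sEMG window
#'
#' `mean_frequency` is the power-weighted mean of the spectrum's frequencies;
#' `median_frequency` is the smallest spectral bin at which cumulative power
#' first reaches half the total power. Both accept either a raw numeric window
#' (a periodogram is computed via [power_spectrum()]) or a `power_spectrum`
#' object.
#'
#' @param x Numeric window or a `power_spectrum`.
#' @param fs Sampling rate in Hz (required for numeric input, ignored for a
#'   spectrum).
#' @return Frequency in Hz, within the range of the spectrum's frequencies.
#' @examples
#' s <- structure(list(freq = c(40, 120), power = c(1, 1)),
#'                class = "power_spectrum")
#' mean_frequency(s)    # 80
#' median_frequency(s)  # 40
#' @export
mean_frequency <- function(x, fs = NULL) {
  s <- as_power_spectrum(x, fs)
  tot <- sum(s$power)
  if (tot <= 0) stop("zero total power", call. = FALSE)
  sum(s$freq * s$power) / tot
}

#' @rdname mean_frequency
#' @export
median_frequency <- function(x, fs = NULL) {
  s <- as_power_spectrum(x, fs)
  tot <- sum(s$power)
  if (tot <= 0) stop("zero total power", call. = FALSE)
  cum <- cumsum(s$power)
  s$freq[which(cum >= tot / 2)[1L]]
}

as_power_spectrum <- function(x, fs) {
  if (inherits(x, "power_spectrum")) {
    stopifnot(length(x$freq) == length(x$power), all(x$power >= 0),
              all(diff(x$freq) > 0))
    return(x)
  }
  if (is.null(fs)) stop("fs is required for a raw signal window", call. = FALSE)
  power_spectrum(x, fs)
}

# The canonical feature order used throughout the package.
emg_feature_names <- function() {
  c("mav", "rms", "zc", "ssc", "wl", "mnf", "mdf")
}

#' All seven window features at once
#'
#' @param td Numeric vector, the time-domain window (default 300 samples).
#' @param fd Numeric vector, the frequency-domain window (default 256
#'   samples); defaults to `td`.
#' @param fs Sampling rate in Hz.
#' @return Named numeric vector `mav, rms, zc, ssc, wl, mnf, mdf`. The
#'   spectral features are `NaN` for a window with zero non-DC power (e.g. a
#'   constant window); the time-domain features are always defined.
#' @export
emg_features <- function(td, fd = td, fs) {
  s <- power_spectrum(fd, fs)
  if (sum(s$power) > 0) {
    mnf <- mean_frequency(s)
    mdf <- median_frequency(s)
  } else {
    mnf <- NaN
    mdf <- NaN
  }
  c(mav = mav(td), rms = rms(td), zc = zero_crossings(td),
    ssc = slope_sign_changes(td), wl = waveform_length(td),
    mnf = mnf, mdf = mdf)
}
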