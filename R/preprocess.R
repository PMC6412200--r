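#' Median-filter denoising
#'
#' Width-3 running median with replicated edges, removing isolated impulse
#' spikes while leaving constant and monotone stretches untouched. Offered as
#' an optional pre-filter for spiky raw streams; the default feature path
#' leaves it off because a median filter is nonlinear and does not commute
#' with axis rotation (see the methods vignette).
#'
#' @param x numeric vector, length >= 3.
#' @return filtered vector of the same length.
#' @export
denoise <- function(x) {
  if (length(x) < 3) stop("denoise requires at least 3 samples")
  as.numeric(stats::runmed(x, k = 3, endrule = "keep"))
}

#' Separate gravity and body acceleration
#'
#' Low-pass filters each accelerometer axis to isolate the quasi-static
#' gravity component; the body (dynamic) component is the residual, so the
#' decomposition is exact: `acc = gravity + body`. The filter is a 3rd-order
#' Butterworth applied forward-backward (zero phase), so gravity stays
#' aligned with the postures that generate it.
#'
#' @param acc numeric matrix `n x 3` of accelerometer axes.
#' @param fs sampling rate (Hz).
#' @param cutoff_hz low-pass cutoff; must be below the Nyquist frequency.
#' @param order Butterworth order.
#' @return list with matrices `gravity` and `body`, both `n x 3`.
#' @export
split_gravity <- function(acc, fs, cutoff_hz = 0.3, order = 3) {
  acc <- as.matrix(acc)
  if (ncol(acc) != 3) stop("acc must have 3 columns")
  if (cutoff_hz >= fs / 2) {
    stop("cutoff_hz (", cutoff_hz, ") must be below the Nyquist frequency ",
         fs / 2, " Hz")
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  # odd-reflection padding tames the forward-backward filter's edge
  # transients (the 0.3 Hz time constant spans seconds of signal)
  n <- nrow(acc)
  pad <- min(n - 1L, ceiling(3 * fs / cutoff_hz))
  gravity <- apply(acc, 2, function(col) {
    padded <- c(2 * col[1] - col[(pad + 1L):2],
                col,
                2 * col[n] - col[(n - 1L):(n - pad)])
    filtered <- signal::filtfilt(bf, padded)
    filtered[(pad + 1L):(pad + n)]
  })
  gravity <- matrix(gravity, ncol = 3, dimnames = dimnames(acc))
  list(gravity = gravity, body = acc - gravity)
}

#' Jerk (time derivative) of a triaxial signal
#'
#' First difference scaled by the sampling rate; the first value is repeated
#' so length is preserved.
#'
#' @param series3 numeric matrix `n x 3`.
#' @param fs sampling rate (Hz).
#' @return matrix `n x 3` in units of input per second.
#' @export
jerk <- function(series3, fs) {
  series3 <- as.matrix(series3)
  if (nrow(series3) < 2) stop("jerk requires at least 2 samples")
  d <- diff(series3) * fs
  rbind(d[1, , drop = FALSE], d)
}

#' Euclidean magnitude of a triaxial signal
#'
#' @param series3 numeric matrix `n x 3`.
#' @return numeric vector of per-sample Euclidean norms.
#' @export
magnitude <- function(series3) {
  series3 <- as.matrix(series3)
  sqrt(rowSums(series3^2))
}

#' Derive the full signal bundle from a recording
#'
#' Produces every source signal the feature manifests draw on: body and
#' gravity acceleration (low-pass separation), body jerk, and the Euclidean
#' magnitudes of the three triaxial signals.
#'
#' @param rec a [recording()].
#' @param cutoff_hz gravity low-pass cutoff (Hz).
#' @param median_filter apply [denoise()] to the raw accelerometer axes
#'   first. Off by default: the median filter breaks exact rotation
#'   invariance of the reduced features.
#' @return a list of class `"SignalBundle"` with elements `body_acc`,
#'   `gravity_acc`, `body_jerk` (matrices `n x 3`) and `mag_body_acc`,
#'   `mag_gravity_acc`, `mag_body_jerk` (vectors).
#' @export
signal_bundle <- function(rec, cutoff_hz = 0.3, median_filter = FALSE) {
  acc <- rec$data[, c("acc_x", "acc_y", "acc_z"), drop = FALSE]
  if (median_filter) acc <- apply(acc, 2, denoise)
  sg <- split_gravity(acc, rec$fs, cutoff_hz = cutoff_hz)
  bj <- jerk(sg$body, rec$fs)
  structure(
    list(body_acc = sg$body, gravity_acc = sg$gravity, body_jerk = bj,
         mag_body_acc = magnitude(sg$body),
         mag_gravity_acc = magnitude(sg$gravity),
         mag_body_jerk = magnitude(bj),
         fs = rec$fs),
    class = "SignalBundle"
  )
}

#' Extract one window from a signal bundle
#'
#' @param bundle a [signal_bundle()].
#' @param start 1-based start sample.
#' @param window_len window length in samples.
#' @return a list with the same signal names as the bundle, restricted to
#'   the window.
#' @export
bundle_window <- function(bundle, start, window_len = 68) {
  idx <- start:(start + window_len - 1L)
  list(
    body_acc = bundle$body_acc[idx, , drop = FALSE],
    gravity_acc = bundle$gravity_acc[idx, , drop = FALSE],
    body_jerk = bundle$body_jerk[idx, , drop = FALSE],
    mag_body_acc = bundle$mag_body_acc[idx],
    mag_gravity_acc = bundle$mag_gravity_acc[idx],
    mag_body_jerk = bundle$mag_body_jerk[idx],
    fs = bundle$fs
  )
}
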