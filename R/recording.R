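#' Canonical IMU channel names
#'
#' Channel order used throughout the package: accelerometer, gyroscope,
#' magnetometer, each as x/y/z. Recordings carry either the first 3
#' (accelerometer-only mode) or all 9 channels.
#'
#' @export
CANONICAL_CHANNELS <- c(
  "acc_x", "acc_y", "acc_z",
  "gyr_x", "gyr_y", "gyr_z",
  "mag_x", "mag_y", "mag_z"
)

#' Activity classes
#'
#' The five target classes: sitting/standing merged, laying, walking,
#' stairs up/down merged, and the transition state covering the first
#' seconds of every activity.
#'
#' @export
ACTIVITY_LEVELS <- c("SIT_STAND", "LAYING", "WALKING", "STAIRS", "TRANSITION")

#' Construct a Recording
#'
#' A `Recording` holds a subject's multichannel IMU stream sampled at a
#' constant nominal rate (25 Hz for the wearable devices targeted here),
#' plus minimal metadata. Accelerometer channels are mandatory; gyroscope
#' and magnetometer are present only in 9-channel mode (required by the
#' convolutional networks, unused by the feature-based classifier).
#'
#' @param data numeric matrix, one column per channel; column names must be
#'   drawn from [CANONICAL_CHANNELS]. Columns are reordered canonically.
#' @param subject_id character scalar.
#' @param device_kind one of `"WWS"`, `"WWBS"`, `"SYNTH"` (the two garment
#'   generations and the synthetic generator).
#' @param fs sampling rate in Hz.
#' @param t0 start time offset in seconds; sample `i` is at
#'   `t0 + (i - 1) / fs`.
#' @return an object of class `"Recording"`.
#' @export
recording <- function(data, subject_id = "anon", device_kind = "SYNTH",
                      fs = 25, t0 = 0) {
  data <- as.matrix(data)
  if (is.null(colnames(data))) {
    if (ncol(data) %in% c(3L, 9L)) {
      colnames(data) <- CANONICAL_CHANNELS[seq_len(ncol(data))]
    } else {
      stop("channel names required for a ", ncol(data), "-column recording")
    }
  }
  unknown <- setdiff(colnames(data), CANONICAL_CHANNELS)
  if (length(unknown) > 0) {
    stop("unknown channel name(s): ", paste(unknown, collapse = ", "))
  }
  keep <- CANONICAL_CHANNELS[CANONICAL_CHANNELS %in% colnames(data)]
  data <- data[, keep, drop = FALSE]
  if (!all(c("acc_x", "acc_y", "acc_z") %in% colnames(data))) {
    stop("accelerometer channels acc_x/acc_y/acc_z are required")
  }
  if (!ncol(data) %in% c(3L, 9L)) {
    stop("recordings must carry 3 (acc) or 9 (acc+gyr+mag) channels, got ",
         ncol(data))
  }
  if (nrow(data) < 1L) stop("recording must contain at least one sample")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be a positive number")
  device_kind <- match.arg(device_kind, c("WWS", "WWBS", "SYNTH"))
  structure(
    list(subject_id = as.character(subject_id), device_kind = device_kind,
         fs = fs, t0 = t0, data = data),
    class = "Recording"
  )
}

#' @export
print.Recording <- function(x, ...) {
  cat(sprintf(
    "Recording '%s' [%s]: %d samples x %d channels @ %g Hz (%.2f s)\n",
    x$subject_id, x$device_kind, nrow(x$data), ncol(x$data), x$fs,
    nrow(x$data) / x$fs))
  cat("  channels:", paste(colnames(x$data), collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples in a Recording
#' @param rec a [recording()].
#' @return integer sample count.
#' @export
n_samples <- function(rec) nrow(rec$data)

#' Read a recording from a delimited text file
#'
#' Expects a comma-separated file with a header row naming each channel
#' column (see [CANONICAL_CHANNELS]) and optionally a timestamp column `t`
#' in seconds. The timestamp column, when present, sets `t0` and is checked
#' for sampling gaps: any gap larger than `2/fs` raises a warning (the
#' stream is not resampled).
#'
#' @param path file path.
#' @param schema optional character vector restricting/declaring the channel
#'   columns expected in the file; unknown names are an error.
#' @param subject_id,device_kind,fs metadata passed to [recording()].
#' @return a [recording()].
#' @export
read_recording <- function(path, schema = NULL, subject_id = NULL,
                           device_kind = "SYNTH", fs = 25) {
  if (!is.null(schema)) {
    unknown <- setdiff(schema, CANONICAL_CHANNELS)
    if (length(unknown) > 0) {
      stop("schema contains unknown channel name(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  df <- utils::read.csv(path, check.names = FALSE)
  if (is.null(subject_id)) {
    subject_id <- sub("_rec$", "", sub("\\.[^.]*$", "", basename(path)))
  }
  t0 <- 0
  if ("t" %in% names(df)) {
    tt <- df[["t"]]
    t0 <- tt[1]
    if (length(tt) > 2 && any(diff(tt) > 2 / fs)) {
      warning("sampling gap larger than 2/fs detected in ", path)
    }
    df[["t"]] <- NULL
  }
  if (!is.null(schema)) {
    missing <- setdiff(schema, names(df))
    if (length(missing) > 0) {
      stop("file ", path, " lacks declared channel(s): ",
           paste(missing, collapse = ", "))
    }
    df <- df[schema]
  }
  bad <- !vapply(df, is.numeric, logical(1))
  if (any(bad)) {
    stop("malformed input: non-numeric channel column(s) ",
         paste(names(df)[bad], collapse = ", "))
  }
  recording(as.matrix(df), subject_id = subject_id,
            device_kind = device_kind, fs = fs, t0 = t0)
}

#' Write a recording to CSV
#'
#' Inverse of [read_recording()]: one column per channel in canonical order,
#' plus a leading timestamp column `t`.
#'
#' @param rec a [recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  t <- rec$t0 + (seq_len(nrow(rec$data)) - 1) / rec$fs
  df <- data.frame(t = t, rec$data, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
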