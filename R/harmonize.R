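#' Estimate the per-axis accelerometer baseline
#'
#' The two garment generations (WWS / WWBS) differ in their measurement
#' baseline, so recordings are mapped to a common reference before
#' classification. The baseline of each accelerometer axis is the mean value
#' of the quiet parts of the signal: the axis is split into non-overlapping
#' segments of `segment_len_s` seconds, the segments whose standard deviation
#' falls at or below the `std_quantile` quantile of all segment standard
#' deviations are kept (static postures dominate these), and the baseline is
#' the median of the kept segments' means. The median (rather than the
#' plain mean) makes the baseline the value of the *dominant* static
#' posture: protocol recordings contain two static levels per axis
#' (sit/stand and laying), and a mean over an arbitrary mixture of the two
#' would depend on which quiet segments happen to pass the filter.
#'
#' @param rec a [recording()].
#' @param segment_len_s segment length in seconds.
#' @param std_quantile quantile of segment standard deviations below which a
#'   segment counts as quiet.
#' @return a named numeric vector of class `"BaselineVector"` with elements
#'   `acc_x`, `acc_y`, `acc_z`.
#' @export
estimate_baseline <- function(rec, segment_len_s = 2, std_quantile = 0.1) {
  seg_len <- floor(segment_len_s * rec$fs)
  axes <- c("acc_x", "acc_y", "acc_z")
  if (seg_len < 2 || nrow(rec$data) < seg_len) {
    warning("recording shorter than one baseline segment; ",
            "falling back to the whole-series mean")
  }
  out <- vapply(axes, function(ax) {
    x <- rec$data[, ax]
    n_seg <- floor(length(x) / seg_len)
    if (seg_len < 2 || n_seg < 1) {
      return(mean(x))
    }
    segs <- matrix(x[seq_len(n_seg * seg_len)], nrow = seg_len)
    stds <- apply(segs, 2, stats::sd)
    thr <- stats::quantile(stds, std_quantile, names = FALSE)
    keep <- stds <= thr
    if (!any(keep)) keep <- which.min(stds)
    stats::median(colMeans(segs[, keep, drop = FALSE]))
  }, numeric(1))
  structure(out, class = "BaselineVector")
}

#' Align a recording's baseline to a reference
#'
#' Shift-only correction: each accelerometer axis is translated so that its
#' estimated baseline equals the reference baseline of that axis. Being a
#' pure shift, the correction preserves all central moments of order two and
#' higher and is idempotent. An optional per-axis scale correction (ratio of
#' quiet-segment spreads) is available behind `correct_scale`, default off.
#'
#' @param rec a [recording()].
#' @param target a `"BaselineVector"` (the reference space baseline).
#' @param own the recording's own baseline; estimated with
#'   [estimate_baseline()] if not supplied.
#' @param correct_scale additionally rescale each axis about its baseline by
#'   the ratio of reference to own quiet-segment standard deviation. Only
#'   available when `target` carries a `scale_ref` attribute.
#' @return the aligned [recording()].
#' @export
align_baseline <- function(rec, target, own = NULL, correct_scale = FALSE) {
  if (is.null(own)) own <- estimate_baseline(rec)
  axes <- c("acc_x", "acc_y", "acc_z")
  out <- rec
  for (ax in axes) {
    shifted <- rec$data[, ax] - own[[ax]]
    if (correct_scale) {
      sref <- attr(target, "scale_ref")
      if (is.null(sref)) stop("target carries no scale reference")
      s_own <- .quiet_spread(rec$data[, ax], rec$fs)
      if (s_own > 1e-12) shifted <- shifted * (sref[[ax]] / s_own)
    }
    out$data[, ax] <- shifted + target[[ax]]
  }
  out
}

# spread (sd) of the quiet segments, used by the optional scale correction
.quiet_spread <- function(x, fs, segment_len_s = 2, std_quantile = 0.1) {
  seg_len <- floor(segment_len_s * fs)
  n_seg <- floor(length(x) / seg_len)
  if (seg_len < 2 || n_seg < 1) return(stats::sd(x))
  segs <- matrix(x[seq_len(n_seg * seg_len)], nrow = seg_len)
  stds <- apply(segs, 2, stats::sd)
  thr <- stats::quantile(stds, std_quantile, names = FALSE)
  keep <- stds <= thr
  if (!any(keep)) keep <- which.min(stds)
  mean(stds[keep])
}
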