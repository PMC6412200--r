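#' Temporal majority-vote smoothing of predicted labels
#'
#' Enforces a minimum plausible activity duration: a centered moving
#' majority-vote filter is run over the per-window label sequence, removing
#' isolated misclassifications (impulse noise) so the predictions describe
#' coherent transitions between activities. The filter width is the nearest
#' odd number of prediction hops covering `min_duration_s` (4 s at the
#' 1.36 s hop gives a width of 3); edges use truncated windows and ties keep
#' the incumbent label so the filter cannot oscillate.
#'
#' @param labels character vector of per-window labels.
#' @param min_duration_s minimum activity duration (seconds).
#' @param hop_s time between consecutive windows (seconds).
#' @return smoothed character vector, same length.
#' @export
majority_smooth <- function(labels, min_duration_s = 4, hop_s = 1.36) {
  n <- length(labels)
  if (n == 0) stop("empty label sequence")
  r <- min_duration_s / hop_s
  w <- max(1L, 2L * as.integer(round((r - 1) / 2)) + 1L)
  if (w == 1L || n == 1L) return(labels)
  half <- (w - 1L) %/% 2L
  out <- labels
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    win <- labels[lo:hi]
    counts <- table(win)
    top <- names(counts)[counts == max(counts)]
    out[i] <- if (labels[i] %in% top) {
      labels[i]                      # tie (or win) keeps the incumbent
    } else {
      win[win %in% top][1]           # otherwise earliest winning label
    }
  }
  out
}
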