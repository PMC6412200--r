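#' Split a recording into fixed-width overlapping windows
#'
#' The classifier (and the convolutional networks) operate on sliding time
#' windows of 68 samples (2.72 s at 25 Hz) with 50% overlap. The hop between
#' consecutive window starts is `round(window_len * (1 - overlap))` samples;
#' a trailing partial window is dropped. When an annotation track is given,
#' each window is labeled by the majority label of its samples, with ties
#' broken in favor of the chronologically earlier interval's label (the
#' established activity); windows whose samples are entirely unannotated get
#' `NA`.
#'
#' @param rec a [recording()].
#' @param track optional [annotation_track()] carrying final activity labels
#'   (see [build_labels()]).
#' @param window_len window length in samples.
#' @param overlap overlap fraction in `[0, 1)`.
#' @return an object of class `"WindowSeries"`: a list with `starts`
#'   (1-based start sample of each window), `start_s` (start times in
#'   seconds), `window_len`, `hop`, `fs`, `labels` (character or `NA`), and
#'   `data` (list of `window_len x n_channels` matrices).
#' @export
segment_windows <- function(rec, track = NULL, window_len = 68, overlap = 0.5) {
  n <- nrow(rec$data)
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  if (n < window_len) {
    stop("empty window series: recording has ", n,
         " samples, shorter than one window (", window_len, ")")
  }
  hop <- round(window_len * (1 - overlap))
  if (hop < 1) stop("overlap too large: hop would be < 1 sample")
  starts <- seq.int(1L, n - window_len + 1L, by = hop)
  data <- lapply(starts, function(s) {
    rec$data[s:(s + window_len - 1L), , drop = FALSE]
  })
  labels <- rep(NA_character_, length(starts))
  if (!is.null(track)) {
    slab <- sample_labels(track, n, rec$fs, rec$t0)
    labels <- vapply(starts, function(s) {
      w <- slab[s:(s + window_len - 1L)]
      w <- w[!is.na(w)]
      if (length(w) == 0) return(NA_character_)
      counts <- table(w)
      top <- names(counts)[counts == max(counts)]
      if (length(top) == 1) return(top)
      # tie: first tied label encountered in sample order belongs to the
      # chronologically earlier interval
      w[w %in% top][1]
    }, character(1))
  }
  structure(
    list(starts = starts,
         start_s = rec$t0 + (starts - 1) / rec$fs,
         window_len = as.integer(window_len), hop = as.integer(hop),
         fs = rec$fs, labels = labels, data = data),
    class = "WindowSeries"
  )
}

#' @export
print.WindowSeries <- function(x, ...) {
  cat(sprintf("WindowSeries: %d windows of %d samples (hop %d) @ %g Hz\n",
              length(x$starts), x$window_len, x$hop, x$fs))
  if (!all(is.na(x$labels))) {
    print(table(x$labels, useNA = "ifany"))
  }
  invisible(x)
}
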