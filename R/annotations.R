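#' Construct an annotation track
#'
#' Interval-based activity annotations as recorded by instructors during the
#' protocol: `(start_s, end_s, label)` per activity bout, sorted and
#' non-overlapping.
#'
#' @param start_s,end_s numeric vectors of interval bounds in seconds.
#' @param label character vector of labels (raw protocol labels or final
#'   activity classes).
#' @return a `data.frame` of class `"AnnotationTrack"`.
#' @export
annotation_track <- function(start_s, end_s, label) {
  df <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                   label = as.character(label), stringsAsFactors = FALSE)
  if (any(df$start_s >= df$end_s)) {
    stop("annotation intervals must satisfy start_s < end_s")
  }
  df <- df[order(df$start_s), , drop = FALSE]
  if (nrow(df) > 1 && any(df$start_s[-1] < df$end_s[-nrow(df)] - 1e-9)) {
    stop("annotation intervals must be non-overlapping")
  }
  rownames(df) <- NULL
  class(df) <- c("AnnotationTrack", "data.frame")
  df
}

#' Read an annotation track from CSV
#'
#' Expects columns `start_s`, `end_s`, `label`.
#'
#' @param path file path.
#' @return an [annotation_track()].
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_s", "end_s", "label")
  if (!all(need %in% names(df))) {
    stop("annotation file must have columns start_s, end_s, label")
  }
  annotation_track(df$start_s, df$end_s, df$label)
}

#' Write an annotation track to CSV
#' @param track an [annotation_track()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(track, path) {
  utils::write.csv(as.data.frame(track), path, row.names = FALSE)
  invisible(path)
}

# raw protocol label -> merged activity class
RAW_LABEL_MAP <- c(
  standing = "SIT_STAND", sitting = "SIT_STAND",
  walking = "WALKING",
  upstairs = "STAIRS", downstairs = "STAIRS",
  laying = "LAYING"
)

#' Map raw protocol annotations to the final activity classes
#'
#' Applies the class construction used for model training: sitting and
#' standing merge into one class, walking upstairs and downstairs merge into
#' one class, and the leading `transition_s` seconds of every activity
#' interval are re-labeled as the transition state (the time needed to switch
#' between activities). Intervals shorter than `transition_s` become entirely
#' transition.
#'
#' @param track an [annotation_track()] with raw labels from
#'   `standing, sitting, walking, upstairs, downstairs, laying`.
#' @param transition_s leading duration per interval re-labeled as
#'   `TRANSITION` (seconds).
#' @return an [annotation_track()] whose labels are [ACTIVITY_LEVELS].
#' @export
build_labels <- function(track, transition_s = 5) {
  raw <- tolower(track$label)
  unknown <- setdiff(unique(raw), names(RAW_LABEL_MAP))
  if (length(unknown) > 0) {
    stop("unknown raw label(s): ", paste(unknown, collapse = ", "))
  }
  mapped <- unname(RAW_LABEL_MAP[raw])
  out_s <- numeric(0); out_e <- numeric(0); out_l <- character(0)
  for (i in seq_len(nrow(track))) {
    s <- track$start_s[i]; e <- track$end_s[i]
    cut <- min(s + transition_s, e)
    out_s <- c(out_s, s); out_e <- c(out_e, cut); out_l <- c(out_l, "TRANSITION")
    if (cut < e) {
      out_s <- c(out_s, cut); out_e <- c(out_e, e); out_l <- c(out_l, mapped[i])
    }
  }
  annotation_track(out_s, out_e, out_l)
}

#' Per-sample labels from an annotation track
#'
#' @param track an [annotation_track()] with final activity labels.
#' @param n number of samples.
#' @param fs sampling rate (Hz).
#' @param t0 time of the first sample (seconds).
#' @return character vector of length `n`; `NA` where no interval covers the
#'   sample (annotation gaps are preserved, not filled).
#' @export
sample_labels <- function(track, n, fs, t0 = 0) {
  t <- t0 + (seq_len(n) - 1) / fs
  lab <- rep(NA_character_, n)
  for (i in seq_len(nrow(track))) {
    sel <- t >= track$start_s[i] & t < track$end_s[i]
    lab[sel] <- track$label[i]
  }
  lab
}
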