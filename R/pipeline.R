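#' Train a model bundle from files on disk
#'
#' Reads every recording/annotation pair from a directory (as written by
#' [write_cohort()]: `<id>_rec.csv` + `<id>_annot.csv`), trains the dual
#' model with [train_bundle()], and optionally persists it.
#'
#' @param recordings_dir directory containing `*_rec.csv` and
#'   `*_annot.csv` pairs.
#' @param out optional path for [save_bundle()].
#' @param seed training seed.
#' @param ... passed to [train_bundle()].
#' @return the `"ModelBundle"`, invisibly when `out` is given.
#' @export
run_train <- function(recordings_dir, out = NULL, seed = 1, ...) {
  rec_files <- sort(list.files(recordings_dir, pattern = "_rec\\.csv$",
                               full.names = TRUE))
  if (length(rec_files) == 0) {
    stop("no *_rec.csv recordings found in ", recordings_dir)
  }
  recs <- lapply(rec_files, read_recording)
  tracks <- lapply(sub("_rec\\.csv$", "_annot.csv", rec_files),
                   read_annotations)
  message("training on ", length(recs), " recordings")
  bundle <- train_bundle(recs, tracks, seed = seed, ...)
  if (!is.null(out)) {
    save_bundle(bundle, out)
    return(invisible(bundle))
  }
  bundle
}

#' Predict activity labels for recordings on disk
#'
#' @param recordings_dir directory of `*_rec.csv` files.
#' @param bundle a `"ModelBundle"` or a path readable by [load_bundle()].
#' @param out_dir optional directory for per-subject prediction CSVs
#'   (`window_start_s,label_raw,label_smoothed`).
#' @param smooth apply temporal smoothing.
#' @return named list of `"PredictionSeries"`.
#' @export
run_predict <- function(recordings_dir, bundle, out_dir = NULL,
                        smooth = TRUE) {
  if (is.character(bundle)) bundle <- load_bundle(bundle)
  rec_files <- sort(list.files(recordings_dir, pattern = "_rec\\.csv$",
                               full.names = TRUE))
  if (length(rec_files) == 0) {
    stop("no *_rec.csv recordings found in ", recordings_dir)
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  preds <- list()
  for (f in rec_files) {
    rec <- read_recording(f)
    pred <- predict_windows(rec, bundle, smooth = smooth)
    message(sprintf("subject=%s rule=%s model=%s min_dist=%s theta=%.4f",
                    rec$subject_id, attr(pred, "rule"),
                    attr(pred, "model_used"),
                    format(attr(pred, "min_dist"), digits = 4),
                    attr(pred, "theta")))
    preds[[rec$subject_id]] <- pred
    if (!is.null(out_dir)) {
      utils::write.csv(as.data.frame(pred),
                       file.path(out_dir, paste0(rec$subject_id, "_pred.csv")),
                       row.names = FALSE)
    }
  }
  preds
}

#' Ground-truth window labels for a recording
#'
#' The evaluation reference: raw protocol annotations are mapped through
#' [build_labels()] and windowed with the same geometry and majority rule as
#' the predictions.
#'
#' @param rec a [recording()].
#' @param track raw-label [annotation_track()].
#' @param transition_s passed to [build_labels()].
#' @return character vector of per-window truth labels.
#' @export
truth_window_labels <- function(rec, track, transition_s = 5) {
  built <- build_labels(track, transition_s = transition_s)
  ws <- segment_windows(rec, built)
  ws$labels
}

#' Evaluate predictions against ground truth
#'
#' Window-level accuracy of the smoothed labels, the row-normalized 5x5
#' confusion matrix in percent (rows are actual classes and sum to 100),
#' per-subject accuracies, and the model-routing table.
#'
#' @param preds named list of `"PredictionSeries"` (see [run_predict()] /
#'   [predict_windows()]).
#' @param truths named list of character vectors of per-window truth labels
#'   (same names and window counts as `preds`).
#' @return list of class `"EvalReport"`: `overall_accuracy` (percent),
#'   `confusion` (percent), `per_subject` (data.frame), `routing`
#'   (data.frame).
#' @export
run_evaluate <- function(preds, truths) {
  stopifnot(length(preds) == length(truths))
  ids <- names(preds)
  if (is.null(ids)) ids <- paste0("subject", seq_along(preds))
  all_pred <- character(0); all_truth <- character(0)
  per_subject <- data.frame(subject_id = character(0), accuracy = numeric(0),
                            n_windows = integer(0), stringsAsFactors = FALSE)
  routing <- data.frame(subject_id = character(0), rule = integer(0),
                        model = character(0), min_dist = numeric(0),
                        stringsAsFactors = FALSE)
  for (i in seq_along(preds)) {
    p <- preds[[i]]
    truth <- as.character(truths[[i]])
    lab <- p$label_smoothed
    keep <- !is.na(truth)
    if (length(truth) != length(lab)) {
      stop("prediction/truth window count mismatch for ", ids[i])
    }
    all_pred <- c(all_pred, lab[keep])
    all_truth <- c(all_truth, truth[keep])
    per_subject <- rbind(per_subject, data.frame(
      subject_id = ids[i], accuracy = 100 * mean(lab[keep] == truth[keep]),
      n_windows = sum(keep), stringsAsFactors = FALSE))
    routing <- rbind(routing, data.frame(
      subject_id = ids[i],
      rule = if (is.null(attr(p, "rule"))) NA_integer_ else attr(p, "rule"),
      model = if (is.null(attr(p, "model_used"))) NA_character_
              else attr(p, "model_used"),
      min_dist = if (is.null(attr(p, "min_dist"))) NA_real_
                 else attr(p, "min_dist"),
      stringsAsFactors = FALSE))
  }
  lev <- ACTIVITY_LEVELS[ACTIVITY_LEVELS %in% union(all_truth, all_pred)]
  conf <- table(factor(all_truth, levels = lev), factor(all_pred, levels = lev))
  conf_pct <- 100 * prop.table(conf + 0, margin = 1)
  conf_pct[is.nan(conf_pct)] <- 0
  structure(
    list(overall_accuracy = 100 * mean(all_pred == all_truth),
         confusion = conf_pct, per_subject = per_subject, routing = routing),
    class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("EvalReport: overall window accuracy %.2f%% over %d subjects\n",
              x$overall_accuracy, nrow(x$per_subject)))
  cat("confusion matrix (% of actual class):\n")
  print(round(x$confusion, 2))
  cat("routing:\n")
  print(x$routing, row.names = FALSE)
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report an `"EvalReport"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- list(
    overall_accuracy = report$overall_accuracy,
    confusion = as.data.frame.matrix(report$confusion),
    per_subject = report$per_subject,
    routing = report$routing)
  jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
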