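#' 3-D histogram of accelerometer values
#'
#' The signature used by the orientation router: the joint distribution of
#' the three accelerometer axes over a recording, binned on a shared
#' `B x B x B` grid. Values outside the grid are clamped into the edge bins
#' so test recordings that exceed the training range still contribute mass.
#'
#' @param acc numeric matrix `n x 3`.
#' @param edges list of 3 numeric vectors of length `B + 1` (bin edges per
#'   axis).
#' @param normalize divide counts by the total so they sum to 1.
#' @return an object of class `"Histogram3D"`: list with `counts`
#'   (`B x B x B` array), `edges`, `normalized`.
#' @export
hist3d <- function(acc, edges, normalize = TRUE) {
  acc <- as.matrix(acc)
  B <- length(edges[[1]]) - 1L
  idx <- vapply(1:3, function(a) {
    i <- findInterval(acc[, a], edges[[a]], rightmost.closed = TRUE)
    pmin(pmax(i, 1L), B)
  }, integer(nrow(acc)))
  idx <- matrix(idx, ncol = 3)
  counts <- array(0, dim = c(B, B, B))
  flat <- (idx[, 3] - 1L) * B * B + (idx[, 2] - 1L) * B + idx[, 1]
  tab <- tabulate(flat, nbins = B^3)
  counts[] <- tab
  if (normalize) counts <- counts / sum(counts)
  structure(list(counts = counts, edges = edges, normalized = normalize),
            class = "Histogram3D")
}

#' 3-D binned Kolmogorov-Smirnov distance
#'
#' A multivariate analogue of the Kolmogorov-Smirnov statistic on binned
#' data, in the spirit of the Fasano-Franceschini construction: because a
#' multivariate CDF depends on the cumulation direction, cumulative sums of
#' both histograms are taken in each of the 8 octant directions and the
#' statistic is the maximum absolute difference over all bins and all
#' directions. It is symmetric, lies in `[0, 1]` for normalized histograms,
#' and is zero iff the histograms are identical (a pseudometric on the grid).
#'
#' @param a,b `"Histogram3D"` objects on identical bin edges, normalized.
#' @return the distance, a scalar in `[0, 1]`.
#' @export
ks3d <- function(a, b) {
  if (!isTRUE(all.equal(a$edges, b$edges))) {
    stop("grid error: histograms have different bin edges")
  }
  if (!a$normalized || !b$normalized) stop("histograms must be normalized")
  d <- 0
  for (fx in c(FALSE, TRUE)) for (fy in c(FALSE, TRUE)) for (fz in c(FALSE, TRUE)) {
    ca <- .octant_cumsum(a$counts, fx, fy, fz)
    cb <- .octant_cumsum(b$counts, fx, fy, fz)
    d <- max(d, max(abs(ca - cb)))
  }
  d
}

# cumulative sums along all three dimensions, optionally flipped per axis
.octant_cumsum <- function(arr, fx, fy, fz) {
  B <- dim(arr)[1]
  if (fx) arr <- arr[B:1, , , drop = FALSE]
  if (fy) arr <- arr[, B:1, , drop = FALSE]
  if (fz) arr <- arr[, , B:1, drop = FALSE]
  arr <- apply(arr, c(2, 3), cumsum)                  # cum over dim 1
  arr <- aperm(apply(arr, c(1, 3), cumsum), c(2, 1, 3))  # cum over dim 2
  arr <- aperm(apply(arr, c(1, 2), cumsum), c(2, 3, 1))  # cum over dim 3
  arr
}

#' Learn the reference measurement space from training recordings
#'
#' The training recordings (consistent, correct orientation, `-X` vertical)
#' define the space against which incoming recordings are checked: the
#' pooled central-80% interval of the vertical axis, one normalized 3-D
#' histogram per recording on a shared grid (with 1% tail clipping of the
#' pooled range), the routing threshold `theta` equal to the maximum
#' pairwise histogram distance within the training set (the "normal
#' variation"), and the reference accelerometer baseline.
#'
#' @param train_recs list of [recording()]s, at least 2.
#' @param bins histogram bins per axis.
#' @param vertical_axis channel measuring gravity in the reference
#'   orientation.
#' @param max_duration_s use at most the first this-many seconds of each
#'   recording when building histograms (all if shorter).
#' @return an object of class `"ReferenceSpace"`.
#' @export
fit_reference_space <- function(train_recs, bins = 16,
                                vertical_axis = "acc_x",
                                max_duration_s = 3600) {
  if (length(train_recs) < 2) {
    stop("cannot calibrate theta from fewer than 2 training recordings")
  }
  recs <- lapply(train_recs, .truncate_rec, max_duration_s = max_duration_s)
  acc_list <- lapply(recs, function(r) {
    r$data[, c("acc_x", "acc_y", "acc_z"), drop = FALSE]
  })
  pooled <- do.call(rbind, acc_list)
  edges <- lapply(1:3, function(a) {
    lo <- stats::quantile(pooled[, a], 0.01, names = FALSE)
    hi <- stats::quantile(pooled[, a], 0.99, names = FALSE)
    if (hi - lo < 1e-9) { lo <- lo - 0.5; hi <- hi + 0.5 }
    seq(lo, hi, length.out = bins + 1)
  })
  hists <- lapply(acc_list, hist3d, edges = edges)
  theta <- 0
  if (length(hists) >= 2) {
    for (i in seq_along(hists)) {
      for (j in seq_len(i - 1)) theta <- max(theta, ks3d(hists[[i]], hists[[j]]))
    }
  }
  p10 <- vapply(recs, function(r) {
    stats::quantile(r$data[, vertical_axis], 0.1, names = FALSE)
  }, numeric(1))
  p90 <- vapply(recs, function(r) {
    stats::quantile(r$data[, vertical_axis], 0.9, names = FALSE)
  }, numeric(1))
  baselines <- lapply(train_recs, estimate_baseline)
  ref_baseline <- structure(colMeans(do.call(rbind, baselines)),
                            class = "BaselineVector")
  structure(
    list(vertical_axis = vertical_axis,
         vertical_interval = c(low = min(p10), high = max(p90)),
         p10_range = range(p10), p90_range = range(p90),
         edges = edges, reference_histograms = hists, theta = theta,
         reference_baseline = ref_baseline,
         max_duration_s = max_duration_s),
    class = "ReferenceSpace"
  )
}

.truncate_rec <- function(rec, max_duration_s) {
  n_max <- floor(max_duration_s * rec$fs)
  if (nrow(rec$data) > n_max) rec$data <- rec$data[seq_len(n_max), , drop = FALSE]
  rec
}

#' @export
print.ReferenceSpace <- function(x, ...) {
  cat(sprintf(
    "ReferenceSpace: %d reference histograms (%d^3 bins), theta = %.4f\n",
    length(x$reference_histograms), length(x$edges[[1]]) - 1, x$theta))
  cat(sprintf("  vertical axis %s in [%.3f, %.3f]\n", x$vertical_axis,
              x$vertical_interval["low"], x$vertical_interval["high"]))
  invisible(x)
}

#' Rule 1: does the vertical axis look correctly oriented?
#'
#' Checks that the bulk of the test measurements on the vertical axis lies
#' in the range observed during training. Both ends of the test central-80%
#' interval are compared against the training variation of the matching
#' percentile: the test 10th percentile must fall within the range of the
#' training recordings' 10th percentiles, and likewise for the 90th, each
#' range expanded by `margin` times the overall reference interval width.
#' Comparing percentile to percentile (rather than asking for containment
#' in the overall interval) keeps the rule sensitive when the reference
#' interval is wide — a recording whose gravity has moved off the vertical
#' axis concentrates in a narrow band that plain containment would accept.
#'
#' @param rec a [recording()].
#' @param space a [fit_reference_space()] result.
#' @param margin tolerance, as a fraction of the overall reference interval
#'   width, to prevent boundary flapping.
#' @return logical.
#' @export
vertical_axis_check <- function(rec, space, margin = 0.1) {
  x <- rec$data[, space$vertical_axis]
  lo <- stats::quantile(x, 0.1, names = FALSE)
  hi <- stats::quantile(x, 0.9, names = FALSE)
  w <- space$vertical_interval["high"] - space$vertical_interval["low"]
  m <- margin * w
  lo >= space$p10_range[1] - m && lo <= space$p10_range[2] + m &&
    hi >= space$p90_range[1] - m && hi <= space$p90_range[2] + m
}

#' Route a recording to the axis-dependent or rotation-invariant model
#'
#' Two-rule heuristic. Rule 1: if the vertical-axis distribution of the
#' incoming recording, as measured, matches the reference
#' ([vertical_axis_check()]), the device orientation is considered correct
#' and the axis-dependent model applies. Otherwise the recording either is
#' mis-oriented or merely fell outside rule 1's range (an unusual subject,
#' a moderate baseline shift), so rule 2 examines the full 3-D distribution
#' of raw values: the minimum [ks3d()] distance between the test histogram
#' and the reference histograms is compared against `theta`; below the
#' threshold the recording is still within the training set's normal
#' variation and the axis-dependent model is chosen, above it the recording
#' is treated as mis-oriented and classification falls back to the
#' rotation-invariant model. The histogram is deliberately computed on the
#' values as measured: any per-axis re-centering would translate a rotated
#' recording's dominant static cluster onto the reference cluster and hide
#' the rotation from the statistic (gross baseline shifts therefore also
#' exceed `theta` and take the conservative rotation-invariant path).
#'
#' @param rec a [recording()] as measured.
#' @param space a [fit_reference_space()] result.
#' @param margin rule-1 margin, see [vertical_axis_check()].
#' @return list with `model` (`"AXIS_DEPENDENT"` or `"ROTATION_INVARIANT"`),
#'   `rule` (1 or 2), `min_dist` (`NA` when rule 1 fired), `theta`.
#' @export
select_model <- function(rec, space, margin = 0.1) {
  if (vertical_axis_check(rec, space, margin = margin)) {
    return(list(model = "AXIS_DEPENDENT", rule = 1L, min_dist = NA_real_,
                theta = space$theta))
  }
  rec_t <- .truncate_rec(rec, space$max_duration_s)
  h <- hist3d(rec_t$data[, c("acc_x", "acc_y", "acc_z"), drop = FALSE],
              edges = space$edges)
  dists <- vapply(space$reference_histograms, ks3d, numeric(1), b = h)
  md <- min(dists)
  model <- if (md < space$theta) "AXIS_DEPENDENT" else "ROTATION_INVARIANT"
  list(model = model, rule = 2L, min_dist = md, theta = space$theta)
}
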