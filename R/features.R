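#' @importFrom e1071 skewness kurtosis
NULL

# The 16 feature primitives available to manifests.
FEATURE_PRIMITIVES <- c(
  "MEAN", "STD", "MAD", "MAX", "MIN", "SMA", "ENERGY", "IQR", "ENTROPY",
  "AR_COEF", "CORRELATION", "MAX_FREQ_IND", "MEAN_FREQ", "SKEWNESS_F",
  "KURTOSIS_F", "BANDS_ENERGY"
)

# per-axis statistics applied to every time-domain triaxial signal
.TIME_STATS <- c("MEAN", "STD", "MAD", "MAX", "MIN", "ENERGY", "IQR", "ENTROPY")
# per-axis statistics applied to every frequency-domain triaxial signal
.FREQ_STATS <- c("MEAN", "STD", "MAD", "MAX", "MIN", "ENERGY", "IQR", "ENTROPY",
                 "MAX_FREQ_IND", "MEAN_FREQ", "SKEWNESS_F", "KURTOSIS_F")
.AR_ORDER <- 4L
.N_BANDS <- 8L   # 8 contiguous bands of 8 bins over the 64-bin spectrum
.N_FFT_BINS <- 64L

#' The axis-dependent feature manifest (254 features)
#'
#' The ordered recipe of window features used by the orientation-sensitive
#' classifier. Sources are the signals of a [signal_bundle()]; the
#' composition (fixed, documented in the methods vignette) is:
#'
#' * 3 time-domain triaxial signals (`body_acc`, `gravity_acc`, `body_jerk`),
#'   each with 8 per-axis statistics, 4 autoregression coefficients per axis,
#'   the signal magnitude area, and the 3 axis-pair correlations (40 each);
#' * 3 paired correlations between `body_acc` and `body_jerk` axes;
#' * 3 magnitude signals with `MEAN`, `STD`, `ENERGY` (9);
#' * 2 frequency-domain triaxial signals (spectra of `body_acc` and
#'   `body_jerk`), each with 12 per-axis spectral statistics plus 8 band
#'   energies per axis (60 each);
#' * `MAX_FREQ_IND` and `MEAN_FREQ` of the body-acc-magnitude spectrum (2).
#'
#' Total: exactly 254, asserted when the package loads.
#'
#' @return a `data.frame` with one row per feature: `signal`, `axis`,
#'   `domain`, `primitive`, `param`, `group` (triplet identifier, empty for
#'   non-triplet features), `name`.
#' @export
axis_manifest <- function() {
  if (!is.null(.imuhar_env$axis_manifest)) return(.imuhar_env$axis_manifest)
  rows <- list()
  add <- function(signal, axis, domain, primitive, param = "", group = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      signal = signal, axis = axis, domain = domain, primitive = primitive,
      param = as.character(param), group = group, stringsAsFactors = FALSE)
  }
  triax <- c("body_acc", "gravity_acc", "body_jerk")
  for (sig in triax) {
    for (prim in .TIME_STATS) {
      for (ax in c("x", "y", "z")) {
        add(sig, ax, "time", prim, group = paste(sig, "t", prim, sep = "|"))
      }
    }
    for (lag in seq_len(.AR_ORDER)) {
      for (ax in c("x", "y", "z")) {
        add(sig, ax, "time", "AR_COEF", lag,
            group = paste(sig, "t", "AR", lag, sep = "|"))
      }
    }
    add(sig, "xyz", "time", "SMA")
    for (pair in c("x:y", "x:z", "y:z")) {
      add(sig, pair, "time", "CORRELATION")
    }
  }
  for (ax in c("x", "y", "z")) {
    add("body_acc:body_jerk", ax, "time", "CORRELATION")
  }
  for (sig in c("mag_body_acc", "mag_gravity_acc", "mag_body_jerk")) {
    for (prim in c("MEAN", "STD", "ENERGY")) add(sig, "", "time", prim)
  }
  for (sig in c("body_acc", "body_jerk")) {
    fsig <- paste0("f_", sig)
    for (prim in .FREQ_STATS) {
      for (ax in c("x", "y", "z")) {
        add(fsig, ax, "freq", prim, group = paste(fsig, "f", prim, sep = "|"))
      }
    }
    for (b in seq_len(.N_BANDS)) {
      for (ax in c("x", "y", "z")) {
        add(fsig, ax, "freq", "BANDS_ENERGY", b,
            group = paste(fsig, "f", "BAND", b, sep = "|"))
      }
    }
  }
  for (prim in c("MAX_FREQ_IND", "MEAN_FREQ")) {
    add("f_mag_body_acc", "", "freq", prim)
  }
  man <- do.call(rbind, rows)
  man$name <- paste0(man$signal,
                     ifelse(man$axis == "", "", paste0("_", man$axis)),
                     "_", tolower(man$primitive),
                     ifelse(man$param == "", "", paste0("_", man$param)))
  attr(man, "manifest_name") <- "AXIS_DEP"
  .imuhar_env$axis_manifest <- man
  man
}

#' The rotation-invariant feature manifest (90 features)
#'
#' Derived from [axis_manifest()] by the triplet reduction of
#' [rotation_invariant_reduce()]: every per-axis feature triplet collapses to
#' the magnitude of its 3-D vector, magnitude-signal features pass through,
#' and axis-pair correlations are dropped. The `invariant` column marks the
#' features whose rotation invariance is mathematically exact (see the
#' methods vignette); the rest are only empirically stable.
#'
#' @return a `data.frame` with `signal`, `domain`, `primitive`, `param`,
#'   `kind` (`"reduced"` or `"pass"`), `invariant`, `name`.
#' @export
rotinv_manifest <- function() {
  if (!is.null(.imuhar_env$rotinv_manifest)) return(.imuhar_env$rotinv_manifest)
  man <- axis_manifest()
  rows <- list()
  seen <- character(0)
  for (i in seq_len(nrow(man))) {
    r <- man[i, ]
    if (r$primitive == "CORRELATION") next
    if (r$group != "") {
      if (r$group %in% seen) next
      seen <- c(seen, r$group)
      exact <- (r$domain == "time" && r$primitive %in% c("MEAN", "STD")) ||
        r$primitive %in% c("ENERGY", "BANDS_ENERGY")
      rows[[length(rows) + 1L]] <- data.frame(
        signal = r$signal, domain = r$domain, primitive = r$primitive,
        param = r$param, kind = "reduced", invariant = exact,
        name = paste0(sub("^(.*)$", "\\1", r$signal), "_",
                      tolower(r$primitive),
                      ifelse(r$param == "", "", paste0("_", r$param)), "_norm"),
        stringsAsFactors = FALSE)
    } else {
      exact <- grepl("mag", r$signal)
      rows[[length(rows) + 1L]] <- data.frame(
        signal = r$signal, domain = r$domain, primitive = r$primitive,
        param = r$param, kind = "pass", invariant = exact, name = r$name,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "manifest_name") <- "ROT_INV"
  .imuhar_env$rotinv_manifest <- out
  out
}

#' Write / read a feature manifest as plain text
#'
#' Tab-separated, one feature per line, so the exact recipe shipped with a
#' model can be inspected and diffed.
#'
#' @param manifest a manifest `data.frame` ([axis_manifest()] or
#'   [rotinv_manifest()]).
#' @param path file path.
#' @return `path` (write) or the manifest `data.frame` (read).
#' @export
write_manifest <- function(manifest, path) {
  df <- as.data.frame(manifest)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, colClasses = "character")
}

# 64-bin one-sided magnitude spectrum of a window: mean removed, rectangular
# window, zero-padded to 128 samples so the one-sided spectrum has exactly
# 64 bins at frequencies (1:64) * fs / 128.
.spectrum64 <- function(x, fs) {
  xm <- x - mean(x)
  padded <- c(xm, rep(0, 2L * .N_FFT_BINS - length(xm)))
  Mod(stats::fft(padded))[2:(.N_FFT_BINS + 1L)]
}

.spectrum_freqs <- function(fs) (seq_len(.N_FFT_BINS)) * fs / (2 * .N_FFT_BINS)

.shannon_entropy <- function(s) {
  tot <- sum(s)
  if (tot <= 0) return(0)
  p <- s / tot
  p <- p[p > 0]
  -sum(p * log(p))
}

.ar_coefs <- function(x, order = .AR_ORDER) {
  if (stats::var(x) < 1e-24) return(rep(0, order))
  fit <- try(stats::ar.yw(x, aic = FALSE, order.max = order, demean = TRUE),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(rep(0, order))
  a <- fit$ar
  if (length(a) < order) a <- c(a, rep(0, order - length(a)))
  a
}

.safe_cor <- function(a, b) {
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) {
    warning("zero-variance input to CORRELATION; defined as 0")
    return(0)
  }
  stats::cor(a, b)
}

#' Evaluate a single feature primitive
#'
#' Pinned definitions of the 16 window statistics. Time-domain primitives
#' take a signal window; frequency-domain primitives take a 64-bin magnitude
#' spectrum (see the manifest). `SMA` takes an `n x 3` matrix, `CORRELATION`
#' two series, `AR_COEF` returns `order` values.
#'
#' @param primitive one of [FEATURE_PRIMITIVES].
#' @param x numeric vector (series or spectrum), or `n x 3` matrix for
#'   `SMA`, or list of two series for `CORRELATION`.
#' @param fs sampling rate, needed by frequency-aware primitives.
#' @param param primitive parameter: AR order for `AR_COEF`, band index
#'   (1..8) for `BANDS_ENERGY`.
#' @return numeric scalar, or vector of length `param` for `AR_COEF`.
#' @export
primitive_value <- function(primitive, x, fs = 25, param = NULL) {
  switch(primitive,
    MEAN = mean(x),
    STD = stats::sd(x),
    MAD = stats::median(abs(x - stats::median(x))),
    MAX = max(x),
    MIN = min(x),
    SMA = {
      m <- as.matrix(x)
      mean(rowSums(abs(m)))
    },
    ENERGY = mean(x^2),
    IQR = stats::IQR(x),
    ENTROPY = .shannon_entropy(.spectrum64(x, fs)),
    AR_COEF = .ar_coefs(x, if (is.null(param)) .AR_ORDER else as.integer(param)),
    CORRELATION = .safe_cor(x[[1]], x[[2]]),
    MAX_FREQ_IND = which.max(x),
    MEAN_FREQ = {
      tot <- sum(x)
      if (tot <= 0) 0 else sum(.spectrum_freqs(fs) * x) / tot
    },
    SKEWNESS_F = {
      v <- e1071::skewness(x)
      if (!is.finite(v)) 0 else v
    },
    KURTOSIS_F = {
      v <- e1071::kurtosis(x)
      if (!is.finite(v)) 0 else v
    },
    BANDS_ENERGY = {
      b <- as.integer(param)
      width <- .N_FFT_BINS / .N_BANDS
      bins <- ((b - 1L) * width + 1L):(b * width)
      mean(x[bins]^2)
    },
    stop("unknown primitive: ", primitive)
  )
}

# frequency-domain evaluation on an already-computed spectrum
.freq_primitive <- function(primitive, s, fs, param) {
  switch(primitive,
    MEAN = mean(s), STD = stats::sd(s),
    MAD = stats::median(abs(s - stats::median(s))),
    MAX = max(s), MIN = min(s), ENERGY = mean(s^2), IQR = stats::IQR(s),
    ENTROPY = .shannon_entropy(s),
    MAX_FREQ_IND = which.max(s),
    MEAN_FREQ = primitive_value("MEAN_FREQ", s, fs),
    SKEWNESS_F = primitive_value("SKEWNESS_F", s),
    KURTOSIS_F = primitive_value("KURTOSIS_F", s),
    BANDS_ENERGY = primitive_value("BANDS_ENERGY", s, fs, param),
    stop("primitive ", primitive, " not defined in the frequency domain")
  )
}

#' Extract the feature vector of one window
#'
#' Computes the [axis_manifest()] features (length 254) of a windowed
#' [signal_bundle()]; with `manifest = rotinv_manifest()` the axis features
#' are computed first and then reduced with [rotation_invariant_reduce()]
#' (length 90).
#'
#' @param win a window as returned by [bundle_window()].
#' @param manifest [axis_manifest()] (default) or [rotinv_manifest()].
#' @return named numeric vector of manifest length.
#' @export
extract_features <- function(win, manifest = axis_manifest()) {
  mname <- attr(manifest, "manifest_name")
  if (identical(mname, "ROT_INV")) {
    return(rotation_invariant_reduce(extract_features(win, axis_manifest())))
  }
  fs <- win$fs
  triax <- list(body_acc = win$body_acc, gravity_acc = win$gravity_acc,
                body_jerk = win$body_jerk)
  mags <- list(mag_body_acc = win$mag_body_acc,
               mag_gravity_acc = win$mag_gravity_acc,
               mag_body_jerk = win$mag_body_jerk)
  # per-signal caches: spectra and AR coefficients
  spectra <- list(
    f_body_acc = apply(win$body_acc, 2, .spectrum64, fs = fs),
    f_body_jerk = apply(win$body_jerk, 2, .spectrum64, fs = fs),
    f_mag_body_acc = .spectrum64(win$mag_body_acc, fs)
  )
  ar_cache <- new.env(parent = emptyenv())
  get_ar <- function(sig, ax) {
    key <- paste(sig, ax)
    if (is.null(ar_cache[[key]])) {
      ar_cache[[key]] <- .ar_coefs(triax[[sig]][, .axis_col(ax)])
    }
    ar_cache[[key]]
  }
  ent_cache <- new.env(parent = emptyenv())
  out <- numeric(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    r_sig <- manifest$signal[i]; r_ax <- manifest$axis[i]
    r_dom <- manifest$domain[i]; r_prim <- manifest$primitive[i]
    r_par <- manifest$param[i]
    out[i] <- if (r_dom == "freq") {
      s <- spectra[[r_sig]]
      sv <- if (is.matrix(s)) s[, .axis_col(r_ax)] else s
      .freq_primitive(r_prim, sv, fs, r_par)
    } else if (r_prim == "SMA") {
      if (r_sig %in% names(triax)) {
        primitive_value("SMA", triax[[r_sig]])
      } else {
        mean(abs(mags[[r_sig]]))
      }
    } else if (r_prim == "CORRELATION") {
      if (grepl(":", r_sig, fixed = TRUE)) {
        sigs <- strsplit(r_sig, ":", fixed = TRUE)[[1]]
        .safe_cor(triax[[sigs[1]]][, .axis_col(r_ax)],
                  triax[[sigs[2]]][, .axis_col(r_ax)])
      } else {
        axes <- strsplit(r_ax, ":", fixed = TRUE)[[1]]
        .safe_cor(triax[[r_sig]][, .axis_col(axes[1])],
                  triax[[r_sig]][, .axis_col(axes[2])])
      }
    } else if (r_prim == "AR_COEF") {
      get_ar(r_sig, r_ax)[as.integer(r_par)]
    } else if (r_prim == "ENTROPY") {
      key <- paste(r_sig, r_ax)
      if (is.null(ent_cache[[key]])) {
        fsig <- paste0("f_", r_sig)
        sv <- if (!is.null(spectra[[fsig]])) {
          spectra[[fsig]][, .axis_col(r_ax)]
        } else {
          .spectrum64(.series_of(triax, mags, r_sig, r_ax), fs)
        }
        ent_cache[[key]] <- .shannon_entropy(sv)
      }
      ent_cache[[key]]
    } else {
      primitive_value(r_prim, .series_of(triax, mags, r_sig, r_ax), fs)
    }
  }
  names(out) <- manifest$name
  out
}

.axis_col <- function(ax) match(ax, c("x", "y", "z"))

.series_of <- function(triax, mags, sig, ax) {
  if (sig %in% names(triax)) triax[[sig]][, .axis_col(ax)] else mags[[sig]]
}

#' Reduce axis-dependent features to the rotation-invariant set
#'
#' Every per-axis feature triplet `(fX, fY, fZ)` collapses to the magnitude
#' of its 3-D vector. For `ENERGY` and `BANDS_ENERGY` triplets the magnitude
#' is taken of the per-axis root-mean-square vector, i.e.
#' `sqrt(fX + fY + fZ)` — the RMS of the 3-D signal — which is exactly
#' rotation invariant (the plain norm of per-axis mean-squares is not). Features computed on magnitude signals and
#' the signal magnitude areas pass through unchanged; axis-pair correlation
#' features are dropped.
#'
#' @param axis_features named numeric vector (or matrix, one row per window)
#'   following the [axis_manifest()] layout.
#' @return named numeric vector (or matrix) following [rotinv_manifest()].
#' @export
rotation_invariant_reduce <- function(axis_features) {
  man <- axis_manifest()
  plan <- .reduction_plan()
  if (is.matrix(axis_features)) {
    if (ncol(axis_features) != nrow(man)) {
      stop("layout mismatch: expected ", nrow(man), " axis features, got ",
           ncol(axis_features))
    }
    out <- matrix(0, nrow(axis_features), length(plan),
                  dimnames = list(NULL, rotinv_manifest()$name))
    for (i in seq_along(plan)) {
      p <- plan[[i]]
      out[, i] <- switch(p$op,
        pass = axis_features[, p$idx],
        norm = sqrt(axis_features[, p$idx[1]]^2 +
                      axis_features[, p$idx[2]]^2 +
                      axis_features[, p$idx[3]]^2),
        sqrtsum = sqrt(axis_features[, p$idx[1]] +
                         axis_features[, p$idx[2]] +
                         axis_features[, p$idx[3]]))
    }
    return(out)
  }
  if (length(axis_features) != nrow(man)) {
    stop("layout mismatch: expected ", nrow(man), " axis features, got ",
         length(axis_features))
  }
  out <- vapply(plan, function(p) {
    v <- axis_features[p$idx]
    switch(p$op, pass = v, norm = sqrt(sum(v^2)), sqrtsum = sqrt(sum(v)))
  }, numeric(1))
  names(out) <- rotinv_manifest()$name
  out
}

# cached index plan mapping axis-manifest columns to reduced features
.reduction_plan <- function() {
  if (!is.null(.imuhar_env$reduction_plan)) return(.imuhar_env$reduction_plan)
  man <- axis_manifest()
  rman <- rotinv_manifest()
  plan <- vector("list", nrow(rman))
  seen <- character(0)
  j <- 0L
  for (i in seq_len(nrow(man))) {
    if (man$primitive[i] == "CORRELATION") next
    if (man$group[i] != "") {
      if (man$group[i] %in% seen) next
      seen <- c(seen, man$group[i])
      j <- j + 1L
      idx <- which(man$group == man$group[i])
      op <- if (man$primitive[i] %in% c("ENERGY", "BANDS_ENERGY")) "sqrtsum"
            else "norm"
      plan[[j]] <- list(op = op, idx = idx)
    } else {
      j <- j + 1L
      plan[[j]] <- list(op = "pass", idx = i)
    }
  }
  stopifnot(j == nrow(rman))
  .imuhar_env$reduction_plan <- plan
  plan
}

#' Feature matrix of a whole recording
#'
#' Convenience wrapper: builds the [signal_bundle()], segments windows, and
#' extracts the axis-dependent feature vector of every window.
#'
#' @param rec a [recording()].
#' @param track optional [annotation_track()] with final labels; windows with
#'   no annotated samples are dropped.
#' @param window_len,overlap window geometry, see [segment_windows()].
#' @param cutoff_hz gravity low-pass cutoff.
#' @return list with `X` (matrix `n_windows x 254`), `labels` (character or
#'   `NA`), `start_s` (window start times).
#' @export
recording_features <- function(rec, track = NULL, window_len = 68,
                               overlap = 0.5, cutoff_hz = 0.3) {
  bundle <- signal_bundle(rec, cutoff_hz = cutoff_hz)
  ws <- segment_windows(rec, track, window_len = window_len, overlap = overlap)
  keep <- if (is.null(track)) seq_along(ws$starts) else which(!is.na(ws$labels))
  X <- matrix(0, nrow = length(keep), ncol = nrow(axis_manifest()),
              dimnames = list(NULL, axis_manifest()$name))
  for (j in seq_along(keep)) {
    w <- bundle_window(bundle, ws$starts[keep[j]], window_len)
    X[j, ] <- extract_features(w)
  }
  list(X = X, labels = ws$labels[keep], start_s = ws$start_s[keep])
}

#' Fit / apply z-score scaling
#'
#' Standardization centers each feature at zero and scales it to unit
#' variance; the fitted parameters are stored with the model and re-applied
#' to incoming data. Population (divide-by-n) standard deviation is used;
#' zero-variance columns use divisor 1 so they map to exactly zero.
#'
#' @param X numeric matrix, one row per window.
#' @return `fit_scaler`: a list of class `"ScalerParams"` with `mean` and
#'   `std` per column; `apply_scaler`: the scaled matrix.
#' @export
fit_scaler <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("fit_scaler needs at least 2 rows")
  mu <- colMeans(X)
  sdev <- sqrt(colMeans(sweep(X, 2, mu)^2))
  sdev[sdev < 1e-12] <- 1
  structure(list(mean = mu, std = sdev), class = "ScalerParams")
}

#' @rdname fit_scaler
#' @param params a `"ScalerParams"` object from [fit_scaler()].
#' @export
apply_scaler <- function(X, params) {
  X <- as.matrix(X)
  if (ncol(X) != length(params$mean)) {
    stop("shape error: matrix has ", ncol(X), " columns, scaler has ",
         length(params$mean))
  }
  sweep(sweep(X, 2, params$mean), 2, params$std, "/")
}

#' Invert z-score scaling
#' @inheritParams apply_scaler
#' @return matrix on the original scale.
#' @export
invert_scaler <- function(X, params) {
  sweep(sweep(as.matrix(X), 2, params$std, "*"), 2, params$mean, "+")
}
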