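#' Rotation matrix about an axis
#'
#' Rodrigues formula for a proper rotation of `angle_deg` degrees about
#' `axis` (active convention: vectors are rotated, `v' = R v`).
#'
#' @param axis numeric length-3 vector (normalized internally).
#' @param angle_deg rotation angle in degrees.
#' @return `3 x 3` rotation matrix.
#' @export
rotation_about <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# minimal rotation taking unit vector u onto unit vector v
.rotation_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # opposite vectors: rotate 180 deg about any perpendicular axis
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * u) * u
    return(rotation_about(ax, 180))
  }
  ax <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  rotation_about(ax, acos(c_) * 180 / pi)
}

# spherical interpolation between unit vectors, f in [0,1]
.slerp <- function(u, v, f) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  d <- max(-1, min(1, sum(u * v)))
  th <- acos(d)
  if (th < 1e-9) return(u)
  (sin((1 - f) * th) * u + sin(f * th) * v) / sin(th)
}

#' Default recording protocol
#'
#' The scripted activity sequence performed under instructor supervision:
#' standing 1 min, sitting 1 min, walking 1 min, walking upstairs 30 s,
#' walking downstairs 30 s, laying 30 s (270 s total).
#'
#' @return an [annotation_track()] with raw labels.
#' @export
default_protocol <- function() {
  annotation_track(
    start_s = c(0, 60, 120, 180, 210, 240),
    end_s = c(60, 120, 180, 210, 240, 270),
    label = c("standing", "sitting", "walking", "upstairs", "downstairs",
              "laying"))
}

#' Draw per-subject generator parameters
#'
#' Subject-level gait and sensor parameters: walking step frequency
#' 1.4-2.0 Hz with oscillation amplitude 0.10-0.30 g, stairs 0.9-1.4 Hz at
#' 0.15-0.40 g, sensor noise 0.03 g, gyroscope locomotion amplitude
#' 30-80 deg/s, and the laying orientation (gravity moved onto Y or Z).
#'
#' @param seed integer seed.
#' @return named list of parameters (see [simulate_recording()]).
#' @export
draw_subject_params <- function(seed) {
  set.seed(seed)
  list(
    step_freq_walk = stats::runif(1, 1.4, 2.0),
    step_freq_stairs = stats::runif(1, 0.9, 1.4),
    amp_walk = stats::runif(1, 0.10, 0.30),
    amp_stairs = stats::runif(1, 0.15, 0.40),
    noise_sigma = 0.03,
    gyro_amp_dps = stats::runif(1, 30, 80),
    mag_field = c(0.25, 0.35, 0),
    laying_axis = sample(c("y", "z"), 1),
    seed = seed
  )
}

# gravity direction (device frame, g units) per raw activity label
.posture_dir <- function(raw_label, laying_axis) {
  if (raw_label == "laying") {
    if (laying_axis == "y") c(0, -1, 0) else c(0, 0, -1)
  } else {
    c(-1, 0, 0)  # upright: -X is the vertical axis
  }
}

#' Simulate one annotated 9-channel IMU recording
#'
#' Generates the statistical structure the recognition pipeline assumes, at
#' 25 Hz: static postures are the oriented gravity vector plus Gaussian
#' sensor noise; walking and stairs superimpose a step-frequency sinusoid
#' with harmonics on the vertical and anteroposterior axes (stairs with
#' stronger harmonics and lateral sway at half the step rate); every
#' activity change interpolates the device orientation smoothly over the
#' transition window and adds a low-frequency posture-adjustment burst;
#' the gyroscope oscillates during locomotion and is near-zero at rest; the
#' magnetometer is a fixed field vector co-rotated with the body
#' orientation. Fully reproducible from `params$seed`.
#'
#' @param params parameter list from [draw_subject_params()].
#' @param protocol raw-label [annotation_track()]; [default_protocol()] by
#'   default.
#' @param fs sampling rate (Hz).
#' @param transition_s duration of the smooth orientation change at every
#'   activity boundary.
#' @param subject_id subject identifier for the returned recording.
#' @return list with `rec` (9-channel [recording()], device kind `SYNTH`)
#'   and `track` (the raw-label protocol).
#' @export
simulate_recording <- function(params, protocol = default_protocol(),
                               fs = 25, transition_s = 5,
                               subject_id = paste0("synth", params$seed)) {
  set.seed(params$seed)
  n <- floor(max(protocol$end_s) * fs)
  t <- (seq_len(n) - 1) / fs
  raw <- tolower(protocol$label)
  g_dir <- matrix(0, n, 3)
  env <- numeric(n)       # locomotion amplitude envelope
  freq <- numeric(n)      # instantaneous step frequency
  is_stairs <- logical(n)
  burst <- numeric(n)     # posture-adjustment burst envelope
  for (i in seq_len(nrow(protocol))) {
    sel <- t >= protocol$start_s[i] & t < protocol$end_s[i]
    cur <- .posture_dir(raw[i], params$laying_axis)
    prev <- if (i == 1) cur else .posture_dir(raw[i - 1], params$laying_axis)
    tau <- t[sel] - protocol$start_s[i]
    f_tr <- pmin(tau / transition_s, 1)
    g_dir[sel, ] <- t(vapply(f_tr, function(f) .slerp(prev, cur, f),
                             numeric(3)))
    loco <- raw[i] %in% c("walking", "upstairs", "downstairs")
    if (loco) {
      env[sel] <- f_tr
      freq[sel] <- if (raw[i] == "walking") params$step_freq_walk
                   else params$step_freq_stairs
      is_stairs[sel] <- raw[i] != "walking"
    }
    if (i > 1) burst[sel] <- sin(pi * pmin(tau / transition_s, 1))^2
  }
  phase <- cumsum(2 * pi * freq / fs)
  amp <- ifelse(is_stairs, params$amp_stairs, params$amp_walk) * env
  harm <- ifelse(is_stairs, 0.8, 0.4)
  osc_v <- amp * (sin(phase) + harm * sin(2 * phase))
  osc_ap <- 0.5 * amp * sin(phase + pi / 4)
  osc_lat <- ifelse(is_stairs, 0.5, 0.1) * amp * sin(phase / 2)
  move <- 0.25 * burst * sin(2 * pi * 0.8 * t)
  acc <- g_dir
  acc[, 1] <- acc[, 1] + osc_v + move
  acc[, 2] <- acc[, 2] + osc_lat
  acc[, 3] <- acc[, 3] + osc_ap + 0.6 * move
  acc <- acc + matrix(stats::rnorm(3 * n, 0, params$noise_sigma), n, 3)
  gyr_env <- env * params$gyro_amp_dps
  gyr <- cbind(0.3 * gyr_env * sin(phase + pi / 6),
               gyr_env * sin(phase),
               0.6 * gyr_env * sin(phase + pi / 3)) +
    matrix(stats::rnorm(3 * n, 0, 1), n, 3)
  mag <- t(vapply(seq_len(n), function(k) {
    A <- .rotation_between(c(-1, 0, 0), g_dir[k, ])
    as.numeric(A %*% params$mag_field)
  }, numeric(3))) + matrix(stats::rnorm(3 * n, 0, 0.01), n, 3)
  data <- cbind(acc, gyr, mag)
  colnames(data) <- CANONICAL_CHANNELS
  rec <- recording(data, subject_id = subject_id, device_kind = "SYNTH",
                   fs = fs)
  list(rec = rec, track = protocol)
}

#' Rotate a recording's sensor axes
#'
#' Emulates a mis-oriented device: every sensor triplet (accelerometer,
#' gyroscope, magnetometer) is rotated per sample by the proper rotation
#' `R` (active convention). Per-sample magnitudes are preserved exactly.
#'
#' @param rec a [recording()].
#' @param R `3 x 3` proper rotation matrix.
#' @return the rotated [recording()].
#' @export
apply_rotation <- function(rec, R) {
  R <- as.matrix(R)
  if (max(abs(crossprod(R) - diag(3))) > 1e-8 || abs(det(R) - 1) > 1e-8) {
    stop("R must be a proper rotation matrix (orthonormal, det +1)")
  }
  out <- rec
  for (s in c("acc", "gyr", "mag")) {
    cols <- paste0(s, c("_x", "_y", "_z"))
    if (all(cols %in% colnames(rec$data))) {
      out$data[, cols] <- rec$data[, cols, drop = FALSE] %*% t(R)
    }
  }
  out
}

#' Inject a device measurement bias
#'
#' Emulates the older garment device's measurement profile: each
#' accelerometer axis is transformed as `scale * x + offset`. The recording
#' is re-tagged as device kind `WWS`.
#'
#' @param rec a [recording()].
#' @param offset numeric length-3 per-axis offset (g).
#' @param scale numeric length-3 per-axis positive scale.
#' @return the biased [recording()].
#' @export
apply_device_bias <- function(rec, offset = c(0, 0, 0), scale = c(1, 1, 1)) {
  offset <- rep_len(offset, 3); scale <- rep_len(scale, 3)
  if (any(scale <= 0)) stop("scale factors must be positive")
  out <- rec
  cols <- c("acc_x", "acc_y", "acc_z")
  out$data[, cols] <- sweep(sweep(rec$data[, cols, drop = FALSE], 2, scale,
                                  "*"), 2, offset, "+")
  out$device_kind <- "WWS"
  out
}

#' Generate a full synthetic cohort
#'
#' Training subjects are always upright with the reference device profile
#' (they define the reference space); test subjects are mis-oriented and/or
#' biased according to the requested fractions. Rotations are drawn as a
#' uniform random axis with an angle uniform in 45-180 degrees, re-drawn
#' until the rotation moves the vertical (gravity) axis by at least 45
#' degrees: the injected condition emulates a visibly mis-worn device (the
#' kind a rater would flag as incorrectly oriented), not wear jitter or a
#' pure heading change that leaves the garment looking correctly placed.
#' Bias offsets have magnitude uniform in 0.1-0.3 g with random sign per
#' axis. Ground-truth injector metadata is kept for evaluation.
#'
#' @param n_train,n_test subject counts (`n_train >= 2`).
#' @param fraction_rotated,fraction_wws fractions of test subjects receiving
#'   a rotation / a device bias (rounded; independent assignments).
#' @param master_seed integer seed driving every draw.
#' @param protocol raw-label protocol passed to [simulate_recording()].
#' @return list of class `"SynthCohort"` with `train`, `test` (lists of
#'   `list(rec, track)`), and `meta` (data.frame with per-subject ground
#'   truth: `subject_id`, `split`, `rotated`, `wws`) plus injector details
#'   in `injectors`.
#' @export
make_cohort <- function(n_train = 8, n_test = 12, fraction_rotated = 0.5,
                        fraction_wws = 0.2, master_seed = 1,
                        protocol = default_protocol()) {
  if (n_train < 2) stop("n_train must be at least 2")
  set.seed(master_seed)
  n <- n_train + n_test
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  n_rot <- round(fraction_rotated * n_test)
  n_wws <- round(fraction_wws * n_test)
  rot_idx <- sample(n_test, n_rot)
  wws_idx <- sample(n_test, n_wws)
  injectors <- vector("list", n_test)
  make_one <- function(i, split) {
    sid <- sprintf("%s%02d", split, i)
    sim <- simulate_recording(draw_subject_params(seeds[
      if (split == "train") i else n_train + i]),
      protocol = protocol, subject_id = sid)
    sim
  }
  train <- lapply(seq_len(n_train), make_one, split = "train")
  test <- lapply(seq_len(n_test), make_one, split = "test")
  for (i in seq_len(n_test)) {
    inj <- list(R = NULL, offset = NULL)
    if (i %in% rot_idx) {
      repeat {
        R <- rotation_about(stats::rnorm(3), stats::runif(1, 45, 180))
        # displacement of the vertical axis: angle between R(-x) and -x
        if (acos(min(1, max(-1, R[1, 1]))) >= 45 * pi / 180) break
      }
      inj$R <- R
      test[[i]]$rec <- apply_rotation(test[[i]]$rec, inj$R)
    }
    if (i %in% wws_idx) {
      inj$offset <- sample(c(-1, 1), 3, replace = TRUE) *
        stats::runif(3, 0.1, 0.3)
      test[[i]]$rec <- apply_device_bias(test[[i]]$rec, offset = inj$offset)
    }
    injectors[[i]] <- inj
  }
  meta <- data.frame(
    subject_id = c(vapply(train, function(s) s$rec$subject_id, character(1)),
                   vapply(test, function(s) s$rec$subject_id, character(1))),
    split = rep(c("train", "test"), c(n_train, n_test)),
    rotated = c(rep(FALSE, n_train), seq_len(n_test) %in% rot_idx),
    wws = c(rep(FALSE, n_train), seq_len(n_test) %in% wws_idx),
    stringsAsFactors = FALSE)
  structure(list(train = train, test = test, meta = meta,
                 injectors = injectors, master_seed = master_seed),
            class = "SynthCohort")
}

#' Write a cohort to disk as CSV files plus a JSON manifest
#'
#' @param cohort a [make_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in c(cohort$train, cohort$test)) {
    sid <- s$rec$subject_id
    write_recording(s$rec, file.path(dir, paste0(sid, "_rec.csv")))
    write_annotations(s$track, file.path(dir, paste0(sid, "_annot.csv")))
  }
  meta <- cohort$meta
  jsonlite::write_json(meta, file.path(dir, "cohort.json"), dataframe = "rows")
  invisible(dir)
}
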