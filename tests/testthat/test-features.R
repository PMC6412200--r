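test_that("the manifests pin exactly 254 and 90 features", {
  man <- axis_manifest()
  rman <- rotinv_manifest()
  expect_equal(nrow(man), 254)
  expect_equal(nrow(rman), 90)
  expect_setequal(unique(man$primitive), FEATURE_PRIMITIVES)
  # manifest serialization round-trips
  path <- withr::local_tempfile(fileext = ".tsv")
  write_manifest(man, path)
  back <- read_manifest(path)
  expect_equal(back$name, man$name)
  expect_equal(back$primitive, man$primitive)
})

test_that("primitive values match closed forms and oracles", {
  w <- rep(0.5, 68)
  expect_equal(primitive_value("MEAN", w), 0.5)
  expect_equal(primitive_value("SMA", matrix(1, 68, 3)), 3)
  expect_equal(primitive_value("ENERGY", w), 0.25)
  expect_equal(primitive_value("MAX", w), 0.5)
  expect_equal(primitive_value("IQR", w), 0)

  # AR(1) with coefficient 0.5: Yule-Walker on a long realization
  set.seed(7)
  x <- as.numeric(stats::arima.sim(list(ar = 0.5), n = 1e5))
  coefs <- primitive_value("AR_COEF", x, param = 4)
  expect_equal(length(coefs), 4)
  expect_lt(abs(coefs[1] - 0.5), 0.1)

  # pure sinusoid on the 128-point FFT grid peaks at its own bin
  fs <- 25
  for (k in c(5, 20, 40)) {
    t <- (0:67) / fs
    x <- sin(2 * pi * (k * fs / 128) * t)
    s <- imuhar:::.spectrum64(x, fs)
    expect_equal(primitive_value("MAX_FREQ_IND", s), k)
  }

  # zero-variance correlation is defined as 0 with a warning
  expect_warning(v <- primitive_value("CORRELATION", list(rep(1, 68), rnorm(68))),
                 "zero-variance")
  expect_equal(v, 0)
})

test_that("extraction is deterministic and respects manifest lengths", {
  sub <- short_subject()
  b <- signal_bundle(sub$rec)
  w <- bundle_window(b, 1)
  v1 <- extract_features(w)
  v2 <- extract_features(w)
  expect_identical(v1, v2)
  expect_length(v1, 254)
  expect_length(extract_features(w, rotinv_manifest()), 90)
})

test_that("triplet reduction matches hand computations", {
  v <- rep(0, 254)
  man <- axis_manifest()
  # a MEAN triplet (3,4,0) reduces to 5
  grp <- man$group == "body_acc|t|MEAN"
  v[grp] <- c(3, 4, 0)
  red <- rotation_invariant_reduce(v)
  expect_equal(unname(red["body_acc_mean_norm"]), 5)
  # an ENERGY triplet reduces as the RMS of the 3-D signal
  v2 <- rep(0, 254)
  v2[man$group == "body_acc|t|ENERGY"] <- c(1, 4, 4)
  expect_equal(unname(rotation_invariant_reduce(v2)["body_acc_energy_norm"]), 3)
  expect_error(rotation_invariant_reduce(rep(0, 100)), "layout mismatch")
})

test_that("reduced MEAN/STD triplets equal their rotation-invariant closed forms", {
  sub <- short_subject(103)
  b <- signal_bundle(sub$rec)
  w <- bundle_window(b, 1000)
  red <- rotation_invariant_reduce(extract_features(w))
  # norm of the column-mean vector
  expect_equal(unname(red["gravity_acc_mean_norm"]),
               sqrt(sum(colMeans(w$gravity_acc)^2)), tolerance = 1e-12)
  # sqrt of the covariance trace
  expect_equal(unname(red["body_acc_std_norm"]),
               sqrt(sum(apply(w$body_acc, 2, sd)^2)), tolerance = 1e-12)
})

test_that("certified-invariant reduced features survive arbitrary rotation", {
  sub <- short_subject(104)
  set.seed(11)
  b <- signal_bundle(sub$rec)
  inv <- rotinv_manifest()$invariant
  starts <- c(1, 500, 1500, 2500)
  base <- t(vapply(starts, function(s) {
    rotation_invariant_reduce(extract_features(bundle_window(b, s)))
  }, numeric(90)))
  for (rep in 1:3) {
    rot <- apply_rotation(sub$rec, random_rotation())
    br <- signal_bundle(rot)
    rotv <- t(vapply(starts, function(s) {
      rotation_invariant_reduce(extract_features(bundle_window(br, s)))
    }, numeric(90)))
    reldiff <- abs(rotv[, inv] - base[, inv]) /
      pmax(abs(base[, inv]), 1e-9)
    expect_lt(max(reldiff), 1e-6)
  }
})

test_that("non-certified reduced features are stable in aggregate under rotation", {
  # window-by-window, argmax-type features on noise spectra may jump under
  # rotation; averaged over the static-posture windows of a recording the
  # isotropic sensor noise makes every reduced feature distributionally
  # stable (relative change < 15%)
  sub <- short_subject(105)
  labs <- truth_window_labels(sub$rec, sub$track)
  static_idx <- which(labs %in% c("SIT_STAND", "LAYING"))[1:30]
  avg_reduced <- function(rec) {
    b <- signal_bundle(rec)
    ws <- segment_windows(rec)
    colMeans(t(vapply(ws$starts[static_idx], function(s) {
      rotation_invariant_reduce(extract_features(bundle_window(b, s)))
    }, numeric(90))))
  }
  base <- avg_reduced(sub$rec)
  rman <- rotinv_manifest()
  # stability tiers: the 15% bound cannot hold for l1-type aggregates (the
  # triaxial SMA varies by up to sqrt(3)-1 = 73% under rotation by
  # construction), for AR coefficients of the quasi-constant gravity signal
  # (near-degenerate fits driven by residual noise), or as tightly for
  # spectral shape statistics (skewness/kurtosis of 64-bin spectra have
  # high sampling variance); those carry documented looser bounds
  is_sma <- rman$primitive == "SMA" & rman$kind == "pass" &
    !grepl("mag", rman$signal)
  is_grav_ar <- rman$signal == "gravity_acc" & rman$primitive == "AR_COEF"
  is_shape <- rman$primitive %in% c("SKEWNESS_F", "KURTOSIS_F")
  tight <- !rman$invariant & !is_sma & !is_grav_ar & !is_shape
  set.seed(17)
  for (rep in 1:2) {
    rotated <- avg_reduced(apply_rotation(sub$rec, random_rotation()))
    rel <- abs(rotated - base) / pmax(abs(base), 1e-9)
    expect_lt(max(rel[tight]), 0.15)
    expect_lt(max(rel[is_shape]), 0.50)
    expect_lt(max(rel[is_sma]), 0.75)
    expect_lt(max(rel[is_grav_ar]), 1.00)
  }
})

test_that("the z-score scaler matches the closed form and round-trips", {
  X <- matrix(c(1, 2, 3), ncol = 1)
  sp <- fit_scaler(X)
  expect_equal(as.numeric(apply_scaler(X, sp)),
               c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  # constant columns are guarded
  Xc <- cbind(c(1, 2, 3), c(7, 7, 7))
  spc <- fit_scaler(Xc)
  expect_equal(apply_scaler(Xc, spc)[, 2], rep(0, 3))
  # scaled training data has mean 0, population sd 1
  set.seed(3)
  Xr <- matrix(rnorm(200), ncol = 4)
  Z <- apply_scaler(Xr, fit_scaler(Xr))
  expect_lt(max(abs(colMeans(Z))), 1e-9)
  expect_equal(sqrt(colMeans(sweep(Z, 2, colMeans(Z))^2)), rep(1, 4),
               tolerance = 1e-9, ignore_attr = TRUE)
  # apply-then-invert on new data is the identity
  Xnew <- matrix(rnorm(40), ncol = 4)
  expect_equal(invert_scaler(apply_scaler(Xnew, fit_scaler(Xr)),
                             fit_scaler(Xr)), Xnew, tolerance = 1e-12)
  expect_error(apply_scaler(matrix(1, 2, 3), fit_scaler(Xr)), "shape")
})
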