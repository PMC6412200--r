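test_that("the default protocol yields 270 s / 6750 samples with all classes", {
  sim <- simulate_recording(draw_subject_params(201))
  expect_equal(nrow(sim$rec$data), 6750)
  expect_equal(ncol(sim$rec$data), 9)
  labs <- truth_window_labels(sim$rec, sim$track)
  expect_setequal(unique(labs[!is.na(labs)]), ACTIVITY_LEVELS)
})

test_that("static postures read 1 g on average and locomotion oscillates", {
  p <- draw_subject_params(202)
  sim <- simulate_recording(p)
  fs <- 25
  mag <- magnitude(sim$rec$data[, 1:3])
  static <- mag[(10 * fs):(50 * fs)]   # inside the standing bout
  expect_lt(abs(mean(static) - 1), 3 * p$noise_sigma)
  walking <- mag[(130 * fs):(175 * fs)]
  expect_gt(stats::sd(walking), 3 * stats::sd(static))
  # gyroscope near zero at rest, oscillating while walking
  gyr <- magnitude(sim$rec$data[, 4:6])
  expect_gt(mean(gyr[(130 * fs):(175 * fs)]), 5 * 0 + mean(gyr[(10 * fs):(50 * fs)]))
})

test_that("simulation is bit-identical under a fixed seed", {
  a <- simulate_recording(draw_subject_params(203))
  b <- simulate_recording(draw_subject_params(203))
  expect_identical(a$rec$data, b$rec$data)
})

test_that("apply_rotation follows the active convention and is an isometry", {
  sub <- short_subject(204)
  expect_equal(apply_rotation(sub$rec, diag(3))$data, sub$rec$data)
  Rz <- rotation_about(c(0, 0, 1), 90)
  rot <- apply_rotation(sub$rec, Rz)
  expect_equal(rot$data[, "acc_x"], -sub$rec$data[, "acc_y"],
               tolerance = 1e-12)
  R <- random_rotation()
  rot2 <- apply_rotation(sub$rec, R)
  expect_equal(magnitude(rot2$data[, 1:3]), magnitude(sub$rec$data[, 1:3]),
               tolerance = 1e-12)
  expect_error(apply_rotation(sub$rec, diag(3) * 2), "proper rotation")
})

test_that("device bias shifts the estimated baseline by exactly the offset", {
  sub <- short_subject(205)
  biased <- apply_device_bias(sub$rec, offset = c(0.2, 0, 0))
  b0 <- estimate_baseline(sub$rec)
  b1 <- estimate_baseline(biased)
  expect_equal(b1[["acc_x"]] - b0[["acc_x"]], 0.2, tolerance = 1e-12)
  expect_equal(b1[["acc_y"]], b0[["acc_y"]], tolerance = 1e-12)
  expect_equal(apply_device_bias(sub$rec)$data, sub$rec$data)
  expect_error(apply_device_bias(sub$rec, scale = c(-1, 1, 1)), "positive")
})

test_that("cohorts have the requested composition and are reproducible", {
  co <- make_cohort(8, 12, 0.5, 0.2, master_seed = 77)
  expect_length(co$train, 8)
  expect_length(co$test, 12)
  expect_equal(sum(co$meta$rotated), 6)
  expect_equal(sum(co$meta$wws), round(0.2 * 12))
  expect_true(all(!co$meta$rotated[co$meta$split == "train"]))
  co2 <- make_cohort(8, 12, 0.5, 0.2, master_seed = 77)
  expect_identical(co$test[[5]]$rec$data, co2$test[[5]]$rec$data)
  # every injected rotation moves the vertical axis substantially
  for (inj in co$injectors) {
    if (!is.null(inj$R)) {
      expect_gte(acos(min(1, inj$R[1, 1])) * 180 / pi, 45 - 1e-9)
    }
  }
  # every subject has windows of every class
  labs <- truth_window_labels(co$train[[1]]$rec, co$train[[1]]$track)
  expect_setequal(unique(labs[!is.na(labs)]), ACTIVITY_LEVELS)
})

test_that("static and locomotion windows separate in the (STD, ENERGY) plane", {
  sub <- simulate_recording(draw_subject_params(206))
  b <- signal_bundle(sub$rec)
  labs <- truth_window_labels(sub$rec, sub$track)
  ws <- segment_windows(sub$rec, build_labels(sub$track))
  stds <- vapply(seq_along(ws$starts), function(i) {
    stats::sd(bundle_window(b, ws$starts[i])$mag_body_acc)
  }, numeric(1))
  static <- labs %in% c("SIT_STAND", "LAYING")
  loco <- labs %in% c("WALKING", "STAIRS")
  expect_lt(max(stds[static]), min(stds[loco]))
})

test_that("cohorts round-trip through the on-disk CSV layout", {
  co <- make_cohort(2, 1, 0, 0, master_seed = 55,
                    protocol = short_protocol())
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  files <- list.files(dir)
  expect_true("cohort.json" %in% files)
  rec <- read_recording(file.path(dir, "train01_rec.csv"))
  expect_equal(rec$data, co$train[[1]]$rec$data, tolerance = 1e-12)
  track <- read_annotations(file.path(dir, "train01_annot.csv"))
  expect_equal(track$label, co$train[[1]]$track$label)
})
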