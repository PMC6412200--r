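test_that("baselines of constant and burst-contaminated recordings are exact", {
  fs <- 25
  const <- recording(matrix(rep(c(0.2, -1, 0.5), each = 500), ncol = 3,
                            dimnames = list(NULL, c("acc_x", "acc_y", "acc_z"))),
                     fs = fs)
  expect_equal(unclass(estimate_baseline(const)),
               c(acc_x = 0.2, acc_y = -1, acc_z = 0.5))

  # 60 s static at -1 g with a 5 s high-variance burst: quiet-segment filter
  # must exclude the burst
  n <- 60 * fs
  x <- rep(-1, n)
  burst <- 500:(500 + 5 * fs)
  set.seed(5)
  x[burst] <- x[burst] + rnorm(length(burst), 0, 0.5)
  rec <- recording(cbind(acc_x = x, acc_y = 0, acc_z = 0), fs = fs)
  expect_lt(abs(estimate_baseline(rec)[["acc_x"]] - (-1)), 1e-3)

  # shorter than one segment: whole-series mean with a warning
  tiny <- recording(cbind(acc_x = c(1, 3), acc_y = c(0, 0), acc_z = c(2, 2)),
                    fs = fs)
  expect_warning(bl <- estimate_baseline(tiny), "whole-series mean")
  expect_equal(bl[["acc_x"]], 2)
})

test_that("alignment is an exact shift: idempotent, moment-preserving", {
  sub <- short_subject(110)
  rec <- sub$rec
  own <- estimate_baseline(rec)
  # own == target: identity
  same <- align_baseline(rec, own, own = own)
  expect_equal(same$data, rec$data, tolerance = 1e-12)
  # align to zero: pure shift by the own baseline
  zero <- structure(c(acc_x = 0, acc_y = 0, acc_z = 0),
                    class = "BaselineVector")
  shifted <- align_baseline(rec, zero, own = own)
  expect_equal(shifted$data[, "acc_x"], rec$data[, "acc_x"] - own[["acc_x"]])
  # post-condition: the aligned recording's baseline equals the target
  expect_equal(unclass(estimate_baseline(shifted)), unclass(zero),
               tolerance = 1e-9)
  # idempotence
  twice <- align_baseline(shifted, zero)
  expect_lt(max(abs(twice$data - shifted$data)), 1e-9)
  # central moments of order >= 2 are untouched
  for (ax in c("acc_x", "acc_y", "acc_z")) {
    expect_equal(stats::var(shifted$data[, ax]), stats::var(rec$data[, ax]),
                 tolerance = 1e-12)
    x0 <- rec$data[, ax] - mean(rec$data[, ax])
    x1 <- shifted$data[, ax] - mean(shifted$data[, ax])
    expect_equal(mean(x1^3), mean(x0^3), tolerance = 1e-12)
  }
})

test_that("injected device offsets are recovered exactly by alignment", {
  sub <- short_subject(111)
  offset <- c(0.23, -0.17, 0.08)
  biased <- apply_device_bias(sub$rec, offset = offset)
  expect_equal(biased$device_kind, "WWS")
  target <- estimate_baseline(sub$rec)
  aligned <- align_baseline(biased, target)
  # residual per-axis offset relative to the unbiased recording
  resid <- colMeans(aligned$data[, 1:3] - sub$rec$data[, 1:3])
  expect_lt(max(abs(resid)), 1e-6)
})
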