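make_hist_pair <- function(seed = 1, n = 5000) {
  set.seed(seed)
  edges <- lapply(1:3, function(i) seq(-3, 3, length.out = 17))
  a <- hist3d(matrix(rnorm(3 * n), ncol = 3), edges)
  b <- hist3d(matrix(rnorm(3 * n, mean = 0.3), ncol = 3), edges)
  list(a = a, b = b, edges = edges)
}

test_that("ks3d is a pseudometric: zero on equals, one on disjoint, symmetric", {
  hp <- make_hist_pair()
  expect_equal(ks3d(hp$a, hp$a), 0)
  expect_equal(ks3d(hp$a, hp$b), ks3d(hp$b, hp$a))
  expect_gte(ks3d(hp$a, hp$b), 0)
  expect_lte(ks3d(hp$a, hp$b), 1)
  # disjoint unit masses in opposite corners
  edges <- hp$edges
  lo <- hist3d(matrix(rep(-2.9, 3), 1), edges)
  hi <- hist3d(matrix(rep(2.9, 3), 1), edges)
  expect_equal(ks3d(lo, hi), 1)
  bad <- hist3d(matrix(0, 1, 3), lapply(1:3, function(i) seq(-1, 1, length.out = 17)))
  expect_error(ks3d(hp$a, bad), "grid error")
})

test_that("the reference space calibrates theta and the vertical interval", {
  # two identical recordings: theta must be exactly 0
  rec <- short_subject(120)$rec
  sp0 <- fit_reference_space(list(rec, rec))
  expect_equal(sp0$theta, 0)
  expect_error(fit_reference_space(list(rec)), "2 training recordings")

  # standard-normal vertical axis: central-80% interval near +-1.2816
  set.seed(8)
  n <- 2e5
  mk <- function() recording(cbind(acc_x = rnorm(n), acc_y = rnorm(n),
                                   acc_z = rnorm(n)), fs = 25)
  sp <- fit_reference_space(list(mk(), mk()))
  expect_equal(unname(sp$vertical_interval["low"]), qnorm(0.1), tolerance = 0.05)
  expect_equal(unname(sp$vertical_interval["high"]), qnorm(0.9), tolerance = 0.05)
})

test_that("rule 1 accepts in-distribution data and rejects shifts/rotations", {
  subs <- lapply(121:124, function(s) short_subject(s)$rec)
  space <- fit_reference_space(subs)
  test_rec <- short_subject(130)$rec
  expect_true(vertical_axis_check(test_rec, space))
  # +2 g shift on the vertical axis: disjoint intervals
  shifted <- test_rec
  shifted$data[, "acc_x"] <- shifted$data[, "acc_x"] + 2
  expect_false(vertical_axis_check(shifted, space))
  # 90 degrees about Z moves gravity off X
  rot <- apply_rotation(test_rec, rotation_about(c(0, 0, 1), 90))
  expect_false(vertical_axis_check(rot, space))
})

test_that("routing follows the two-rule logic and is order-invariant", {
  subs <- lapply(131:135, function(s) short_subject(s)$rec)
  space <- fit_reference_space(subs)
  # training recordings route axis-dependent under their own space
  for (r in subs) {
    expect_equal(select_model(r, space)$model, "AXIS_DEPENDENT")
  }
  fresh <- short_subject(140)$rec
  sel_up <- select_model(fresh, space)
  expect_equal(sel_up$model, "AXIS_DEPENDENT")
  # heavily rotated recording goes rotation-invariant
  rot <- apply_rotation(fresh, rotation_about(c(0, 0, 1), 120))
  sel_rot <- select_model(rot, space)
  expect_equal(sel_rot$model, "ROTATION_INVARIANT")
  expect_equal(sel_rot$rule, 2L)
  # an in-distribution recording that fails rule 1 (margin forced shut) is
  # recovered by rule 2: its raw histogram sits within normal variation
  sel_r2 <- select_model(fresh, space, margin = -10)
  expect_equal(sel_r2$model, "AXIS_DEPENDENT")
  expect_equal(sel_r2$rule, 2L)
  expect_lt(sel_r2$min_dist, space$theta)
  # a grossly baseline-shifted recording exceeds normal variation and takes
  # the conservative rotation-invariant path
  biased <- apply_device_bias(fresh, offset = c(0.6, -0.5, 0.55))
  sel_b <- select_model(biased, space)
  expect_equal(sel_b$rule, 2L)
  expect_equal(sel_b$model, "ROTATION_INVARIANT")
  # routing does not depend on the order of reference histograms
  space_rev <- space
  space_rev$reference_histograms <- rev(space$reference_histograms)
  sel_rot2 <- select_model(rot, space_rev)
  expect_equal(sel_rot2$model, sel_rot$model)
  expect_equal(sel_rot2$min_dist, sel_rot$min_dist)
})
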