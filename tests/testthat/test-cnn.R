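test_that("input layouts are pure rearrangements with the pinned shapes", {
  set.seed(71)
  w <- matrix(rnorm(68 * 9), 68, 9, dimnames = list(NULL, CANONICAL_CHANNELS))
  x1 <- layout_input(w, "CNN1")
  expect_equal(dim(x1), c(68, 1, 9))
  expect_equal(sum(abs(x1)), sum(abs(w)))
  x2 <- layout_input(w, "CNN2")
  expect_equal(dim(x2), c(68, 3, 3))
  # invert the CNN2 permutation: sensor s, axis a -> channel (s-1)*3+a
  back <- matrix(0, 68, 9)
  for (s in 1:3) for (a in 1:3) back[, (s - 1) * 3 + a] <- x2[, s, a]
  expect_equal(back, unname(w))
  x3 <- layout_input(w, "CNN3")
  expect_equal(dim(x3), c(68, 12, 1))
  # rows 10-12 duplicate rows 1-3 (accelerometer reintroduced)
  expect_equal(x3[, 10:12, 1], x3[, 1:3, 1])
  expect_equal(sum(abs(x3)), sum(abs(w)) + sum(abs(w[, 1:3])))
  expect_error(layout_input(w[, 1:3], "CNN1"), "9 channels")
})

test_that("descriptors follow valid-convolution arithmetic with clamping", {
  d1 <- build_network(cnn_spec("CNN1"))
  conv_w <- vapply(Filter(function(l) l$type == "conv", d1$layers),
                   function(l) l$out_shape[1], numeric(1))
  expect_equal(conv_w, c(64, 60, 56))
  d3 <- build_network(cnn_spec("CNN3"))
  convs3 <- Filter(function(l) l$type == "conv", d3$layers)
  expect_equal(convs3[[1]]$out_shape, c(64, 3, 59))  # (12-6)/3+1 = 3
  expect_equal(convs3[[2]]$kernel[2], 3)             # clamped to height 3
  expect_equal(convs3[[2]]$out_shape[2], 1)
  d2 <- build_network(cnn_spec("CNN2"))
  convs2 <- Filter(function(l) l$type == "conv", d2$layers)
  expect_equal(convs2[[1]]$out_shape, c(64, 1, 100))
  expect_equal(convs2[[2]]$kernel[2], 1)

  # parameter counts equal closed-form sums computed independently
  count1 <- (5 * 1 * 9 * 65 + 65) + 2 * 65 +
    (5 * 1 * 65 * 100 + 100) + 2 * 100 +
    (5 * 1 * 100 * 45 + 45) + 2 * 45 +
    (56 * 1 * 45 * 583 + 583) + (583 * 5 + 5)
  expect_equal(sum(vapply(d1$layers, `[[`, numeric(1), "n_params")), count1)
  count3_conv1 <- 5 * 6 * 1 * 59 + 59
  expect_equal(convs3[[1]]$n_params, count3_conv1)

  # too many layers for the temporal extent
  tiny <- cnn_spec("CNN1")
  tiny$kernel <- c(40L, 1L)
  expect_error(build_network(tiny), "architecture error")
})

test_that("softmax outputs are proper distributions for all three layouts", {
  set.seed(72)
  wins <- lapply(1:8, function(i) matrix(rnorm(68 * 9), 68, 9))
  labs <- rep(c("WALKING", "SIT_STAND"), 4)
  for (layout in c("CNN1", "CNN2", "CNN3")) {
    spec <- cnn_spec(layout)
    spec$filters <- c(4L, 5L, 4L); spec$dense_size <- 8L; spec$batch <- 4L
    m <- train_cnn(wins, labs, spec, epochs = 1, seed = 3)
    probs <- predict_cnn(m, wins)
    expect_equal(rowSums(probs), rep(1, 8), tolerance = 1e-6)
    expect_true(all(probs >= 0))
  }
})

test_that("training is deterministic and learns a separable toy problem", {
  set.seed(73)
  # two synthetic window families differing in oscillation frequency
  mk <- function(f) {
    t <- (0:67) / 25
    base <- matrix(rnorm(68 * 9, 0, 0.05), 68, 9)
    base[, 1] <- base[, 1] + sin(2 * pi * f * t)
    base
  }
  wins <- c(lapply(runif(30, 1.6, 2.0), mk), lapply(runif(30, 0.6, 1.0), mk))
  labs <- rep(c("WALKING", "STAIRS"), each = 30)
  spec <- cnn_spec("CNN1")
  spec$filters <- c(8L, 8L, 8L); spec$dense_size <- 16L; spec$batch <- 20L
  m1 <- train_cnn(wins, labs, spec, epochs = 15, seed = 11)
  m2 <- train_cnn(wins, labs, spec, epochs = 15, seed = 11)
  expect_identical(m1$history, m2$history)
  ev <- evaluate_cnn(m1, wins, labs)
  expect_gt(ev$accuracy, 0.9)
  expect_equal(dim(ev$confusion), c(2, 2))
  expect_equal(unname(rowSums(ev$confusion)), c(100, 100), tolerance = 1e-9)
})
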