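test_that("recordings round-trip through CSV and keep canonical channel order", {
  rec <- toy_recording(680)
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path, subject_id = "toy")
  expect_equal(back$data, rec$data, tolerance = 1e-12)
  expect_equal(nrow(back$data), 680)
  expect_equal(colnames(back$data), c("acc_x", "acc_y", "acc_z"))

  # 9 named columns given shuffled are reordered canonically
  set.seed(1)
  m <- matrix(rnorm(9 * 50), ncol = 9)
  shuffled <- sample(CANONICAL_CHANNELS)
  colnames(m) <- shuffled
  df <- as.data.frame(m)
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, p2, row.names = FALSE)
  rec9 <- read_recording(p2)
  expect_equal(colnames(rec9$data), CANONICAL_CHANNELS)
  # values must follow the columns, not the positions
  expect_equal(rec9$data[, "gyr_y"], m[, which(shuffled == "gyr_y")])
})

test_that("malformed inputs are rejected", {
  expect_error(recording(matrix(1:10, ncol = 2)), "channel")
  m <- matrix(rnorm(30), ncol = 3,
              dimnames = list(NULL, c("acc_x", "acc_y", "bogus")))
  expect_error(recording(m), "unknown channel")
  rec <- toy_recording()
  expect_error(read_recording(tempfile(), schema = c("nope")), "unknown")
})

test_that("build_labels merges classes and carves transition prefixes", {
  out <- build_labels(annotation_track(0, 60, "standing"))
  expect_equal(as.data.frame(out),
               data.frame(start_s = c(0, 5), end_s = c(5, 60),
                          label = c("TRANSITION", "SIT_STAND")))
  short <- build_labels(annotation_track(0, 4, "walking"))
  expect_equal(short$label, "TRANSITION")
  expect_equal(short$end_s, 4)
  down <- build_labels(annotation_track(0, 30, "downstairs"))
  expect_equal(down$label, c("TRANSITION", "STAIRS"))
  expect_equal(down$start_s, c(0, 5))
  expect_equal(down$end_s, c(5, 30))
  expect_error(build_labels(annotation_track(0, 10, "jumping")),
               "unknown raw label")
})

test_that("build_labels covers exactly the input intervals with no overlap", {
  track <- short_protocol()
  built <- build_labels(track)
  expect_equal(min(built$start_s), min(track$start_s))
  expect_equal(max(built$end_s), max(track$end_s))
  # contiguity: each interval begins where the previous ended
  expect_equal(built$start_s[-1], built$end_s[-nrow(built)])
  expect_true(all(built$label %in% ACTIVITY_LEVELS))
})

test_that("segment_windows implements the 68/34 geometry", {
  rec <- toy_recording(680)
  ws <- segment_windows(rec)
  expect_equal(length(ws$starts), 19)          # floor((680-68)/34)+1
  expect_equal(ws$hop, 34L)
  expect_equal(unique(diff(ws$starts)), 34L)
  expect_equal(dim(ws$data[[1]]), c(68L, 3L))

  one <- segment_windows(toy_recording(68))
  expect_equal(length(one$starts), 1)
  expect_equal(one$starts, 1L)

  expect_error(segment_windows(toy_recording(60)), "empty window series")
})

test_that("window coverage is loss-bounded and interior samples appear twice", {
  rec <- toy_recording(680)
  ws <- segment_windows(rec)
  counts <- integer(680)
  for (s in ws$starts) counts[s:(s + 67)] <- counts[s:(s + 67)] + 1L
  covered_until <- max(ws$starts) + 67
  expect_true(680 - covered_until < ws$hop)
  expect_true(all(counts[1:covered_until] >= 1))
  interior <- 35:(covered_until - 34)
  expect_true(all(counts[interior] == 2))
})

test_that("window labels follow the majority rule with earliest-interval ties", {
  rec <- toy_recording(68)
  # 40 samples WALKING (1.6 s) then 28 samples TRANSITION
  track <- annotation_track(c(0, 1.6), c(1.6, 2.72),
                            c("WALKING", "TRANSITION"))
  ws <- segment_windows(rec, track)
  expect_equal(ws$labels, "WALKING")
  # exact tie 34/34: earlier interval wins
  tie <- annotation_track(c(0, 1.36), c(1.36, 2.72),
                          c("LAYING", "WALKING"))
  expect_equal(segment_windows(rec, tie)$labels, "LAYING")
})

test_that("a sampling gap in the timestamp column raises a warning", {
  t <- c(seq(0, 1, by = 0.04), seq(2, 3, by = 0.04))
  df <- data.frame(t = t, acc_x = rnorm(length(t)), acc_y = 0, acc_z = 0)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  expect_warning(read_recording(path), "gap")
})
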