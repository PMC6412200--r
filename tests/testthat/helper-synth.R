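# shared fixtures, built in code

# a shortened protocol (half durations) for fast unit tests
short_protocol <- function() {
  annotation_track(
    start_s = c(0, 30, 60, 90, 105, 120),
    end_s = c(30, 60, 90, 105, 120, 135),
    label = c("standing", "sitting", "walking", "upstairs", "downstairs",
              "laying"))
}

# one short synthetic subject (135 s, 3375 samples)
short_subject <- function(seed = 101) {
  simulate_recording(draw_subject_params(seed), protocol = short_protocol())
}

# tiny deterministic 3-channel recording
toy_recording <- function(n = 200, fs = 25) {
  set.seed(99)
  recording(matrix(rnorm(3 * n), ncol = 3,
                   dimnames = list(NULL, c("acc_x", "acc_y", "acc_z"))),
            subject_id = "toy", fs = fs)
}

# uniform random proper rotation
random_rotation <- function() {
  rotation_about(rnorm(3), runif(1, 0, 360))
}

# brute-force sliding majority vote (independent oracle for majority_smooth)
oracle_majority <- function(labels, w) {
  n <- length(labels)
  half <- (w - 1) %/% 2
  out <- labels
  for (i in seq_len(n)) {
    win <- labels[max(1, i - half):min(n, i + half)]
    counts <- table(win)
    top <- names(counts)[counts == max(counts)]
    out[i] <- if (labels[i] %in% top) labels[i] else win[win %in% top][1]
  }
  out
}

# naive loop implementation of the Relief-F update rule (independent oracle)
oracle_relief <- function(X, y, k) {
  X <- as.matrix(X); y <- as.character(y)
  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, function(col) max(max(col) - min(col), 1e-12))
  rng[apply(X, 2, function(col) max(col) - min(col)) < 1e-12] <- 1
  Xs <- X
  for (j in 1:p) Xs[, j] <- (X[, j] - min(X[, j])) / rng[j]
  classes <- sort(unique(y))
  priors <- sapply(classes, function(cl) mean(y == cl))
  W <- numeric(p)
  for (i in 1:n) {
    d <- sapply(1:n, function(m) sum(abs(Xs[i, ] - Xs[m, ])))
    d[i] <- Inf
    hit_idx <- which(y == y[i])
    hit_idx <- hit_idx[order(d[hit_idx])][1:k]
    for (j in 1:p) {
      W[j] <- W[j] - mean(abs(Xs[i, j] - Xs[hit_idx, j])) / n
    }
    for (cl in classes[classes != y[i]]) {
      miss_idx <- which(y == cl)
      miss_idx <- miss_idx[order(d[miss_idx])][1:k]
      for (j in 1:p) {
        W[j] <- W[j] + (priors[cl] / (1 - priors[y[i]])) *
          mean(abs(Xs[i, j] - Xs[miss_idx, j])) / n
      }
    }
  }
  W
}
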