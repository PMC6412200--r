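#' Relief-F feature ranking
#'
#' Multiclass Relief-F: every instance updates each feature's weight
#' downward by its distance to the k nearest same-class neighbours (hits)
#' and upward by its distance to the k nearest neighbours of every other
#' class (misses), the latter weighted by the class prior relative to the
#' complement of the instance's class. Features are scaled to `[0, 1]`
#' internally so per-feature differences are comparable; distances between
#' instances are Manhattan distances on the scaled features. Higher weight
#' means more relevant; ranking is by descending weight with ties broken by
#' feature index.
#'
#' @param X numeric matrix, instances in rows.
#' @param y class labels (character or factor), at least 2 classes.
#' @param k_neighbors number of nearest hits/misses per instance; must be
#'   smaller than the smallest class size.
#' @param n_iter number of instances used for updates (all by default,
#'   making the result deterministic).
#' @return numeric vector of feature weights (one per column of `X`), with
#'   a `"ranking"` attribute giving column indices in descending relevance.
#' @export
relief_f <- function(X, y, k_neighbors = 10, n_iter = nrow(X)) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("relief_f needs at least 2 classes")
  counts <- table(y)
  if (k_neighbors >= min(counts)) {
    stop("k_neighbors (", k_neighbors, ") must be smaller than the ",
         "smallest class size (", min(counts), ")")
  }
  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, function(col) {
    r <- max(col) - min(col)
    if (r < 1e-12) 1 else r
  })
  Xs <- sweep(sweep(X, 2, apply(X, 2, min)), 2, rng, "/")
  priors <- as.numeric(counts[classes]) / n
  names(priors) <- classes
  D <- as.matrix(stats::dist(Xs, method = "manhattan"))
  m <- min(n_iter, n)
  W <- numeric(p)
  for (i in seq_len(m)) {
    di <- D[i, ]
    di[i] <- Inf
    same <- which(y == y[i])
    hits <- same[order(di[same])][seq_len(k_neighbors)]
    hit_diff <- colMeans(abs(Xs[hits, , drop = FALSE] -
                               matrix(Xs[i, ], k_neighbors, p, byrow = TRUE)))
    W <- W - hit_diff / m
    for (cl in classes[classes != y[i]]) {
      other <- which(y == cl)
      miss <- other[order(di[other])][seq_len(k_neighbors)]
      miss_diff <- colMeans(abs(Xs[miss, , drop = FALSE] -
                                  matrix(Xs[i, ], k_neighbors, p, byrow = TRUE)))
      W <- W + (priors[[cl]] / (1 - priors[[y[i]]])) * miss_diff / m
    }
  }
  names(W) <- colnames(X)
  attr(W, "ranking") <- order(-W, seq_len(p))
  W
}

#' Top-ranked features by Relief-F weight
#'
#' @param weights result of [relief_f()].
#' @param n_keep number of features to keep.
#' @return integer vector of column indices, in rank order.
#' @export
relief_top <- function(weights, n_keep) {
  utils::head(attr(weights, "ranking"), n_keep)
}
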