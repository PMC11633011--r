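# Class-imbalance correction for one binary task. Applied strictly to the
# training partition, after the train/test split; per-row provenance flags
# make leakage assertable downstream.

.resampled_set <- function(features, labels, method, seed, provenance) {
  stopifnot(nrow(features) == length(labels),
            length(provenance) == length(labels))
  structure(list(features = features, labels = as.integer(labels),
                 method = method, seed = seed, provenance = provenance),
            class = "resampled_set")
}

#' @export
print.resampled_set <- function(x, ...) {
  cat("resampled_set [", x$method, "]: ", nrow(x$features), " rows (",
      sum(x$labels == 1), " pos / ", sum(x$labels == 0), " neg); ",
      sum(x$provenance != "original"), " resampled rows\n", sep = "")
  invisible(x)
}

#' Leave a training set unresampled
#'
#' Wraps features and labels in the same container as the resamplers, with
#' `method = "none"`, so the training code handles all three strategies
#' uniformly.
#'
#' @param X Numeric feature matrix.
#' @param y Binary label vector (0/1).
#' @return A `resampled_set`.
#' @export
no_resample <- function(X, y) {
  .resampled_set(X, y, "none", NA_integer_, rep("original", length(y)))
}

#' SMOTE oversampling of the minority class
#'
#' Grows the minority class to the majority count. Every synthetic row is
#' `x_i + u * (x_j - x_i)` for a random minority point `x_i`, one of its
#' `k_neighbors` nearest minority neighbours `x_j`, and `u ~ U(0, 1)`;
#' original rows are passed through unchanged. On binary fingerprint input
#' the interpolated rows are fractional and are deliberately not
#' re-binarized.
#'
#' @param X Numeric feature matrix.
#' @param y Binary label vector (0/1).
#' @param k_neighbors Number of minority nearest neighbours (default 5).
#' @param seed Integer seed.
#' @return A `resampled_set` with equal class counts and provenance flags
#'   `original` / `synthetic`.
#' @export
smote_oversample <- function(X, y, k_neighbors = 5, seed = 1) {
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0L, 1L)))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  if (n1 == n0) {
    return(.resampled_set(X, y, "smote", seed, rep("original", length(y))))
  }
  minority <- if (n1 < n0) 1L else 0L
  min_idx <- which(y == minority)
  n_new <- abs(n0 - n1)
  if (length(min_idx) <= k_neighbors) {
    stop("minority count (", length(min_idx), ") must exceed k_neighbors (",
         k_neighbors, "); use a smaller k_neighbors")
  }
  Xm <- X[min_idx, , drop = FALSE]
  dmat <- as.matrix(stats::dist(Xm))
  diag(dmat) <- Inf
  nn <- t(apply(dmat, 1, function(d) order(d)[seq_len(k_neighbors)]))

  set.seed(seed)
  base <- sample.int(nrow(Xm), n_new, replace = TRUE)
  pick <- nn[cbind(base, sample.int(k_neighbors, n_new, replace = TRUE))]
  u <- stats::runif(n_new)
  synth <- Xm[base, , drop = FALSE] +
    u * (Xm[pick, , drop = FALSE] - Xm[base, , drop = FALSE])
  rownames(synth) <- NULL

  .resampled_set(rbind(X, synth),
                 c(y, rep(minority, n_new)),
                 "smote", seed,
                 c(rep("original", length(y)), rep("synthetic", n_new)))
}

#' Cluster-centroid undersampling of the majority class
#'
#' Replaces the majority class by the centroids of a k-means clustering with
#' k equal to the minority count; minority rows are unchanged. If the
#' classes are already balanced (or inverted) the input is returned
#' unchanged with a warning.
#'
#' @param X Numeric feature matrix.
#' @param y Binary label vector (0/1).
#' @param seed Integer seed (k-means uses multiple restarts under this
#'   seed for determinism).
#' @return A `resampled_set` with equal class counts and provenance flags
#'   `original` / `centroid`.
#' @export
centroid_undersample <- function(X, y, seed = 1) {
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0L, 1L)))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  minority <- if (n1 < n0) 1L else 0L
  k <- min(n1, n0)
  if (n1 == n0 || k == max(n1, n0)) {
    warning("minority count is not smaller than majority count; returned unchanged")
    return(.resampled_set(X, y, "centroid", seed, rep("original", length(y))))
  }
  maj_idx <- which(y != minority)
  min_idx <- which(y == minority)
  Xmaj <- X[maj_idx, , drop = FALSE]

  set.seed(seed)
  uniq <- nrow(unique(Xmaj))
  if (uniq <= k) {
    centers <- unique(Xmaj)[seq_len(min(k, uniq)), , drop = FALSE]
    if (nrow(centers) < k) {
      centers <- centers[rep(seq_len(nrow(centers)), length.out = k), , drop = FALSE]
    }
  } else {
    km <- stats::kmeans(Xmaj, centers = k, nstart = 5, iter.max = 100)
    centers <- km$centers
  }
  rownames(centers) <- NULL
  colnames(centers) <- colnames(X)

  Xout <- rbind(X[min_idx, , drop = FALSE], centers)
  yout <- c(rep(minority, length(min_idx)), rep(1L - minority, k))
  .resampled_set(Xout, yout, "centroid", seed,
                 c(rep("original", length(min_idx)), rep("centroid", k)))
}

#' Apply a named resampling strategy
#'
#' @param X Numeric feature matrix.
#' @param y Binary labels.
#' @param method One of `"none"`, `"smote"`, `"centroid"`.
#' @param seed Integer seed.
#' @param k_neighbors SMOTE neighbour count.
#' @return A `resampled_set`.
#' @export
resample_training_set <- function(X, y, method = c("none", "smote", "centroid"),
                                  seed = 1, k_neighbors = 5) {
  method <- match.arg(method)
  switch(method,
         none = no_resample(X, y),
         smote = smote_oversample(X, y, k_neighbors = k_neighbors, seed = seed),
         centroid = centroid_undersample(X, y, seed = seed))
}
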