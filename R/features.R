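# FeatureMatrix container and the fixed feature-filter pipeline:
# invalid (non-finite) columns -> near-constant columns -> pairwise Pearson
# correlation (descriptors only). Every dropped feature is recorded once in
# the filter log; rows always stay aligned 1:1 with the input records.

#' Construct a feature matrix
#'
#' @param values Numeric matrix (compounds x features) with unique column
#'   names.
#' @param representation Either `"descriptors"` or `"fingerprint"`.
#' @param filter_log List of past filter steps, each
#'   `list(filter =, dropped =)`.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(values, representation = c("descriptors", "fingerprint"),
                           filter_log = list()) {
  representation <- match.arg(representation)
  stopifnot(is.matrix(values), !is.null(colnames(values)),
            !anyDuplicated(colnames(values)))
  structure(list(values = values,
                 feature_names = colnames(values),
                 representation = representation,
                 filter_log = filter_log),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix [", x$representation, "]: ",
      nrow(x$values), " compounds x ", ncol(x$values), " features\n", sep = "")
  for (step in x$filter_log) {
    cat("  filter '", step$filter, "': dropped ", length(step$dropped),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

.drop_features <- function(m, drop_names, filter_name, extra = NULL) {
  keep <- setdiff(colnames(m$values), drop_names)
  entry <- list(filter = filter_name, dropped = drop_names)
  if (!is.null(extra)) entry$detail <- extra
  feature_matrix(m$values[, keep, drop = FALSE],
                 representation = m$representation,
                 filter_log = c(m$filter_log, list(entry)))
}

#' Drop features with invalid (non-finite) values
#'
#' A column is removed if any cell is `NA`, `NaN` or infinite, so every
#' retained column is finite for all rows.
#'
#' @param m A `feature_matrix`.
#' @return Filtered `feature_matrix` with the step appended to the log.
#' @export
drop_invalid_features <- function(m) {
  stopifnot(inherits(m, "feature_matrix"))
  bad <- colnames(m$values)[!apply(is.finite(m$values), 2, all)]
  .drop_features(m, bad, "invalid")
}

#' Drop near-constant features
#'
#' A column is removed iff its single most frequent value occupies more than
#' `dominance` of the rows (default 0.97). This removes uninformative
#' features such as fingerprint bits set (or unset) in almost every
#' molecule.
#'
#' @param m A `feature_matrix`.
#' @param dominance Fraction in (0, 1); strictly-greater comparison.
#' @return Filtered `feature_matrix`.
#' @export
drop_near_constant <- function(m, dominance = 0.97) {
  stopifnot(inherits(m, "feature_matrix"), dominance > 0, dominance < 1)
  n <- nrow(m$values)
  top_frac <- apply(m$values, 2, function(col) {
    max(table(col, useNA = "ifany")) / n
  })
  bad <- colnames(m$values)[top_frac > dominance]
  .drop_features(m, bad, "near-constant")
}

#' Drop highly correlated features
#'
#' Greedy scan in feature order: for each later column whose absolute
#' Pearson correlation with an already-kept earlier column exceeds `r_max`,
#' the later column is dropped. The log records each (kept, dropped, r)
#' pair. Intended for the descriptor representation; zero-variance columns
#' must have been removed by the preceding filters.
#'
#' @param m A `feature_matrix`.
#' @param r_max Absolute correlation threshold (default 0.95).
#' @return Filtered `feature_matrix`.
#' @export
drop_correlated <- function(m, r_max = 0.95) {
  stopifnot(inherits(m, "feature_matrix"))
  vals <- m$values
  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s) reached the correlation filter (",
         paste(colnames(vals)[sds == 0], collapse = ", "),
         "); run drop_near_constant() first")
  }
  cm <- suppressWarnings(stats::cor(vals))
  p <- ncol(vals)
  kept <- logical(p)
  pairs <- list()
  for (j in seq_len(p)) {
    conflict <- which(kept & abs(cm[, j]) > r_max)
    if (length(conflict) == 0) {
      kept[j] <- TRUE
    } else {
      i <- conflict[1]
      pairs[[length(pairs) + 1]] <- data.frame(
        kept = colnames(vals)[i], dropped = colnames(vals)[j],
        r = cm[i, j], stringsAsFactors = FALSE)
    }
  }
  detail <- if (length(pairs)) do.call(rbind, pairs) else NULL
  .drop_features(m, colnames(vals)[!kept], "correlation", extra = detail)
}

#' Run the full feature-filter pipeline
#'
#' Fixed order: invalid -> near-constant -> correlation. The correlation
#' filter applies to the descriptor representation only; fingerprints pass
#' through it unchanged.
#'
#' @param m A `feature_matrix`.
#' @param dominance Near-constant dominance threshold.
#' @param r_max Correlation threshold.
#' @return Filtered `feature_matrix` with a complete filter log.
#' @export
apply_feature_filters <- function(m, dominance = 0.97, r_max = 0.95) {
  m <- drop_invalid_features(m)
  m <- drop_near_constant(m, dominance)
  if (m$representation == "descriptors") m <- drop_correlated(m, r_max)
  m
}

#' Reproducible (optionally stratified) 80:20 split
#'
#' @param n Number of rows (must be >= 5).
#' @param seed Integer seed; the same seed always gives the same split.
#' @param labels Optional binary vector of length `n`; if given, the split
#'   is stratified so both classes appear in the test partition whenever the
#'   class has at least 3 members.
#' @param test_fraction Test proportion (default 0.2).
#' @return A `split_index` object with `train_idx`, `test_idx`, `seed`,
#'   `ratio`.
#' @export
split_80_20 <- function(n, seed, labels = NULL, test_fraction = 0.2) {
  if (n < 5) stop("need at least 5 rows to split 80:20")
  set.seed(seed)
  if (is.null(labels)) {
    n_test <- round(test_fraction * n)
    test_idx <- sort(sample.int(n, n_test))
  } else {
    stopifnot(length(labels) == n)
    test_idx <- integer(0)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      n_test_c <- round(test_fraction * length(idx))
      if (length(idx) >= 3) n_test_c <- max(1L, n_test_c)
      if (n_test_c > 0) test_idx <- c(test_idx, sample(idx, n_test_c))
    }
    test_idx <- sort(test_idx)
  }
  structure(list(train_idx = setdiff(seq_len(n), test_idx),
                 test_idx = test_idx,
                 seed = seed,
                 ratio = c(train = 1 - test_fraction, test = test_fraction)),
            class = "split_index")
}

#' @export
print.split_index <- function(x, ...) {
  cat("split_index: ", length(x$train_idx), " train / ",
      length(x$test_idx), " test (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}
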