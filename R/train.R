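# Per-flavor binary classifier training: cross-validated grid search over
# random-forest (ranger) and k-nearest-neighbour models, and assembly of the
# seven-model backbone using the winning algorithm x representation x
# resampler combination per flavor.

#' Hyperparameter grid presets
#'
#' `"default"` is the full grid (forest: 100/300/500 trees, unlimited/10/20
#' depth, min leaf 1/5; neighbours: k 3/5/7/11, uniform/distance weights);
#' `"fast"` is a small subset used for end-to-end runs where the full grid
#' adds little at substantial cost.
#'
#' @param algorithm `"random-forest"` or `"k-nearest-neighbors"`.
#' @param preset `"default"` or `"fast"`.
#' @return Named list of candidate value vectors.
#' @export
default_grid <- function(algorithm = c("random-forest", "k-nearest-neighbors"),
                         preset = c("default", "fast")) {
  algorithm <- match.arg(algorithm)
  preset <- match.arg(preset)
  if (algorithm == "random-forest") {
    if (preset == "default") {
      list(num_trees = c(100, 300, 500), max_depth = c(0, 10, 20),
           min_node = c(1, 5))
    } else {
      list(num_trees = 300, max_depth = 0, min_node = c(1, 5))
    }
  } else {
    if (preset == "default") {
      list(k = c(3, 5, 7, 11), weights = c("uniform", "distance"))
    } else {
      list(k = c(3, 5), weights = "distance")
    }
  }
}

#' Specify one per-flavor model
#'
#' @param flavor One of the seven canonical categories.
#' @param algorithm `"random-forest"` or `"k-nearest-neighbors"`.
#' @param representation `"descriptors"` or `"fingerprint"`.
#' @param resampler `"none"`, `"smote"` or `"centroid"`.
#' @param grid Named list of hyperparameter candidates (non-empty).
#' @param cv_folds Cross-validation folds (>= 2, default 5).
#' @param seed Integer seed.
#' @return A `flavor_model_spec`.
#' @export
model_spec <- function(flavor,
                       algorithm = c("random-forest", "k-nearest-neighbors"),
                       representation = c("descriptors", "fingerprint"),
                       resampler = c("none", "smote", "centroid"),
                       grid = NULL, cv_folds = 5, seed = 1) {
  algorithm <- match.arg(algorithm)
  stopifnot(flavor %in% FLAVOR_CATEGORIES, cv_folds >= 2)
  if (is.null(grid)) grid <- default_grid(algorithm)
  stopifnot(length(grid) > 0)
  structure(list(flavor = flavor, algorithm = algorithm,
                 representation = match.arg(representation),
                 resampler = match.arg(resampler),
                 grid = grid, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)),
            class = "flavor_model_spec")
}

# stratified fold assignment; every fold gets both classes
.stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

.fit_one <- function(algorithm, X, y, params, seed) {
  if (algorithm == "random-forest") {
    fit <- ranger::ranger(
      x = X, y = factor(y, levels = c(0, 1)),
      num.trees = params$num_trees,
      max.depth = params$max_depth,
      min.node.size = params$min_node,
      probability = TRUE, importance = "impurity",
      seed = seed, num.threads = 1)
    structure(list(rf = fit), class = "fc_rf")
  } else {
    structure(list(X = X, y = as.integer(y),
                   k = params$k, weights = params$weights),
              class = "fc_knn")
  }
}

.predict_fit <- function(fit, X) {
  if (inherits(fit, "fc_rf")) {
    p <- stats::predict(fit$rf, data = X, num.threads = 1)$predictions
    unname(p[, "1"])
  } else {
    tr <- fit$X
    d2 <- outer(rowSums(X^2), rowSums(tr^2), "+") - 2 * X %*% t(tr)
    d2[d2 < 0] <- 0
    k <- min(fit$k, nrow(tr))
    apply_rows <- function(i) {
      d <- sqrt(d2[i, ])
      nn <- order(d)[seq_len(k)]
      if (fit$weights == "uniform") {
        mean(fit$y[nn])
      } else {
        w <- 1 / (d[nn] + 1e-8)
        sum(w * fit$y[nn]) / sum(w)
      }
    }
    vapply(seq_len(nrow(X)), apply_rows, numeric(1))
  }
}

#' Predicted positive-class probabilities
#'
#' @param model A `trained_flavor_model`.
#' @param X Feature matrix whose columns match the model's
#'   `feature_names`.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "trained_flavor_model"))
  if (!identical(colnames(X), model$feature_names)) {
    if (!all(model$feature_names %in% colnames(X))) {
      stop("feature-name mismatch between model and featurizer; ",
           "the model was fitted on features absent from the input")
    }
    X <- X[, model$feature_names, drop = FALSE]
  }
  .predict_fit(model$fit_obj, X)
}

#' Cross-validated grid search for one flavor model
#'
#' Exhaustive search over the spec's hyperparameter grid; the selection
#' metric is mean ROC AUC over stratified cross-validation folds. The best
#' parameter set (first on ties, in grid order) is refit on the full
#' training set. Deterministic for a fixed spec seed.
#'
#' @param spec A `flavor_model_spec`.
#' @param train_set A `resampled_set` (already balanced per the spec's
#'   resampler).
#' @return A `trained_flavor_model` with fields `spec`, `best_params`,
#'   `cv_scores` (per-fold metrics at the best point), `grid_results`
#'   (mean AUC per grid point), `feature_names`.
#' @export
grid_search <- function(spec, train_set) {
  stopifnot(inherits(spec, "flavor_model_spec"),
            inherits(train_set, "resampled_set"))
  X <- train_set$features
  y <- train_set$labels
  grid <- expand.grid(spec$grid, stringsAsFactors = FALSE)
  folds <- .stratified_folds(y, spec$cv_folds, spec$seed)
  for (f in seq_len(spec$cv_folds)) {
    if (length(unique(y[folds == f])) < 2) {
      stop("cross-validation fold ", f, " contains a single class; ",
           "use stratified folds (enforced by default) or more data")
    }
  }

  fold_metrics <- vector("list", nrow(grid))
  mean_auc <- numeric(nrow(grid))
  for (gidx in seq_len(nrow(grid))) {
    params <- as.list(grid[gidx, , drop = FALSE])
    per_fold <- data.frame(fold = seq_len(spec$cv_folds), roc_auc = NA_real_,
                           recall = NA_real_, specificity = NA_real_)
    for (f in seq_len(spec$cv_folds)) {
      hold <- folds == f
      fit <- .fit_one(spec$algorithm, X[!hold, , drop = FALSE], y[!hold],
                      params, spec$seed)
      p <- .predict_fit(fit, X[hold, , drop = FALSE])
      cm <- confusion_metrics(y[hold], as.integer(p >= 0.5))
      per_fold$roc_auc[f] <- roc_auc(y[hold], p)
      per_fold$recall[f] <- cm$recall
      per_fold$specificity[f] <- cm$specificity
    }
    fold_metrics[[gidx]] <- per_fold
    mean_auc[gidx] <- mean(per_fold$roc_auc)
  }

  best <- which.max(mean_auc)
  best_params <- stats::setNames(
    lapply(names(grid), function(nm) unname(grid[best, nm])), names(grid))
  fit <- .fit_one(spec$algorithm, X, y, best_params, spec$seed)

  structure(list(spec = spec,
                 fit_obj = fit,
                 fit = if (inherits(fit, "fc_rf")) fit$rf else fit,
                 best_params = best_params,
                 cv_scores = fold_metrics[[best]],
                 grid_results = cbind(grid, mean_roc_auc = mean_auc),
                 feature_names = colnames(X)),
            class = "trained_flavor_model")
}

#' @export
print.trained_flavor_model <- function(x, ...) {
  cat("trained_flavor_model:", x$spec$flavor, "|", x$spec$algorithm, "|",
      x$spec$representation, "| resampler:", x$spec$resampler, "\n")
  cat("  best params:",
      paste(names(x$best_params), unlist(x$best_params),
            sep = "=", collapse = ", "), "\n")
  cat("  CV ROC AUC:", round(mean(x$cv_scores$roc_auc), 3), "\n")
  invisible(x)
}

#' The backbone configuration: winning combination per flavor
#'
#' Random forest on SMOTE-oversampled fingerprints for bitter, fruity,
#' sweet and off-flavor; random forest on descriptors for floral and nutty;
#' k-nearest neighbours on SMOTE-oversampled fingerprints for sour.
#'
#' @return Data.frame with columns `flavor`, `algorithm`, `representation`,
#'   `resampler`, in canonical flavor order.
#' @export
backbone_config <- function() {
  data.frame(
    flavor = FLAVOR_CATEGORIES,
    algorithm = c("random-forest", "random-forest", "random-forest",
                  "random-forest", "random-forest", "k-nearest-neighbors",
                  "random-forest"),
    representation = c("fingerprint", "descriptors", "fingerprint",
                       "fingerprint", "descriptors", "fingerprint",
                       "fingerprint"),
    resampler = c("smote", "smote", "smote", "smote", "smote", "smote",
                  "smote"),
    stringsAsFactors = FALSE)
}

#' Train the seven-model backbone
#'
#' End-to-end training on a curated record set: featurizes both retained
#' representations, filters them, makes a per-flavor stratified 80:20
#' split, resamples the training partition, grid-searches each model and
#' evaluates it on the untouched test partition. Train-phase metrics are
#' means over the cross-validation folds.
#'
#' @param records A labelled `flavor_records` data.frame (every flavor
#'   needs at least 10 positives).
#' @param seed Integer seed controlling splits, resampling and model fits.
#' @param nbits Fingerprint length.
#' @param grid_preset `"fast"` (default, small grids) or `"default"` (full
#'   grids).
#' @param cv_folds Cross-validation folds.
#' @param config Backbone configuration table; defaults to
#'   [backbone_config()].
#' @param threshold Probability threshold for binary calls.
#' @return A `flavor_backbone`: named list of models, the combined
#'   evaluation report, the filtered feature matrices' column names, and
#'   run metadata.
#' @export
train_backbone <- function(records, seed = 1, nbits = 2048,
                           grid_preset = c("fast", "default"),
                           cv_folds = 5, config = backbone_config(),
                           threshold = 0.5) {
  grid_preset <- match.arg(grid_preset)
  labels <- one_hot(records)
  npos <- colSums(labels)
  if (any(npos < 10)) {
    stop("flavor(s) with fewer than 10 positives cannot be trained: ",
         paste(FLAVOR_CATEGORIES[npos < 10], collapse = ", "))
  }

  desc <- apply_feature_filters(compute_descriptors(records))
  fp <- apply_feature_filters(compute_fingerprints(records, nbits = nbits))
  reps <- list(descriptors = desc, fingerprint = fp)

  models <- list()
  reports <- list()
  splits <- list()
  for (i in seq_len(nrow(config))) {
    flavor <- config$flavor[i]
    y <- labels[, flavor]
    Xall <- reps[[config$representation[i]]]$values
    spl <- split_80_20(nrow(Xall), seed + i, labels = y)
    splits[[flavor]] <- spl
    rs <- resample_training_set(Xall[spl$train_idx, , drop = FALSE],
                                y[spl$train_idx],
                                method = config$resampler[i],
                                seed = seed + i)
    spec <- model_spec(flavor, config$algorithm[i], config$representation[i],
                       config$resampler[i],
                       grid = default_grid(config$algorithm[i], grid_preset),
                       cv_folds = cv_folds, seed = seed + i)
    model <- grid_search(spec, rs)
    models[[flavor]] <- model

    train_rep <- evaluation_report(
      flavor, "train-cv",
      mean(model$cv_scores$recall), mean(model$cv_scores$specificity),
      mean(model$cv_scores$roc_auc),
      sum(rs$labels == 1), sum(rs$labels == 0))
    test_rep <- evaluate_model(model, Xall[spl$test_idx, , drop = FALSE],
                               y[spl$test_idx], phase = "test",
                               threshold = threshold)
    test_rep$overfit <- overfit_score(train_rep, test_rep)
    reports[[flavor]] <- rbind(train_rep, test_rep)
  }

  structure(list(models = models,
                 reports = do.call(rbind, c(reports, make.row.names = FALSE)),
                 splits = splits,
                 feature_names = lapply(reps, function(r) r$feature_names),
                 filter_logs = lapply(reps, function(r) r$filter_log),
                 nbits = nbits, threshold = threshold, seed = seed,
                 version = as.character(utils::packageVersion("flavorcast"))),
            class = "flavor_backbone")
}

#' @export
print.flavor_backbone <- function(x, ...) {
  cat("flavor_backbone:", length(x$models), "models (seed", x$seed, ")\n")
  tst <- x$reports[x$reports$phase == "test", ]
  print(tst[, c("flavor", "recall", "specificity", "roc_auc", "bias")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Save a trained backbone to a directory
#'
#' Writes one serialized estimator plus a JSON sidecar (spec, best
#' parameters, feature names, seed, metric summary, checksum) per flavor,
#' and a `backbone.json` manifest.
#'
#' @param backbone A `flavor_backbone`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_models <- function(backbone, dir) {
  stopifnot(inherits(backbone, "flavor_backbone"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (flavor in names(backbone$models)) {
    model <- backbone$models[[flavor]]
    rds <- file.path(dir, paste0(flavor, "_model.rds"))
    saveRDS(model, rds)
    sidecar <- list(
      flavor = flavor,
      algorithm = model$spec$algorithm,
      representation = model$spec$representation,
      resampler = model$spec$resampler,
      best_params = model$best_params,
      feature_names = model$feature_names,
      seed = model$spec$seed,
      cv_mean_roc_auc = mean(model$cv_scores$roc_auc),
      md5 = unname(tools::md5sum(rds)))
    jsonlite::write_json(sidecar, file.path(dir, paste0(flavor, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(package = "flavorcast",
                   version = backbone$version,
                   flavors = names(backbone$models),
                   nbits = backbone$nbits,
                   threshold = backbone$threshold,
                   seed = backbone$seed)
  jsonlite::write_json(manifest, file.path(dir, "backbone.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(backbone$reports, file.path(dir, "reports.rds"))
  invisible(dir)
}

#' Load a backbone saved with [save_models()]
#'
#' Verifies the manifest version and each model file's checksum before
#' loading; a corrupted file or missing flavor is refused with an explicit
#' error.
#'
#' @param dir Directory written by [save_models()].
#' @return A `flavor_backbone`.
#' @export
load_models <- function(dir) {
  mf_path <- file.path(dir, "backbone.json")
  if (!file.exists(mf_path)) stop("no backbone.json manifest in ", dir)
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  current <- as.character(utils::packageVersion("flavorcast"))
  if (!identical(manifest$version, current)) {
    stop("model directory was written by flavorcast ", manifest$version,
         " but this is ", current, "; refusing to load across versions")
  }
  models <- list()
  for (flavor in manifest$flavors) {
    rds <- file.path(dir, paste0(flavor, "_model.rds"))
    side <- file.path(dir, paste0(flavor, ".json"))
    if (!file.exists(rds) || !file.exists(side)) {
      stop("model files for flavor '", flavor, "' are missing from ", dir)
    }
    sidecar <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!identical(unname(tools::md5sum(rds)), sidecar$md5)) {
      stop("checksum mismatch for flavor '", flavor,
           "': model file is corrupted")
    }
    models[[flavor]] <- readRDS(rds)
  }
  reports_path <- file.path(dir, "reports.rds")
  reports <- if (file.exists(reports_path)) readRDS(reports_path) else NULL
  structure(list(models = models, reports = reports, splits = NULL,
                 feature_names = NULL, filter_logs = NULL,
                 nbits = manifest$nbits, threshold = manifest$threshold,
                 seed = manifest$seed, version = manifest$version),
            class = "flavor_backbone")
}
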