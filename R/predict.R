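# Deployment pipeline: canonicalize queries, match them against the curated
# known-flavor table, predict the rest with the trained backbone, and
# summarise flavor recurrence for the radar chart.

#' Look up a query structure in the curated table
#'
#' Matching is by canonical isomeric SMILES equality; names and PubChem ids
#' are ignored because metabolomics tables often lack them.
#'
#' @param smiles One query SMILES (need not be canonical).
#' @param curated_table A `flavor_records` data.frame.
#' @return The stored 7-label integer vector, or `NULL` if there is no
#'   match (or the query does not parse).
#' @export
database_match <- function(smiles, curated_table) {
  canon <- canonicalize_smiles(smiles)
  if (is.na(canon)) return(NULL)
  hit <- which(curated_table$smiles == canon)
  if (!length(hit)) return(NULL)
  stats::setNames(as.integer(curated_table[hit[1], FLAVOR_CATEGORIES]),
                  FLAVOR_CATEGORIES)
}

#' Predict flavor profiles for a batch of query molecules
#'
#' For each parseable query: if its canonical structure is present in the
#' curated table the stored labels are returned with probabilities of
#' exactly 0/1 and `source = "database"`; otherwise the seven backbone
#' models predict probabilities from the representation each was trained
#' on, and calls are thresholded at the backbone threshold
#' (`source = "model"`). Unparsable queries are kept in place with
#' `source = "error"` rather than dropped; input row order is preserved.
#'
#' @param queries Data.frame with columns `query_id` and `smiles` (a bare
#'   character vector of SMILES is also accepted).
#' @param backbone A `flavor_backbone` from [train_backbone()] or
#'   [load_models()].
#' @param curated_table Optional `flavor_records` used for database
#'   matching; `NULL` disables lookup.
#' @return A `flavor_predictions` data.frame: `query_id`, `smiles`
#'   (canonical), `source`, seven `prob_*` columns, seven `call_*` columns,
#'   `model_version`.
#' @export
predict_profiles <- function(queries, backbone, curated_table = NULL) {
  stopifnot(inherits(backbone, "flavor_backbone"))
  if (!is.data.frame(queries)) {
    queries <- data.frame(query_id = as.character(seq_along(queries)),
                          smiles = as.character(queries),
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(c("query_id", "smiles") %in% names(queries)))
  n <- nrow(queries)
  canon <- canonicalize_smiles(queries$smiles)

  probs <- matrix(NA_real_, n, 7,
                  dimnames = list(NULL, paste0("prob_", FLAVOR_CATEGORIES)))
  calls <- matrix(NA_integer_, n, 7,
                  dimnames = list(NULL, paste0("call_", FLAVOR_CATEGORIES)))
  source <- rep("model", n)
  source[is.na(canon)] <- "error"

  # database matches
  if (!is.null(curated_table)) {
    idx <- match(canon, curated_table$smiles)
    hit <- !is.na(idx) & !is.na(canon)
    if (any(hit)) {
      lab <- as.matrix(curated_table[idx[hit], FLAVOR_CATEGORIES, drop = FALSE])
      storage.mode(lab) <- "integer"
      probs[hit, ] <- lab
      calls[hit, ] <- lab
      source[hit] <- "database"
    }
  }

  todo <- which(source == "model")
  if (length(todo)) {
    reps_needed <- unique(vapply(backbone$models,
                                 function(m) m$spec$representation, ""))
    feats <- list()
    if ("descriptors" %in% reps_needed) {
      feats$descriptors <- compute_descriptors(canon[todo])$values
    }
    if ("fingerprint" %in% reps_needed) {
      feats$fingerprint <- compute_fingerprints(canon[todo],
                                                nbits = backbone$nbits)$values
    }
    for (flavor in FLAVOR_CATEGORIES) {
      model <- backbone$models[[flavor]]
      if (is.null(model)) stop("backbone lacks a model for flavor ", flavor)
      X <- feats[[model$spec$representation]]
      p <- predict_proba(model, X)
      probs[todo, paste0("prob_", flavor)] <- p
      calls[todo, paste0("call_", flavor)] <-
        as.integer(p >= backbone$threshold)
    }
  }

  out <- data.frame(query_id = queries$query_id, smiles = canon,
                    source = source, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(probs), as.data.frame(calls))
  out$model_version <- paste0("flavorcast-", backbone$version)
  structure(out, class = c("flavor_predictions", "data.frame"))
}

#' Flavor recurrence counts for the radar chart
#'
#' @param predictions A `flavor_predictions` data.frame.
#' @return A `radar_summary`: per-flavor counts of positive calls and the
#'   number of queries. Rows with unparsable structures contribute nothing.
#' @export
radar_counts <- function(predictions) {
  cols <- paste0("call_", FLAVOR_CATEGORIES)
  if (nrow(predictions) == 0) {
    counts <- stats::setNames(integer(7), FLAVOR_CATEGORIES)
    return(structure(list(counts = counts, n_queries = 0L),
                     class = "radar_summary"))
  }
  m <- as.matrix(predictions[, cols, drop = FALSE])
  counts <- stats::setNames(as.integer(colSums(m == 1, na.rm = TRUE)),
                            FLAVOR_CATEGORIES)
  structure(list(counts = counts, n_queries = nrow(predictions)),
            class = "radar_summary")
}

#' @export
print.radar_summary <- function(x, ...) {
  cat("radar_summary over", x$n_queries, "queries:\n")
  print(x$counts)
  invisible(x)
}

#' Plot flavor recurrence as a radar chart
#'
#' @param summary A `radar_summary`.
#' @param main Plot title.
#' @return The summary, invisibly.
#' @export
plot_radar <- function(summary, main = "Flavor recurrence") {
  stopifnot(inherits(summary, "radar_summary"))
  counts <- summary$counts
  k <- length(counts)
  top <- max(counts, 1)
  theta <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)] + pi / 2
  graphics::plot(NA, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  for (ring in c(0.25, 0.5, 0.75, 1)) {
    graphics::polygon(ring * cos(theta), ring * sin(theta),
                      border = "grey80")
  }
  r <- counts / top
  graphics::polygon(r * cos(theta), r * sin(theta),
                    col = grDevices::adjustcolor("steelblue", 0.4),
                    border = "steelblue")
  graphics::text(1.18 * cos(theta), 1.18 * sin(theta),
                 labels = sub("_", "-", names(counts)), cex = 0.8)
  invisible(summary)
}

#' Write predictions to CSV
#'
#' @param predictions A `flavor_predictions` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions_csv <- function(predictions, path) {
  utils::write.csv(as.data.frame(predictions), path, row.names = FALSE)
  invisible(path)
}
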