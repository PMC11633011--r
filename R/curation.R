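# Curation: parse raw flavor-compound tables, clean and deduplicate them,
# and label every retained compound with the 7-bit flavor vector.
#
# Cleaning rules, applied first-match per row:
#   invalid-structure    SMILES does not parse
#   salt/multi-fragment  more than one disconnected fragment (salts are
#                        dropped, not desalted)
#   min-heavy-atoms      fewer than 2 heavy atoms
#   no-flavor-terms      empty flavor cell (training records need >= 1 term)
#   duplicate            canonical isomeric SMILES already seen (raw terms
#                        are merged into the first occurrence)

#' Parse a raw flavor-compound training table
#'
#' Reads a delimited text table with the five required columns (name,
#' PubChem id, SMILES, flavor terms, source). Rows are returned verbatim in
#' file order with missing cells as `NA`; all validation happens in
#' [clean_records()].
#'
#' @param path Path to a CSV (or TSV via `sep`) file.
#' @param schema Named character vector mapping the five canonical roles
#'   `name`, `pubchem_id`, `smiles`, `flavor`, `source` to the column names
#'   used in the file.
#' @param sep Field separator, default `","`.
#' @return A data.frame of raw rows with canonical column names.
#' @export
parse_training_table <- function(path,
                                 schema = c(name = "name",
                                            pubchem_id = "pubchem_id",
                                            smiles = "smiles",
                                            flavor = "flavor",
                                            source = "source"),
                                 sep = ",") {
  if (!file.exists(path)) stop("cannot read training table: ", path)
  required <- c("name", "pubchem_id", "smiles", "flavor", "source")
  if (!all(required %in% names(schema))) {
    stop("schema must name columns for: ",
         paste(setdiff(required, names(schema)), collapse = ", "))
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, comment.char = "",
                           check.names = FALSE, na.strings = c("", "NA"))
  missing_cols <- setdiff(unname(schema[required]), names(tab))
  if (length(missing_cols)) {
    stop("training table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(name = as.character(tab[[schema[["name"]]]]),
                    pubchem_id = tab[[schema[["pubchem_id"]]]],
                    smiles = as.character(tab[[schema[["smiles"]]]]),
                    flavor = as.character(tab[[schema[["flavor"]]]]),
                    source = as.character(tab[[schema[["source"]]]]),
                    stringsAsFactors = FALSE)
  out
}

# split a raw flavor cell into lower-cased terms
.split_terms <- function(flavor_cell) {
  if (is.na(flavor_cell)) return(character(0))
  terms <- unlist(strsplit(flavor_cell, "[;,/|@]+"))
  terms <- tolower(trimws(terms))
  unique(terms[nzchar(terms)])
}

#' Clean raw rows into labelled flavor records
#'
#' Applies the cleaning rules (invalid structures, salts/multi-fragment
#' species, molecules with fewer than 2 heavy atoms, rows without flavor
#' terms, duplicates by canonical isomeric SMILES) and labels every retained
#' record through the flavor wheel. Duplicate rows have their raw terms
#' merged into the first occurrence and the union re-mapped, so conflicting
#' duplicate labels resolve to the union. Unparsable SMILES never crash the
#' run; they are dropped and logged.
#'
#' @param rows Data.frame from [parse_training_table()], or anything with
#'   columns `name`, `pubchem_id`, `smiles`, `flavor` (or `raw_terms`),
#'   `source`.
#' @param wheel A `flavor_wheel` used for labelling.
#' @return A `flavor_records` data.frame with columns `name`, `pubchem_id`,
#'   `smiles` (canonical), `raw_terms` (list column), the seven label
#'   columns, and `source`. The rejection log is available via
#'   [rejection_log()].
#' @export
clean_records <- function(rows, wheel = default_flavor_wheel()) {
  stopifnot(is.data.frame(rows))
  n <- nrow(rows)
  raw_terms <- if ("raw_terms" %in% names(rows)) {
    lapply(rows$raw_terms, function(x) unique(tolower(trimws(as.character(x)))))
  } else {
    lapply(rows$flavor, .split_terms)
  }

  canon <- canonicalize_smiles(rows$smiles)
  rule <- rep(NA_character_, n)

  rule[is.na(canon)] <- "invalid-structure"
  ok <- is.na(rule)
  multi <- ok & smiles_fragment_count(ifelse(is.na(canon), "", canon)) > 1
  rule[multi] <- "salt/multi-fragment"
  ok <- is.na(rule)

  heavy <- rep(NA_integer_, n)
  if (any(ok)) heavy[ok] <- heavy_atom_count(canon[ok])
  rule[ok & heavy < 2] <- "min-heavy-atoms"
  ok <- is.na(rule)

  rule[ok & lengths(raw_terms) == 0] <- "no-flavor-terms"
  ok <- is.na(rule)

  # duplicates: keep first occurrence, merge raw terms
  first_idx <- integer(0)
  seen <- new.env(parent = emptyenv())
  merged_terms <- raw_terms
  for (i in which(ok)) {
    key <- canon[i]
    j <- seen[[key]]
    if (is.null(j)) {
      seen[[key]] <- i
      first_idx <- c(first_idx, i)
    } else {
      merged_terms[[j]] <- unique(c(merged_terms[[j]], raw_terms[[i]]))
      rule[i] <- "duplicate"
    }
  }

  rejections <- data.frame(row_index = which(!is.na(rule)),
                           smiles = rows$smiles[!is.na(rule)],
                           rule = rule[!is.na(rule)],
                           stringsAsFactors = FALSE)

  pcid <- suppressWarnings(as.numeric(rows$pubchem_id[first_idx]))
  pcid <- ifelse(!is.na(pcid) & pcid > 0 & pcid == floor(pcid),
                 as.integer(pcid), NA_integer_)

  labels <- t(vapply(merged_terms[first_idx], map_terms, integer(7),
                     wheel = wheel))
  colnames(labels) <- FLAVOR_CATEGORIES

  rec <- data.frame(name = rows$name[first_idx],
                    pubchem_id = pcid,
                    smiles = canon[first_idx],
                    stringsAsFactors = FALSE)
  rec$raw_terms <- I(merged_terms[first_idx])
  rec <- cbind(rec, as.data.frame(labels))
  rec$source <- rows$source[first_idx]
  rownames(rec) <- NULL
  structure(rec, class = c("flavor_records", "data.frame"),
            rejections = rejections)
}

#' Rejection log of a cleaning run
#'
#' @param records A `flavor_records` object from [clean_records()].
#' @return Data.frame with columns `row_index`, `smiles`, `rule` (one row
#'   per dropped input row, first matching rule).
#' @export
rejection_log <- function(records) {
  log <- attr(records, "rejections")
  if (is.null(log)) {
    data.frame(row_index = integer(0), smiles = character(0),
               rule = character(0), stringsAsFactors = FALSE)
  } else {
    log
  }
}

#' One-hot label matrix of a record set
#'
#' @param records A `flavor_records` data.frame.
#' @return Integer matrix (n records x 7 categories), rows aligned with the
#'   record order, columns in canonical category order.
#' @export
one_hot <- function(records) {
  stopifnot(all(FLAVOR_CATEGORIES %in% names(records)))
  m <- as.matrix(records[, FLAVOR_CATEGORIES, drop = FALSE])
  storage.mode(m) <- "integer"
  stopifnot(all(m %in% c(0L, 1L)))
  rownames(m) <- NULL
  m
}

#' @export
print.flavor_records <- function(x, ...) {
  cat("flavor_records:", nrow(x), "compounds\n")
  pos <- colMeans(as.matrix(x[, FLAVOR_CATEGORIES, drop = FALSE]))
  cat("positive fractions:\n")
  print(round(pos, 3))
  rej <- rejection_log(x)
  if (nrow(rej)) cat("rejected during cleaning:", nrow(rej), "rows\n")
  invisible(x)
}

#' Write records to the standard training-table CSV schema
#'
#' Emits the same CSV layout consumed by [parse_training_table()]; raw terms
#' are joined with `";"`.
#'
#' @param records A `flavor_records` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  out <- data.frame(name = records$name,
                    pubchem_id = records$pubchem_id,
                    smiles = records$smiles,
                    flavor = vapply(records$raw_terms, paste,
                                    character(1), collapse = ";"),
                    source = records$source,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
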