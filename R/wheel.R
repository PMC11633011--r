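# The flavor wheel: a mapping from fine-grained sensory descriptor terms to
# the seven coarse flavor categories. The packaged vocabulary is a plain-text
# config so users can extend or replace it; the mapping is deliberately
# user-overridable because published wheels differ between commodities.

#' Read a flavor wheel from a delimited config file
#'
#' The file must have two tab-separated columns, `term` and `categories`,
#' where `categories` is a comma-separated subset of the seven canonical
#' flavor categories (see [flavor_categories()]).
#'
#' @param path Path to a two-column TSV config.
#' @param unmapped_policy What to do with a raw term absent from the wheel:
#'   `"drop-term"` silently ignores it, `"error"` aborts naming the term.
#' @return A `flavor_wheel` object.
#' @export
read_flavor_wheel <- function(path, unmapped_policy = c("drop-term", "error")) {
  unmapped_policy <- match.arg(unmapped_policy)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("term", "categories") %in% names(tab))) {
    stop("flavor wheel config must have columns 'term' and 'categories'")
  }
  term_map <- lapply(strsplit(tab$categories, ","), trimws)
  names(term_map) <- tolower(trimws(tab$term))
  bad <- setdiff(unique(unlist(term_map)), FLAVOR_CATEGORIES)
  if (length(bad)) {
    stop("flavor wheel maps to unknown categories: ", paste(bad, collapse = ", "))
  }
  structure(list(term_map = term_map, unmapped_policy = unmapped_policy),
            class = "flavor_wheel")
}

#' The packaged default flavor wheel
#'
#' Loads the vocabulary shipped in `inst/extdata/flavor_wheel.tsv`. The
#' packaged wheel is a pragmatic stand-in seeded with an obvious vocabulary
#' (e.g. "rancid" is an off-flavor, "citrus" is fruity); projects with their
#' own sensory lexicon should supply it via [read_flavor_wheel()].
#'
#' @inheritParams read_flavor_wheel
#' @return A `flavor_wheel` object.
#' @export
default_flavor_wheel <- function(unmapped_policy = c("drop-term", "error")) {
  path <- system.file("extdata", "flavor_wheel.tsv", package = "flavorcast")
  read_flavor_wheel(path, match.arg(unmapped_policy))
}

#' @export
print.flavor_wheel <- function(x, ...) {
  cat("flavor_wheel:", length(x$term_map), "terms,",
      "unmapped_policy =", x$unmapped_policy, "\n")
  invisible(x)
}

#' Map raw flavor terms to the 7-category label vector
#'
#' Union semantics: label i is 1 iff any raw term maps to category i. The
#' result is independent of term order and duplicates.
#'
#' @param raw_terms Character vector of raw descriptor terms (case
#'   insensitive).
#' @param wheel A `flavor_wheel`; defaults to the packaged vocabulary.
#' @return Named integer vector of length 7 in canonical category order.
#' @export
map_terms <- function(raw_terms, wheel = default_flavor_wheel()) {
  stopifnot(inherits(wheel, "flavor_wheel"))
  labels <- stats::setNames(integer(7), FLAVOR_CATEGORIES)
  terms <- unique(tolower(trimws(as.character(raw_terms))))
  terms <- terms[nzchar(terms)]
  for (tm in terms) {
    cats <- wheel$term_map[[tm]]
    if (is.null(cats)) {
      if (wheel$unmapped_policy == "error") {
        stop("unmapped flavor term: '", tm, "'")
      }
      next
    }
    labels[cats] <- 1L
  }
  labels
}
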