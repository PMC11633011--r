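# Rule-labelled synthetic molecule generator. Molecules are assembled from
# a fragment grammar of flavor-bearing motifs (alkyl esters, terpenoid-style
# unsaturated alcohols, pyrazines, pyridines, vicinal polyols, short fatty
# acids, thiol/aldehyde off-notes) so that chemical validity is guaranteed
# by construction and the noise-free labels are decidable by substructure
# rules. This gives every other module a ground truth to recover without
# any external data.

# noise-free label rules: flavor -> substructure condition
#   fruity     ester            [CX3](=O)[OX2][#6]
#   sour       carboxylic acid  [CX3](=O)[OX2H1]
#   sweet      vicinal diol     [OX2H][CX4][CX4][OX2H]
#   bitter     pyridine ring    c1ccncc1
#   nutty      pyrazine ring    c1cnccn1
#   floral     methyl-branched alkene AND hydroxyl
#   off_flavor thiol OR aldehyde
.fixture_rules <- list(
  bitter = list(all = "c1ccncc1"),
  floral = list(all = c("[CH3][CX3]=[CX3]", "[OX2H]")),
  fruity = list(all = "[CX3](=O)[OX2][#6]"),
  off_flavor = list(any = c("[SX2H]", "[CX3H1]=O")),
  nutty = list(all = "c1cnccn1"),
  sour = list(all = "[CX3](=O)[OX2H1]"),
  sweet = list(all = "[OX2H][CX4][CX4][OX2H]")
)

# category-pure vocabulary used for the raw_terms of generated records
.fixture_terms <- list(
  bitter = c("bitter", "quinine"),
  floral = c("floral", "rose", "jasmine"),
  fruity = c("fruity", "citrus", "apple", "berry"),
  off_flavor = c("rancid", "musty", "putrid"),
  nutty = c("nutty", "almond", "roasted"),
  sour = c("sour", "vinegar", "acidic"),
  sweet = c("sweet", "honey", "caramel")
)

#' Specify a synthetic fixture dataset
#'
#' @param n Number of compounds (>= 50).
#' @param imbalance Named per-flavor positive fractions. The default mimics
#'   the curated-table structure: sweet near-balanced (0.48), sour rare
#'   (0.03), the rest around 0.2.
#' @param noise Per-label flip probability in `[0, 0.5)`.
#' @param seed Integer seed.
#' @return A `fixture_spec`.
#' @export
fixture_spec <- function(n,
                         imbalance = c(bitter = 0.2, floral = 0.2,
                                       fruity = 0.2, off_flavor = 0.2,
                                       nutty = 0.2, sour = 0.03,
                                       sweet = 0.48),
                         noise = 0, seed = 1) {
  stopifnot(n >= 50, noise >= 0, noise < 0.5)
  imbalance <- imbalance[FLAVOR_CATEGORIES]
  if (any(is.na(imbalance))) stop("imbalance must name all 7 categories")
  if (any(imbalance <= 0) || any(imbalance > 0.95)) {
    stop("positive fractions must lie in (0, 0.95]; the fragment grammar ",
         "cannot realise fractions outside that range")
  }
  structure(list(n = as.integer(n), imbalance = imbalance,
                 noise = noise, seed = as.integer(seed)),
            class = "fixture_spec")
}

# intent probabilities adjusted so that, conditional on >= 1 positive flavor
# per molecule, the marginal fractions match the requested targets
.adjust_intent <- function(target) {
  p <- target
  for (it in 1:25) {
    p0 <- prod(1 - p)
    p <- pmin(target * (1 - p0), 0.97)
  }
  p
}

.alkyl <- function(len) strrep("C", len)

# random branched alkyl segment: diversifies the carbon scaffolds so the
# generated chemical space is not a handful of straight chains
.rand_alkyl <- function(min_len = 1, max_len = 5) {
  len <- sample(min_len:max_len, 1)
  s <- strrep("C", len)
  if (len >= 3 && stats::runif(1) < 0.4) {
    pos <- sample(2:(len - 1), 1)
    s <- paste0(substr(s, 1, pos), "(C)", substr(s, pos + 1, len))
  }
  s
}

# assemble one molecule's SMILES from its intended flavor set
.build_smiles <- function(intent) {
  parts <- .rand_alkyl(1, 5)
  spacer <- function() if (stats::runif(1) < 0.6) .rand_alkyl(1, 4) else ""
  if (stats::runif(1) < 0.25) parts <- paste0(parts, "OCC")  # ether variety
  if (intent["fruity"])  parts <- paste0(parts, "C(=O)OC", spacer())
  if (intent["sour"])    parts <- paste0(parts, "C(C(=O)O)", spacer())
  if (intent["sweet"])   parts <- paste0(parts, "C(O)C(O)", spacer())
  if (intent["floral"])  parts <- paste0(parts, "C(C)=CC(O)", spacer())
  if (intent["off_flavor"]) {
    motif <- if (stats::runif(1) < 0.5) "C(S)" else "C(C=O)"
    parts <- paste0(parts, motif, spacer())
  }
  parts <- paste0(parts, .rand_alkyl(1, 4))
  if (intent["bitter"]) parts <- paste0(parts, "c1ccncc1")
  if (intent["nutty"])  parts <- paste0(parts, "c1cnccn1")
  parts
}

# evaluate the noise-free substructure label rules over a set of SMILES
.rule_labels <- function(smiles) {
  sdf <- parse_molecules(smiles)
  hits <- new.env(parent = emptyenv())
  match_smarts <- function(s) {
    key <- s
    if (is.null(hits[[key]])) hits[[key]] <- smarts_hits(sdf, s)
    hits[[key]]
  }
  out <- matrix(0L, length(smiles), 7,
                dimnames = list(NULL, FLAVOR_CATEGORIES))
  for (flavor in FLAVOR_CATEGORIES) {
    rule <- .fixture_rules[[flavor]]
    if (!is.null(rule$all)) {
      m <- Reduce(`&`, lapply(rule$all, match_smarts))
    } else {
      m <- Reduce(`|`, lapply(rule$any, match_smarts))
    }
    out[, flavor] <- as.integer(m)
  }
  out
}

#' Generate a rule-labelled synthetic record set
#'
#' Molecules are assembled from the fragment grammar according to
#' per-flavor Bernoulli intents (adjusted so that achieved positive
#' fractions match the spec after conditioning on at least one flavor per
#' molecule), labelled by the substructure rules, and optionally corrupted
#' by independent per-label flips with probability `noise`. Raw terms are
#' drawn from a category-pure vocabulary matching the noise-free labels, so
#' the records survive curation unchanged.
#'
#' @param spec A `fixture_spec`.
#' @return A `flavor_records` data.frame; the stored label columns carry
#'   the noise, [truth_table()] re-derives the rule labels.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  p <- .adjust_intent(spec$imbalance)

  smiles <- character(spec$n)
  for (i in seq_len(spec$n)) {
    repeat {
      intent <- stats::rbinom(7, 1, p) == 1
      names(intent) <- FLAVOR_CATEGORIES
      if (any(intent)) break
    }
    smiles[i] <- .build_smiles(intent)
  }
  canon <- canonicalize_smiles(smiles)
  if (anyNA(canon)) {
    stop("fragment grammar produced unparsable SMILES: ",
         paste(smiles[is.na(canon)][1:3], collapse = ", "))
  }

  truth <- .rule_labels(canon)
  labels <- truth
  if (spec$noise > 0) {
    flips <- matrix(stats::runif(length(labels)) < spec$noise,
                    nrow(labels), ncol(labels))
    labels <- abs(labels - flips * 1L)
    storage.mode(labels) <- "integer"
  }

  raw_terms <- lapply(seq_len(spec$n), function(i) {
    pos <- FLAVOR_CATEGORIES[truth[i, ] == 1]
    if (!length(pos)) return("flavorless")
    vapply(pos, function(f) sample(.fixture_terms[[f]], 1), character(1),
           USE.NAMES = FALSE)
  })

  rec <- data.frame(name = sprintf("FX-%05d", seq_len(spec$n)),
                    pubchem_id = NA_integer_,
                    smiles = canon,
                    stringsAsFactors = FALSE)
  rec$raw_terms <- I(raw_terms)
  rec <- cbind(rec, as.data.frame(labels))
  rec$source <- "synthetic"
  structure(rec, class = c("flavor_records", "data.frame"),
            fixture = list(seed = spec$seed, noise = spec$noise,
                           imbalance = spec$imbalance))
}

#' Noise-free label matrix of a generated fixture
#'
#' Re-derives the substructure rule labels, ignoring any label noise that
#' was applied at generation time; used for recall-against-truth tests.
#'
#' @param records A `flavor_records` produced by [generate_fixture()].
#' @return Integer matrix (n x 7).
#' @export
truth_table <- function(records) {
  if (is.null(attr(records, "fixture"))) {
    stop("truth_table() is only defined for records from generate_fixture()")
  }
  .rule_labels(records$smiles)
}
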