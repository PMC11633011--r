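# Parsing, cleaning, deduplication and labelling of raw flavor tables.

test_that("parse_training_table reads well-formed tables and enforces the schema", {
  path <- write_tiny_table(data.frame(
    name = c("ethanol", "benzene", "acetone"),
    pubchem_id = c(702, 241, 180),
    smiles = c("CCO", "c1ccccc1", "CC(=O)C"),
    flavor = c("sweet", "sweet", NA),
    source = "testdb"))
  rows <- parse_training_table(path)
  expect_equal(nrow(rows), 3)
  expect_equal(rows$smiles, c("CCO", "c1ccccc1", "CC(=O)C"))
  # row with empty flavor cell is retained here (dropped later by cleaning)
  expect_true(is.na(rows$flavor[3]))

  bad <- write_tiny_table(data.frame(name = "x", pubchem_id = 1,
                                     flavor = "sweet", source = "db"))
  expect_error(parse_training_table(bad), "smiles")
  expect_error(parse_training_table(tempfile()), "cannot read")
})

test_that("clean_records applies the drop rules with one logged rule per row", {
  rows <- data.frame(
    name = c("salt", "methane", "ethanol", "ethanol-again", "broken", "noterm"),
    pubchem_id = c(5234, 297, 702, 702, NA, 1),
    smiles = c("[Na+].[Cl-]", "C", "CCO", "OCC", "xx((", "CCC"),
    flavor = c("salty", "sweet", "sweet", "fruity", "sweet", NA),
    source = "db", stringsAsFactors = FALSE)
  rec <- clean_records(rows)
  log <- rejection_log(rec)

  expect_equal(nrow(rec), 1)            # only ethanol survives
  expect_equal(rec$smiles, "CCO")
  # duplicate raw terms merged and re-mapped as a union
  expect_setequal(rec$raw_terms[[1]], c("sweet", "fruity"))
  expect_equal(rec$sweet, 1L)
  expect_equal(rec$fruity, 1L)

  expect_equal(nrow(log), 5)
  expect_equal(log$rule[log$row_index == 1], "salt/multi-fragment")
  expect_equal(log$rule[log$row_index == 2], "min-heavy-atoms")
  expect_equal(log$rule[log$row_index == 4], "duplicate")
  expect_equal(log$rule[log$row_index == 5], "invalid-structure")
  expect_equal(log$rule[log$row_index == 6], "no-flavor-terms")
  # exactly one rule per dropped row
  expect_equal(anyDuplicated(log$row_index), 0)
})

test_that("cleaning is idempotent and non-increasing", {
  rows <- data.frame(
    name = letters[1:5], pubchem_id = 1:5,
    smiles = c("CCO", "OCC", "CCCC(=O)O", "c1ccncc1", "CC(C)O"),
    flavor = c("sweet", "fruity", "sour", "bitter", "sweet"),
    source = "db", stringsAsFactors = FALSE)
  c1 <- clean_records(rows)
  c2 <- clean_records(c1)
  expect_lte(nrow(c1), nrow(rows))
  expect_equal(c2$smiles, c1$smiles)
  expect_equal(one_hot(c2), one_hot(c1))
  expect_equal(nrow(rejection_log(c2)), 0)
})

test_that("non-positive or non-integer PubChem ids become absent", {
  rows <- data.frame(name = c("a", "b", "c"),
                     pubchem_id = c("-5", "12.7", "42"),
                     smiles = c("CCO", "CCC", "CCCC"),
                     flavor = "sweet", source = "db",
                     stringsAsFactors = FALSE)
  rec <- clean_records(rows)
  expect_equal(rec$pubchem_id, c(NA_integer_, NA_integer_, 42L))
})

test_that("map_terms uses union semantics and is order independent", {
  e_bitter <- c(bitter = 1L, floral = 0L, fruity = 0L, off_flavor = 0L,
                nutty = 0L, sour = 0L, sweet = 0L)
  expect_equal(map_terms("bitter"), e_bitter)

  lab <- map_terms(c("grape", "bitter"))
  expect_equal(lab[["bitter"]], 1L)
  expect_equal(lab[["fruity"]], 1L)
  expect_equal(sum(lab), 2L)

  expect_equal(map_terms(c("bitter", "grape")), lab)
  expect_equal(map_terms(c("grape", "bitter", "grape")), lab)

  # empty set maps to the zero vector (clean_records rejects such training rows)
  expect_equal(sum(map_terms(character(0))), 0L)

  wheel_err <- default_flavor_wheel(unmapped_policy = "error")
  expect_error(map_terms("zorblax", wheel_err), "zorblax")
  expect_equal(sum(map_terms("zorblax")), 0L)  # drop-term policy
})

test_that("one_hot preserves record order and canonical column order", {
  rec <- shared_records
  m <- one_hot(rec)
  expect_equal(dim(m), c(nrow(rec), 7))
  expect_equal(colnames(m), flavor_categories())
  expect_true(all(m %in% c(0L, 1L)))
  expect_equal(m[3, ], unlist(rec[3, flavor_categories()]))
})
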