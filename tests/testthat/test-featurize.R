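# Descriptor matrix, circular fingerprints, feature filters and the split.

test_that("descriptors are deterministic and carry the named features", {
  d <- compute_descriptors(c("CCCCCC", "CCCCCC", "CCO"))
  expect_s3_class(d, "feature_matrix")
  expect_equal(d$representation, "descriptors")
  expect_equal(d$values[1, ], d$values[2, ])
  expect_true(all(c("TPSA", "MolLogP", "MinEStateIndex", "PEOE_VSA1",
                    "EState_VSA1", "SMR_VSA1") %in% d$feature_names))
  # hexane: apolar hydrocarbon
  expect_equal(unname(d$values[1, "TPSA"]), 0)
  expect_gt(d$values[1, "MolLogP"], 1)
})

test_that("baseline property descriptors match a direct library computation", {
  smis <- c("CCCCCC", "CCO", "c1ccccc1")
  d <- compute_descriptors(smis)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(
    stats::setNames(smis, paste0("m", 1:3))))
  ref <- suppressWarnings(ChemmineR::propOB(sdf))
  expect_equal(unname(d$values[, "MolLogP"]), as.numeric(ref$logP))
  expect_equal(unname(d$values[, "TPSA"]), as.numeric(ref$TPSA))
  expect_equal(unname(d$values[, "MolWt"]), as.numeric(ref$MW))
})

test_that("fingerprints are binary, deterministic and hydrogen-isotope free", {
  fp <- compute_fingerprints(c("CC(=O)OCC", "CC(=O)OCC", "CCO"), nbits = 512)
  expect_true(all(fp$values %in% c(0L, 1L)))
  expect_equal(fp$values[1, ], fp$values[2, ])
  expect_false(all(fp$values[1, ] == fp$values[3, ]))

  f1 <- compute_fingerprints("CCO", nbits = 512)$values
  f2 <- compute_fingerprints("CCO[2H]", nbits = 512)$values
  expect_equal(f1, f2)
})

test_that("set-bit counts equal the independent circular-fingerprint oracle", {
  # at nbits = 4096 with tiny molecules there are no fold collisions, so the
  # set-bit count equals the number of distinct atom environments; compare
  # against OpenBabel's independent ECFP4 implementation
  smis <- c(bz = "c1ccccc1", et = "CC", pr = "CCC", eth = "CCO")
  mine <- rowSums(compute_fingerprints(unname(smis), nbits = 4096)$values)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smis))
  ref <- rowSums(ChemmineR::fingerprintOB(sdf, "ECFP4")@fpma)
  expect_equal(unname(mine), unname(ref))
  expect_equal(unname(mine), c(3, 3, 6, 9))
})

test_that("invalid and near-constant filters drop exactly the right columns", {
  vals <- cbind(a = c(1, 2, 3), b = c(1, NaN, 2), c = c(0, 1, 0))
  m <- feature_matrix(vals)
  f <- drop_invalid_features(m)
  expect_equal(f$feature_names, c("a", "c"))
  expect_equal(f$filter_log[[1]]$dropped, "b")
  # all-finite matrix unchanged
  f2 <- drop_invalid_features(feature_matrix(vals[, c("a", "c")]))
  expect_length(f2$filter_log[[1]]$dropped, 0)

  # 100-row column with 98 identical entries is dropped at 0.97
  vals <- cbind(dom = c(rep(0, 98), 1, 2),
                half = rep(c(0, 1), 50),
                allzero = rep(0, 100))
  f3 <- drop_near_constant(feature_matrix(vals), 0.97)
  expect_setequal(f3$filter_log[[1]]$dropped, c("dom", "allzero"))
  expect_equal(f3$feature_names, "half")
})

test_that("correlation filter is greedy in feature order", {
  set.seed(1)
  x <- rnorm(200)
  vals <- cbind(f1 = x, f2 = x + rnorm(200, sd = 0.01), f3 = rnorm(200))
  expect_gt(abs(cor(vals[, 1], vals[, 2])), 0.99)
  f <- drop_correlated(feature_matrix(vals), 0.95)
  expect_equal(f$feature_names, c("f1", "f3"))
  detail <- f$filter_log[[1]]$detail
  expect_equal(detail$kept, "f1")
  expect_equal(detail$dropped, "f2")

  # exact duplicate column: r = 1
  dup <- cbind(a = x, b = x)
  fd <- drop_correlated(feature_matrix(dup))
  expect_equal(fd$feature_names, "a")
  expect_equal(fd$filter_log[[1]]$detail$r, 1)

  # two independent random columns at n = 1000 are both kept
  set.seed(2)
  ind <- cbind(u = rnorm(1000), v = rnorm(1000))
  expect_equal(drop_correlated(feature_matrix(ind))$feature_names, c("u", "v"))

  # zero-variance columns must be caught by the earlier filter
  zv <- cbind(a = x, z = rep(1, 200))
  expect_error(drop_correlated(feature_matrix(zv)), "zero-variance")
})

test_that("correlation filter agrees with the exhaustive pairwise oracle", {
  set.seed(99)
  for (rep in 1:5) {
    base <- matrix(rnorm(30 * 6), 30, 6)
    X <- cbind(base,
               base[, 1] + rnorm(30, sd = 0.01),
               base[, 2] * 1.5,
               -base[, 3] + rnorm(30, sd = 0.005),
               matrix(rnorm(30 * 1), 30, 1))
    colnames(X) <- sprintf("c%02d", seq_len(ncol(X)))
    got <- drop_correlated(feature_matrix(X))$feature_names
    expect_equal(got, greedy_corr_oracle(X))
    kept <- X[, got, drop = FALSE]
    cc <- stats::cor(kept)
    expect_true(all(abs(cc[upper.tri(cc)]) <= 0.95))
  }
})

test_that("the filter pipeline is order-fixed, idempotent, and complete", {
  d <- compute_descriptors(shared_records[1:60, ])
  f1 <- apply_feature_filters(d)
  filters <- vapply(f1$filter_log, function(s) s$filter, "")
  expect_equal(filters, c("invalid", "near-constant", "correlation"))
  # every dropped feature appears exactly once; counts add up
  dropped <- unlist(lapply(f1$filter_log, function(s) s$dropped))
  expect_equal(anyDuplicated(dropped), 0)
  expect_equal(ncol(d$values), ncol(f1$values) + length(dropped))
  # idempotent end-to-end
  f2 <- apply_feature_filters(f1)
  expect_equal(f2$feature_names, f1$feature_names)
  # fingerprint representation skips the correlation filter
  fp <- apply_feature_filters(compute_fingerprints(shared_records[1:60, ],
                                                   nbits = 256))
  expect_false("correlation" %in%
                 vapply(fp$filter_log, function(s) s$filter, ""))
})

test_that("split_80_20 is reproducible, sized correctly, and stratified", {
  s1 <- split_80_20(10, seed = 5)
  expect_length(s1$train_idx, 8)
  expect_length(s1$test_idx, 2)
  expect_equal(split_80_20(10, seed = 5), s1)
  expect_false(identical(split_80_20(10, seed = 6)$test_idx, s1$test_idx))
  expect_length(intersect(s1$train_idx, s1$test_idx), 0)
  expect_setequal(c(s1$train_idx, s1$test_idx), 1:10)
  expect_error(split_80_20(4, 1), "at least 5")

  # 97:3 stratified split keeps at least one test positive
  y <- c(rep(0, 97), rep(1, 3))
  s2 <- split_80_20(100, seed = 3, labels = y)
  expect_gte(sum(y[s2$test_idx]), 1)
  expect_equal(length(s2$test_idx), 20, tolerance = 0.1)
})
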