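# Metric suite and importance analyses.

test_that("confusion metrics are exact rational values from counts", {
  expect_equal(confusion_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0)),
               list(recall = 1, specificity = 1))
  # the majority-class failure mode: all-negative predictions
  y <- c(rep(1, 3), rep(0, 7))
  expect_equal(confusion_metrics(y, rep(0, 10)),
               list(recall = 0, specificity = 1))
  # TP=3 FN=1 TN=4 FP=1
  y_true <- c(1, 1, 1, 1, 0, 0, 0, 0, 0)
  y_pred <- c(1, 1, 1, 0, 0, 0, 0, 0, 1)
  expect_equal(confusion_metrics(y_true, y_pred),
               list(recall = 0.75, specificity = 0.8))
  expect_error(confusion_metrics(rep(1, 5), rep(1, 5)), "single class")
})

test_that("confusion metrics agree with direct 2x2 tables on random inputs", {
  set.seed(10)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))  # both classes present
    p <- sample(0:1, n, replace = TRUE)
    got <- confusion_metrics(y, p)
    expect_equal(got$recall, sum(y == 1 & p == 1) / sum(y == 1))
    expect_equal(got$specificity, sum(y == 0 & p == 0) / sum(y == 0))
  }
})

test_that("roc_auc equals the exhaustive pair-counting oracle", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  # 3 pos / 3 neg with one inversion: oracle counts 8 wins out of 9 pairs
  y <- c(1, 1, 1, 0, 0, 0)
  s <- c(0.9, 0.8, 0.3, 0.4, 0.2, 0.1)
  expect_equal(pair_count_auc(y, s), 8 / 9)
  expect_equal(roc_auc(y, s), 8 / 9)

  set.seed(20)
  for (i in 1:60) {
    n <- sample(4:20, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- round(runif(n), 1)  # coarse scores force ties
    expect_equal(roc_auc(y, s), pair_count_auc(y, s))
  }
  expect_error(roc_auc(rep(1, 4), runif(4)), "single class")
})

test_that("roc_auc agrees with an independent ROC package", {
  skip_if_not_installed("pROC")
  set.seed(30)
  y <- sample(0:1, 50, replace = TRUE, prob = c(0.6, 0.4))
  y[1:2] <- c(0, 1)
  s <- rnorm(50) + y
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(roc_auc(y, s), ref, tolerance = 1e-12)
})

test_that("bias and overfit are the stated differences", {
  rep1 <- data.frame(recall = 0.5, specificity = 0.9)
  expect_equal(majority_bias(rep1), 0.4)
  expect_equal(majority_bias(data.frame(recall = 0.7, specificity = 0.7)), 0)
  expect_equal(majority_bias(data.frame(recall = 1, specificity = 0)), -1)

  tr <- data.frame(recall = 0.95)
  te <- data.frame(recall = 0.45)
  expect_equal(overfit_score(tr, te), 0.5)
  expect_equal(overfit_score(te, te), 0)
  # test recall above train recall flags underfitting (negative)
  expect_lt(overfit_score(data.frame(recall = 0.4),
                          data.frame(recall = 0.6)), 0)
})

test_that("VIP importance ranks a planted informative feature first", {
  set.seed(40)
  n <- 200
  X <- cbind(signal = c(rnorm(n / 2, 0), rnorm(n / 2, 4)),
             matrix(rnorm(n * 5), ncol = 5,
                    dimnames = list(NULL, paste0("noise", 1:5))))
  y <- c(rep(0L, n / 2), rep(1L, n / 2))
  spec <- model_spec("sweet", "random-forest", "descriptors", "none",
                     grid = list(num_trees = 100, max_depth = 0, min_node = 1),
                     seed = 4)
  m <- grid_search(spec, no_resample(X, y))
  vip <- vip_importance(m)
  expect_equal(vip$feature[1], "signal")
  expect_equal(sum(vip$score), 1, tolerance = 1e-12)
  expect_equal(vip$rank, seq_len(nrow(vip)))
  expect_true(all(diff(vip$score) <= 1e-12))

  kspec <- model_spec("sweet", "k-nearest-neighbors", "descriptors", "none",
                      grid = list(k = 3, weights = "uniform"), seed = 4)
  km <- grid_search(kspec, no_resample(X, y))
  expect_error(vip_importance(km), "permutation_importance")
})

test_that("permutation importance finds the planted feature, zero for constants", {
  set.seed(41)
  n <- 120
  X <- cbind(signal = c(rnorm(n / 2, 0), rnorm(n / 2, 4)),
             noise = rnorm(n),
             const = rep(1, n))
  y <- c(rep(0L, n / 2), rep(1L, n / 2))
  spec <- model_spec("sweet", "k-nearest-neighbors", "descriptors", "none",
                     grid = list(k = 5, weights = "distance"), seed = 4)
  m <- grid_search(spec, no_resample(X, y))
  pi10 <- permutation_importance(m, X, y, n_repeats = 10, seed = 7)
  expect_equal(pi10$feature[1], "signal")
  expect_equal(pi10$score[pi10$feature == "const"], 0)
  expect_true(all(pi10$score >= 0))
  # ranking of the dominant feature is stable across repeat counts
  pi1 <- permutation_importance(m, X, y, n_repeats = 1, seed = 7)
  expect_equal(pi1$feature[1], "signal")
})

test_that("bit_to_fragments recovers the shared atom environment", {
  # molecules sharing an ether C-O-C environment
  ethers <- c("COC", "CCOC", "CCOCC", "COCCC")
  fp <- compute_fingerprints(ethers, nbits = 256)
  common <- which(colSums(fp$values) == length(ethers)) - 1L
  expect_gt(length(common), 0)
  # the ether oxygen's environment is one of the shared bits; every fragment
  # of every shared bit must contain the oxygen or its carbon neighbourhood
  frs <- lapply(common, function(b) bit_to_fragments(ethers, b, nbits = 256))
  expect_true(any(vapply(frs, function(f) any(grepl("O", f)), logical(1))))
  # determinism
  expect_identical(bit_to_fragments(ethers, common[1], nbits = 256),
                   bit_to_fragments(ethers, common[1], nbits = 256))
  # a bit never set yields an empty result with a warning
  unused <- setdiff(0:255, unlist(lapply(attr(fp, "bit_info"),
                                         function(b) b$bit)))[1]
  expect_warning(out <- bit_to_fragments(ethers, unused, nbits = 256),
                 "never set")
  expect_length(out, 0)
})
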