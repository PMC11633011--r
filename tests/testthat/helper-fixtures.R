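# Shared fixtures built once per test run. Kept small: the heavy end-to-end
# runs live in test-acceptance.R.

# a small balanced-ish record set where every flavor has enough positives to
# train the backbone
shared_records <- generate_fixture(fixture_spec(
  n = 150,
  imbalance = c(bitter = 0.3, floral = 0.3, fruity = 0.3, off_flavor = 0.3,
                nutty = 0.3, sour = 0.25, sweet = 0.45),
  seed = 42))

shared_backbone <- train_backbone(shared_records, seed = 42)

# independent exhaustive pair-counting AUC oracle
pair_count_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# independent greedy correlation-filter oracle
greedy_corr_oracle <- function(X, r_max = 0.95) {
  kept <- integer(0)
  for (j in seq_len(ncol(X))) {
    drop <- FALSE
    for (i in kept) {
      if (abs(stats::cor(X[, i], X[, j])) > r_max) { drop <- TRUE; break }
    }
    if (!drop) kept <- c(kept, j)
  }
  colnames(X)[kept]
}

# write a tiny training CSV and return its path
write_tiny_table <- function(rows) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(rows, path, row.names = FALSE)
  path
}
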