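# A linearly separable 4-class fingerprint fixture: ten designated bits per
# class carry the signal, the remaining bits are noise.
separableFixture <- function(n_per_class = 30, n_noise = 60, flip = 0.02,
                             seed = 99) {
  set.seed(seed)
  classes <- ACTIVITY_LEVELS
  rows <- lapply(seq_along(classes), function(k) {
    sig <- matrix(0L, n_per_class, 40)
    sig[, (10 * (k - 1) + 1):(10 * k)] <- 1L
    flipmask <- matrix(runif(n_per_class * 40) < flip, n_per_class)
    sig[flipmask] <- 1L - sig[flipmask]
    noise <- matrix(rbinom(n_per_class * n_noise, 1, 0.3), n_per_class)
    cbind(sig, noise)
  })
  x <- do.call(rbind, rows)
  colnames(x) <- paste0("bit", seq_len(ncol(x)))
  rownames(x) <- paste0("s", seq_len(nrow(x)))
  list(x = x, y = factor(rep(classes, each = n_per_class),
                         levels = ACTIVITY_LEVELS))
}

test_that("oversampling raises every class to the majority size", {
  labels <- rep(ACTIVITY_LEVELS, c(122, 432, 604, 520))
  idx <- oversampleIndices(labels, seed = 42)
  expect_equal(unname(table(labels[idx])), rep(604L, 4),
               ignore_attr = TRUE)
  # every original row is still present
  expect_true(all(seq_along(labels) %in% idx))
  # already balanced input is a no-op
  bal <- rep(ACTIVITY_LEVELS, each = 10)
  expect_equal(oversampleIndices(bal), seq_along(bal))
  # seeded reproducibility
  expect_identical(oversampleIndices(labels, seed = 1),
                   oversampleIndices(labels, seed = 1))
  expect_error(oversampleIndices(factor(rep("potent", 3),
                                        levels = ACTIVITY_LEVELS)),
               "empty class")
})

test_that("feature selection removes low-variance then correlated columns", {
  set.seed(3)
  base <- rbinom(40, 1, 0.5)
  x <- cbind(const = rep(1, 40),                    # variance 0
             a = base,                              # kept
             dup = base,                            # r = 1 with a, later
             b = rbinom(40, 1, 0.5),                # kept
             rare = c(rep(0, 39), 1),               # variance ~0.025
             c = rbinom(40, 1, 0.4))                # kept
  out <- selectFeatures(x)
  expect_setequal(colnames(out), c("a", "b", "c"))
  expect_equal(attr(out, "n_after_variance"), 4)
  expect_equal(attr(out, "n_after_correlation"), 3)
  # re-applying the recorded retained set is idempotent
  again <- selectFeatures(x[, attr(out, "retained")])
  expect_equal(colnames(again), colnames(out))
  expect_error(selectFeatures(cbind(k = rep(1, 10))), "variance")
})

test_that("hand-computed 6-column selection matches", {
  x <- cbind(f1 = c(0, 0, 0, 0, 0, 0, 0, 1),     # var 7/64 ~ 0.109, kept
             f2 = c(1, 0, 1, 0, 1, 0, 1, 0),
             f3 = c(1, 0, 1, 0, 1, 0, 1, 0),     # duplicate of f2
             f4 = c(0, 0, 0, 0, 0, 0, 0, 0),     # constant
             f5 = c(1, 1, 0, 0, 1, 1, 0, 0),
             f6 = c(0, 1, 1, 0, 0, 1, 1, 0))
  # sample variances: f1 = 7/64... compute directly
  v <- apply(x, 2, var)
  keep1 <- names(v)[v >= 0.1]
  out <- selectFeatures(x)
  expect_true(all(colnames(out) %in% keep1))
  expect_false("f3" %in% colnames(out))  # later duplicate removed
  expect_true(all(c("f2", "f5", "f6") %in% colnames(out)))
})

test_that("the stratified split and folds partition the data deterministically", {
  y <- rep(ACTIVITY_LEVELS, each = 25)
  sp <- splitAndCV(y, test_frac = 0.2, folds = 5, seed = 42)
  expect_equal(length(sp$test), 20)
  expect_equal(sort(c(sp$train, sp$test)), seq_along(y))
  expect_equal(length(sp$fold), length(sp$train))
  expect_setequal(unique(sp$fold), 1:5)
  # stratification: each class contributes 20% to the test set
  expect_equal(unname(table(y[sp$test])), rep(5L, 4), ignore_attr = TRUE)
  sp2 <- splitAndCV(y, test_frac = 0.2, folds = 5, seed = 42)
  expect_identical(sp, sp2)
  expect_error(splitAndCV(rep(ACTIVITY_LEVELS, c(3, 25, 25, 25)),
                          folds = 10), "fewer")
})

test_that("confusion metrics match hand arithmetic and the binary formula", {
  m <- confusionMetrics(diag(c(3, 4, 5, 6)))
  expect_equal(unname(m), c(1, 1, 1))
  # chance-level single-class prediction on balanced classes
  cm <- matrix(0, 4, 4); cm[, 1] <- 5
  m2 <- confusionMetrics(cm)
  expect_equal(m2[["accuracy"]], 0.25)
  expect_equal(m2[["mcc"]], 0)
  # binary hand case: [[2,1],[0,3]]
  m3 <- confusionMetrics(matrix(c(2, 0, 1, 3), 2))
  expect_equal(m3[["accuracy"]], 5 / 6)
  expect_equal(m3[["mcc"]], (2 * 3 - 1 * 0) / sqrt(3 * 3 * 4 * 2))
  expect_error(confusionMetrics(matrix(0, 2, 2)), "empty")
})

test_that("multiclass MCC agrees with the binary MCC formula on 2x2 oracles", {
  set.seed(17)
  for (i in 1:25) {
    cm <- matrix(rpois(4, 6), 2)
    if (sum(cm) == 0) next
    tp <- cm[1, 1]; fn <- cm[1, 2]; fp <- cm[2, 1]; tn <- cm[2, 2]
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    expected <- if (den == 0) 0 else (tp * tn - fp * fn) / den
    expect_equal(confusionMetrics(cm)[["mcc"]], expected, tolerance = 1e-12)
  }
})

test_that("metrics are invariant under consistent class relabelling", {
  set.seed(23)
  cm <- matrix(rpois(16, 4), 4)
  perm <- sample(4)
  expect_equal(confusionMetrics(cm[perm, perm]), confusionMetrics(cm))
})

test_that("the full 12-algorithm bench runs, one report row each", {
  fx <- separableFixture()
  b <- trainBench(fx$x, fx$y, folds = 2, var_min = 0.05)
  expect_equal(nrow(b), 12)
  expect_setequal(b$algorithm, c("dt", "et", "rf", "gb", "lgbm", "xgb",
                                 "svm", "mlp", "lr", "knn", "nb", "gp"))
  expect_false(any(b$failed))
  expect_true(all(b$accuracy_train >= 0 & b$accuracy_train <= 1,
                  na.rm = TRUE))
  expect_true(all(abs(b$mcc_test) <= 1, na.rm = TRUE))
  # ensembles separate the constructed classes almost perfectly
  ens <- b[b$algorithm %in% c("et", "rf", "gb", "lgbm", "xgb"), ]
  expect_true(all(ens$accuracy_train >= 0.95))
})

test_that("bench reports are reproducible for deterministic learners", {
  fx <- separableFixture()
  b1 <- trainBench(fx$x, fx$y, algorithms = c("dt", "rf", "lr"), folds = 2,
                   var_min = 0.05)
  b2 <- trainBench(fx$x, fx$y, algorithms = c("dt", "rf", "lr"), folds = 2,
                   var_min = 0.05)
  expect_identical(b1, b2)
})

test_that("published-parity mode oversamples before the split", {
  fx <- separableFixture(n_per_class = 20)
  # drop rows to unbalance: 10/20/20/15
  keep <- c(1:10, 21:40, 41:60, 61:75)
  b <- trainBench(fx$x[keep, ], fx$y[keep], algorithms = "dt",
                  mode = "published-parity", folds = 2, var_min = 0.05)
  sizes <- attr(b, "split")
  # oversampled total: 4 * 20 = 80 rows split 80:20
  expect_equal(unname(sizes["train"] + sizes["test"]), 80)
})
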