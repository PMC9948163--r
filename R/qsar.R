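# Multiclass QSAR bench: class rebalancing, fingerprint featurisation,
# variance/correlation feature selection, stratified 80:20 split with
# 10-fold CV, a 12-algorithm one-vs-rest classifier bench, and
# accuracy / macro recall / multiclass MCC metrics.

#' Random oversampling to the majority class size
#'
#' Duplicates randomly chosen rows (with replacement) within each minority
#' class until every class matches the majority class size. Original rows
#' are always retained; the operation is seeded and reproducible.
#'
#' @param labels Factor/character class labels.
#' @param seed Integer seed (default 42).
#' @return Integer vector of row indices into the original data (original
#'   indices first, then the sampled duplicates).
#' @export
oversampleIndices <- function(labels, seed = 42) {
  labels <- as.factor(labels)
  tab <- table(labels)
  if (any(tab == 0)) stop("oversampleIndices: empty class ",
                          paste(names(tab)[tab == 0], collapse = ", "))
  target <- max(tab)
  set.seed(seed)
  extra <- unlist(lapply(names(tab), function(cl) {
    idx <- which(labels == cl)
    need <- target - length(idx)
    if (need > 0) sample(idx, need, replace = TRUE) else integer(0)
  }))
  c(seq_along(labels), extra)
}

#' Oversample a curated set
#'
#' @param curated A [CuratedSet-class] (or `data.frame` with an
#'   `activity_class` column).
#' @param seed Integer seed (default 42).
#' @return The input rows with duplicates appended so all activity classes
#'   have the majority-class size.
#' @export
oversampleClasses <- function(curated, seed = 42) {
  m <- if (is(curated, "CuratedSet")) molecules(curated) else curated
  idx <- oversampleIndices(m$activity_class, seed = seed)
  out <- m[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Variance and correlation feature selection
#'
#' Two-stage filter: (1) remove columns with sample variance below
#' `var_min`; (2) scan the surviving columns left to right and drop any
#' column whose absolute Pearson correlation with an already-retained
#' column exceeds `corr_max` (for binary columns Pearson r is the phi
#' coefficient). The retained column names are recorded so the same
#' selection can be applied to new data.
#'
#' @param x Numeric matrix (rows = samples).
#' @param var_min Variance threshold (default 0.1, strict `<` removal).
#' @param corr_max Correlation threshold (default 0.95, strict `>` removal).
#' @return The filtered matrix with attributes `retained` (column names),
#'   `n_after_variance` and `n_after_correlation`.
#' @export
selectFeatures <- function(x, var_min = 0.1, corr_max = 0.95) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  v <- apply(x, 2, stats::var)
  x1 <- x[, v >= var_min, drop = FALSE]
  if (ncol(x1) == 0) stop("selectFeatures: all columns removed by the ",
                          "variance filter")
  n_var <- ncol(x1)
  cm <- abs(suppressWarnings(stats::cor(x1)))
  keep <- logical(ncol(x1))
  for (j in seq_len(ncol(x1))) {
    keep[j] <- !any(keep & cm[seq_len(ncol(x1)), j] > corr_max &
                      seq_len(ncol(x1)) != j)
  }
  out <- x1[, keep, drop = FALSE]
  attr(out, "retained") <- colnames(out)
  attr(out, "n_after_variance") <- n_var
  attr(out, "n_after_correlation") <- ncol(out)
  out
}

#' Stratified train/test split with cross-validation folds
#'
#' Splits samples 80:20 (by default) stratified on the class labels, then
#' assigns stratified `folds`-fold cross-validation memberships within the
#' training portion. Fully seeded.
#'
#' @param labels Class labels.
#' @param test_frac Test fraction (default 0.2).
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed (default 42).
#' @return List with `train` (indices), `test` (indices), `fold` (fold id
#'   per training index, parallel to `train`).
#' @export
splitAndCV <- function(labels, test_frac = 0.2, folds = 10, seed = 42) {
  labels <- as.factor(labels)
  tab <- table(labels)
  if (any(tab < folds))
    stop("splitAndCV: class ", names(tab)[which.min(tab)], " has fewer ",
         "samples than folds -- use fewer folds")
  set.seed(seed)
  test <- sort(unlist(lapply(levels(labels), function(cl) {
    idx <- which(labels == cl)
    sample(idx, round(length(idx) * test_frac))
  })))
  train <- setdiff(seq_along(labels), test)
  fold <- integer(length(train))
  for (cl in levels(labels)) {
    pos <- which(labels[train] == cl)
    fold[pos] <- sample(rep_len(seq_len(folds), length(pos)))
  }
  list(train = train, test = test, fold = fold)
}

#' Metrics from a multiclass confusion matrix
#'
#' Accuracy (trace over total), macro-averaged recall (mean per-class
#' TP/(TP+FN), classes absent from the truth contribute 0), and the
#' multiclass Matthews correlation coefficient in its confusion-matrix
#' (R_K) form, which reduces to the familiar binary MCC for two classes.
#'
#' @param confusion Square count matrix, rows = truth, columns = predicted.
#' @return Named vector `accuracy`, `recall`, `mcc`.
#' @export
confusionMetrics <- function(confusion) {
  cm <- as.matrix(confusion)
  stopifnot(nrow(cm) == ncol(cm))
  s <- sum(cm)
  if (s == 0) stop("confusionMetrics: empty confusion matrix")
  acc <- sum(diag(cm)) / s
  rec_cl <- ifelse(rowSums(cm) == 0, 0, diag(cm) / rowSums(cm))
  rec <- mean(rec_cl)
  t_k <- rowSums(cm); p_k <- colSums(cm); c_ <- sum(diag(cm))
  num <- c_ * s - sum(p_k * t_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  mcc <- if (den == 0) 0 else num / den
  c(accuracy = acc, recall = rec, mcc = mcc)
}

# Single-hidden-layer perceptron (ReLU hidden layer, logistic output)
# trained by full-batch Adam on the binary cross-entropy; seeded He
# initialisation makes fits reproducible. Sized for the bench's
# 100-hidden-unit configuration, where quasi-Newton optimisers are
# impractically slow.
.mlpFit <- function(x, y, hidden = 100, iters = 300, lr = 1e-3,
                    seed = 42) {
  x <- as.matrix(x); n <- nrow(x); p <- ncol(x)
  set.seed(seed)
  w1 <- matrix(stats::rnorm(p * hidden, 0, sqrt(2 / p)), p)
  b1 <- numeric(hidden)
  w2 <- matrix(stats::rnorm(hidden, 0, sqrt(2 / hidden)), hidden)
  b2 <- 0
  ms <- vs <- list(w1 = 0 * w1, b1 = 0 * b1, w2 = 0 * w2, b2 = 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  for (t in seq_len(iters)) {
    z1 <- sweep(x %*% w1, 2, b1, `+`)
    a1 <- pmax(z1, 0)
    z2 <- as.numeric(a1 %*% w2) + b2
    pr <- 1 / (1 + exp(-z2))
    d2 <- (pr - y) / n
    g <- list(w2 = crossprod(a1, d2), b2 = sum(d2))
    d1 <- (d2 %*% t(w2)) * (z1 > 0)
    g$w1 <- crossprod(x, d1)
    g$b1 <- colSums(d1)
    for (nm in names(g)) {
      ms[[nm]] <- beta1 * ms[[nm]] + (1 - beta1) * g[[nm]]
      vs[[nm]] <- beta2 * vs[[nm]] + (1 - beta2) * g[[nm]]^2
      mhat <- ms[[nm]] / (1 - beta1^t)
      vhat <- vs[[nm]] / (1 - beta2^t)
      upd <- lr * mhat / (sqrt(vhat) + eps)
      if (nm == "w1") w1 <- w1 - upd
      else if (nm == "b1") b1 <- b1 - as.numeric(upd)
      else if (nm == "w2") w2 <- w2 - upd
      else b2 <- b2 - as.numeric(upd)
    }
  }
  list(w1 = w1, b1 = b1, w2 = w2, b2 = b2)
}

.mlpProb <- function(m, x) {
  a1 <- pmax(sweep(as.matrix(x) %*% m$w1, 2, m$b1, `+`), 0)
  as.numeric(1 / (1 + exp(-(as.numeric(a1 %*% m$w2) + m$b2))))
}

# ---- one-vs-rest classifier registry -------------------------------------
# Each entry: fit(x, y01, seed) -> model; prob(model, x) -> P(positive).
# Hyperparameters follow the bench definition: 500 trees for the ensemble
# methods, random forest mtry 3 with Gini splitting, MLP with one hidden
# layer of 100 units, remaining settings at package defaults.

.benchAlgorithms <- function() {
  num01 <- function(y) factor(y, levels = c("0", "1"))
  list(
    dt = list(fit = function(x, y, seed) {
      set.seed(seed)
      rpart::rpart(y ~ ., data = data.frame(x, y = num01(y)),
                   method = "class")
    }, prob = function(m, x) predict(m, data.frame(x))[, "1"]),
    et = list(fit = function(x, y, seed) {
      ranger::ranger(x = x, y = num01(y), num.trees = 500,
                     splitrule = "extratrees", num.random.splits = 1,
                     probability = TRUE, seed = seed, num.threads = 1)
    }, prob = function(m, x) predict(m, x,
                                     num.threads = 1)$predictions[, "1"]),
    rf = list(fit = function(x, y, seed) {
      set.seed(seed)
      randomForest::randomForest(x = x, y = num01(y), ntree = 500,
                                 mtry = min(3, ncol(x)))
    }, prob = function(m, x) predict(m, x, type = "prob")[, "1"]),
    gb = list(fit = function(x, y, seed) {
      set.seed(seed)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = 0.1,
                      max_depth = 3, nthread = 1, seed = seed),
        data = xgboost::xgb.DMatrix(x,
          label = as.numeric(as.character(y))),
        nrounds = 500, verbose = 0)
    }, prob = function(m, x) predict(m, xgboost::xgb.DMatrix(x))),
    lgbm = list(fit = function(x, y, seed) {
      set.seed(seed)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = 0.1,
                      tree_method = "hist", grow_policy = "lossguide",
                      max_leaves = 31, max_depth = 0, nthread = 1,
                      seed = seed),
        data = xgboost::xgb.DMatrix(x,
          label = as.numeric(as.character(y))),
        nrounds = 500, verbose = 0)
    }, prob = function(m, x) predict(m, xgboost::xgb.DMatrix(x))),
    xgb = list(fit = function(x, y, seed) {
      set.seed(seed)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", nthread = 1,
                      seed = seed),
        data = xgboost::xgb.DMatrix(x,
          label = as.numeric(as.character(y))),
        nrounds = 500, verbose = 0)
    }, prob = function(m, x) predict(m, xgboost::xgb.DMatrix(x))),
    svm = list(fit = function(x, y, seed) {
      set.seed(seed)
      e1071::svm(x = x, y = num01(y), probability = TRUE)
    }, prob = function(m, x) {
      attr(predict(m, x, probability = TRUE), "probabilities")[, "1"]
    }),
    mlp = list(fit = function(x, y, seed) {
      .mlpFit(x, as.numeric(as.character(y)), hidden = 100, seed = seed)
    }, prob = function(m, x) .mlpProb(m, x)),
    lr = list(fit = function(x, y, seed) {
      set.seed(seed)
      suppressWarnings(stats::glm.fit(cbind(1, x),
                                      as.numeric(as.character(y)),
                                      family = stats::binomial()))
    }, prob = function(m, x) {
      eta <- cbind(1, x) %*% ifelse(is.na(m$coefficients), 0,
                                    m$coefficients)
      1 / (1 + exp(-eta))
    }),
    knn = list(fit = function(x, y, seed) list(x = x, y = num01(y)),
               prob = function(m, x) {
      pr <- class::knn(m$x, x, m$y, k = 5, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "1", p, 1 - p)
    }),
    nb = list(fit = function(x, y, seed) {
      e1071::naiveBayes(x = data.frame(x), y = num01(y))
    }, prob = function(m, x) {
      predict(m, data.frame(x), type = "raw")[, "1"]
    }),
    gp = list(fit = function(x, y, seed) {
      set.seed(seed)
      m <- NULL
      utils::capture.output(
        m <- kernlab::gausspr(x = x, y = num01(y), prob.model = TRUE))
      m
    }, prob = function(m, x) kernlab::predict(m, x,
                                              type = "probabilities")[, "1"])
  )
}

# One-vs-rest multiclass prediction: one binary model per class, argmax of
# the positive-class probabilities.
.fitOVR <- function(x, y, algo, seed) {
  lv <- levels(y)
  models <- lapply(seq_along(lv), function(i) {
    y01 <- factor(as.integer(y == lv[i]), levels = c(0, 1))
    algo$fit(x, y01, seed + i)
  })
  list(models = models, levels = lv, algo = algo)
}

.predictOVR <- function(ovr, x) {
  probs <- vapply(ovr$models, function(m)
    as.numeric(ovr$algo$prob(m, x)), numeric(nrow(x)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  factor(ovr$levels[max.col(probs, ties.method = "first")],
         levels = ovr$levels)
}

.evalSet <- function(ovr, x, y) {
  pred <- .predictOVR(ovr, x)
  cm <- table(truth = y, pred = factor(pred, levels = levels(y)))
  confusionMetrics(cm)
}

#' Train the multiclass QSAR classifier bench
#'
#' Runs the one-vs-rest classifier bench on a fingerprint feature matrix:
#' stratified 80:20 split, feature selection, random oversampling to class
#' balance, k-fold cross-validation inside the training portion, and
#' held-out test evaluation, reporting accuracy, macro recall and
#' multiclass MCC for train / CV / test per algorithm.
#'
#' Two orders of operations are supported. In `"safe"` mode (default) the
#' split is made first; feature selection is fitted on the training portion
#' only and oversampling happens inside each training fold, so no test or
#' validation molecule is ever duplicated into a training set. In
#' `"published-parity"` mode oversampling and feature selection are applied to
#' the full data before splitting, reproducing the common (leakier)
#' pipeline order.
#'
#' @param x Binary feature matrix, rows named by molecule id.
#' @param labels Activity classes aligned with `x`.
#' @param algorithms Character subset of the bench (default all 12:
#'   dt, et, rf, gb, lgbm, xgb, svm, mlp, lr, knn, nb, gp).
#' @param mode `"safe"` or `"published-parity"`.
#' @param test_frac,folds,seed Split/CV/oversampling controls (defaults
#'   0.2, 10, 42).
#' @param var_min,corr_max Feature-selection thresholds.
#' @return `data.frame` (one row per algorithm): accuracy/recall/mcc for
#'   train, cv and test, plus `failed` flag. Attributes: `majority_baseline`
#'   (test accuracy of always predicting the most frequent training class),
#'   `n_features` (after selection), `split` sizes.
#' @export
trainBench <- function(x, labels,
                       algorithms = names(.benchAlgorithms()),
                       mode = c("safe", "published-parity"),
                       test_frac = 0.2, folds = 10, seed = 42,
                       var_min = 0.1, corr_max = 0.95) {
  mode <- match.arg(mode)
  registry <- .benchAlgorithms()
  stopifnot(all(algorithms %in% names(registry)))
  y <- factor(labels, levels = intersect(ACTIVITY_LEVELS,
                                         unique(as.character(labels))))
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y))

  if (mode == "published-parity") {
    ov <- oversampleIndices(y, seed = seed)
    x <- x[ov, , drop = FALSE]; y <- y[ov]
    x <- selectFeatures(x, var_min, corr_max)
    sp <- splitAndCV(y, test_frac, folds, seed)
  } else {
    sp <- splitAndCV(y, test_frac, folds, seed)
    xsel <- selectFeatures(x[sp$train, , drop = FALSE], var_min, corr_max)
    x <- x[, attr(xsel, "retained"), drop = FALSE]
  }
  xtr <- x[sp$train, , drop = FALSE]; ytr <- y[sp$train]
  xte <- x[sp$test, , drop = FALSE]; yte <- y[sp$test]

  balance <- function(xx, yy, s) {
    if (mode == "published-parity") return(list(x = xx, y = yy))
    ov <- oversampleIndices(yy, seed = s)
    list(x = xx[ov, , drop = FALSE], y = yy[ov])
  }

  rows <- list()
  for (nm in algorithms) {
    algo <- registry[[nm]]
    res <- tryCatch({
      full <- balance(xtr, ytr, seed)
      ovr <- .fitOVR(full$x, full$y, algo, seed)
      m_train <- .evalSet(ovr, full$x, full$y)
      cvm <- vapply(seq_len(folds), function(f) {
        hold <- sp$fold == f
        tr <- balance(xtr[!hold, , drop = FALSE], ytr[!hold], seed + f)
        ofit <- .fitOVR(tr$x, tr$y, algo, seed)
        .evalSet(ofit, xtr[hold, , drop = FALSE], ytr[hold])
      }, numeric(3))
      m_cv <- rowMeans(cvm)
      m_test <- .evalSet(ovr, xte, yte)
      data.frame(algorithm = nm,
                 accuracy_train = m_train[["accuracy"]],
                 accuracy_cv = m_cv[["accuracy"]],
                 accuracy_test = m_test[["accuracy"]],
                 recall_train = m_train[["recall"]],
                 recall_cv = m_cv[["recall"]],
                 recall_test = m_test[["recall"]],
                 mcc_train = m_train[["mcc"]],
                 mcc_cv = m_cv[["mcc"]],
                 mcc_test = m_test[["mcc"]],
                 failed = FALSE, stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("bench algorithm '", nm, "' failed: ", conditionMessage(e))
      data.frame(algorithm = nm, accuracy_train = NA_real_,
                 accuracy_cv = NA_real_, accuracy_test = NA_real_,
                 recall_train = NA_real_, recall_cv = NA_real_,
                 recall_test = NA_real_, mcc_train = NA_real_,
                 mcc_cv = NA_real_, mcc_test = NA_real_, failed = TRUE,
                 stringsAsFactors = FALSE)
    })
    rows[[nm]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "majority_baseline") <-
    mean(yte == names(which.max(table(ytr))))
  attr(out, "n_features") <- ncol(x)
  attr(out, "split") <- c(train = length(sp$train), test = length(sp$test))
  out
}

#' QSAR bench on a curated set
#'
#' Convenience wrapper: fingerprints the curated molecules
#' ([moleculeFingerprints()]), then runs [trainBench()] on the binary
#' feature matrix with the molecules' activity classes.
#'
#' @param curated A [CuratedSet-class].
#' @param kind Fingerprint kind (default `"pubchem"`).
#' @param ... Passed to [trainBench()].
#' @return See [trainBench()].
#' @export
qsarBench <- function(curated, kind = "pubchem", ...) {
  stopifnot(is(curated, "CuratedSet"))
  m <- molecules(curated)
  fp <- moleculeFingerprints(m$smiles, kind, ids = m$molecule_id)
  fp <- fp[m$molecule_id, , drop = FALSE]
  trainBench(fp, m$activity_class, ...)
}
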