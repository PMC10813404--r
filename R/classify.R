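## ---- K-nearest-neighbor core (brute force) ------------------------------

## Pairwise distances between query rows and training rows.
knnDistances <- function(query, train, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  q <- as.matrix(query); tr <- as.matrix(train)
  if (metric == "euclidean") {
    d2 <- outer(rowSums(q^2), rowSums(tr^2), "+") - 2 * tcrossprod(q, tr)
    sqrt(pmax(d2, 0))
  } else {
    qn <- sqrt(rowSums(q^2)); tn <- sqrt(rowSums(tr^2))
    qn[qn == 0] <- 1; tn[tn == 0] <- 1
    1 - tcrossprod(q / qn, tr / tn)
  }
}

#' Brute-force KNN prediction
#'
#' Majority (optionally inverse-distance-weighted) vote among the k nearest
#' training points. Ties break toward the smaller class index for
#' reproducibility.
#'
#' @param train numeric matrix of training features.
#' @param labels training labels (character or factor).
#' @param query numeric matrix of query features.
#' @param k neighbors; clipped to the training size with a warning.
#' @param metric `"euclidean"` or `"cosine"`.
#' @param weighted inverse-distance vote weighting.
#' @return character vector of predicted labels.
#' @export
knnPredict <- function(train, labels, query, k = 10L,
                       metric = "euclidean", weighted = FALSE) {
  labels <- as.character(labels)
  n <- nrow(train)
  if (k > n) {
    warning(sprintf("k = %d clipped to the training size %d", k, n))
    k <- n
  }
  D <- knnDistances(query, train, metric)
  classes <- sort(unique(labels))
  out <- character(nrow(query))
  for (i in seq_len(nrow(query))) {
    ord <- order(D[i, ], seq_len(n))[seq_len(k)]
    wts <- if (weighted) 1 / pmax(D[i, ord], 1e-12) else rep(1, k)
    votes <- vapply(classes, function(cl)
      sum(wts[labels[ord] == cl]), numeric(1))
    out[i] <- classes[which.max(votes)]
  }
  out
}

## ---- classifier variant specs -------------------------------------------

#' SVM variant specifications
#'
#' The six kernel variants used for HR grading comparisons: polynomial
#' degrees 1/2/3 (linear, quadratic, cubic; kernel `(x.z + 1)^degree`) and
#' Gaussian kernels with bandwidth gamma scaled fine > medium > coarse
#' (`4/d`, `1/d`, `0.25/d` with `d = 24` features), so that for a distant
#' point pair the fine kernel value is the smallest.
#'
#' @param kind one of `"linear"`, `"quadratic"`, `"cubic"`,
#'   `"fine_gaussian"`, `"medium_gaussian"`, `"coarse_gaussian"`.
#' @param d feature dimension used in the gamma scaling (default 24).
#' @return model spec list consumed by [fitClassifier()] and [kfoldCV()].
#' @export
svmVariant <- function(kind = c("linear", "quadratic", "cubic",
                                "fine_gaussian", "medium_gaussian",
                                "coarse_gaussian"), d = 24) {
  kind <- match.arg(kind)
  spec <- switch(kind,
    linear = list(kernel = "polynomial", degree = 1, gamma = 1, coef0 = 1),
    quadratic = list(kernel = "polynomial", degree = 2, gamma = 1, coef0 = 1),
    cubic = list(kernel = "polynomial", degree = 3, gamma = 1, coef0 = 1),
    fine_gaussian = list(kernel = "radial", gamma = 4 / d),
    medium_gaussian = list(kernel = "radial", gamma = 1 / d),
    coarse_gaussian = list(kernel = "radial", gamma = 0.25 / d))
  structure(c(list(type = "svm", kind = kind), spec),
            class = "classifierSpec")
}

#' KNN variant specifications
#'
#' Fine (k = 1), medium (k = 10) and coarse (k = 100) Euclidean KNN, cosine
#' KNN (k = 10) and inverse-distance-weighted KNN (k = 10). For the coarse
#' variant, k is clipped to the training size with a warning when fewer
#' than 100 points are available.
#'
#' @param kind one of `"fine"`, `"medium"`, `"coarse"`, `"cosine"`,
#'   `"weighted"`.
#' @return model spec list consumed by [fitClassifier()] and [kfoldCV()].
#' @export
knnVariant <- function(kind = c("fine", "medium", "coarse", "cosine",
                                "weighted")) {
  kind <- match.arg(kind)
  spec <- switch(kind,
    fine = list(k = 1L, metric = "euclidean", weighted = FALSE),
    medium = list(k = 10L, metric = "euclidean", weighted = FALSE),
    coarse = list(k = 100L, metric = "euclidean", weighted = FALSE),
    cosine = list(k = 10L, metric = "cosine", weighted = FALSE),
    weighted = list(k = 10L, metric = "euclidean", weighted = TRUE))
  structure(c(list(type = "knn", kind = kind), spec),
            class = "classifierSpec")
}

#' Spec for the boosted classifiers
#'
#' @param type `"improved_svm"` or `"improved_knn"`.
#' @param ... passed through to the trainer ([trainImprovedSVM()] /
#'   [trainImprovedKNN()]).
#' @return model spec list.
#' @export
improvedVariant <- function(type = c("improved_svm", "improved_knn"), ...) {
  type <- match.arg(type)
  structure(list(type = type, args = list(...)), class = "classifierSpec")
}

#' Fit a classifier from a spec
#'
#' @param spec a `classifierSpec` from [svmVariant()], [knnVariant()] or
#'   [improvedVariant()].
#' @param x numeric feature matrix.
#' @param y labels.
#' @param seed integer seed for the stochastic trainers.
#' @return fitted model object (class depends on the spec).
#' @export
fitClassifier <- function(spec, x, y, seed = 1L) {
  x <- as.matrix(x); y <- as.character(y)
  switch(spec$type,
    svm = {
      args <- spec[setdiff(names(spec), c("type", "kind"))]
      fit <- do.call(e1071::svm,
                     c(list(x = x, y = factor(y), scale = FALSE), args))
      structure(list(fit = fit, spec = spec), class = "fittedSVM")
    },
    knn = {
      structure(list(train = x, labels = y, spec = spec),
                class = "fittedKNN")
    },
    improved_svm = do.call(trainImprovedSVM,
                           c(list(x = x, y = y, seed = seed), spec$args)),
    improved_knn = do.call(trainImprovedKNN,
                           c(list(x = x, y = y, seed = seed), spec$args)),
    stop(sprintf("unknown classifier type '%s'", spec$type)))
}

#' Predict from a fitted classifier
#'
#' @param model object from [fitClassifier()].
#' @param x numeric feature matrix.
#' @return character vector of predictions.
#' @export
predictClassifier <- function(model, x) {
  x <- as.matrix(x)
  if (inherits(model, "fittedSVM"))
    return(as.character(predict(model$fit, x)))
  if (inherits(model, "fittedKNN")) {
    sp <- model$spec
    k <- sp$k
    if (k > nrow(model$train)) k <- nrow(model$train)
    return(knnPredict(model$train, model$labels, x, k = k,
                      metric = sp$metric, weighted = sp$weighted))
  }
  if (is(model, "ImprovedSVM")) return(predictImprovedSVM(model, x))
  if (is(model, "ImprovedKNN")) return(predictImprovedKNN(model, x))
  stop("unknown model object")
}

## ---- improved (boosted) SVM ---------------------------------------------

## Weighted one-vs-rest linear hinge scorers by full-batch subgradient
## descent with L2 regularization.
fitLinearOVR <- function(x, y, classes, sampleWeights, C = 1,
                         iters = 150L, lr = 0.1) {
  n <- nrow(x); d <- ncol(x)
  W <- matrix(0, length(classes), d + 1L)
  xa <- cbind(x, 1)
  lambda <- 1 / (C * n)
  for (ci in seq_along(classes)) {
    t <- ifelse(y == classes[ci], 1, -1)
    w <- numeric(d + 1L)
    for (it in seq_len(iters)) {
      marg <- t * (xa %*% w)
      active <- marg < 1
      gw <- lambda * c(w[seq_len(d)], 0) -
        colSums(xa[active, , drop = FALSE] *
                  (sampleWeights[active] * t[active]))
      w <- w - (lr / sqrt(it)) * gw
    }
    W[ci, ] <- w
  }
  W
}

svmScores <- function(W, x) cbind(x, 1) %*% t(W)

#' Train the improved (boosted) SVM
#'
#' Iterative scheme over `n_rounds`: each round fits one-vs-rest linear
#' hinge-loss scorers on the current sample weights, evaluates the
#' per-sample multiclass hinge loss, and up-weights samples with positive
#' loss (weight proportional to `exp(min(loss, 2))`, renormalized to sum
#' 1). Round weights follow the weighted training error
#' (`log((1-err)/err) + log(K-1)`, floored at a small positive value) and
#' the final score is the round-weight-averaged score vector. With
#' `n_rounds = 1` this reduces to a plain one-vs-rest linear SVM.
#'
#' @param x numeric feature matrix (24 columns for HR descriptors).
#' @param y labels, at least two classes, no missing feature values.
#' @param n_rounds boosting rounds, at least 1.
#' @param C regularization parameter of the hinge fit.
#' @param seed integer seed.
#' @return an [ImprovedSVM-class].
#' @export
trainImprovedSVM <- function(x, y, n_rounds = 5L, C = 1, seed = 1L) {
  x <- as.matrix(x); y <- as.character(y)
  if (any(!is.finite(x))) stop("features contain missing or infinite values")
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("at least two classes required")
  if (n_rounds < 1) stop("n_rounds must be at least 1")
  n <- nrow(x); K <- length(classes)
  wts <- rep(1 / n, n)
  rounds <- vector("list", n_rounds)
  withSeed(seed, {
    for (r in seq_len(n_rounds)) {
      W <- fitLinearOVR(x, y, classes, wts, C = C)
      sc <- svmScores(W, x)
      pred <- classes[max.col(sc, ties.method = "first")]
      err <- sum(wts * (pred != y))
      alpha <- log((1 - err + 1e-10) / (err + 1e-10)) + log(K - 1)
      alpha <- max(alpha, 1e-3)
      rounds[[r]] <- list(W = W, alpha = alpha, err = err)
      yi <- match(y, classes)
      strue <- sc[cbind(seq_len(n), yi)]
      sc2 <- sc; sc2[cbind(seq_len(n), yi)] <- -Inf
      loss <- pmax(0, 1 + apply(sc2, 1, max) - strue)
      wts <- wts * exp(pmin(loss, 2))
      wts <- wts / sum(wts)
    }
  })
  new("ImprovedSVM", rounds = rounds, classes = classes,
      featureNames = colnames(x) %||% paste0("f", seq_len(ncol(x))),
      finalSampleWeights = wts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

predictImprovedSVM <- function(model, x) {
  x <- as.matrix(x)
  alphas <- vapply(model@rounds, `[[`, numeric(1), "alpha")
  total <- 0
  for (r in seq_along(model@rounds))
    total <- total + alphas[r] * svmScores(model@rounds[[r]]$W, x)
  model@classes[max.col(total / sum(alphas), ties.method = "first")]
}

## ---- improved (boosted) KNN ---------------------------------------------

#' Train the improved (boosted) KNN ensemble
#'
#' Boosting-by-resampling over weak KNN learners: each learner sees a
#' weighted bootstrap of the training set, a random feature subset (half
#' of the features, at least 2) and a random k from \{1, 3, 5\}.
#' Per round, the weighted training error determines the learner's vote
#' weight and misclassified samples are up-weighted. The weak learner with
#' the lowest weighted training error is recorded as the best; the ensemble
#' predicts by the alpha-weighted vote. The variance of the per-learner
#' weighted errors is logged as `training_variance`.
#'
#' @param x numeric feature matrix.
#' @param y labels, at least two classes.
#' @param n_learners weak learners, at least 1.
#' @param seed integer seed.
#' @return an [ImprovedKNN-class].
#' @export
trainImprovedKNN <- function(x, y, n_learners = 10L, seed = 1L) {
  x <- as.matrix(x); y <- as.character(y)
  if (n_learners < 1) stop("n_learners must be at least 1")
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("at least two classes required")
  n <- nrow(x); d <- ncol(x); K <- length(classes)
  wts <- rep(1 / n, n)
  learners <- vector("list", n_learners)
  withSeed(seed, {
    for (r in seq_len(n_learners)) {
      feats <- sort(sample.int(d, max(2L, floor(d / 2))))
      k <- sample(c(1L, 3L, 5L), 1L)
      idx <- sample.int(n, n, replace = TRUE, prob = wts)
      pred <- knnPredict(x[idx, feats, drop = FALSE], y[idx],
                         x[, feats, drop = FALSE], k = k)
      err <- sum(wts * (pred != y))
      alpha <- max(log((1 - err + 1e-10) / (err + 1e-10)) + log(K - 1),
                   1e-3)
      learners[[r]] <- list(features = feats, k = k, idx = idx,
                            alpha = alpha, err = err)
      wts <- wts * exp(alpha * (pred != y))
      wts <- wts / sum(wts)
    }
  })
  errs <- vapply(learners, `[[`, numeric(1), "err")
  obj <- new("ImprovedKNN", learners = learners, classes = classes,
             best = which.min(errs), trainX = x, trainY = y)
  attr(obj, "training_variance") <- var(errs)
  obj
}

predictImprovedKNN <- function(model, x) {
  x <- as.matrix(x)
  classes <- model@classes
  votes <- matrix(0, nrow(x), length(classes))
  for (L in model@learners) {
    pred <- knnPredict(model@trainX[L$idx, L$features, drop = FALSE],
                       model@trainY[L$idx],
                       x[, L$features, drop = FALSE], k = L$k)
    votes <- votes + L$alpha * outer(pred, classes, "==")
  }
  classes[max.col(votes, ties.method = "first")]
}

## Predictions of a single weak learner (used in tests and diagnostics).
predictWeakKNN <- function(model, which, x) {
  L <- model@learners[[which]]
  knnPredict(model@trainX[L$idx, L$features, drop = FALSE],
             model@trainY[L$idx],
             as.matrix(x)[, L$features, drop = FALSE], k = L$k)
}

## ---- cross-validation and splitting -------------------------------------

## Stratified fold assignment; falls back to plain folds with a warning
## when a class has fewer than k members.
stratifiedFolds <- function(y, k, seed = 1L) {
  y <- as.character(y)
  n <- length(y)
  withSeed(seed, {
    counts <- table(y)
    fold <- integer(n)
    if (any(counts < k)) {
      warning("a class has fewer members than folds; non-stratified folds used")
      fold <- sample(rep_len(seq_len(k), n))
    } else {
      for (cl in names(counts)) {
        idx <- sample(which(y == cl))
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    }
    lapply(seq_len(k), function(f) which(fold == f))
  })
}

#' k-fold cross-validation
#'
#' Stratified k-fold cross-validation of a classifier spec: each fold is
#' used exactly once as the test set, per-fold one-vs-rest confusion counts
#' are recorded and the aggregate is the mean of the per-fold macro
#' metrics.
#'
#' @param x feature matrix or data.frame of features.
#' @param y labels.
#' @param k folds, at least 2 and at most `length(y)`.
#' @param spec a `classifierSpec` (see [svmVariant()], [knnVariant()],
#'   [improvedVariant()]).
#' @param seed integer seed (fold assignment and trainers).
#' @return a [CVResult-class].
#' @export
kfoldCV <- function(x, y, k = 10L, spec = improvedVariant("improved_svm"),
                    seed = 1L) {
  x <- as.matrix(x); y <- as.character(y)
  n <- length(y)
  if (k < 2 || k > n) stop("k must lie in [2, n]")
  folds <- stratifiedFolds(y, k, seed)
  perFold <- vector("list", k)
  mets <- data.frame(accuracy = numeric(k), precision = numeric(k),
                     recall = numeric(k), f1 = numeric(k))
  classes <- sort(unique(y))
  for (f in seq_len(k)) {
    te <- folds[[f]]; tr <- setdiff(seq_len(n), te)
    model <- fitClassifier(spec, x[tr, , drop = FALSE], y[tr],
                           seed = seed + f)
    pred <- predictClassifier(model, x[te, , drop = FALSE])
    cc <- confusionCounts(pred, y[te], classes)
    perFold[[f]] <- cc
    ms <- metricSuite(cc)
    mets[f, ] <- c(ms$accuracy, ms$macro["precision"], ms$macro["recall"],
                   ms$macro["f1"])
  }
  new("CVResult", k = as.integer(k), folds = folds, perFold = perFold,
      metrics = mets, aggregate = colMeans(mets), seed = as.integer(seed))
}

#' Stratified 80:20 train/test split
#'
#' Per class, the test share is `round(0.2 * n_class)` with the remainder
#' going to training; applied to the reference class distribution
#' (200/400/200/200/200) this yields 960 training and 240 test images.
#'
#' @param y labels, length at least 5.
#' @param seed integer seed.
#' @return list with integer vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
splitTrainTest <- function(y, seed = 1L) {
  y <- as.character(y)
  if (length(y) < 5) stop("need at least 5 observations")
  counts <- table(y)
  if (any(counts == 0)) stop("empty class")
  withSeed(seed, {
    test <- integer(0)
    for (cl in names(counts)) {
      idx <- which(y == cl)
      nTest <- round(0.2 * length(idx))
      if (nTest > 0) test <- c(test, sample(idx, nTest))
    }
    test <- sort(test)
    list(train = setdiff(seq_along(y), test), test = test)
  })
}
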