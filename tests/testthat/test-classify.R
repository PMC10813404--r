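twoClassTable <- function(seed = 1, n = 100, shift = 10) {
  tab <- generateFeatureTable(seed = seed, n_per_class = n,
                              class_shift = shift)
  tab <- tab[tab$grade %in% c("normal", "severe"), ]
  list(x = as.matrix(tab[, 1:24]), y = as.character(tab$grade))
}

test_that("improved SVM separates a wide-margin 2-class set in one round", {
  d <- twoClassTable(seed = 1, n = 50, shift = 10)
  m <- trainImprovedSVM(d$x, d$y, n_rounds = 1, seed = 1)
  expect_equal(mean(predictClassifier(m, d$x) == d$y), 1.0)
})

test_that("boosting bookkeeping: weights renormalize, rounds recorded", {
  d <- twoClassTable(seed = 2, n = 30, shift = 3)
  m <- trainImprovedSVM(d$x, d$y, n_rounds = 4, seed = 1)
  expect_equal(length(m@rounds), 4)
  expect_equal(sum(m@finalSampleWeights), 1, tolerance = 1e-12)
  expect_true(all(m@finalSampleWeights > 0))
  expect_true(all(vapply(m@rounds, `[[`, numeric(1), "alpha") > 0))
  expect_equal(ncol(m@rounds[[1]]$W), 25)    # 24 features + intercept
})

test_that("one-round improved SVM equals its plain one-vs-rest fit", {
  d <- twoClassTable(seed = 3, n = 40, shift = 4)
  m <- trainImprovedSVM(d$x, d$y, n_rounds = 1, seed = 9)
  W <- fundusHR:::fitLinearOVR(d$x, d$y, sort(unique(d$y)),
                               rep(1 / nrow(d$x), nrow(d$x)), C = 1)
  plainPred <- sort(unique(d$y))[max.col(fundusHR:::svmScores(W, d$x),
                                         ties.method = "first")]
  expect_identical(predictClassifier(m, d$x), plainPred)
})

test_that("improved SVM input validation", {
  d <- twoClassTable(seed = 1, n = 10, shift = 1)
  expect_error(trainImprovedSVM(d$x, rep("a", nrow(d$x))), "two classes")
  xb <- d$x; xb[1, 1] <- NA
  expect_error(trainImprovedSVM(xb, d$y), "missing")
  expect_error(trainImprovedSVM(d$x, d$y, n_rounds = 0), "at least 1")
})

test_that("improved KNN: ensemble at least matches its best weak learner", {
  d <- twoClassTable(seed = 4, n = 50, shift = 8)
  m <- trainImprovedKNN(d$x, d$y, n_learners = 7, seed = 2)
  accEns <- mean(predictClassifier(m, d$x) == d$y)
  accBest <- mean(fundusHR:::predictWeakKNN(m, m@best, d$x) == d$y)
  expect_gte(accEns, accBest)
  errs <- vapply(m@learners, `[[`, numeric(1), "err")
  expect_equal(m@learners[[m@best]]$err, min(errs))
  expect_true(is.finite(attr(m, "training_variance")))
})

test_that("a single weak learner is the ensemble", {
  d <- twoClassTable(seed = 5, n = 30, shift = 5)
  m <- trainImprovedKNN(d$x, d$y, n_learners = 1, seed = 3)
  expect_identical(predictClassifier(m, d$x),
                   fundusHR:::predictWeakKNN(m, 1L, d$x))
  expect_error(trainImprovedKNN(d$x, d$y, n_learners = 0), "at least 1")
})

test_that("boosted trainers are deterministic under a fixed seed", {
  d <- twoClassTable(seed = 6, n = 30, shift = 4)
  a <- trainImprovedKNN(d$x, d$y, n_learners = 5, seed = 11)
  b <- trainImprovedKNN(d$x, d$y, n_learners = 5, seed = 11)
  expect_identical(a@learners, b@learners)
  sa <- trainImprovedSVM(d$x, d$y, n_rounds = 3, seed = 11)
  sb <- trainImprovedSVM(d$x, d$y, n_rounds = 3, seed = 11)
  expect_identical(sa@rounds, sb@rounds)
})

test_that("SVM kernel variants encode the stated kernels", {
  expect_error(svmVariant("sigmoid"))
  q <- svmVariant("quadratic")
  x <- c(1, 2); z <- c(0.5, -1)
  kq <- (q$gamma * sum(x * z) + q$coef0)^q$degree
  expect_equal(kq, (sum(x * z) + 1)^2)
  ## fine vs coarse Gaussian on a distant pair
  f <- svmVariant("fine_gaussian"); cg <- svmVariant("coarse_gaussian")
  expect_gt(f$gamma, svmVariant("medium_gaussian")$gamma)
  d2 <- 50
  expect_lte(exp(-f$gamma * d2), exp(-cg$gamma * d2))
  ## every variant trains and predicts on the synthetic table
  d <- twoClassTable(seed = 7, n = 25, shift = 6)
  for (kind in c("linear", "quadratic", "cubic", "fine_gaussian",
                 "medium_gaussian", "coarse_gaussian")) {
    m <- fitClassifier(svmVariant(kind), d$x, d$y)
    p <- predictClassifier(m, d$x)
    expect_equal(length(p), nrow(d$x))
    expect_true(all(p %in% d$y))
  }
})

test_that("KNN variants: fine memorizes, cosine is scale invariant", {
  d <- twoClassTable(seed = 8, n = 25, shift = 2)
  fine <- fitClassifier(knnVariant("fine"), d$x, d$y)
  expect_equal(mean(predictClassifier(fine, d$x) == d$y), 1.0)
  cos <- fitClassifier(knnVariant("cosine"), abs(d$x) + 1, d$y)
  p1 <- predictClassifier(cos, abs(d$x) + 1)
  cos2 <- fitClassifier(knnVariant("cosine"), 3 * (abs(d$x) + 1), d$y)
  p2 <- predictClassifier(cos2, 7 * (abs(d$x) + 1))
  expect_identical(p1, p2)
  expect_error(knnVariant("mystery"))
})

test_that("coarse KNN matches the brute-force 100-neighbor majority oracle", {
  set.seed(10)
  x <- matrix(rnorm(150 * 4), 150, 4)
  y <- ifelse(x[, 1] + rnorm(150, sd = 2) > 0, "pos", "neg")
  q <- matrix(rnorm(20 * 4), 20, 4)
  got <- knnPredict(x, y, q, k = 100)
  expect_identical(got, oracleKnn(x, y, q, 100))
  ## k clipping warns
  expect_warning(knnPredict(x[1:50, ], y[1:50], q, k = 100), "clipped")
})

test_that("weighted KNN votes by inverse distance", {
  train <- matrix(c(0, 0, 1, 1, 1.1, 1.1), 3, 2, byrow = TRUE)
  y <- c("a", "b", "b")
  ## query near 'a' but with two 'b' further away: unweighted k=3 says b,
  ## inverse-distance weighting keeps a
  q <- matrix(c(0.05, 0.05), 1, 2)
  expect_identical(knnPredict(train, y, q, k = 3, weighted = TRUE), "a")
  expect_identical(knnPredict(train, y, q, k = 3, weighted = FALSE), "b")
})

test_that("stratified folds partition the data for k in 2, 5, 10", {
  set.seed(12)
  y <- sample(rep(hrGrades(), each = 20))
  for (k in c(2, 5, 10)) {
    folds <- fundusHR:::stratifiedFolds(y, k, seed = 1)
    idx <- sort(unlist(folds))
    expect_identical(idx, seq_along(y))
    expect_equal(length(folds), k)
    sizes <- lengths(folds)
    expect_lte(max(sizes) - min(sizes), length(unique(y)))
  }
})

test_that("leave-one-out cross-validation gives singleton disjoint folds", {
  d <- twoClassTable(seed = 13, n = 5, shift = 10)
  expect_warning(cv <- kfoldCV(d$x, d$y, k = 10, spec = knnVariant("fine"),
                               seed = 1), "fewer")
  expect_equal(cv@k, 10L)
  expect_true(all(lengths(cvFolds(cv)) == 1))
  expect_identical(sort(unlist(cvFolds(cv))), 1:10)
})

test_that("a perfect classifier scores aggregate accuracy 1 for any k", {
  d <- twoClassTable(seed = 14, n = 30, shift = 12)
  for (k in c(2, 5)) {
    cv <- kfoldCV(d$x, d$y, k = k, spec = knnVariant("fine"), seed = 2)
    expect_equal(unname(cvAggregate(cv)[["accuracy"]]), 1.0)
  }
  expect_error(kfoldCV(d$x, d$y, k = 1), "k must lie")
})

test_that("five- and ten-fold CV agree on a well-separated table", {
  tab <- generateFeatureTable(seed = 15, n_per_class = 40, class_shift = 6)
  x <- as.matrix(tab[, 1:24]); y <- as.character(tab$grade)
  spec <- improvedVariant("improved_svm", n_rounds = 2)
  cv10 <- kfoldCV(x, y, k = 10, spec = spec, seed = 3)
  cv5 <- kfoldCV(x, y, k = 5, spec = spec, seed = 3)
  a10 <- unname(cvAggregate(cv10)[["accuracy"]])
  a5 <- unname(cvAggregate(cv5)[["accuracy"]])
  expect_gte(a10, 0.95)
  expect_gte(a5, 0.95)
  expect_lt(abs(a10 - a5), 0.05)
})

test_that("stratified 80:20 split reproduces the study's class arithmetic", {
  y <- rep(hrGrades(), c(200, 400, 200, 200, 200))
  sp <- splitTrainTest(y, seed = 1)
  expect_equal(length(sp$train), 960)
  expect_equal(length(sp$test), 240)
  expect_identical(sort(c(sp$train, sp$test)), seq_along(y))
  expect_equal(length(intersect(sp$train, sp$test)), 0)
  ## per-class 80:20
  expect_equal(as.vector(table(y[sp$test])),
               as.vector(round(0.2 * table(y))))
  ## single class of ten: 8/2
  sp2 <- splitTrainTest(rep("normal", 10), seed = 2)
  expect_equal(length(sp2$train), 8)
  expect_equal(length(sp2$test), 2)
  expect_error(splitTrainTest(c("a", "b")), "at least 5")
})
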