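# Pair enumeration, the L1 squared-hinge SVM, ranking metrics and
# cross-validation plumbing.

toy_xy <- function(seed = 1, n = 40, d = 6) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  y <- ifelse(X[, 1] + 0.5 * X[, 2] > 0, 1, -1)
  list(X = X, y = y)
}

test_that("ordered-pair counting follows n(n-1)", {
  expect_equal(countOrderedPairs(2), 2)
  expect_equal(countOrderedPairs(6922), 47907162)
})

test_that("candidate enumeration labels positives and excludes them from negatives", {
  ids <- c("a", "b", "c")
  pos <- data.frame(id1 = c("a", "b"), id2 = c("b", "a"))
  pairs <- enumerateCandidatePairs(ids, pos)
  expect_equal(nrow(pairs), 6L)
  expect_equal(sum(pairs$label == 1L), 2L)
  key <- paste(pairs$id1, pairs$id2)
  expect_false(any(duplicated(key)))
  expect_true(all(pairs$label[key %in% c("a b", "b a")] == 1L))
  # two compounds -> two ordered pairs
  expect_equal(nrow(enumerateCandidatePairs(c("x", "y"), pos[0, ])), 2L)
  expect_error(enumerateCandidatePairs(ids, data.frame(id1 = "a", id2 = "zz")),
               "unknown compound")
  sub <- enumerateCandidatePairs(ids, pos, negRatio = 1, seed = 3)
  expect_equal(sum(sub$label == -1L), 2L)
  expect_equal(sum(sub$label == 1L), 2L)
})

test_that("a separable toy problem is fit to training accuracy 1", {
  d <- toy_xy()
  m <- trainLinearSvm(d$X, d$y, C = 10)
  expect_equal(sign(scorePairs(m, d$X)), d$y)
  expect_error(trainLinearSvm(d$X, rep(1, nrow(d$X))), "both classes")
})

test_that("training loss is non-increasing in C", {
  d <- toy_xy(2)
  loss_at <- function(C) {
    m <- trainLinearSvm(d$X, d$y, C = C, maxit = 4000)
    sum(pmax(0, 1 - d$y * scorePairs(m, d$X))^2)
  }
  losses <- vapply(c(0.01, 0.1, 1, 10), loss_at, numeric(1))
  expect_false(is.unsorted(rev(losses)))
})

test_that("duplicated feature columns share the single-column model score", {
  d <- toy_xy(3, n = 30, d = 3)
  X1 <- d$X
  X2 <- cbind(d$X, d$X[, 1])  # duplicate the first column
  m1 <- trainLinearSvm(X1, d$y, C = 1, maxit = 8000, tol = 1e-12)
  m2 <- trainLinearSvm(X2, d$y, C = 1, maxit = 8000, tol = 1e-12)
  s1 <- scorePairs(m1, X1)
  w2 <- modelWeights(m2)
  s2 <- as.numeric(X1 %*% c(w2[1] + w2[4], w2[2:3])) + modelBias(m2)
  expect_equal(s2, s1, tolerance = 1e-4)
})

test_that("training is deterministic", {
  d <- toy_xy(4)
  m1 <- trainLinearSvm(d$X, d$y, C = 1)
  m2 <- trainLinearSvm(d$X, d$y, C = 1)
  expect_identical(modelWeights(m1), modelWeights(m2))
  expect_identical(modelBias(m1), modelBias(m2))
})

test_that("scoring honors the bias and rejects mismatched spaces", {
  m <- new("SvmModel", w = numeric(3), bias = 0.7, cost = 1,
           penalty = "l1", mode = "diff-common")
  X <- matrix(rnorm(6), 2, 3)
  expect_equal(scorePairs(m, X), c(0.7, 0.7))
  expect_error(scorePairs(m, matrix(0, 2, 4)), "feature-space mismatch")
})

test_that("diff-common scores of identical compounds use only the common block", {
  space <- new("FeatureSpace", keys = paste0("ATOM:", letters[1:3]),
               cap = NA_integer_)
  a <- mk_desc(c(a = 2, b = 1))
  v <- pairFeatures(a, a, "diff-common", space)
  expect_equal(unname(v[4:9]), rep(0, 6))
  w <- stats::setNames(rnorm(9), names(v))
  expect_equal(sum(w * v), sum(w[1:3] * v[1:3]))
})

test_that("trapezoidal AUC equals the Mann-Whitney statistic", {
  set.seed(5)
  for (i in 1:25) {
    n <- sample(10:40, 1)
    scores <- sample(seq(0, 1, 0.05), n, TRUE)  # plenty of ties
    labels <- sample(c(-1, 1), n, TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(aucROC(scores, labels), mw_auc(scores, labels),
                 tolerance = 1e-10)
  }
  expect_error(aucROC(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  scores <- c(rnorm(40, 1), rnorm(60))
  labels <- rep(c(1, -1), c(40, 60))
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<", levels = c(-1, 1))))
  expect_equal(aucROC(scores, labels), ref, tolerance = 1e-12)
})

test_that("AUPR is 1 for a perfect ranking and near prevalence for random", {
  scores <- c(5, 4, 3, 2, 1)
  labels <- c(1, 1, -1, -1, -1)
  expect_equal(auPR(scores, labels), 1.0)
  expect_equal(aucROC(scores, labels), 1.0)
  set.seed(8)
  s <- runif(2000); l <- rep(c(1, -1), c(200, 1800))
  expect_lt(abs(auPR(s, l) - 0.1), 0.03)
})

test_that("cross-validation assigns every pair to exactly one test fold", {
  suppressWarnings({
    bm <- syntheticReactionPairs(seed = 11, nPairs = 20)
    pairs <- enumerateCandidatePairs(names(bm$compounds), bm$positives,
                                     negRatio = 5, seed = 11)
    cv <- crossValidate(pairs, bm$descriptors, mode = "diff-only",
                        folds = 4, Cgrid = 1, seed = 11)
  })
  expect_equal(sort(unique(cv$fold)), 1:4)
  expect_length(cv$fold, nrow(pairs))
  expect_gt(cv$auc, 0.5)
  # a fold without positives is an error
  tiny <- pairs[c(which(pairs$label == 1L)[1:2], which(pairs$label == -1L)[1:10]), ]
  expect_error(crossValidate(tiny, bm$descriptors, folds = 5, seed = 1),
               "no positive")
})

test_that("L1 models are sparser than L2 models at matched C", {
  suppressWarnings({
    bm <- syntheticReactionPairs(seed = 11, nPairs = 20)
    pairs <- enumerateCandidatePairs(names(bm$compounds), bm$positives,
                                     negRatio = 5, seed = 11)
    space <- featureSpace(bm$descriptors)
    X <- pairFeatureMatrix(pairs, bm$descriptors, "diff-common", space)
  })
  m_l1 <- trainLinearSvm(X, pairs$label, C = 1, penalty = "l1", maxit = 4000)
  m_l2 <- trainLinearSvm(X, pairs$label, C = 1, penalty = "l2", maxit = 4000)
  expect_lt(sum(modelWeights(m_l1) != 0), sum(modelWeights(m_l2) != 0))
})

test_that("the baseline score is the pair's weighted Jaccard", {
  descs <- list(a = fixture_desc("ethanol"), b = fixture_desc("ethanol"),
                c = fixture_desc("benzene"))
  pairs <- data.frame(id1 = c("a", "a"), id2 = c("b", "c"))
  s <- baselineScore(pairs, descs)
  expect_equal(s[1], 1.0)
  expect_equal(s[2], weightedJaccard(descs$a, descs$c))
  disjoint <- baselineScore(data.frame(id1 = "a", id2 = "b"),
                            list(a = mk_desc(c(x = 1)), b = mk_desc(c(y = 1))))
  expect_equal(disjoint, 0.0)
})
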