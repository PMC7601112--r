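# well-separated 6-class Gaussian clusters for recovery checks
separable_samples <- function(n_per_class = 20, d = 5, gap = 10, sd = 0.5,
                              seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(0:5, function(cl)
    matrix(rnorm(n_per_class * d, mean = gap * cl, sd = sd), n_per_class, d)))
  list(x = x, y = factor(rep(EMOTIONS, each = n_per_class)))
}

test_that("cityblock distance: worked example, identity, permutation symmetry", {
  expect_equal(cityblock_distance(c(1, 2), c(4, 6)), 7)
  expect_equal(cityblock_distance(c(3, -1, 2), c(3, -1, 2)), 0)
  a <- c(1, 5, 2, 8); b <- c(0, 3, 9, 1); p <- c(3, 1, 4, 2)
  expect_equal(cityblock_distance(a[p], b[p]), cityblock_distance(a, b))
  expect_error(cityblock_distance(1:3, 1:4), "length")
})

test_that("KNN: exact match, majority vote, and the nearest-neighbour tie rule", {
  x <- rbind(c(0, 0), c(1, 0), c(5, 5), c(5, 6))
  y <- c("A", "A", "B", "B")
  expect_equal(as.character(knn_predict(x, y, c(5, 5), k = 1)), "B")

  # k = 3 with nearest labels (A, A, B) -> A
  expect_equal(as.character(knn_predict(x, y, c(1, 1), k = 3)), "A")

  # k = 2 tie (one A at d = 1, one B at d = 2) -> nearest neighbour's label
  x2 <- rbind(c(1, 0), c(2, 0))
  expect_equal(as.character(knn_predict(x2, c("A", "B"), c(0, 0), k = 2)),
               "A")
  expect_equal(as.character(knn_predict(x2, c("B", "A"), c(3, 0), k = 2)),
               "A")

  expect_error(knn_predict(x[0, , drop = FALSE], character(0), c(0, 0)),
               "empty")
  expect_error(knn_predict(x, y, c(0, 0), k = 9), "k must be")
})

test_that("KNN with k = 1 resubstitutes perfectly on conflict-free training data", {
  s <- separable_samples(seed = 2)
  pred <- knn_predict(s$x, s$y, s$x, k = 1)
  expect_equal(as.character(pred), as.character(s$y))
})

test_that("PNN: kernel monotonicity, spread limits, and tie-breaking", {
  # one training point per class -> Euclidean-nearest label at any spread
  x <- rbind(c(0, 0), c(4, 0), c(0, 6))
  y <- c("A", "B", "C")
  for (s in c(0.05, 0.4, 1.5, 50))
    expect_equal(as.character(pnn_predict(x, y, c(3, 0), spread = s)), "B")

  # two classes at d = 1 and d = 2, spread 1 -> nearer class
  x2 <- rbind(c(1, 0), c(2, 0))
  expect_equal(as.character(pnn_predict(x2, c("A", "B"), c(0, 0), 1)), "A")

  # small spread approaches the Euclidean 1-NN decision
  s <- separable_samples(n_per_class = 10, seed = 3)
  q <- s$x + matrix(rnorm(length(s$x), 0, 0.2), nrow(s$x))
  p_small <- pnn_predict(s$x, s$y, q, spread = 1e-3)
  nn1 <- apply(q, 1, function(qi) {
    s$y[which.min(colSums((t(s$x) - qi)^2))]
  })
  expect_equal(as.character(p_small), as.character(nn1))

  # very large spread with unbalanced classes and an equidistant query:
  # scores converge under the 1/n_c normalization; the deterministic
  # lowest-index tie-break selects the first class
  ang <- seq(0, pi, length.out = 6)
  x3 <- cbind(cos(ang), sin(ang))
  y3 <- c(rep("A", 5), "B")
  expect_equal(as.character(pnn_predict(x3, y3, c(0, 0), spread = 1e6)), "A")

  expect_error(pnn_predict(x, y, c(0, 0), spread = 0), "positive")
})

test_that("stratified cross-validation: fold sizes, confusion bookkeeping", {
  set.seed(5)
  x <- matrix(rnorm(540 * 4), 540, 4)
  y <- factor(rep(EMOTIONS, each = 90))
  res <- crossvalidate(x, y, "knn", parameter = 1, n_folds = 10, seed = 7)
  # 540 samples / 10 folds -> 54 per fold, 9 per class
  expect_true(all(table(res$folds) == 54))
  expect_true(all(table(res$folds, y) == 9))
  # column sums equal per-class totals over all folds
  expect_true(all(colSums(res$confusion) == 90))
  expect_equal(colSums(res$confusion_normalized), rep(1, 6),
               ignore_attr = TRUE)
  expect_equal(res$average_accuracy, mean(res$per_class_accuracy))

  # class D present with only 5 samples cannot be stratified over 10 folds
  expect_error(crossvalidate(x[1:95, ], y[1:95], n_folds = 10), "n_folds")
})

test_that("well-separated classes are recovered and shuffled labels fall to chance", {
  s <- separable_samples(n_per_class = 20, seed = 8)
  knn_res <- crossvalidate(s$x, s$y, "knn", 1, n_folds = 10, seed = 1)
  expect_gte(knn_res$average_accuracy, 99)
  pnn_res <- crossvalidate(s$x, s$y, "pnn", 0.4, n_folds = 10, seed = 1)
  expect_gte(pnn_res$average_accuracy, 95)

  set.seed(9)
  y_perm <- sample(s$y)
  null_res <- crossvalidate(s$x, y_perm, "knn", 1, n_folds = 10, seed = 1)
  se <- sqrt((1 / 6) * (5 / 6) / length(y_perm))
  expect_lt(abs(null_res$average_accuracy / 100 - 1 / 6), 3 * se)
})

test_that("parameter sweeps return one result per value with shared folds", {
  s <- separable_samples(n_per_class = 12, seed = 10)
  sw <- sweep_classifier(s$x, s$y, "knn", parameters = 1:5, n_folds = 4,
                         seed = 2)
  expect_equal(nrow(sw$sweep), 5)
  expect_equal(sw$sweep$parameter, 1:5)
  folds <- lapply(sw$results, `[[`, "folds")
  expect_true(all(vapply(folds, identical, logical(1), folds[[1]])))
})

test_that("summaries report per-class recalls from the confusion matrix", {
  mk_result <- function(conf) {
    totals <- colSums(conf)
    structure(list(classifier = "knn", parameter = 1, confusion = conf,
                   confusion_normalized = sweep(conf, 2, totals, "/"),
                   per_class_accuracy = 100 * diag(conf) / totals,
                   average_accuracy = mean(100 * diag(conf) / totals),
                   folds = NULL),
              class = "classification_result")
  }
  ident <- diag(6) * 54
  dimnames(ident) <- list(predicted = EMOTIONS, actual = EMOTIONS)
  s1 <- summarize_classification(mk_result(ident))
  expect_true(all(s1$recall_pct == 100))

  # printed 6 x 6 confusion matrix with anger column
  # (35, 4, 5, 3, 3, 4): anger recall = 35/54
  conf <- matrix(c(35, 4, 5, 3, 3, 4,
                   8, 31, 5, 2, 3, 5,
                   4, 6, 31, 7, 5, 1,
                   3, 3, 3, 41, 4, 0,
                   2, 5, 2, 7, 35, 3,
                   8, 5, 2, 3, 5, 31), nrow = 6,
                 dimnames = list(predicted = EMOTIONS, actual = EMOTIONS))
  s2 <- summarize_classification(mk_result(conf))
  expect_equal(s2$recall_pct[s2$class == "A"], 100 * 35 / 54)

  zero_diag <- matrix(9, 6, 6) - diag(9, 6)
  dimnames(zero_diag) <- list(predicted = EMOTIONS, actual = EMOTIONS)
  expect_true(all(summarize_classification(mk_result(zero_diag))$recall_pct
                  == 0))
})

test_that("trial vectors are assembled channel-major then window, bands concatenated", {
  grid <- expand.grid(window = 1:2, channel = c("AF3", "F7"),
                      band = c("alpha", "beta"),
                      trial = 1:2, emotion = c("A", "D"), subject = 1,
                      stringsAsFactors = FALSE)
  grid$group <- "NC"
  # encode the slot into the value so ordering is testable
  grid$H3 <- match(grid$band, c("alpha", "beta")) * 100 +
    match(grid$channel, c("AF3", "F7")) * 10 + grid$window
  sv <- trial_feature_vectors(grid, "H3", bands = c("alpha", "beta"))
  expect_equal(dim(sv$x), c(4, 8))
  expect_equal(sv$x[1, ], c(111, 112, 121, 122, 211, 212, 221, 222))
  expect_equal(as.character(sort(unique(sv$y))), c("A", "D"))

  # a missing cell is an error, not a silent NA
  expect_error(trial_feature_vectors(grid[-1, ], "H3",
                                     bands = c("alpha", "beta")),
               "missing cells")
  expect_error(trial_feature_vectors(grid, "H3", bands = "gamma"),
               "no rows")
})
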