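## Emotion classification: cityblock KNN (k = 1..15) and Parzen-window PNN
## (spread = 0.1..1.5), under stratified 10-fold cross-validation.

#' Cityblock (Manhattan) distance
#'
#' @param a,b numeric vectors of equal length.
#' @return `sum(abs(a - b))`.
#' @export
cityblock_distance <- function(a, b) {
  if (length(a) != length(b))
    stop("cityblock_distance: length mismatch", call. = FALSE)
  sum(abs(a - b))
}

# pairwise cityblock distances: rows of Q vs rows of X
.cityblock_matrix <- function(Q, X) {
  D <- matrix(0, nrow(Q), nrow(X))
  for (j in seq_len(ncol(Q)))
    D <- D + abs(outer(Q[, j], X[, j], "-"))
  D
}

.euclid2_matrix <- function(Q, X) {
  q2 <- rowSums(Q^2)
  x2 <- rowSums(X^2)
  outer(q2, x2, "+") - 2 * Q %*% t(X)
}

#' k-nearest-neighbour prediction with cityblock distance
#'
#' Majority label among the k cityblock-nearest training samples; a tied
#' vote is broken by the label of the single nearest neighbour.
#'
#' @param train_x numeric matrix of training samples (rows).
#' @param train_y factor (or character) of training labels.
#' @param query numeric matrix of query rows (or a single vector).
#' @param k neighbourhood size, `1 <= k <= nrow(train_x)`.
#' @return factor of predicted labels, levels those of `train_y`.
#' @export
knn_predict <- function(train_x, train_y, query, k = 1) {
  train_x <- as.matrix(train_x)
  if (!nrow(train_x))
    stop("knn_predict: empty training set", call. = FALSE)
  if (k < 1 || k > nrow(train_x))
    stop("knn_predict: k must be in 1..nrow(train_x)", call. = FALSE)
  if (is.null(dim(query))) query <- matrix(query, nrow = 1)
  train_y <- factor(train_y)
  D <- .cityblock_matrix(as.matrix(query), train_x)
  lev <- levels(train_y)
  pred <- character(nrow(D))
  for (i in seq_len(nrow(D))) {
    ord <- order(D[i, ])            # stable: distance ties keep input order
    nn <- train_y[ord[seq_len(k)]]
    tab <- table(nn)
    top <- names(tab)[tab == max(tab)]
    pred[i] <- if (length(top) == 1L) top else as.character(nn[1L])
  }
  factor(pred, levels = lev)
}

#' Parzen-window probabilistic neural network prediction
#'
#' Estimates each class density with isotropic Gaussian Parzen kernels of
#' width `spread` and assigns by the maximum class-averaged kernel score
#' (Bayes rule under equal priors):
#' `score_c = 1/n_c * sum over class-c points of exp(-d^2 / (2 spread^2))`
#' with `d` Euclidean. Scores are computed relative to the nearest training
#' point so small spreads do not underflow; this leaves the argmax
#' unchanged. A score tie is broken by the lowest class index. Large
#' spreads flatten the kernels, the scores of all classes converge and the
#' classifier becomes less selective.
#'
#' @param train_x numeric matrix of training samples (rows).
#' @param train_y factor (or character) of training labels; every class
#'   needs at least one sample.
#' @param query numeric matrix of query rows (or a single vector).
#' @param spread positive Parzen kernel width.
#' @return factor of predicted labels.
#' @export
pnn_predict <- function(train_x, train_y, query, spread) {
  train_x <- as.matrix(train_x)
  if (!nrow(train_x))
    stop("pnn_predict: empty training set", call. = FALSE)
  if (!is.numeric(spread) || length(spread) != 1L || spread <= 0)
    stop("pnn_predict: spread must be a positive scalar", call. = FALSE)
  if (is.null(dim(query))) query <- matrix(query, nrow = 1)
  train_y <- factor(train_y)
  lev <- levels(train_y)
  D2 <- .euclid2_matrix(as.matrix(query), train_x)
  D2[D2 < 0] <- 0                      # numerical guard
  pred <- integer(nrow(D2))
  for (i in seq_len(nrow(D2))) {
    z <- exp(-(D2[i, ] - min(D2[i, ])) / (2 * spread^2))
    scores <- vapply(lev, function(cl) mean(z[train_y == cl]), numeric(1))
    pred[i] <- which.max(scores)       # which.max: first (lowest) index wins
  }
  factor(lev[pred], levels = lev)
}

# stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin over folds
.stratified_folds <- function(y, n_folds, seed) {
  y <- factor(y)
  if (any(table(y) < n_folds))
    stop("crossvalidate: every class needs at least n_folds samples",
         call. = FALSE)
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

#' Stratified k-fold cross-validated classification
#'
#' Builds seeded stratified folds, trains on the complement of each fold,
#' and sums the fold confusion matrices. Per-class accuracy is the class
#' recall (confusion diagonal over the actual-class column total); the
#' average accuracy is the mean recall over classes.
#'
#' @param x numeric sample matrix (rows = samples).
#' @param y class labels.
#' @param classifier `"knn"` or `"pnn"`.
#' @param parameter `k` for KNN, `spread` for PNN.
#' @param n_folds number of folds (default 10).
#' @param seed fold-construction seed.
#' @return a `classification_result`: list with `classifier`, `parameter`,
#'   `confusion` (rows = predicted, columns = actual, summed over folds),
#'   `confusion_normalized` (columns scaled to proportions),
#'   `per_class_accuracy`, `average_accuracy` (percent), `folds`.
#' @export
crossvalidate <- function(x, y, classifier = c("knn", "pnn"), parameter = 1,
                          n_folds = 10, seed = 1) {
  classifier <- match.arg(classifier)
  x <- as.matrix(x)
  y <- factor(y)
  folds <- .stratified_folds(y, n_folds, seed)
  lev <- levels(y)
  conf <- matrix(0L, length(lev), length(lev),
                 dimnames = list(predicted = lev, actual = lev))
  for (f in seq_len(n_folds)) {
    te <- folds == f
    pred <- if (classifier == "knn")
      knn_predict(x[!te, , drop = FALSE], y[!te], x[te, , drop = FALSE],
                  k = parameter)
    else
      pnn_predict(x[!te, , drop = FALSE], y[!te], x[te, , drop = FALSE],
                  spread = parameter)
    conf <- conf + unclass(table(factor(pred, lev), factor(y[te], lev)))
  }
  totals <- colSums(conf)
  per_class <- 100 * diag(conf) / totals
  structure(list(classifier = classifier, parameter = parameter,
                 confusion = conf,
                 confusion_normalized = sweep(conf, 2, totals, "/"),
                 per_class_accuracy = per_class,
                 average_accuracy = mean(per_class),
                 folds = folds),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %s (parameter = %g): average accuracy %.2f%%\n",
              x$classifier, x$parameter, x$average_accuracy))
  print(x$confusion)
  invisible(x)
}

#' Parameter sweep of a classifier under cross-validation
#'
#' Runs [crossvalidate()] once per parameter value (k = 1..15 for KNN,
#' spread = 0.1..1.5 step 0.1 for PNN by default) with identical folds.
#'
#' @inheritParams crossvalidate
#' @param parameters vector of k values or spread values.
#' @return list with `sweep` (data.frame of parameter vs average accuracy)
#'   and `results` (one `classification_result` per value).
#' @export
sweep_classifier <- function(x, y, classifier = c("knn", "pnn"),
                             parameters = NULL, n_folds = 10, seed = 1) {
  classifier <- match.arg(classifier)
  if (is.null(parameters))
    parameters <- if (classifier == "knn") 1:15 else seq(0.1, 1.5, by = 0.1)
  results <- lapply(parameters, function(p)
    crossvalidate(x, y, classifier, p, n_folds, seed))
  list(sweep = data.frame(
         classifier = classifier, parameter = parameters,
         average_accuracy = vapply(results, `[[`, numeric(1),
                                   "average_accuracy")),
       results = results)
}

#' Summarize a classification result as report rows
#'
#' @param result a `classification_result`.
#' @return data.frame with one row per class: `class`, `n_actual`,
#'   `n_correct`, `recall_pct`, plus the classifier, parameter and average
#'   accuracy repeated on each row.
#' @export
summarize_classification <- function(result) {
  stopifnot(inherits(result, "classification_result"))
  conf <- result$confusion
  data.frame(classifier = result$classifier, parameter = result$parameter,
             class = colnames(conf), n_actual = colSums(conf),
             n_correct = diag(conf),
             recall_pct = 100 * diag(conf) / colSums(conf),
             average_accuracy = result$average_accuracy,
             row.names = NULL)
}

#' Per-trial sample vectors from an epoch-level feature table
#'
#' Builds one sample per (subject, emotion, trial): for each band in
#' `bands`, the selected feature's values ordered channel-major then window
#' (channels x windows values per band), concatenated across bands. With the
#' full design this gives 84 values per band and 252 for the three-band
#' combination.
#'
#' @param feature_table output of [build_feature_table()].
#' @param feature one of `"v"`, `"H1"`, `"H2"`, `"H3"`, `"H4"`, `"H5"`.
#' @param bands bands to use, in concatenation order.
#' @param scale z-score each column? Off by default.
#' @return list with `x` (sample matrix), `y` (emotion factor) and `keys`
#'   (data.frame of subject, emotion, trial).
#' @export
trial_feature_vectors <- function(feature_table, feature,
                                  bands = c("alpha", "beta", "gamma"),
                                  scale = FALSE) {
  stopifnot(feature %in% names(feature_table))
  ft <- feature_table[feature_table$band %in% bands, , drop = FALSE]
  if (!nrow(ft))
    stop("trial_feature_vectors: no rows for requested bands", call. = FALSE)
  channels <- unique(ft$channel)
  windows <- sort(unique(ft$window))
  keys <- unique(ft[, c("subject", "emotion", "trial")])
  keys <- keys[order(keys$subject, match(keys$emotion, unique(ft$emotion)),
                     keys$trial), , drop = FALSE]
  d_band <- length(channels) * length(windows)
  X <- matrix(NA_real_, nrow(keys), d_band * length(bands))
  # deterministic slot per (band, channel, window): band-major blocks,
  # channel-major within block
  slot <- function(band, channel, window)
    (match(band, bands) - 1L) * d_band +
      (match(channel, channels) - 1L) * length(windows) +
      match(window, windows)
  row_id <- function(s, e, tr) paste(s, e, tr, sep = "\r")
  ridx <- match(row_id(ft$subject, ft$emotion, ft$trial),
                row_id(keys$subject, keys$emotion, keys$trial))
  cidx <- slot(ft$band, ft$channel, ft$window)
  X[cbind(ridx, cidx)] <- ft[[feature]]
  if (anyNA(X))
    stop("trial_feature_vectors: missing cells (incomplete design)",
         call. = FALSE)
  if (scale) X <- base::scale(X)
  list(x = X, y = factor(keys$emotion), keys = keys)
}
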