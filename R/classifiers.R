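#' Classifier settings for fitness evaluation
#'
#' One common specification covers the three classifiers used as genetic
#' algorithm fitness functions: k-nearest neighbours (`"knn"`), nearest
#' centroid (`"nearcent"`) and a radial-kernel soft-margin support vector
#' machine (`"svm"`).
#'
#' @param method `"knn"`, `"nearcent"` or `"svm"`.
#' @param k neighbour count for KNN; odd and >= 1 so binary votes cannot tie.
#' @param sigma RBF kernel width for the SVM; `NULL` (default) uses the
#'   median heuristic on pairwise training distances.
#' @param cost SVM margin penalty (> 0).
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(method = c("knn", "nearcent", "svm"),
                            k = 3L, sigma = NULL, cost = 1) {
  method <- match.arg(method)
  if (method == "knn") {
    if (k < 1 || k %% 2 == 0)
      stop_config("k must be odd and >= 1 (got %s)", k)
  }
  if (!is.null(sigma) && sigma <= 0) stop_config("sigma must be > 0")
  if (cost <= 0) stop_config("cost must be > 0")
  structure(list(method = method, k = as.integer(k), sigma = sigma,
                 cost = cost),
            class = "classifier_spec")
}

#' Cross-validation scheme
#'
#' @param n_splits folds (>= 2, and at most the smallest class size so every
#'   stratified training fold keeps both classes).
#' @param n_repeats independent repetitions of the split.
#' @param stratified preserve class proportions per fold? (default `TRUE`)
#' @param seed RNG seed for the fold draws; a fixed seed makes
#'   [cv_average_accuracy()] deterministic.
#' @return an object of class `cv_scheme`.
#' @export
cv_scheme <- function(n_splits = 5L, n_repeats = 4L, stratified = TRUE,
                      seed = 1L) {
  if (n_splits < 2) stop_config("n_splits must be >= 2")
  if (n_repeats < 1) stop_config("n_repeats must be >= 1")
  structure(list(n_splits = as.integer(n_splits),
                 n_repeats = as.integer(n_repeats),
                 stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "cv_scheme")
}

check_xy <- function(train_x, train_y, test_x) {
  if (!is.matrix(train_x)) train_x <- as.matrix(train_x)
  if (!is.matrix(test_x)) test_x <- as.matrix(test_x)
  if (nrow(train_x) == 0L) stop_config("empty training set")
  if (length(train_y) != nrow(train_x))
    stop_config("train_y length (%d) != training rows (%d)",
                length(train_y), nrow(train_x))
  if (ncol(test_x) != ncol(train_x))
    stop_config("dimension mismatch: train has %d features, test has %d",
                ncol(train_x), ncol(test_x))
  list(train_x = train_x, train_y = as.character(train_y), test_x = test_x)
}

#' K-nearest-neighbour prediction
#'
#' Labels each test point by majority vote among its `k` Euclidean-nearest
#' training points. Tied votes (possible for even `k`) are broken first by
#' the smaller summed neighbour distance, then by the lexicographically
#' smaller label; equidistant neighbours are taken in training order. All
#' three rules are deterministic.
#'
#' @param train_x,train_y training matrix and labels.
#' @param test_x matrix of points to label.
#' @param k neighbour count (<= number of training points).
#' @return character vector of predicted labels.
#' @export
knn_predict <- function(train_x, train_y, test_x, k = 3L) {
  z <- check_xy(train_x, train_y, test_x)
  if (k > nrow(z$train_x))
    stop_config("k (%d) exceeds training size (%d)", k, nrow(z$train_x))
  knn_core(z$train_x, z$train_y, z$test_x, k)
}

knn_core <- function(train_x, train_y, test_x, k) {
  d2 <- euclid2(test_x, train_x)
  vapply(seq_len(nrow(test_x)), function(i) {
    ord <- order(d2[i, ])[seq_len(k)]
    labs <- train_y[ord]
    cnt <- table(labs)
    top <- names(cnt)[cnt == max(cnt)]
    if (length(top) > 1L) {
      sums <- vapply(top, function(l) sum(d2[i, ord[labs == l]]), numeric(1))
      top <- top[sums == min(sums)]
      top <- sort(top)[1L]
    }
    top
  }, character(1))
}

# squared Euclidean distances between rows of a (n_a x p) and b (n_b x p)
euclid2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' Nearest-centroid prediction
#'
#' Computes each class centroid as the mean of its training vectors and
#' assigns every test point to the class of its Euclidean-nearest centroid
#' (ties to the lexicographically smaller label). With one training sample
#' per class this reduces to 1-NN.
#'
#' @inheritParams knn_predict
#' @return character vector of predicted labels.
#' @export
nearcent_fit_predict <- function(train_x, train_y, test_x) {
  z <- check_xy(train_x, train_y, test_x)
  y <- factor(z$train_y)
  if (any(table(y) == 0L))
    stop_config("class \"%s\" has no training samples",
                levels(y)[table(y) == 0L][1L])
  cent <- rowsum(z$train_x, y) / as.vector(table(y))
  d2 <- euclid2(z$test_x, cent)
  lv <- sort(rownames(cent))
  d2 <- d2[, lv, drop = FALSE]  # column order = tie-break order
  lv[max.col(-d2, ties.method = "first")]
}

#' Radial-basis-function kernel
#'
#' `K(x, x') = exp(-||x - x'||^2 / (2 sigma^2))`; equals 1 when `x = x'`.
#'
#' @param a,b matrices of row vectors.
#' @param sigma kernel width (> 0).
#' @return `nrow(a)` x `nrow(b)` kernel matrix.
#' @export
rbf_kernel <- function(a, b = a, sigma = 1) {
  if (sigma <= 0) stop_config("sigma must be > 0")
  exp(-euclid2(as.matrix(a), as.matrix(b)) / (2 * sigma^2))
}

# median heuristic for the RBF width: median pairwise training distance
median_sigma <- function(x) {
  d <- stats::dist(x)
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m <= 0) 1 else m
}

#' RBF support-vector-machine prediction
#'
#' Fits a binary soft-margin SVM with the radial kernel
#' `K(x, x') = exp(-||x - x'||^2 / (2 sigma^2))` (via libsvm) and labels the
#' test points by the sign of the learned discriminant. When `sigma` is not
#' given it is set by the median heuristic on pairwise training distances.
#'
#' @inheritParams knn_predict
#' @param sigma RBF width; `NULL` for the median heuristic.
#' @param cost margin penalty (> 0).
#' @return character vector of predicted labels.
#' @export
svm_fit_predict <- function(train_x, train_y, test_x, sigma = NULL,
                            cost = 1) {
  z <- check_xy(train_x, train_y, test_x)
  if (length(unique(z$train_y)) < 2L)
    stop_config("SVM training set must contain two classes")
  sigma <- sigma %||% median_sigma(z$train_x)
  fit <- e1071::svm(x = z$train_x, y = factor(z$train_y),
                    type = "C-classification", kernel = "radial",
                    gamma = 1 / (2 * sigma^2), cost = cost, scale = FALSE)
  as.character(stats::predict(fit, z$test_x))
}

as_xy <- function(data) {
  if (inherits(data, "comparison_dataset"))
    return(list(x = data$table$intensities, y = data$table$stages))
  if (inherits(data, "feature_table"))
    return(list(x = data$intensities, y = data$stages))
  if (is.list(data) && all(c("x", "y") %in% names(data)))
    return(list(x = as.matrix(data$x), y = as.character(data$y)))
  stop_config("data must be a comparison_dataset, feature_table or list(x, y)")
}

make_fold_ids <- function(y, n_splits, stratified) {
  n <- length(y)
  fold <- integer(n)
  if (stratified) {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(n_splits),
                                                    length(idx))
    }
  } else {
    fold[sample.int(n)] <- rep_len(seq_len(n_splits), n)
  }
  fold
}

# Precomputed cross-validation context. Fold membership and the per-fold
# z-scoring (training-fold statistics applied to the full feature matrix)
# do not depend on which feature subset is evaluated, so they are computed
# once and shared by every chromosome evaluation of a GA blast or forward
# selection — identical results to evaluating from scratch, at a fraction
# of the cost.
cv_context <- function(data, spec, scheme) {
  xy <- as_xy(data)
  x <- xy$x
  y <- xy$y
  # Intensity matrices (non-negative by construction) are classified on the
  # log scale: LC-MS intensities are log-normal, and distance-based
  # classifiers on the raw scale are dominated by the heavy right tail.
  # Matrices containing negative values are assumed already transformed and
  # pass through untouched.
  if (all(x >= 0)) x <- log1p(x)
  cls <- table(y)
  if (length(cls) < 2L) stop_config("data must contain two classes")
  if (scheme$n_splits > min(cls))
    stop_config("n_splits (%d) exceeds smallest class size (%d)",
                scheme$n_splits, min(cls))
  lev <- sort(unique(y))
  yint <- match(y, lev)

  fold_ids <- with_seed(scheme$seed, {
    lapply(seq_len(scheme$n_repeats), function(r) {
      fold <- make_fold_ids(y, scheme$n_splits, scheme$stratified)
      if (!scheme$stratified) {
        tries <- 0L
        while (any(vapply(seq_len(scheme$n_splits), function(f)
          length(unique(y[fold != f])) < 2L, logical(1)))) {
          tries <- tries + 1L
          if (tries > 100L)
            stop_config("cannot form folds with two classes in every training set")
          fold <- make_fold_ids(y, scheme$n_splits, scheme$stratified)
        }
      }
      fold
    })
  })
  fold_data <- list()
  for (r in seq_len(scheme$n_repeats)) {
    for (f in seq_len(scheme$n_splits)) {
      tr <- fold_ids[[r]] != f
      xtr <- x[tr, , drop = FALSE]
      mu <- colMeans(xtr)
      sd <- sqrt(colSums((xtr - rep(mu, each = nrow(xtr)))^2) /
                   (nrow(xtr) - 1L))
      sd[!is.finite(sd) | sd == 0] <- 1
      fold_data[[length(fold_data) + 1L]] <-
        list(xtr = t((t(xtr) - mu) / sd),
             xte = t((t(x[!tr, , drop = FALSE]) - mu) / sd),
             ytr = yint[tr], yte = yint[!tr])
    }
  }
  structure(list(fold_data = fold_data, lev = lev, spec = spec,
                 scheme = scheme, n_features = ncol(x)),
            class = "cv_context")
}

# per-fold held-out accuracies of one feature subset
ctx_accuracy <- function(ctx, genes = NULL) {
  spec <- ctx$spec
  lev <- ctx$lev
  vapply(ctx$fold_data, function(fd) {
    a <- if (is.null(genes)) fd$xtr else fd$xtr[, genes, drop = FALSE]
    b <- if (is.null(genes)) fd$xte else fd$xte[, genes, drop = FALSE]
    pred <- fold_predict(spec, a, fd$ytr, b, lev)
    mean(pred == fd$yte)
  }, numeric(1))
}

# integer-coded per-fold prediction; fast paths for the binary hot loop
fold_predict <- function(spec, xtr, ytr, xte, lev) {
  switch(spec$method,
         knn = {
           k <- min(spec$k, nrow(xtr))
           if (k %% 2 == 1L && length(lev) == 2L) {
             d2 <- euclid2(xte, xtr)
             nb <- matrix(0L, nrow(xte), k)
             for (j in seq_len(k)) {
               hit <- max.col(-d2, ties.method = "first")
               nb[, j] <- hit
               d2[cbind(seq_len(nrow(xte)), hit)] <- Inf
             }
             votes1 <- rowSums(matrix(ytr[nb] == 1L, nrow(xte), k))
             ifelse(2L * votes1 > k, 1L, 2L)
           } else {
             match(knn_core(xtr, lev[ytr], xte, k), lev)
           }
         },
         nearcent = {
           cnt <- tabulate(ytr, length(lev))
           cent <- rowsum(xtr, factor(ytr, levels = seq_along(lev))) / cnt
           max.col(-euclid2(xte, cent), ties.method = "first")
         },
         svm = {
           sigma <- spec$sigma %||% median_sigma(xtr)
           fit <- e1071::svm(x = xtr, y = factor(lev[ytr], levels = lev),
                             type = "C-classification", kernel = "radial",
                             gamma = 1 / (2 * sigma^2), cost = spec$cost,
                             scale = FALSE)
           match(as.character(stats::predict(fit, xte)), lev)
         })
}

#' Cross-validated average accuracy of a feature subset
#'
#' The fitness function of the whole pipeline: mean held-out classification
#' accuracy of a classifier restricted to a feature subset, over
#' `n_splits x n_repeats` (stratified by default) cross-validation splits.
#' Features are z-scored inside every fold using training-fold statistics
#' only, so no test information leaks into the distances. Deterministic under
#' a fixed `scheme` seed; the caller's RNG stream is left untouched.
#'
#' Non-negative matrices (intensity tables) are `log1p`-transformed before
#' standardization, the conventional scale for LC-MS data; matrices with
#' negative entries are taken as already transformed and used as-is.
#'
#' @param data a `comparison_dataset`, [feature_table()] with two stages, or
#'   `list(x, y)`.
#' @param features optional column indices or names restricting the subset
#'   (default: all features).
#' @param spec a [classifier_spec()].
#' @param scheme a [cv_scheme()]; `n_splits` must not exceed the smallest
#'   class size.
#' @return list with `average_accuracy` (in `[0, 1]`) and `per_split`
#'   (accuracy of every split x repeat).
#' @export
cv_average_accuracy <- function(data, features = NULL,
                                spec = classifier_spec("knn"),
                                scheme = cv_scheme()) {
  ctx <- cv_context(data, spec, scheme)
  if (!is.null(features)) {
    if (is.character(features)) {
      xy <- as_xy(data)
      features <- match(features, colnames(xy$x))
      if (anyNA(features)) stop_config("unknown feature name in subset")
    }
    if (length(features) == 0L) stop_config("empty feature subset")
  }
  accs <- ctx_accuracy(ctx, features)
  list(average_accuracy = mean(accs), per_split = accs)
}
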