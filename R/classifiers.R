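#' Fit a binary pair classifier
#'
#' Registry of the four classifiers compared in the benchmark: `"rf"` (random
#' forest, the default), `"gbdt"` (gradient-boosted trees), `"lr"` (logistic
#' regression) and `"knn"` (k-nearest neighbors). Hyperparameters follow the
#' common library defaults: rf = 100 trees, `mtry = floor(sqrt(p))`, fully
#' grown; gbdt = 100 rounds of depth-3 trees with shrinkage 0.1; knn = 5
#' neighbors (Euclidean); lr = unpenalized maximum likelihood.
#'
#' The tree learners are in-package CART implementations (variance split,
#' which equals Gini impurity on 0/1 labels), compiled code, deterministic
#' per seed.
#'
#' @param x Numeric feature matrix, one row per pair.
#' @param y 0/1 labels.
#' @param classifier One of `"rf"`, `"gbdt"`, `"lr"`, `"knn"`.
#' @param seed Integer seed for the stochastic learners.
#' @param ntree,mtry Random-forest size and per-split feature sample.
#' @param n_rounds,shrinkage,gbdt_depth Gradient-boosting controls.
#' @param k Neighbor count for knn.
#' @return A `pair_classifier` object for [predict_classifier()].
#' @export
fit_classifier <- function(x, y, classifier = c("rf", "gbdt", "lr", "knn"),
                           seed = 1L, ntree = 100L, mtry = NULL,
                           n_rounds = 100L, shrinkage = 0.1,
                           gbdt_depth = 3L, k = 5L) {
  classifier <- match.arg(classifier)
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  fit <- switch(classifier,
    rf = {
      if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
      list(forest = cpp_forest_fit(x, y, as.integer(ntree), as.integer(mtry),
                                   2L, 0L, as.integer(seed)))
    },
    gbdt = {
      p0 <- min(max(mean(y), 1e-10), 1 - 1e-10)
      f0 <- log(p0 / (1 - p0))
      f <- rep(f0, length(y))
      trees <- vector("list", n_rounds)
      for (b in seq_len(n_rounds)) {
        r <- y - stats::plogis(f)
        tr <- cpp_grow_tree(x, r, ncol(x), 2L, as.integer(gbdt_depth),
                            as.integer(seed) + b)
        trees[[b]] <- tr
        f <- f + shrinkage * cpp_tree_predict(tr, x)
      }
      list(f0 = f0, trees = trees, shrinkage = shrinkage)
    },
    lr = {
      xx <- cbind(1, x)
      co <- tryCatch(
        suppressWarnings(stats::glm.fit(xx, y,
          family = stats::binomial())$coefficients),
        error = function(e) stop("logistic regression failed: ",
                                 conditionMessage(e)))
      co[is.na(co)] <- 0
      list(coef = co)
    },
    knn = {
      list(x = x, y = y, k = as.integer(k))
    })
  structure(list(classifier = classifier, fit = fit, p = ncol(x)),
            class = "pair_classifier")
}

#' Score pairs with a fitted classifier
#'
#' @param model A `pair_classifier` from [fit_classifier()].
#' @param newx Feature matrix with the same column layout as at fit time.
#' @return Numeric scores in `[0, 1]` (interaction probability).
#' @export
predict_classifier <- function(model, newx) {
  stopifnot(inherits(model, "pair_classifier"))
  newx <- as.matrix(newx)
  if (ncol(newx) != model$p)
    stop("dimension error: model expects ", model$p, " features, got ",
         ncol(newx))
  switch(model$classifier,
    rf = cpp_forest_predict(model$fit$forest, newx),
    gbdt = {
      f <- rep(model$fit$f0, nrow(newx))
      for (tr in model$fit$trees)
        f <- f + model$fit$shrinkage * cpp_tree_predict(tr, newx)
      stats::plogis(f)
    },
    lr = as.numeric(stats::plogis(cbind(1, newx) %*% model$fit$coef)),
    knn = {
      tr <- model$fit$x
      # squared Euclidean distances in one BLAS call
      d2 <- outer(rowSums(newx^2), rowSums(tr^2), "+") -
        2 * tcrossprod(newx, tr)
      apply(d2, 1L, function(row) {
        mean(model$fit$y[order(row)[seq_len(model$fit$k)]])
      })
    })
}
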