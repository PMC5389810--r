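#' Fit a K-nearest-neighbour behaviour classifier
#'
#' The KNN classifier works on individual acceleration measurements (not
#' segments): the three raw channel values are min-max normalized to
#' `[0, 1]` using ranges fitted on the training set only, and a query is
#' classified by majority vote of its `k` nearest training points under
#' Euclidean distance.  Distance ties at the k-th neighbour are resolved
#' by stable training order and vote ties by the smallest class index, so
#' predictions are fully deterministic.
#'
#' @param x matrix or data frame of training measurements (columns x, y,
#'   z acceleration in g).
#' @param labels class label per training row.
#' @param k neighbour count.
#' @return An object of class `behavior_knn`.
#' @export
behavior_knn <- function(x, labels, k = 5) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("training measurements contain NA")
  if (k < 1 || k > nrow(x)) stop("k must be in [1, nrow(x)]")
  y <- factor(as.character(labels))
  rng_min <- apply(x, 2, min)
  rng_max <- apply(x, 2, max)
  if (any(!is.finite(rng_min)) || any(rng_min >= rng_max))
    stop("degenerate normalization range (constant column?)")
  xn <- sweep(sweep(x, 2, rng_min), 2, rng_max - rng_min, "/")
  structure(list(train = xn, labels_int = as.integer(y),
                 classes = levels(y), k = as.integer(k),
                 range_min = rng_min, range_max = rng_max),
            class = "behavior_knn")
}

#' @export
print.behavior_knn <- function(x, ...) {
  cat(sprintf("<behavior_knn> k = %d, %d training points, %d classes\n",
              x$k, nrow(x$train), length(x$classes)))
  invisible(x)
}

# normalize new measurements with the training ranges; clip to [-0.5, 1.5]
knn_normalize <- function(model, newdata) {
  newdata <- as.matrix(newdata)
  xn <- sweep(sweep(newdata, 2, model$range_min), 2,
              model$range_max - model$range_min, "/")
  pmin(pmax(xn, -0.5), 1.5)
}

#' @export
predict.behavior_knn <- function(object, newdata, k = object$k, ...) {
  xn <- knn_normalize(object, newdata)
  nb <- cpp_knn_neighbors(object$train, xn, as.integer(k))
  pred <- cpp_knn_vote(nb, object$labels_int, as.integer(k),
                       length(object$classes))
  object$classes[pred]
}

#' Majority vote of per-sample predictions within segments
#'
#' Collapses per-sample KNN predictions to one label per segment, enabling
#' a segment-level accuracy comparable with the segment random forest.
#' Off the beaten path by default — the KNN's native evaluation unit is
#' the individual measurement — but useful for model comparisons.  Vote
#' ties go to the lexicographically first label.
#'
#' @param labels per-sample predicted labels.
#' @param groups segment id per sample, same length.
#' @return Named character vector of one majority label per group.
#' @export
majority_vote <- function(labels, groups) {
  if (length(labels) != length(groups))
    stop("labels and groups must be equal length")
  vapply(split(as.character(labels), groups), function(v) {
    tab <- sort(table(v), decreasing = TRUE)
    names(tab)[1]
  }, "")
}

#' KNN search configuration
#' @param k_coarse coarse grid of candidate K values (default 5 to 50 in
#'   steps of 5).
#' @param seed integer seed (splits only; the classifier is deterministic).
#' @return An object of class `knn_config`.
#' @export
knn_config <- function(k_coarse = seq(5, 50, by = 5), seed = 1) {
  if (any(k_coarse < 1)) stop("K must be >= 1")
  structure(list(k_coarse = as.integer(sort(k_coarse)),
                 seed = as.integer(seed)),
            class = "knn_config")
}

#' Optimize K and classify the test set
#'
#' The search protocol: accuracy on the test set is computed for each
#' coarse K (5 to 50 by 5); the two K values with the highest accuracy
#' bracket a unit-step refinement, and the final K is the refined argmax
#' (ties to the smaller K).  Neighbour lists are computed once up to the
#' largest candidate K, so the sweep costs a single distance pass.
#'
#' @param train_x,train_labels training measurements and labels.
#' @param test_x,test_labels test measurements and labels (the accuracy
#'   yardstick for the K search).
#' @param config a [knn_config()].
#' @return List with `k` (selected), `model` (a [behavior_knn()] at the
#'   selected K), `predictions` (test-set predictions at the selected K),
#'   `accuracy`, and the `coarse` and `refined` search tables.
#' @export
knn_optimize <- function(train_x, train_labels, test_x, test_labels,
                         config = knn_config()) {
  stopifnot(inherits(config, "knn_config"))
  model <- behavior_knn(train_x, train_labels, k = 1)
  kmax <- min(max(config$k_coarse), nrow(model$train))
  ks <- config$k_coarse[config$k_coarse <= kmax]
  xn <- knn_normalize(model, as.matrix(test_x))
  nb <- cpp_knn_neighbors(model$train, xn, as.integer(kmax))
  truth <- as.character(test_labels)
  acc_at <- function(k) {
    pred <- model$classes[cpp_knn_vote(nb, model$labels_int,
                                       as.integer(k),
                                       length(model$classes))]
    mean(pred == truth)
  }
  coarse <- data.frame(k = ks, accuracy = vapply(ks, acc_at, 0))
  top2 <- coarse$k[order(-coarse$accuracy, coarse$k)][1:2]
  refine_ks <- seq(min(top2), max(top2))
  refined <- data.frame(k = refine_ks,
                        accuracy = vapply(refine_ks, acc_at, 0))
  k_sel <- refined$k[order(-refined$accuracy, refined$k)][1]
  pred <- model$classes[cpp_knn_vote(nb, model$labels_int,
                                     as.integer(k_sel),
                                     length(model$classes))]
  model$k <- as.integer(k_sel)
  list(k = k_sel, model = model, predictions = pred,
       accuracy = mean(pred == truth), coarse = coarse, refined = refined)
}
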