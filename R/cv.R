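#' Model specifications for cross-validation
#'
#' A model spec is a pair of closures (`fit`, `predict`) that
#' [repeated_kfold()] can drive.  `make_rf_spec()` wraps the segment-level
#' random forest, `make_knn_spec()` the per-sample KNN.
#'
#' @param ntree,mtry forest size and predictors per split.
#' @param seed integer seed passed to the forest fit.
#' @return A list with functions `fit(x, labels)` and
#'   `predict(model, x)`.
#' @export
make_rf_spec <- function(ntree = 500, mtry = 5, seed = 1) {
  list(fit = function(x, labels)
         behavior_rf(x, labels, ntree = ntree, mtry = mtry, seed = seed),
       predict = function(model, x) predict(model, x))
}

#' @rdname make_rf_spec
#' @param k neighbour count for the KNN spec.
#' @export
make_knn_spec <- function(k = 5) {
  list(fit = function(x, labels) behavior_knn(x, labels, k = k),
       predict = function(model, x) predict(model, x))
}

#' Repeated stratified k-fold cross-validation
#'
#' For each repetition a fresh, seeded, class-stratified fold assignment
#' is drawn; the repetition error is the mean fold misclassification rate
#' and the summary is the five-number summary plus the mean over
#' repetition errors.  Folds are stratified so small classes do not vanish
#' from training sets; if a class is nevertheless absent from a training
#' fold, the fold is flagged and its error is computed over the items
#' whose class the model could have predicted.
#'
#' @param x feature matrix (segments for RF, measurements for KNN).
#' @param labels class label per row.
#' @param spec a model spec from [make_rf_spec()] or [make_knn_spec()].
#' @param k folds per repetition (default 10).
#' @param reps repetitions (default 10).
#' @param seed integer seed.
#' @return An object of class `cv_summary` with `rep_errors`, `min`, `q1`,
#'   `median`, `mean`, `q3`, `max`, and `flagged_folds`.
#' @export
repeated_kfold <- function(x, labels, spec, k = 10, reps = 10, seed = 1) {
  x <- as.data.frame(x)
  labels <- as.character(labels)
  n <- nrow(x)
  if (n < k) stop("need at least k rows")
  rep_errors <- numeric(reps)
  flagged <- 0L
  for (r in seq_len(reps)) {
    set.seed(seed + r)
    fold <- integer(n)
    for (cl in unique(labels)) {          # stratified assignment
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(sample(k), length(idx))
    }
    fold_err <- numeric(k)
    for (f in seq_len(k)) {
      tr <- fold != f
      model <- spec$fit(x[tr, , drop = FALSE], labels[tr])
      te <- which(!tr)
      predictable <- labels[te] %in% unique(labels[tr])
      if (!all(predictable)) flagged <- flagged + 1L
      te <- te[predictable]
      pred <- spec$predict(model, x[te, , drop = FALSE])
      fold_err[f] <- mean(pred != labels[te])
    }
    rep_errors[r] <- mean(fold_err)
  }
  fn <- stats::fivenum(rep_errors)
  structure(list(rep_errors = rep_errors, min = fn[1], q1 = fn[2],
                 median = fn[3], mean = mean(rep_errors), q3 = fn[4],
                 max = fn[5], k = k, reps = reps,
                 flagged_folds = flagged),
            class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat(sprintf("<cv_summary> %d x %d-fold CV error rates\n", x$reps, x$k))
  cat(sprintf(
    "  min %.4f | q1 %.4f | median %.4f | mean %.4f | q3 %.4f | max %.4f\n",
    x$min, x$q1, x$median, x$mean, x$q3, x$max))
  if (x$flagged_folds > 0L)
    cat(sprintf("  (%d fold(s) flagged: class absent from training)\n",
                x$flagged_folds))
  invisible(x)
}
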