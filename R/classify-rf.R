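#' Stratified 70/30 train/test split
#'
#' Splits item indices into disjoint, exhaustive train and test sets,
#' stratified by class so each class contributes ~70% of its items to
#' training (`round(0.7 * n_class)`).
#'
#' @param labels class label per item.
#' @param seed integer seed.
#' @param train_fraction training share, default 0.7.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_70_30 <- function(labels, seed = 1, train_fraction = 0.7) {
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < 2L))
    stop("every class needs at least 2 items to split: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  set.seed(seed)
  train <- integer(0)
  for (cl in names(counts)) {
    idx <- which(labels == cl)
    n_tr <- max(1L, min(length(idx) - 1L, round(train_fraction *
                                                  length(idx))))
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Random-forest tuning configuration
#'
#' The grids mirror the standard tuning protocol for this pipeline:
#' `ntree` from 500 to 4000 in steps of 500 and `mtry` from 1 to 28.
#' (`mtry = 0` is meaningless for split sampling, so the scan starts
#' at 1.)
#'
#' @param ntree_grid candidate tree counts.
#' @param mtry_grid candidate predictors sampled per split.
#' @param seed integer seed.
#' @return An object of class `rf_config`.
#' @export
rf_config <- function(ntree_grid = seq(500, 4000, by = 500),
                      mtry_grid = 1:28, seed = 1) {
  if (any(ntree_grid < 1) || any(mtry_grid < 1))
    stop("ntree and mtry must be >= 1")
  structure(list(ntree_grid = as.integer(ntree_grid),
                 mtry_grid = as.integer(mtry_grid),
                 ntree = NULL, mtry = NULL, oob_error_surface = NULL,
                 seed = as.integer(seed)),
            class = "rf_config")
}

#' Fit a random-forest behaviour classifier
#'
#' Thin, seeded wrapper around [randomForest::randomForest()] on a
#' per-segment feature matrix, returning a classed model object with
#' `predict`, `print` and `summary` methods.  Rows containing `NA`
#' features are refused (segments shorter than 3 samples lack
#' skewness/kurtosis and should be filtered upstream).
#'
#' @param x data frame or matrix of per-segment features (typically the 28
#'   statistics of [feature_names()]).
#' @param labels behaviour label per row.
#' @param ntree number of trees.
#' @param mtry predictors sampled per split; default `floor(sqrt(p))`.
#' @param seed integer seed.
#' @return An object of class `behavior_rf`.
#' @export
behavior_rf <- function(x, labels, ntree = 500,
                        mtry = max(1, floor(sqrt(ncol(x)))), seed = 1) {
  x <- as.data.frame(x)
  if (anyNA(x)) stop("feature matrix contains NA")
  y <- factor(as.character(labels))
  if (nlevels(y) < 2L) stop("training labels hold a single class")
  set.seed(seed)
  fit <- randomForest::randomForest(x = x, y = y, ntree = ntree,
                                    mtry = mtry, importance = TRUE)
  structure(list(fit = fit, feature_names = colnames(x),
                 classes = levels(y), ntree = ntree, mtry = mtry,
                 oob_error = unname(fit$err.rate[ntree, "OOB"]),
                 seed = seed),
            class = "behavior_rf")
}

#' @export
print.behavior_rf <- function(x, ...) {
  cat(sprintf(
    "<behavior_rf> %d classes, %d features, ntree = %d, mtry = %d\n",
    length(x$classes), length(x$feature_names), x$ntree, x$mtry))
  cat(sprintf("OOB error: %.4f\n", x$oob_error))
  invisible(x)
}

#' @export
summary.behavior_rf <- function(object, ...) {
  print(object)
  cat("\nTop variables by OOB permutation importance:\n")
  imp <- rf_importance(object)
  print(utils::head(imp, 10), row.names = FALSE)
  invisible(object)
}

#' @export
predict.behavior_rf <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)[, object$feature_names, drop = FALSE]
  as.character(predict(object$fit, newdata = newdata, ...))
}

#' Grid-search ntree and mtry by out-of-bag error
#'
#' Fits one forest per grid cell and selects the cell with the lowest OOB
#' error; ties go to the smaller `ntree`, then the smaller `mtry`.
#'
#' @param x per-segment feature matrix.
#' @param labels behaviour label per row.
#' @param config an [rf_config()].
#' @return The config with `ntree`, `mtry`, `oob_error_surface` (a matrix
#'   ntree x mtry) and `oob_error` filled in.
#' @export
optimize_rf <- function(x, labels, config = rf_config()) {
  stopifnot(inherits(config, "rf_config"))
  x <- as.data.frame(x)
  mgrid <- config$mtry_grid[config$mtry_grid <= ncol(x)]
  if (!length(mgrid)) stop("mtry grid entirely above the feature count")
  surface <- matrix(NA_real_, length(config$ntree_grid), length(mgrid),
                    dimnames = list(config$ntree_grid, mgrid))
  best <- Inf
  cell <- 0L
  for (i in seq_along(config$ntree_grid)) {
    for (j in seq_along(mgrid)) {
      cell <- cell + 1L
      fit <- behavior_rf(x, labels, ntree = config$ntree_grid[i],
                         mtry = mgrid[j], seed = config$seed + cell)
      surface[i, j] <- fit$oob_error
      if (fit$oob_error < best) {    # strict: earlier (smaller) cell wins ties
        best <- fit$oob_error
        config$ntree <- config$ntree_grid[i]
        config$mtry <- mgrid[j]
      }
    }
  }
  config$oob_error_surface <- surface
  config$oob_error <- best
  config
}

#' Variable importance from OOB permutation
#'
#' Mean decrease in accuracy when each predictor's out-of-bag values are
#' permuted, read from the fitted forest and sorted descending.
#'
#' @param model a [behavior_rf()].
#' @return Data frame with `feature` and `mean_decrease_accuracy`, sorted
#'   descending.
#' @export
rf_importance <- function(model) {
  stopifnot(inherits(model, "behavior_rf"))
  imp <- randomForest::importance(model$fit, type = 1)
  out <- data.frame(feature = rownames(imp),
                    mean_decrease_accuracy = imp[, 1],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_decrease_accuracy), ]
  rownames(out) <- NULL
  out
}
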