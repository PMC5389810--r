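test_that("the 70/30 split is stratified, seeded and exhaustive", {
  labels <- rep(c("a", "b", "c"), c(500, 300, 200))
  sp <- split_70_30(labels, seed = 3)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_length(intersect(sp$train, sp$test), 0)
  for (cl in c("a", "b", "c")) {
    frac <- sum(labels[sp$train] == cl) / sum(labels == cl)
    expect_gte(frac, 0.69)
    expect_lte(frac, 0.71)
  }
  expect_identical(sp, split_70_30(labels, seed = 3))
  expect_error(split_70_30(c("a", "a", "b"), seed = 1), "at least 2")
})

test_that("balanced classes split 70/30 within one item per class", {
  labels <- rep(c("a", "b", "c"), each = 33)
  sp <- split_70_30(labels, seed = 9)
  for (cl in c("a", "b", "c"))
    expect_lte(abs(sum(labels[sp$train] == cl) - 0.7 * 33), 1)
})

brute_knn <- function(train, labels, test, k) {
  classes <- sort(unique(labels))
  apply(test, 1, function(q) {
    d <- sqrt(colSums((t(train) - q)^2))
    ord <- order(d, seq_along(d))[1:k]        # distance, then train order
    votes <- table(factor(labels[ord], levels = classes))
    names(votes)[which.max(votes)]            # ties -> first class index
  })
}

test_that("KNN predictions equal a brute-force distance oracle", {
  set.seed(5)
  n <- 300
  train <- matrix(runif(3 * n), ncol = 3)
  labels <- sample(c("flapping", "sitting", "soaring"), n, replace = TRUE)
  test <- matrix(runif(3 * 120), ncol = 3)
  model <- behavior_knn(train, labels, k = 1)
  # brute oracle works in normalized space, like the model
  trn <- model$train
  tstn <- soarclass:::knn_normalize(model, test)
  for (k in c(1, 5, 29)) {
    expect_identical(predict(model, test, k = k),
                     unname(brute_knn(trn, labels, tstn, k)))
  }
})

test_that("KNN at k = 1 returns the label of an exact training match", {
  set.seed(6)
  train <- matrix(runif(60), ncol = 3)
  labels <- sample(c("p", "q"), 20, replace = TRUE)
  model <- behavior_knn(train, labels, k = 1)
  expect_identical(predict(model, train), labels)
})

test_that("the K search refines between the two best coarse values", {
  set.seed(7)
  n <- 400
  train <- matrix(rnorm(3 * n), ncol = 3)
  labels <- ifelse(train[, 1] + 0.5 * rnorm(n) > 0, "up", "down")
  test <- matrix(rnorm(3 * 200), ncol = 3)
  test_labels <- ifelse(test[, 1] > 0, "up", "down")
  res <- knn_optimize(train, labels, test, test_labels)
  top2 <- res$coarse$k[order(-res$coarse$accuracy, res$coarse$k)][1:2]
  expect_equal(res$refined$k, seq(min(top2), max(top2)))
  expect_true(res$k %in% res$refined$k)
  best <- max(res$refined$accuracy)
  expect_equal(res$refined$accuracy[res$refined$k == res$k], best)
  # tie-break: no smaller refined K does as well
  smaller <- res$refined$k < res$k
  expect_true(all(res$refined$accuracy[smaller] < best))
})

test_that("confusion metrics agree with an independent implementation", {
  skip_if_not_installed("caret")
  set.seed(12)
  lev <- c("flapping", "sitting", "soaring")
  truth <- factor(sample(lev, 300, replace = TRUE, prob = c(.3, .2, .5)),
                  levels = lev)
  pred <- truth
  flip <- sample(300, 60)
  pred[flip] <- sample(lev, 60, replace = TRUE)
  rep <- confusion_metrics(truth, pred)
  cm <- caret::confusionMatrix(factor(pred, levels = lev), truth)
  expect_equal(rep$overall_accuracy, unname(cm$overall["Accuracy"]),
               tolerance = 1e-12)
  expect_equal(rep$kappa, unname(cm$overall["Kappa"]), tolerance = 1e-12)
  for (i in seq_along(lev)) {
    byc <- cm$byClass[paste("Class:", lev[i]), ]
    expect_equal(rep$per_class$sensitivity[i],
                 unname(byc["Sensitivity"]), tolerance = 1e-12)
    expect_equal(rep$per_class$specificity[i],
                 unname(byc["Specificity"]), tolerance = 1e-12)
    expect_equal(rep$per_class$ppv[i], unname(byc["Pos Pred Value"]),
                 tolerance = 1e-12)
    expect_equal(rep$per_class$npv[i], unname(byc["Neg Pred Value"]),
                 tolerance = 1e-12)
    expect_equal(rep$per_class$prevalence[i], unname(byc["Prevalence"]),
                 tolerance = 1e-12)
    expect_equal(rep$per_class$balanced_accuracy[i],
                 unname(byc["Balanced Accuracy"]), tolerance = 1e-12)
  }
})

test_that("confusion metrics satisfy their internal identities", {
  set.seed(2)
  truth <- sample(c("a", "b", "c"), 200, replace = TRUE)
  pred <- sample(c("a", "b", "c"), 200, replace = TRUE)
  rep <- confusion_metrics(truth, pred)
  expect_equal(rep$per_class$balanced_accuracy,
               (rep$per_class$sensitivity + rep$per_class$specificity) / 2)
  expect_equal(sum(rep$per_class$prevalence), 1)
  # perfect predictions
  perf <- confusion_metrics(truth, truth)
  expect_equal(perf$overall_accuracy, 1)
  expect_equal(perf$kappa, 1)
  # zero denominators are NA, not zero
  r2 <- confusion_metrics(c("a", "a", "b"), c("a", "a", "a"))
  expect_true(is.na(r2$per_class$ppv[r2$per_class$class == "b"]))
})

test_that("kappa is invariant to class relabelling", {
  set.seed(3)
  truth <- sample(c("a", "b", "c"), 300, replace = TRUE)
  pred <- sample(c("a", "b", "c"), 300, replace = TRUE, prob = c(.5, .3, .2))
  k1 <- confusion_metrics(truth, pred)$kappa
  perm <- c(a = "c", b = "a", c = "b")
  k2 <- confusion_metrics(perm[truth], perm[pred])$kappa
  expect_equal(k1, k2, tolerance = 1e-12)
})

test_that("the RF grid search selects the OOB argmin with ordered ties", {
  segs <- small_pipeline()
  x <- segs[, feature_names()]
  # one-cell grid is selected trivially
  cfg1 <- rf_config(ntree_grid = 100, mtry_grid = 4, seed = 2)
  res1 <- optimize_rf(x, segs$label, cfg1)
  expect_equal(res1$ntree, 100L)
  expect_equal(res1$mtry, 4L)
  # small grid: the selected cell attains the surface minimum
  cfg <- rf_config(ntree_grid = c(100, 200), mtry_grid = c(2, 5, 9),
                   seed = 2)
  res <- optimize_rf(x, segs$label, cfg)
  expect_equal(res$oob_error, min(res$oob_error_surface))
  expect_equal(
    res$oob_error_surface[as.character(res$ntree),
                          as.character(res$mtry)],
    res$oob_error)
})

test_that("planted signal outranks pure noise in RF importance", {
  set.seed(20)
  n <- 400
  labels <- rep(c("one", "two"), each = n / 2)
  x <- data.frame(signal = ifelse(labels == "one", 0, 1) + rnorm(n, 0, .3),
                  noise1 = rnorm(n), noise2 = rnorm(n))
  fit <- behavior_rf(x, labels, ntree = 300, seed = 4)
  imp <- rf_importance(fit)
  expect_equal(imp$feature[1], "signal")
  expect_setequal(imp$feature, names(x))
})

test_that("the class-separating static mean outranks kurtosis on synthetic data", {
  segs <- small_pipeline()
  fit <- behavior_rf(segs[, feature_names()], segs$label, ntree = 500,
                     mtry = 7, seed = 8)
  imp <- rf_importance(fit)
  rank_of <- function(f) which(imp$feature == f)
  expect_lt(min(rank_of("mean_z"), rank_of("odba"), rank_of("sd_z")),
            min(rank_of("kurt_x"), rank_of("kurt_y")))
})

test_that("repeated k-fold CV is exact on separable data, chance on noise", {
  set.seed(30)
  n <- 120
  labels <- rep(c("a", "b", "c"), each = n / 3)
  x <- data.frame(u = as.numeric(factor(labels)) + rnorm(n, 0, 1e-3),
                  v = rnorm(n))
  cv <- repeated_kfold(x, labels, make_knn_spec(k = 3), k = 10, reps = 3,
                       seed = 5)
  expect_equal(cv$mean, 0)
  # shuffled labels: error near chance (2/3) for 3 balanced classes
  shuffled <- sample(labels)
  cv2 <- repeated_kfold(x, shuffled, make_knn_spec(k = 7), k = 10,
                        reps = 3, seed = 6)
  expect_lt(abs(cv2$mean - 2 / 3), 0.12)
  # order statistics of the summary
  expect_true(cv2$min <= cv2$q1 && cv2$q1 <= cv2$median &&
                cv2$median <= cv2$q3 && cv2$q3 <= cv2$max)
  expect_gte(cv2$mean, cv2$min)
  expect_lte(cv2$mean, cv2$max)
})
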