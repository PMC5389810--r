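#' Confusion-matrix metrics
#'
#' Builds the true-by-predicted confusion matrix and the standard
#' one-vs-rest statistics per class: sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, positive predictive value `TP/(TP+FP)`, negative
#' predictive value `TN/(TN+FN)`, prevalence `(TP+FN)/N` and balanced
#' accuracy `(sensitivity+specificity)/2`; plus overall accuracy
#' (trace/N) and Cohen's kappa `(po - pe)/(1 - pe)` with the chance
#' agreement `pe` from the marginals.  Ratios with a zero denominator are
#' reported as `NA`, not 0.
#'
#' @param true,predicted equal-length label vectors (character or factor).
#' @return An object of class `confusion_report` with fields `table`,
#'   `per_class` (data frame), `overall_accuracy`, `kappa`, `n`.
#' @export
confusion_metrics <- function(true, predicted) {
  if (length(true) != length(predicted) || length(true) == 0L)
    stop("true and predicted must be equal-length and non-empty")
  lev <- if (is.factor(true)) levels(true) else
    sort(unique(c(as.character(true), as.character(predicted))))
  true <- factor(as.character(true), levels = lev)
  predicted <- factor(as.character(predicted), levels = lev)
  tab <- table(true = true, predicted = predicted)
  n <- sum(tab)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  per <- do.call(rbind, lapply(lev, function(cl) {
    tp <- tab[cl, cl]
    fn <- sum(tab[cl, ]) - tp
    fp <- sum(tab[, cl]) - tp
    tn <- n - tp - fn - fp
    sens <- ratio(tp, tp + fn)
    spec <- ratio(tn, tn + fp)
    data.frame(class = cl,
               sensitivity = sens,
               specificity = spec,
               ppv = ratio(tp, tp + fp),
               npv = ratio(tn, tn + fn),
               prevalence = ratio(tp + fn, n),
               balanced_accuracy = (sens + spec) / 2,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else NA_real_
  structure(list(table = tab, per_class = per, overall_accuracy = po,
                 kappa = kappa, n = n),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, digits = 4, ...) {
  cat("Confusion matrix (true x predicted):\n")
  print(x$table)
  cat("\nPer-class statistics:\n")
  per <- x$per_class
  per[-1] <- lapply(per[-1], round, digits)
  print(per, row.names = FALSE)
  cat(sprintf("\nOverall accuracy: %.4f   Kappa: %.4f   (n = %d)\n",
              x$overall_accuracy, x$kappa, x$n))
  invisible(x)
}

#' Balanced accuracy from sensitivity and specificity
#' @param sensitivity,specificity per-class rates in `[0, 1]`.
#' @return `(sensitivity + specificity) / 2`.
#' @export
balanced_accuracy <- function(sensitivity, specificity) {
  (sensitivity + specificity) / 2
}

#' Negative predictive value from sensitivity, specificity and prevalence
#'
#' Bayes identity:
#' `npv = spec (1 - prev) / ((1 - sens) prev + spec (1 - prev))`.
#'
#' @param sensitivity,specificity,prevalence per-class rates in `[0, 1]`.
#' @return The negative predictive value.
#' @export
npv_from_rates <- function(sensitivity, specificity, prevalence) {
  num <- specificity * (1 - prevalence)
  num / ((1 - sensitivity) * prevalence + num)
}
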