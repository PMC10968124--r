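#' Summarize repeated optimizer runs
#'
#' Computes the run-level statistics reported for stochastic wrapper
#' searches: mean best fitness across runs, mean accuracy of the best
#' subsets (`1 - error`), and the mean feature-selection ratio (selected
#' size over total features).
#'
#' @param results Non-empty list of `bgoa_result` objects sharing one
#'   feature count.
#' @param total_features Total feature count `D`.
#' @return An object of class `experiment_summary` with fields
#'   `mean_fitness`, `mean_accuracy`, `mean_subset_ratio`, `n_runs`,
#'   `per_run`.
#' @export
run_statistics <- function(results, total_features) {
  if (length(results) == 0L) stop("`results` must be a non-empty list")
  lens <- vapply(results, function(r) length(r$best_mask), integer(1))
  if (any(lens != total_features)) {
    stop("all results must share `total_features` dimensions")
  }
  fitness <- vapply(results, function(r) r$best_fitness, numeric(1))
  errors <- vapply(results, function(r) r$best_error, numeric(1))
  sizes <- vapply(results, function(r) r$subset_size, numeric(1))
  structure(
    list(
      mean_fitness = mean(fitness),
      mean_accuracy = mean(1 - errors),
      mean_subset_ratio = mean(sizes / total_features),
      n_runs = length(results),
      per_run = results
    ),
    class = "experiment_summary"
  )
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat(sprintf("%d runs: mean fitness %.4f, mean accuracy %.4f, mean subset ratio %.4f\n",
              x$n_runs, x$mean_fitness, x$mean_accuracy, x$mean_subset_ratio))
  invisible(x)
}

#' Confusion-matrix classification indices
#'
#' From the four counts of a binary confusion matrix computes the true
#' positive rate (recall), positive predictive value (precision), true
#' negative rate (specificity), negative predictive value and accuracy.
#' An index whose denominator is zero is reported as `NA` (undefined)
#' rather than silently set to 0.
#'
#' @param tp,fp,tn,fn Non-negative counts; alternatively `tp` may be a
#'   list with those four named elements.
#' @return Named numeric vector `c(tpr, ppv, tnr, npv, acc)`.
#' @examples
#' confusion_metrics(tp = 3, fp = 1, tn = 4, fn = 1)
#' @export
confusion_metrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.list(tp)) {
    counts <- tp
    tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  }
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn >= 1)
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  c(
    tpr = safe(tp, tp + fn),
    ppv = safe(tp, tp + fp),
    tnr = safe(tn, tn + fp),
    npv = safe(tn, tn + fn),
    acc = (tp + tn) / (tp + tn + fp + fn)
  )
}

#' Classification indices from labels
#'
#' For two classes the second factor level is taken as the positive
#' class and the indices are exactly the binary definitions.  For more
#' classes each class is scored one-vs-rest and the indices are
#' macro-averaged, with undefined (zero-denominator) values excluded
#' from the average.
#'
#' @param truth,predicted Label vectors of equal length; coerced to a
#'   common factor.
#' @param positive Optional positive-class label for the binary case.
#' @return Named numeric vector `c(tpr, ppv, tnr, npv, acc)`.
#' @export
classification_indices <- function(truth, predicted, positive = NULL) {
  lev <- union(levels(as.factor(truth)), levels(as.factor(predicted)))
  truth <- factor(truth, levels = lev)
  predicted <- factor(predicted, levels = lev)
  stopifnot(length(truth) == length(predicted))
  one_vs_rest <- function(pos) {
    confusion_metrics(
      tp = sum(truth == pos & predicted == pos),
      fp = sum(truth != pos & predicted == pos),
      tn = sum(truth != pos & predicted != pos),
      fn = sum(truth == pos & predicted != pos)
    )
  }
  if (length(lev) == 2L) {
    if (is.null(positive)) positive <- lev[2L]
    one_vs_rest(positive)
  } else {
    per_class <- vapply(lev, one_vs_rest, numeric(5))
    out <- rowMeans(per_class, na.rm = TRUE)
    out[is.nan(out)] <- NA_real_
    # overall accuracy rather than macro-averaged one-vs-rest accuracy
    out["acc"] <- mean(truth == predicted)
    out
  }
}
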