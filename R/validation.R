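#' Random train/validation split
#'
#' Disjoint, exhaustive partition of the records, sized either by a
#' validation fraction (the survey analysis used a randomly selected 40%
#' subset) or by an exact validation count.
#'
#' @param records data frame of records.
#' @param validation_fraction fraction held out (used if
#'   `validation_count` is `NULL`).
#' @param validation_count exact number of validation records; overrides the
#'   fraction.
#' @param seed integer seed; the partition is deterministic given the seed.
#' @return list with data frames `train` and `validation`.
#' @export
split_records <- function(records, validation_fraction = 0.4,
                          validation_count = NULL, seed = 1L) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  n <- nrow(records)
  n_val <- if (!is.null(validation_count)) {
    as.integer(validation_count)
  } else {
    if (validation_fraction <= 0 || validation_fraction >= 1) {
      stop("validation_fraction must be in (0, 1)", call. = FALSE)
    }
    as.integer(round(n * validation_fraction))
  }
  if (n_val < 1 || n_val >= n) {
    stop("split would leave an empty side (validation n = ", n_val, ")",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  idx <- sample.int(n, n_val)
  list(train = records[-idx, , drop = FALSE],
       validation = records[idx, , drop = FALSE])
}

#' Predicted treatment probabilities
#'
#' Plug-in prediction: the 3PL response probability at each record's
#' standardised covariate under the supplied (typically posterior-mean)
#' parameters.
#'
#' @param records data frame with column `x`.
#' @param item an [item_parameters] object.
#' @param trait a [trait_model] object (fixed-effect variants for
#'   prediction on new records).
#' @return numeric vector of probabilities, one per record.
#' @export
predict_treatment <- function(records, item, trait) {
  theta <- latent_trait(trait$alpha, trait$beta, records$x)
  response_probability(item, theta)
}

#' Confusion matrix at a probability cut-off
#'
#' A record is classified as treated when its predicted probability is
#' greater than or equal to the cut-off (0.65 in the survey validation).
#'
#' @param probabilities predicted probabilities.
#' @param truths observed 0/1 responses, same length.
#' @param cutoff classification threshold in (0, 1).
#' @return an object of class `confusion_matrix`: list with counts `tp`,
#'   `fp`, `tn`, `fn`.
#' @export
classify <- function(probabilities, truths, cutoff = 0.65) {
  if (length(probabilities) != length(truths)) {
    stop("probabilities and truths must have equal length", call. = FALSE)
  }
  stopifnot(cutoff > 0, cutoff < 1, all(truths %in% c(0, 1)))
  pred <- probabilities >= cutoff
  confusion_matrix(tp = sum(pred & truths == 1),
                   fp = sum(pred & truths == 0),
                   tn = sum(!pred & truths == 0),
                   fn = sum(!pred & truths == 1))
}

#' @rdname classify
#' @param tp,fp,tn,fn non-negative counts.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Confusion matrix: TP %d  FP %d  TN %d  FN %d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' sensitivity = TP/(TP+FN); specificity = TN/(TN+FP);
#' accuracy = (TP+TN)/total.
#'
#' @param cm a [confusion_matrix].
#' @return list with `sensitivity`, `specificity`, `accuracy`.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tp + cm$fn == 0 || cm$tn + cm$fp == 0) {
    stop("metrics undefined: a class margin is empty", call. = FALSE)
  }
  total <- cm$tp + cm$fp + cm$tn + cm$fn
  list(sensitivity = cm$tp / (cm$tp + cm$fn),
       specificity = cm$tn / (cm$tn + cm$fp),
       accuracy = (cm$tp + cm$tn) / total)
}

#' ROC curve and AUC
#'
#' Thresholds are the sorted unique scores with infinite sentinels;
#' classification is score >= threshold; AUC by trapezoidal integration,
#' which equals the Mann-Whitney concordance probability with ties counted
#' one half.
#'
#' @param probabilities predicted scores.
#' @param truths observed 0/1 responses.
#' @return an object of class `roc_result`: data frame `curve` with columns
#'   `threshold`, `sensitivity`, `specificity`, and scalar `auc`.
#' @export
roc <- function(probabilities, truths) {
  if (length(probabilities) != length(truths)) {
    stop("probabilities and truths must have equal length", call. = FALSE)
  }
  stopifnot(all(truths %in% c(0, 1)))
  n_pos <- sum(truths == 1)
  n_neg <- sum(truths == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC requires both classes present", call. = FALSE)
  }
  thr <- c(Inf, sort(unique(probabilities), decreasing = TRUE), -Inf)
  sens <- vapply(thr, function(t)
    sum(probabilities >= t & truths == 1) / n_pos, numeric(1))
  spec <- vapply(thr, function(t)
    sum(probabilities < t & truths == 0) / n_neg, numeric(1))
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  structure(list(curve = data.frame(threshold = thr, sensitivity = sens,
                                    specificity = spec),
                 auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f over %d thresholds\n",
              x$auc, nrow(x$curve)))
  invisible(x)
}
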