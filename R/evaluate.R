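# Evaluation: confusion counts, sensitivity, false-positive rate (per
# sample and per monitored hour), accuracy, seizure prediction time, and
# stratified k-fold cross-validation.

#' Confusion counts
#'
#' Binary counts (TP/FP/TN/FN, positive class = 1) or the full n x n count
#' matrix for multiclass labels.
#' @param truth,pred integer labels (0-based)
#' @param n_classes number of classes
#' @export
confusion_counts <- function(truth, pred, n_classes = 2L) {
  stopifnot(length(truth) == length(pred))
  m <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(truth))
    m[truth[i] + 1L, pred[i] + 1L] <- m[truth[i] + 1L, pred[i] + 1L] + 1L
  if (n_classes == 2L) {
    structure(list(TP = m[2, 2], FP = m[1, 2], TN = m[1, 1], FN = m[2, 1],
                   matrix = m), class = "confusion_counts")
  } else {
    structure(list(matrix = m), class = "confusion_counts")
  }
}

#' Sensitivity (recall of the positive class): TP / (TP + FN)
#' @param c a binary [confusion_counts()]
#' @export
sensitivity <- function(c) {
  if (c$TP + c$FN == 0) stop("sensitivity undefined: no positive samples")
  c$TP / (c$TP + c$FN)
}

#' False-positive rate
#'
#' Per-sample rate FP / (TN + FP); when `hours` is given, additionally the
#' event rate per monitored hour: consecutive positive negative-class
#' samples within `refractory_s` seconds are merged into one false-alarm
#' event, and the event count is divided by the monitored hours.
#' @param c a binary [confusion_counts()]
#' @param hours monitored negative-class (interictal) hours
#' @param times_s timestamps of the false-positive samples (needed for event
#'   merging; without them each false-positive sample counts as an event)
#' @param refractory_s merge window in seconds
#' @return list(per_sample, per_hour, n_events)
#' @export
false_positive_rate <- function(c, hours = NULL, times_s = NULL,
                                refractory_s = 120) {
  if (c$TN + c$FP == 0) stop("FPR undefined: no negative samples")
  per_sample <- c$FP / (c$TN + c$FP)
  per_hour <- NULL; n_events <- NULL
  if (!is.null(hours)) {
    if (hours <= 0) stop("hours must be positive")
    if (is.null(times_s)) {
      n_events <- c$FP
    } else {
      ts <- sort(times_s)
      n_events <- if (length(ts) == 0) 0L else
        1L + sum(diff(ts) > refractory_s)
    }
    per_hour <- n_events / hours
  }
  list(per_sample = per_sample, per_hour = per_hour, n_events = n_events)
}

#' Accuracy: correct / total (trace over total for multiclass)
#' @param c a [confusion_counts()]
#' @export
accuracy <- function(c) {
  m <- c$matrix
  if (sum(m) == 0) stop("accuracy undefined: no samples")
  sum(diag(m)) / sum(m)
}

#' Seizure prediction time
#'
#' The prediction time of an onset is the interval between the first
#' positively classified preictal sample and the annotated onset. An event
#' counts as predicted iff at least one of its preictal samples is positive;
#' otherwise it is missed and its time is undefined.
#' @param scores numeric scores of the event's preictal samples, time order
#' @param times_s sample timestamps (seconds), all before the onset
#' @param onset_s onset time (seconds)
#' @param threshold scores strictly above it are positive
#' @return list(predicted, time_min)
#' @export
prediction_time <- function(scores, times_s, onset_s, threshold = 0.5) {
  stopifnot(length(scores) == length(times_s))
  if (any(times_s >= onset_s)) stop("all samples must precede the onset")
  ord <- order(times_s)
  pos <- which(scores[ord] > threshold)
  if (length(pos) == 0) return(list(predicted = FALSE, time_min = NA_real_))
  list(predicted = TRUE,
       time_min = (onset_s - times_s[ord][pos[1]]) / 60)
}

#' Stratified k-fold split
#'
#' Disjoint folds covering all samples, stratified by class; seeded.
#' @param labels class labels
#' @param k number of folds
#' @param seed RNG seed
#' @return list of integer index vectors (test sets), length `k`
#' @export
kfold_split <- function(labels, k = 10L, seed = 1L) {
  n <- length(labels)
  if (n < k) stop("fewer samples than folds")
  tab <- table(labels)
  if (any(tab < k))
    stop("class with fewer than k members; use a smaller k")
  set.seed(seed)
  folds <- vector("list", k)
  for (cl in names(tab)) {
    idx <- sample(which(labels == cl))
    asg <- rep(seq_len(k), length.out = length(idx))
    for (f in seq_len(k))
      folds[[f]] <- c(folds[[f]], idx[asg == f])
  }
  lapply(folds, sort)
}

#' Evaluate a fitted model on a labeled test set
#'
#' Computes the confusion matrix, accuracy, and (for the binary task)
#' sensitivity, per-sample and per-hour FPR, and per-event prediction times
#' from the dataset's timing metadata.
#' @param model a [seizcast_model()]
#' @param dataset a [spectral_dataset()] with pixels
#' @param idx optional test indices (default: all images)
#' @param threshold positive-probability threshold for the binary task
#' @return list of class `eval_report`
#' @export
evaluate_model <- function(model, dataset, idx = NULL, threshold = 0.5) {
  if (is.null(idx)) idx <- seq_len(nrow(dataset$meta))
  meta <- dataset$meta[idx, , drop = FALSE]
  probs <- predict(model, dataset$pixels[, , , idx, drop = FALSE])
  pred <- max.col(probs) - 1L
  cc <- confusion_counts(meta$y, pred, n_classes = model$n_classes)
  rep <- list(confusion = cc, accuracy = accuracy(cc), n = nrow(meta))
  if (model$n_classes == 2L) {
    rep$sensitivity <- sensitivity(cc)
    neg <- meta$y == 0L
    hours <- sum(neg) * dataset$window_s / 3600
    fp_times <- meta$t_start_s[neg & pred == 1L]
    fpr <- false_positive_rate(cc, hours = hours, times_s = fp_times)
    rep$fpr_per_sample <- fpr$per_sample
    rep$fpr_per_hour <- fpr$per_hour
    # per-event prediction times over preictal events
    ev <- unique(meta[meta$y == 1L, c("patient", "event", "onset_s")])
    times <- numeric(0); predicted <- logical(0)
    for (r in seq_len(nrow(ev))) {
      sel <- meta$y == 1L & meta$patient == ev$patient[r] &
        meta$event == ev$event[r]
      pt <- prediction_time(probs[sel, 2], meta$t_start_s[sel],
                            ev$onset_s[r], threshold)
      predicted <- c(predicted, pt$predicted)
      times <- c(times, pt$time_min)
    }
    rep$prediction_times_min <- times
    rep$events_predicted <- predicted
    rep$mean_prediction_time_min <-
      if (any(predicted)) mean(times[predicted]) else NA_real_
  }
  class(rep) <- "eval_report"
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d, accuracy %.3f\n", x$n, x$accuracy))
  if (!is.null(x$sensitivity))
    cat(sprintf("  sensitivity %.3f, FPR %.3f/sample, %.3f/h, mean prediction time %.1f min\n",
                x$sensitivity, x$fpr_per_sample, x$fpr_per_hour,
                x$mean_prediction_time_min))
  invisible(x)
}
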