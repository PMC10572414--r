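# Hybrid training loss (equal-weight cross-entropy + Dice) and the
# six-metric evaluation suite with fold aggregation and run comparison.

#' Hybrid segmentation loss
#'
#' Computes `total = 0.5 * ce + 0.5 * dice_loss` where
#' `ce = -(1/N) * sum_ij p_ij log q_ij` (classes i, pixels j) and
#' `dice_loss = 1 - (2 * sum(y * q_fg) + alpha) / (sum(y) + sum(q_fg) + alpha)`
#' on the foreground channel. The smoothing term `alpha` keeps the Dice term
#' defined when prediction and target are both empty (`y = q = 0` gives
#' `dice_loss = 0`).
#'
#' @param pred_probs H x W x 2 array of per-pixel class probabilities
#'   (channels sum to 1 within 1e-4).
#' @param target_onehot H x W x 2 one-hot ground truth.
#' @param alpha Dice smoothing constant (> 0), default 1.
#' @return A list with `total`, `ce` and `dice` (the Dice loss component).
#' @export
#' @examples
#' p <- array(c(1, 0), c(1, 1, 2))  # certain background
#' hybrid_loss(p, p)$total          # 0 up to the clipping epsilon
hybrid_loss <- function(pred_probs, target_onehot, alpha = 1) {
  if (!identical(dim(pred_probs), dim(target_onehot)) ||
      length(dim(pred_probs)) != 3L || dim(pred_probs)[3] != 2L) {
    stop("pred_probs and target_onehot must both be H x W x 2", call. = FALSE)
  }
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  sums <- pred_probs[, , 1] + pred_probs[, , 2]
  if (max(abs(sums - 1)) > 1e-4) {
    stop("pred_probs must be normalized per pixel (tolerance 1e-4)",
         call. = FALSE)
  }
  n <- prod(dim(pred_probs)[1:2])
  q <- pmin(pmax(pred_probs, 1e-7), 1 - 1e-7)
  ce <- -sum(target_onehot * log(q)) / n
  y <- target_onehot[, , 2]
  qf <- pred_probs[, , 2]
  dice_loss <- 1 - (2 * sum(y * qf) + alpha) / (sum(y) + sum(qf) + alpha)
  list(total = 0.5 * ce + 0.5 * dice_loss, ce = ce, dice = dice_loss)
}

#' Six-metric evaluation of a binary segmentation
#'
#' Counts TP/FP/FN/TN with foreground (cavity) as the positive class and
#' derives precision, recall (sensitivity), specificity, Dice coefficient
#' `2TP / (2TP + FP + FN)`, Jaccard index `TP / (TP + FP + FN)`, and two
#' accuracy variants: overall pixel accuracy `(TP + TN) / N` (the headline
#' `accuracy` value) and the class-average form
#' `0.5 * (TP / (TP + FN) + TN / (TN + FP))` (`accuracy_class_avg`).
#'
#' When a metric's denominator is zero it is reported as 1 if the
#' corresponding error counts are also zero, else 0; such records are flagged
#' via the `degenerate` field.
#'
#' @param pred_mask,gt_mask Binary H x W matrices of equal size.
#' @return A `metrics_record` list with the six metrics, both accuracy
#'   variants, and the raw counts.
#' @export
compute_metrics <- function(pred_mask, gt_mask) {
  if (!identical(dim(pred_mask), dim(gt_mask))) {
    stop("mask dimensions differ", call. = FALSE)
  }
  if (!all(pred_mask %in% c(0, 1)) || !all(gt_mask %in% c(0, 1))) {
    stop("masks must be strictly binary", call. = FALSE)
  }
  p <- pred_mask == 1
  g <- gt_mask == 1
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g); tn <- sum(!p & !g)
  safe <- function(num, den, err) {
    if (den == 0) { if (err == 0) 1 else 0 } else num / den
  }
  rec <- list(
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    accuracy_class_avg = 0.5 * (safe(tp, tp + fn, fn) + safe(tn, tn + fp, fp)),
    dice = safe(2 * tp, 2 * tp + fp + fn, fp + fn),
    precision = safe(tp, tp + fp, fp),
    recall = safe(tp, tp + fn, fn),
    specificity = safe(tn, tn + fp, fp),
    jaccard = safe(tp, tp + fp + fn, fp + fn),
    TP = tp, FP = fp, FN = fn, TN = tn,
    degenerate = (tp + fp == 0) || (tp + fn == 0) || (tn + fp == 0)
  )
  structure(rec, class = "metrics_record")
}

metric_names <- function() {
  c("accuracy", "dice", "precision", "recall", "specificity", "jaccard")
}

#' Convert a list of per-fold metric records to a data frame
#'
#' @param records List of `metrics_record` objects.
#' @return Data frame, one row per fold.
#' @export
metrics_to_df <- function(records) {
  do.call(rbind, lapply(seq_along(records), function(i) {
    r <- records[[i]]
    data.frame(fold = i, accuracy = r$accuracy,
               accuracy_class_avg = r$accuracy_class_avg, dice = r$dice,
               precision = r$precision, recall = r$recall,
               specificity = r$specificity, jaccard = r$jaccard,
               TP = r$TP, FP = r$FP, FN = r$FN, TN = r$TN)
  }))
}

#' Aggregate per-fold metrics into mean and standard deviation
#'
#' @param records List of at least two `metrics_record` objects (or a data
#'   frame from [metrics_to_df()]).
#' @return Data frame with columns `metric`, `mean`, `sd` (sample SD,
#'   n - 1 denominator).
#' @export
aggregate_folds <- function(records) {
  df <- if (is.data.frame(records)) records else metrics_to_df(records)
  if (nrow(df) < 2L) stop("need at least 2 folds", call. = FALSE)
  nms <- metric_names()
  data.frame(
    metric = nms,
    mean = vapply(nms, function(m) mean(df[[m]]), numeric(1)),
    sd = vapply(nms, function(m) stats::sd(df[[m]]), numeric(1)),
    row.names = NULL
  )
}

#' Compare two cross-validated runs metric by metric
#'
#' For each of the six metrics, reports the mean improvement of run `a` over
#' run `b` and a two-sided Welch two-sample t-test p-value. When both runs
#' have zero variance the t statistic is undefined; the p-value is reported
#' as 1 for identical samples (flagged via `zero_variance`).
#'
#' @param a,b Per-fold metrics of the two runs (lists of `metrics_record` or
#'   data frames from [metrics_to_df()]), equal fold counts.
#' @return Data frame with columns `metric`, `mean_a`, `mean_b`, `delta`,
#'   `p_value`, `zero_variance`.
#' @export
compare_runs <- function(a, b) {
  da <- if (is.data.frame(a)) a else metrics_to_df(a)
  db <- if (is.data.frame(b)) b else metrics_to_df(b)
  if (nrow(da) != nrow(db)) stop("fold counts differ", call. = FALSE)
  if (nrow(da) < 2L) stop("need at least 2 folds", call. = FALSE)
  rows <- lapply(metric_names(), function(m) {
    xa <- da[[m]]; xb <- db[[m]]
    zv <- stats::var(xa) == 0 && stats::var(xb) == 0
    p <- if (zv) {
      if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else 0
    } else {
      stats::t.test(xa, xb, var.equal = FALSE)$p.value
    }
    data.frame(metric = m, mean_a = mean(xa), mean_b = mean(xb),
               delta = mean(xa) - mean(xb), p_value = p, zero_variance = zv)
  })
  do.call(rbind, rows)
}

#' Write per-fold metrics to CSV
#'
#' @param records List of `metrics_record` objects or a data frame.
#' @param path Output CSV path.
#' @param model Optional model label added as a column.
#' @export
write_metrics_csv <- function(records, path, model = NULL) {
  df <- if (is.data.frame(records)) records else metrics_to_df(records)
  if (!is.null(model)) df <- cbind(model = model, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
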