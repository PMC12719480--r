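#' Dice coefficient between two binary masks
#'
#' `Dice = 2|X intersect Y| / (|X| + |Y|)`.  When both masks are empty the
#' overlap is vacuously perfect; the conventional value 1 is returned with a
#' warning so dataset-level code can surface the convention.
#'
#' @param x,y binary masks (any numeric/logical arrays of equal shape;
#'   positive means > 0).
#' @return Scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(x, y) {
  check_that(length(x) == length(y), "masks must have equal shape")
  xb <- as.vector(x) > 0
  yb <- as.vector(y) > 0
  sx <- sum(xb)
  sy <- sum(yb)
  if (sx + sy == 0) {
    warning("both masks empty; Dice defined as 1 by convention")
    return(1.0)
  }
  2 * sum(xb & yb) / (sx + sy)
}

#' Jaccard index (IoU) between two binary masks
#'
#' `Jaccard = |X intersect Y| / |X union Y|`; related to Dice by
#' `J = D / (2 - D)`.  Both-empty convention: 1 with a warning.
#'
#' @inheritParams dice_coefficient
#' @export
jaccard_index <- function(x, y) {
  check_that(length(x) == length(y), "masks must have equal shape")
  xb <- as.vector(x) > 0
  yb <- as.vector(y) > 0
  u <- sum(xb | yb)
  if (u == 0) {
    warning("both masks empty; Jaccard defined as 1 by convention")
    return(1.0)
  }
  sum(xb & yb) / u
}

#' Confusion counts
#' @param tp,fp,tn,fn non-negative integers.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  check_that(all(c(tp, fp, tn, fn) >= 0), "confusion counts must be non-negative")
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn), class = "confusion_counts")
}

#' Sensitivity and specificity from confusion counts
#'
#' `Sensitivity = TP / (TP + FN)`, `Specificity = TN / (TN + FP)`.
#'
#' @param counts a [confusion_counts()].
#' @return List with `sensitivity` and `specificity`.
#' @export
sensitivity_specificity <- function(counts) {
  if (counts$tp + counts$fn == 0) {
    abort_arg("sensitivity undefined: no positive ground truth (TP + FN = 0)")
  }
  if (counts$tn + counts$fp == 0) {
    abort_arg("specificity undefined: no negative ground truth (TN + FP = 0)")
  }
  list(
    sensitivity = counts$tp / (counts$tp + counts$fn),
    specificity = counts$tn / (counts$tn + counts$fp)
  )
}

#' Area under the ROC curve
#'
#' Computed via the rank (Mann-Whitney) statistic with midranks for ties:
#' equals `P(score+ > score-) + 0.5 * P(tie)`.
#'
#' @param scores numeric scores (larger = more positive).
#' @param labels binary labels (0/1, logical, or a factor with 2 levels whose
#'   second level is positive).
#' @export
auc_roc <- function(scores, labels) {
  check_that(length(scores) == length(labels), "scores and labels must align")
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  pos <- as.vector(labels) > 0
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    abort_arg("AUC undefined: both classes must be present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Boundary pixels of a binary mask
#'
#' A boundary pixel is a positive pixel with at least one non-positive
#' 4-neighbor; pixels on the image edge count their outside neighbors as
#' non-positive.
#'
#' @param mask H x W binary matrix.
#' @return Two-column matrix of 0-based `(row, col)` coordinates.
#' @export
boundary_pixels <- function(mask) {
  m <- (mask > 0) * 1L
  H <- nrow(m)
  W <- ncol(m)
  pad <- matrix(0L, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- m
  up <- pad[1:H, 2:(W + 1L)]
  dn <- pad[3:(H + 2L), 2:(W + 1L)]
  lf <- pad[2:(H + 1L), 1:W]
  rt <- pad[2:(H + 1L), 3:(W + 2L)]
  bnd <- m == 1L & (up == 0L | dn == 0L | lf == 0L | rt == 0L)
  idx <- which(bnd, arr.ind = TRUE)
  cbind(row = idx[, 1L] - 1L, col = idx[, 2L] - 1L)
}

directed_nn_distances <- function(from, to, spacing) {
  # nearest-neighbor Euclidean distances from each `from` point to the `to` set
  fr <- sweep(from, 2L, spacing, `*`)
  tr <- sweep(to, 2L, spacing, `*`)
  d2 <- outer(rowSums(fr^2), rep(1, nrow(tr))) +
    outer(rep(1, nrow(fr)), rowSums(tr^2)) -
    2 * fr %*% t(tr)
  sqrt(pmax(apply(d2, 1L, min), 0))
}

#' 95th-percentile Hausdorff distance between two masks
#'
#' Boundary pixels of each mask are extracted, nearest-neighbor Euclidean
#' distances are computed in both directions (scaled by `spacing`), and the
#' 95th percentile of each direction is taken with linear interpolation
#' between order statistics (R's default quantile type 7).  The result is the
#' maximum of the two directed values.
#'
#' @param x,y binary masks of equal shape, both non-empty.
#' @param spacing physical pixel spacing `c(row, col)` (e.g. mm); default 1.
#' @param percentile quantile level, default 0.95.
#' @export
hd95 <- function(x, y, spacing = c(1, 1), percentile = 0.95) {
  check_that(all(dim(x) == dim(y)), "masks must have equal shape")
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  if (sum(x > 0) == 0 || sum(y > 0) == 0) {
    abort_arg("hd95 undefined: both masks must be non-empty")
  }
  bx <- boundary_pixels(x)
  by <- boundary_pixels(y)
  dxy <- directed_nn_distances(bx, by, spacing)
  dyx <- directed_nn_distances(by, bx, spacing)
  max(stats::quantile(dxy, percentile, names = FALSE, type = 7),
      stats::quantile(dyx, percentile, names = FALSE, type = 7))
}

#' Evaluate a set of predictions against ground truth
#'
#' Segmentation metrics (Dice, Jaccard, HD95) are macro-averaged per sample;
#' pixel-level sensitivity/specificity are pooled over all pixels of all
#' samples.  Samples where HD95 is undefined (an empty predicted or true
#' mask) are skipped for HD95 and counted in `hd95_skipped`; an empty
#' prediction against a non-empty truth scores Dice and Jaccard 0.  When
#' classifier outputs are supplied, classification accuracy, AUC-ROC, and the
#' classification confusion matrix (over gate decisions) are reported as
#' well.
#'
#' @param predictions list of predicted binary masks.
#' @param ground_truths list of true binary masks (same length/shapes).
#' @param class_probs optional numeric vector of tumor-class probabilities,
#'   one per sample.
#' @param class_labels optional true labels (`"tumor"`/`"non_tumor"` or 0/1).
#' @param gate_tau threshold used to turn `class_probs` into decisions.
#' @param spacing pixel spacing passed to [hd95()].
#' @return A `metrics_report` list.
#' @export
evaluate_dataset <- function(predictions, ground_truths,
                             class_probs = NULL, class_labels = NULL,
                             gate_tau = 0.5, spacing = c(1, 1)) {
  n <- length(predictions)
  check_that(n == length(ground_truths) && n >= 1,
             "predictions and ground truths must be non-empty and aligned")
  if (!is.null(class_probs)) {
    check_that(length(class_probs) == n, "class_probs misaligned with predictions")
    check_that(!is.null(class_labels) && length(class_labels) == n,
               "class_labels required alongside class_probs")
  }
  dice <- jac <- hd <- rep(NA_real_, n)
  tp <- fp <- tn <- fn <- 0
  for (i in seq_len(n)) {
    p <- predictions[[i]] > 0
    g <- ground_truths[[i]] > 0
    check_that(length(p) == length(g), "mask shapes misaligned")
    if (sum(p) + sum(g) == 0) {
      dice[i] <- 1; jac[i] <- 1
    } else {
      dice[i] <- 2 * sum(p & g) / (sum(p) + sum(g))
      jac[i] <- sum(p & g) / sum(p | g)
    }
    if (sum(p) > 0 && sum(g) > 0) {
      hd[i] <- hd95(p, g, spacing = spacing)
    }
    tp <- tp + sum(p & g)
    fp <- fp + sum(p & !g)
    tn <- tn + sum(!p & !g)
    fn <- fn + sum(!p & g)
  }
  pix_conf <- confusion_counts(tp = tp, fp = fp, tn = tn, fn = fn)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_

  cls <- NULL
  if (!is.null(class_probs)) {
    truth <- if (is.character(class_labels)) as.integer(class_labels == "tumor")
             else as.integer(class_labels > 0)
    decision <- as.integer(class_probs >= gate_tau)
    cc <- confusion_counts(
      tp = sum(decision == 1 & truth == 1),
      fp = sum(decision == 1 & truth == 0),
      tn = sum(decision == 0 & truth == 0),
      fn = sum(decision == 0 & truth == 1)
    )
    cls <- list(
      accuracy = mean(decision == truth),
      auc_roc = if (length(unique(truth)) == 2) auc_roc(class_probs, truth) else NA_real_,
      confusion = cc
    )
  }
  structure(
    list(
      dice = mean(dice),
      jaccard = mean(jac),
      sensitivity = sens,
      specificity = spec,
      auc_roc = if (!is.null(cls)) cls$auc_roc else NA_real_,
      hd95 = if (all(is.na(hd))) NA_real_ else mean(hd, na.rm = TRUE),
      hd95_skipped = sum(is.na(hd)),
      confusion = pix_conf,
      classification = cls,
      per_sample = data.frame(dice = dice, jaccard = jac, hd95 = hd),
      n_samples = n
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Segmentation metrics over", x$n_samples, "samples\n")
  cat(sprintf("  Dice        %.4f\n", x$dice))
  cat(sprintf("  Jaccard     %.4f\n", x$jaccard))
  cat(sprintf("  Sensitivity %.4f (pixel-pooled)\n", x$sensitivity))
  cat(sprintf("  Specificity %.4f (pixel-pooled)\n", x$specificity))
  if (!is.na(x$hd95)) {
    cat(sprintf("  HD95        %.3f (%d samples skipped)\n", x$hd95, x$hd95_skipped))
  }
  if (!is.null(x$classification)) {
    cat(sprintf("Classification: accuracy %.4f, AUC-ROC %.4f\n",
                x$classification$accuracy, x$classification$auc_roc))
  }
  invisible(x)
}

#' Write a metrics report as JSON and one-row CSV
#'
#' The CSV row follows the column schema
#' `dice, jaccard, sensitivity, specificity, hd95`.
#'
#' @param report a `metrics_report`.
#' @param path_json,path_csv output files (either may be `NULL`).
#' @export
write_metrics_report <- function(report, path_json = NULL, path_csv = NULL) {
  if (!is.null(path_json)) {
    jsonlite::write_json(unclass_deep(report[setdiff(names(report), "per_sample")]),
                         path_json, auto_unbox = TRUE, digits = NA, na = "null")
  }
  if (!is.null(path_csv)) {
    row <- data.frame(dice = report$dice, jaccard = report$jaccard,
                      sensitivity = report$sensitivity,
                      specificity = report$specificity, hd95 = report$hd95)
    utils::write.csv(row, path_csv, row.names = FALSE)
  }
  invisible(report)
}
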