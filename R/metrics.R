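#' Pixel confusion matrix between two class masks
#'
#' @param truth,pred integer matrices of class labels with identical
#'   dimensions.
#' @param num_classes total number of classes K + 1 (background included);
#'   inferred from the data when `NULL`.
#' @return `confusion_matrix`: an integer (K+1) x (K+1) table, rows =
#'   truth class, columns = predicted class.
#' @export
confusion <- function(truth, pred, num_classes = NULL) {
  truth <- as_class_mask(truth)
  pred <- as_class_mask(pred)
  if (!all(dim(truth) == dim(pred))) stop("truth and pred shapes differ")
  if (is.null(num_classes)) num_classes <- max(truth, pred) + 1L
  idx <- as.integer(truth) * num_classes + as.integer(pred) + 1L
  cm <- matrix(tabulate(idx, nbins = num_classes^2),
               num_classes, num_classes, byrow = TRUE)
  dimnames(cm) <- list(truth = 0:(num_classes - 1L),
                       pred = 0:(num_classes - 1L))
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Segmentation metrics from a confusion matrix
#'
#' Per class i: TP = cm\[i,i\], FP = column sum - TP, FN = row sum - TP.
#' MIoU is the mean over the K+1 classes of TP / (TP + FP + FN). Precision
#' and recall are averaged over classes ("macro", default) or weighted by
#' truth pixel frequency ("weighted"); the reported F1 is the harmonic
#' mean of the reported precision and recall. A class with an empty
#' denominator contributes 0 and raises a warning rather than NaN, so the
#' metrics stay defined on degenerate masks.
#'
#' @param cm a `confusion_matrix` (or plain square count matrix).
#' @param average "macro" or "weighted".
#' @return list with `miou`, `precision`, `recall`, `f1` and a
#'   `per_class` data.frame of iou/precision/recall/f1.
#' @export
seg_metrics <- function(cm, average = c("macro", "weighted")) {
  average <- match.arg(average)
  cm <- unclass(cm)
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  if (sum(cm) == 0) stop("confusion matrix is empty")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe <- function(num, den, what) {
    bad <- den == 0
    if (any(bad))
      warning(sprintf("%s undefined for %d class(es); contributing 0",
                      what, sum(bad)))
    ifelse(bad, 0, num / den)
  }
  iou <- safe(tp, tp + fp + fn, "IoU")
  prec <- safe(tp, tp + fp, "precision")
  rec <- safe(tp, tp + fn, "recall")
  f1c <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  if (average == "macro") {
    miou <- mean(iou); p <- mean(prec); r <- mean(rec)
  } else {
    wts <- rowSums(cm) / sum(cm)
    miou <- sum(wts * iou); p <- sum(wts * prec); r <- sum(wts * rec)
  }
  list(miou = miou, precision = p, recall = r,
       f1 = if (p + r == 0) 0 else 2 * p * r / (p + r),
       per_class = data.frame(class = seq_len(nrow(cm)) - 1L, iou = iou,
                              precision = prec, recall = rec, f1 = f1c))
}

#' Agreement between manual and estimated measurements
#'
#' Coefficient of determination R^2 = 1 - sum((t - m)^2) / sum((t - mean(t))^2)
#' and RMSE = sqrt(mean((t - m)^2)), for paired manual values `t` and
#' estimates `m`.
#'
#' @param t numeric vector of manual (reference) values.
#' @param m numeric vector of estimated values, same length.
#' @return list with `r2` (NA with a warning when `t` is constant),
#'   `rmse`, and `n`.
#' @export
agreement <- function(t, m) {
  stopifnot(is.numeric(t), is.numeric(m))
  if (length(t) != length(m)) stop("t and m lengths differ")
  n <- length(t)
  if (n < 2L) stop("need at least 2 pairs")
  ss_res <- sum((t - m)^2)
  ss_tot <- sum((t - mean(t))^2)
  r2 <- if (ss_tot == 0) {
    warning("t is constant; R^2 undefined")
    NA_real_
  } else 1 - ss_res / ss_tot
  list(r2 = r2, rmse = sqrt(ss_res / n), n = n)
}
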