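# Evaluation metrics for affinity regression (RMSE, Pearson, Spearman) and
# binding-site classification (ROC-AUC, PR curve, F1 at the 0.5 rule).

#' Root mean square error
#' @param y,yhat Numeric vectors of equal nonzero length.
#' @return Scalar RMSE.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) == 0)
    stop("y and yhat must have equal nonzero length")
  sqrt(mean((y - yhat)^2))
}

#' Pearson correlation coefficient
#'
#' Computed from centred cross- and auto-moments; constant input yields `NaN`
#' with a warning.
#' @param y,yhat Numeric vectors (length >= 2).
#' @return Scalar in `[-1, 1]` (or `NaN` for degenerate input).
#' @export
pearson_r <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 2)
    stop("need equal lengths >= 2")
  dy <- y - mean(y); dh <- yhat - mean(yhat)
  den <- sqrt(sum(dy^2)) * sqrt(sum(dh^2))
  if (den == 0) {
    warning("constant input: Pearson correlation undefined", call. = FALSE)
    return(NaN)
  }
  sum(dy * dh) / den
}

#' Spearman rank correlation
#'
#' Tie-free inputs use the classical rank-difference form
#' `1 - 6 sum(d^2) / (n (n^2 - 1))`; ties fall back to Pearson on mid-ranks
#' (the standard generalisation, identical to the classical form when no
#' ties are present).
#' @param y,yhat Numeric vectors (length >= 2).
#' @return Scalar in `[-1, 1]` (or `NaN` for degenerate input).
#' @export
spearman_rho <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 2)
    stop("need equal lengths >= 2")
  n <- length(y)
  ry <- rank(y); rh <- rank(yhat)
  ties <- anyDuplicated(y) > 0 || anyDuplicated(yhat) > 0
  if (!ties) {
    d <- ry - rh
    return(1 - 6 * sum(d^2) / (n * (n^2 - 1)))
  }
  pearson_r(ry, rh)
}

#' ROC curve and area under it
#'
#' The ROC curve is traced over all score thresholds (tied scores collapsed
#' into one step) and the AUC is the trapezoidal area under TPR vs FPR --
#' equal to the tie-corrected Mann-Whitney rank statistic.
#'
#' @param labels Binary vector (0/1).
#' @param scores Numeric scores, higher = more positive.
#' @return `roc_curve`: data frame with `threshold`, `fpr`, `tpr`;
#'   `roc_auc`: scalar AUC (`NaN` with a warning if one class is absent).
#' @export
roc_curve <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]; sc <- scores[o]
  P <- sum(lab == 1); N <- sum(lab == 0)
  # collapse tied thresholds
  keep <- c(sc[-length(sc)] != sc[-1], TRUE)
  tp <- cumsum(lab == 1)[keep]
  fp <- cumsum(lab == 0)[keep]
  data.frame(threshold = sc[keep],
             fpr = if (N > 0) fp / N else rep(NaN, sum(keep)),
             tpr = if (P > 0) tp / P else rep(NaN, sum(keep)))
}

#' @rdname roc_curve
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    warning("single-class labels: AUC undefined", call. = FALSE)
    return(NaN)
  }
  rc <- roc_curve(labels, scores)
  fpr <- c(0, rc$fpr); tpr <- c(0, rc$tpr)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Precision-recall curve
#' @param labels Binary labels.
#' @param scores Numeric scores.
#' @return Data frame with `threshold`, `recall`, `precision`.
#' @export
pr_curve <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]; sc <- scores[o]
  P <- sum(lab == 1)
  keep <- c(sc[-length(sc)] != sc[-1], TRUE)
  tp <- cumsum(lab == 1)[keep]
  pred_pos <- seq_along(lab)[keep]
  data.frame(threshold = sc[keep],
             recall = if (P > 0) tp / P else rep(NaN, sum(keep)),
             precision = tp / pred_pos)
}

#' F1 score at a probability threshold
#'
#' Residues with probability strictly greater than the threshold are called
#' binding sites (default rule: 0.5).
#' @param labels Binary labels.
#' @param scores Probabilities.
#' @param threshold Decision threshold.
#' @return Scalar F1 (0 when no positives are predicted or present).
#' @export
f1_at_threshold <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Classification accuracy at the 0.5 rule
#' @inheritParams f1_at_threshold
#' @return Fraction of residues whose thresholded call matches the label.
#' @export
site_accuracy <- function(labels, scores, threshold = 0.5) {
  mean(as.integer(scores > threshold) == as.integer(labels))
}

#' Bundle regression + classification metrics into one report
#'
#' @param y,yhat Affinity labels and predictions (optional).
#' @param site_labels,site_scores Flattened per-residue labels/probabilities
#'   (optional).
#' @return List of class `pairbind_metrics` with `rmse`, `pearson`,
#'   `spearman`, `roc_auc`, `f1`, `n`.
#' @export
metrics_report <- function(y = NULL, yhat = NULL,
                           site_labels = NULL, site_scores = NULL) {
  out <- list(rmse = NA_real_, pearson = NA_real_, spearman = NA_real_,
              roc_auc = NA_real_, f1 = NA_real_,
              n = if (!is.null(y)) length(y) else length(site_labels))
  if (!is.null(y)) {
    out$rmse <- rmse(y, yhat)
    if (length(y) >= 2) {
      out$pearson <- pearson_r(y, yhat)
      out$spearman <- spearman_rho(y, yhat)
    }
  }
  if (!is.null(site_labels)) {
    out$roc_auc <- roc_auc(site_labels, site_scores)
    out$f1 <- f1_at_threshold(site_labels, site_scores)
  }
  structure(out, class = "pairbind_metrics")
}
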