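#' ROC curve of pixel scores against lesion labels
#'
#' Builds the full curve over all distinct score thresholds ("higher score =
#' more lesion-like"; classification rule `score >= threshold`), grouping
#' tied scores, with the trapezoid-rule AUC.  The trapezoid AUC with this tie
#' convention equals the pair-counting probability
#' `P(score_pos > score_neg) + 0.5 P(tie)`.
#'
#' @param score Numeric pixel scores (finite; NAs dropped with their labels).
#' @param label Logical (or 0/1) lesion labels; both classes must be present.
#' @return Object of class `roc_result`: `curve` (threshold, fpr, tpr,
#'   tp, fp), `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(score, label) {
  label <- as.logical(label)
  keep <- !is.na(score) & !is.na(label)
  score <- score[keep]; label <- label[keep]
  if (any(!is.finite(score))) stop("scores must be finite")
  n_pos <- sum(label); n_neg <- sum(!label)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present to construct a curve")
  o <- order(score, decreasing = TRUE)
  s <- score[o]; l <- label[o]
  # group tied scores
  grp_last <- which(!duplicated(s, fromLast = TRUE))   # last index of each tie group
  tp <- cumsum(l)[grp_last]
  fp <- cumsum(!l)[grp_last]
  thr <- s[grp_last]
  curve <- data.frame(threshold = c(Inf, thr),
                      tp = c(0, tp), fp = c(0, fp),
                      tpr = c(0, tp / n_pos), fpr = c(0, fp / n_neg))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                utils::tail(curve$tpr, -1)) / 2)
  structure(list(curve = curve, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f (%d lesion / %d non-lesion px, %d thresholds)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$curve) - 1))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$curve$fpr, x$curve$tpr, type = "l",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Optimal detection threshold from a ROC curve
#'
#' Maximizes Youden's `J = sensitivity + specificity - 1`; ties are broken
#' toward higher specificity.  The returned threshold is the midpoint between
#' the operating score and the next lower distinct score (the centre of the
#' separating gap when the classes separate cleanly), which classifies
#' identically to the operating point.
#'
#' @param r A `roc_result`.
#' @return `list(threshold, sensitivity, specificity, accuracy, youden_j)`.
#' @export
optimal_threshold <- function(r) {
  stopifnot(inherits(r, "roc_result"))
  cv <- r$curve
  if (nrow(cv) < 2) stop("degenerate curve")
  j <- cv$tpr - cv$fpr
  best <- which(j == max(j))
  best <- best[which.min(cv$fpr[best])]      # tie -> higher specificity
  # any threshold in (next lower score, operating score] classifies
  # identically; report the midpoint of that gap
  thr <- cv$threshold[best]
  if (is.finite(thr) && best < nrow(cv))
    thr <- (thr + cv$threshold[best + 1]) / 2
  tn <- r$n_neg - cv$fp[best]
  list(threshold = thr,
       sensitivity = cv$tpr[best],
       specificity = 1 - cv$fpr[best],
       accuracy = (cv$tp[best] + tn) / (r$n_pos + r$n_neg),
       youden_j = j[best])
}

#' Detection metrics at a fixed threshold
#'
#' @param score Numeric scores; `score >= threshold` predicts lesion.
#' @param label Logical truth labels.
#' @param threshold Decision threshold.
#' @return `list(accuracy, sensitivity, specificity, positive_fraction)`.
#' @export
roc_metrics <- function(score, label, threshold) {
  label <- as.logical(label)
  keep <- !is.na(score) & !is.na(label)
  score <- score[keep]; label <- label[keep]
  pred <- score >= threshold
  list(accuracy = mean(pred == label),
       sensitivity = if (any(label)) mean(pred[label]) else NA_real_,
       specificity = if (any(!label)) mean(!pred[!label]) else NA_real_,
       positive_fraction = mean(pred))
}

#' Leave-one-out cross-validation of ROC threshold training
#'
#' For each held-out subject the Youden threshold is trained on the pooled
#' remaining subjects and evaluated on the held-out subject's pixels.
#' Subjects whose labels contain a single class are skipped with a warning.
#'
#' @param score,label,subject Parallel vectors of pixel scores, lesion
#'   labels, and subject (wedge/phantom) ids; at least 3 usable subjects.
#' @return `list(folds = data.frame, train_auc, train_auc_sd, threshold,
#'   threshold_sd, heldout_auc, heldout_auc_sd, heldout_accuracy)`.
#' @export
loo_cv <- function(score, label, subject) {
  label <- as.logical(label)
  subj <- unique(subject)
  usable <- vapply(subj, function(s) {
    l <- label[subject == s]
    any(l) && any(!l)
  }, logical(1))
  if (any(!usable))
    warning(sprintf("%d subject(s) with single-class labels skipped",
                    sum(!usable)))
  subj <- subj[usable]
  if (length(subj) < 3) stop("need at least 3 usable subjects")
  rows <- lapply(subj, function(s) {
    tr_i <- subject != s & subject %in% subj
    te_i <- subject == s
    r_tr <- roc_curve(score[tr_i], label[tr_i])
    op <- optimal_threshold(r_tr)
    r_te <- roc_curve(score[te_i], label[te_i])
    m <- roc_metrics(score[te_i], label[te_i], op$threshold)
    data.frame(subject = s, train_auc = r_tr$auc, threshold = op$threshold,
               heldout_auc = r_te$auc, heldout_accuracy = m$accuracy,
               heldout_sensitivity = m$sensitivity,
               heldout_specificity = m$specificity)
  })
  folds <- do.call(rbind, rows)
  list(folds = folds,
       train_auc = mean(folds$train_auc), train_auc_sd = stats::sd(folds$train_auc),
       threshold = mean(folds$threshold), threshold_sd = stats::sd(folds$threshold),
       heldout_auc = mean(folds$heldout_auc),
       heldout_auc_sd = stats::sd(folds$heldout_auc),
       heldout_accuracy = mean(folds$heldout_accuracy))
}

#' Per-frame detection time course
#'
#' Evaluates, frame by frame, the ROC AUC of a score-map sequence against a
#' fixed truth mask, and (when a trained threshold is given) the detection
#' accuracy / sensitivity / specificity at that operating point.
#'
#' @param scores 3D array of per-pixel scores over frames (e.g. a
#'   cumulative-extrema map); frames that are entirely `NA` (the undefined
#'   first transient frame) yield NA rows.
#' @param truth A [lesion_mask()] or logical matrix; must contain both
#'   classes.
#' @param threshold Optional fixed decision threshold.
#' @return data.frame with one row per frame: `frame`, `auc`, and at the
#'   threshold `accuracy`, `sensitivity`, `specificity`,
#'   `positive_fraction`.
#' @export
detection_timecourse <- function(scores, truth, threshold = NULL) {
  m <- if (inherits(truth, "lesion_mask")) truth$mask else truth
  if (!any(m)) stop("empty truth mask")
  if (!any(!m)) stop("truth mask covers every pixel")
  nt <- dim(scores)[3]
  out <- data.frame(frame = seq_len(nt), auc = NA_real_,
                    accuracy = NA_real_, sensitivity = NA_real_,
                    specificity = NA_real_, positive_fraction = NA_real_)
  lab <- as.vector(m)
  for (t in seq_len(nt)) {
    sc <- as.vector(scores[, , t])
    if (all(is.na(sc))) next
    out$auc[t] <- roc_curve(sc, lab)$auc
    if (!is.null(threshold)) {
      mt <- roc_metrics(sc, lab, threshold)
      out$accuracy[t] <- mt$accuracy
      out$sensitivity[t] <- mt$sensitivity
      out$specificity[t] <- mt$specificity
      out$positive_fraction[t] <- mt$positive_fraction
    }
  }
  out
}

#' Three-band ΔAPA classification
#'
#' Partitions a ΔAPA map into lesion (`dAPA < bounds[1]`), non-lesion change
#' (`bounds[1] <= dAPA < bounds[2]`), and unchanged tissue, with the default
#' bounds at the lesion threshold −0.43 and the detectable-change bound
#' −0.19.
#'
#' @param delta_apa Numeric matrix of ΔAPA values.
#' @param bounds Increasing length-2 numeric `(lesion bound, change bound)`.
#' @return Integer matrix: 2 = lesion, 1 = non-lesion change, 0 = unchanged
#'   (attribute `bands` carries the labels).
#' @export
band_classifier <- function(delta_apa, bounds = c(-0.43, -0.19)) {
  if (length(bounds) != 2 || !(bounds[1] < bounds[2]))
    stop("bounds must be increasing (lesion bound below change bound)")
  out <- matrix(0L, nrow(delta_apa), ncol(delta_apa))
  out[delta_apa < bounds[2]] <- 1L
  out[delta_apa < bounds[1]] <- 2L
  out[is.na(delta_apa)] <- NA_integer_
  attr(out, "bands") <- c("unchanged", "nonlesion_change", "lesion")
  out
}

#' Kruskal–Wallis group comparison
#'
#' Thin wrapper used for phantom cohort summaries.
#'
#' @param values Numeric observations.
#' @param groups Group labels.
#' @return The `htest` from [stats::kruskal.test()].
#' @export
kw_test <- function(values, groups) stats::kruskal.test(values, as.factor(groups))
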