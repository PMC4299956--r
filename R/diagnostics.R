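#' Confusion counts at a decision threshold
#'
#' Scores strictly greater than the threshold are test-positive; ties count
#' as negative. Labels may be logical, 0/1, or the strings
#' "control"/"patient" (patient = positive).
#'
#' @param scores Numeric decision scores.
#' @param labels True condition indicator.
#' @param threshold Decision threshold (default 0).
#' @return A `confusion_matrix`: list with TP, FN, FP, TN, n_pos, n_neg.
#' @export
confusion_counts <- function(scores, labels, threshold = 0) {
  labels <- as_binary_labels(labels)
  if (!length(scores) || length(scores) != length(labels))
    stopf("scores and labels must be equal-length and non-empty")
  pos <- scores > threshold
  confusion_matrix(TP = sum(pos & labels), FN = sum(!pos & labels),
                   FP = sum(pos & !labels), TN = sum(!pos & !labels))
}

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    if (!all(labels %in% c("control", "patient")))
      stopf("string labels must be 'control'/'patient'")
    return(labels == "patient")
  }
  if (is.logical(labels)) return(labels)
  if (all(labels %in% c(0, 1))) return(labels == 1)
  stopf("labels must be binary")
}

#' Construct a confusion matrix from counts
#' @param TP,FN,FP,TN Non-negative integer cell counts.
#' @return A `confusion_matrix`.
#' @export
confusion_matrix <- function(TP, FN, FP, TN) {
  cells <- c(TP = TP, FN = FN, FP = FP, TN = TN)
  if (any(cells < 0) || any(cells != round(cells)))
    stopf("confusion counts must be non-negative integers")
  structure(as.list(stats::setNames(as.integer(cells), names(cells))),
            class = "confusion_matrix")
}

#' Sensitivity, specificity and accuracy with confidence intervals
#'
#' Point rates are plain count ratios. Intervals: `"wald"` (normal
#' approximation, p +/- z*sqrt(p(1-p)/n), clipped to [0,1]) or
#' `"clopper_pearson"` (exact binomial).
#'
#' @param cm A `confusion_matrix`.
#' @param method `"wald"` or `"clopper_pearson"`.
#' @param level Confidence level (default 0.95).
#' @return List with sensitivity, specificity, accuracy, each `c(est, lo, hi)`.
#' @export
rates_with_ci <- function(cm, method = c("wald", "clopper_pearson"),
                          level = 0.95) {
  method <- match.arg(method)
  n_pos <- cm$TP + cm$FN
  n_neg <- cm$FP + cm$TN
  if (n_pos < 1 || n_neg < 1) stopf("need at least one subject per class")
  one <- function(k, n) {
    p <- k / n
    if (method == "wald") {
      z <- stats::qnorm(1 - (1 - level) / 2)
      half <- z * sqrt(p * (1 - p) / n)
      c(est = p, lo = max(0, p - half), hi = min(1, p + half))
    } else {
      ci <- stats::binom.test(k, n, conf.level = level)$conf.int
      c(est = p, lo = ci[1], hi = ci[2])
    }
  }
  list(sensitivity = one(cm$TP, n_pos),
       specificity = one(cm$TN, n_neg),
       accuracy = one(cm$TP + cm$TN, n_pos + n_neg))
}

#' Likelihood ratios with Simel confidence intervals
#'
#' `LR+ = sens/(1-spec)`, `LR- = (1-sens)/spec`, from unrounded count
#' ratios. Intervals are log-normal (Simel):
#' `exp(log LR +/- z * SE)` with
#' `SE(log LR+) = sqrt((1-sens)/TP + spec/FP)` and
#' `SE(log LR-) = sqrt(sens/FN + (1-spec)/TN)`.
#' A zero FP (or FN) cell yields an infinite (or zero) ratio with an
#' undefined interval, flagged with `NA` bounds.
#'
#' @param cm A `confusion_matrix`.
#' @param level Confidence level.
#' @return List with `lr_plus` and `lr_minus`, each `c(est, lo, hi)`.
#' @export
likelihood_ratios_with_ci <- function(cm, level = 0.95) {
  n_pos <- cm$TP + cm$FN
  n_neg <- cm$FP + cm$TN
  if (n_pos < 1 || n_neg < 1) stopf("need at least one subject per class")
  sens <- cm$TP / n_pos
  spec <- cm$TN / n_neg
  z <- stats::qnorm(1 - (1 - level) / 2)
  lrp <- if (cm$FP == 0) c(est = Inf, lo = NA, hi = NA) else {
    est <- sens / (1 - spec)
    if (cm$TP == 0) c(est = 0, lo = NA, hi = NA) else {
      se <- sqrt((1 - sens) / cm$TP + spec / cm$FP)
      c(est = est, lo = exp(log(est) - z * se), hi = exp(log(est) + z * se))
    }
  }
  lrm <- if (cm$FN == 0) c(est = 0, lo = NA, hi = NA) else {
    est <- (1 - sens) / spec
    if (cm$TN == 0) c(est = Inf, lo = NA, hi = NA) else {
      se <- sqrt(sens / cm$FN + (1 - spec) / cm$TN)
      c(est = est, lo = exp(log(est) - z * se), hi = exp(log(est) + z * se))
    }
  }
  list(lr_plus = lrp, lr_minus = lrm)
}

#' Diagnostic odds ratio with log-transform confidence interval
#'
#' `OR = (TP*TN)/(FN*FP)`;
#' `CI = exp(log OR +/- z * sqrt(1/TP + 1/FN + 1/FP + 1/TN))`.
#' With any zero cell the ratio is undefined unless the Haldane-Anscombe
#' 0.5 continuity correction is enabled.
#'
#' @param cm A `confusion_matrix`.
#' @param level Confidence level.
#' @param continuity Add 0.5 to every cell when any cell is zero.
#' @return `c(est, lo, hi)`.
#' @export
odds_ratio_with_ci <- function(cm, level = 0.95, continuity = FALSE) {
  cells <- c(cm$TP, cm$FN, cm$FP, cm$TN)
  if (any(cells == 0)) {
    if (!continuity)
      stopf("zero cell in confusion matrix; enable the continuity correction")
    cells <- cells + 0.5
  }
  or <- cells[1] * cells[4] / (cells[2] * cells[3])
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(sum(1 / cells))
  c(est = or, lo = exp(log(or) - z * se), hi = exp(log(or) + z * se))
}

#' ROC curve over all distinct thresholds
#'
#' Thresholds are the distinct score values (with the strict-greater
#' positivity convention) plus a sentinel above the maximum, giving points
#' from (0,0) to (1,1).
#'
#' @param scores Numeric decision scores.
#' @param labels Binary condition labels.
#' @return A `roc_curve` data frame: threshold, fpr, tpr.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  if (!any(labels) || all(labels)) stopf("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  out <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) mean(scores[!labels] > t), 0),
    tpr = vapply(thr, function(t) mean(scores[labels] > t), 0))
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the curve of [roc_curve()]; with ties handled by
#' threshold grouping this equals the Mann-Whitney statistic with ties
#' counted one half.
#'
#' @param scores Numeric decision scores.
#' @param labels Binary condition labels.
#' @return List with `auc` and the `roc` curve.
#' @export
roc_auc <- function(scores, labels) {
  roc <- roc_curve(scores, labels)
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  list(auc = auc, roc = roc)
}

#' Bootstrap percentile confidence interval for the AUC
#'
#' Resamples subjects with replacement within each class (stratified),
#' recomputes the AUC, and returns the percentile interval.
#'
#' @param scores Numeric decision scores.
#' @param labels Binary condition labels.
#' @param B Number of bootstrap replicates (default 2000).
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return `c(est, lo, hi)` with attribute `boot_aucs`.
#' @export
bootstrap_auc_ci <- function(scores, labels, B = 2000L, seed = 1L,
                             level = 0.95) {
  labels <- as_binary_labels(labels)
  sp <- scores[labels]
  sn <- scores[!labels]
  if (length(sp) < 2L || length(sn) < 2L)
    stopf("need at least 2 subjects per class to bootstrap")
  point <- auc_mw(sp, sn)
  boots <- with_seed(seed, vapply(seq_len(B), function(b)
    auc_mw(sample(sp, replace = TRUE), sample(sn, replace = TRUE)), 0))
  q <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE)
  structure(c(est = point, lo = q[1], hi = q[2]), boot_aucs = boots)
}

# Mann-Whitney AUC: P(pos > neg) + 0.5 P(tie), via midranks.
auc_mw <- function(sp, sn) {
  r <- rank(c(sp, sn))
  m <- length(sp)
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * length(sn))
}

#' Paired comparison of two correlated AUCs
#'
#' Compares the AUCs of two score vectors measured on the same subjects.
#' The variance of the AUC difference is estimated from the per-subject
#' placement values of the two markers (DeLong-style components), which
#' accounts for the correlation induced by the shared subjects.
#' `z = (auc_a - auc_b)/SE`, with a one-sided p-value from the upper normal
#' tail (testing that marker a has the larger AUC).
#'
#' @param scores_a,scores_b Score vectors over the same subjects.
#' @param labels Binary condition labels.
#' @return An `auc_comparison`: list with auc_a, auc_b, se_diff, z, p.
#' @export
paired_auc_z <- function(scores_a, scores_b, labels) {
  labels <- as_binary_labels(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stopf("score vectors and labels must have equal length")
  placements <- function(s) {
    sp <- s[labels]; sn <- s[!labels]
    v10 <- vapply(sp, function(x) mean(x > sn) + 0.5 * mean(x == sn), 0)
    v01 <- vapply(sn, function(x) mean(sp > x) + 0.5 * mean(sp == x), 0)
    list(auc = mean(v10), v10 = v10, v01 = v01)
  }
  a <- placements(scores_a)
  b <- placements(scores_b)
  m <- sum(labels); n <- sum(!labels)
  var_diff <- stats::var(a$v10 - b$v10) / m + stats::var(a$v01 - b$v01) / n
  diff <- a$auc - b$auc
  if (var_diff <= 0) {
    z <- 0
  } else {
    z <- diff / sqrt(var_diff)
  }
  structure(list(auc_a = a$auc, auc_b = b$auc,
                 se_diff = sqrt(max(var_diff, 0)), z = z,
                 p = stats::pnorm(z, lower.tail = FALSE)),
            class = "auc_comparison")
}

#' ROC-optimal decision threshold
#'
#' The threshold whose ROC point lies closest (Euclidean distance) to the
#' ideal point (FPR 0, TPR 1), i.e. sensitivity = specificity = 1. Ties go
#' to the point with higher specificity (lower FPR).
#'
#' @param roc A `roc_curve`.
#' @return List with `threshold`, `fpr`, `tpr`, `distance`.
#' @export
optimal_threshold <- function(roc) {
  if (!nrow(roc)) stopf("empty ROC")
  d <- sqrt(roc$fpr^2 + (1 - roc$tpr)^2)
  best <- which(d == min(d))
  best <- best[order(roc$fpr[best])][1]
  list(threshold = roc$threshold[best], fpr = roc$fpr[best],
       tpr = roc$tpr[best], distance = d[best])
}

#' Reconstruct integer confusion counts from printed 2-decimal rates
#'
#' Exhaustively searches TP in [0, n_pos] and TN in [0, n_neg] for counts
#' whose ratios round (half-up, 2 decimals) to the printed sensitivity and
#' specificity. Errors if no or several solutions exist, listing the
#' candidates.
#'
#' @param sens_2dp,spec_2dp Printed rates (2 decimals).
#' @param n_pos,n_neg Group sizes.
#' @param digits Printed precision (default 2).
#' @return A `confusion_matrix`.
#' @export
reconstruct_confusion <- function(sens_2dp, spec_2dp, n_pos, n_neg,
                                  digits = 2) {
  if (sens_2dp < 0 || sens_2dp > 1 || spec_2dp < 0 || spec_2dp > 1)
    stopf("rates must lie in [0, 1]")
  cand <- function(rate, n) {
    k <- 0:n
    target <- round(rate * 10^digits)
    k[vapply(k, function(a)
      round_ratio_half_up(a, n, digits) * 10^digits, 0) == target]
  }
  tp <- cand(sens_2dp, n_pos)
  tn <- cand(spec_2dp, n_neg)
  if (length(tp) != 1L || length(tn) != 1L)
    stopf(paste0("printed rates do not determine unique counts: ",
                 "TP candidates {%s}, TN candidates {%s}"),
          paste(tp, collapse = ","), paste(tn, collapse = ","))
  confusion_matrix(TP = tp, FN = n_pos - tp, FP = n_neg - tn, TN = tn)
}

#' Full diagnostic accuracy report
#'
#' Confusion counts at the given threshold, rates with intervals,
#' likelihood ratios (Simel), diagnostic odds ratio (log-transform), and
#' AUC with a stratified bootstrap interval.
#'
#' @param scores Decision scores.
#' @param labels Binary condition labels.
#' @param threshold Decision threshold; `"optimal"` picks the ROC point
#'   closest to (0, 1).
#' @param rate_ci_method Passed to [rates_with_ci()].
#' @param B,seed Bootstrap settings for the AUC interval.
#' @param level Confidence level.
#' @return A `diagnostic_report` list.
#' @export
diagnostic_report <- function(scores, labels, threshold = "optimal",
                              rate_ci_method = "wald", B = 2000L, seed = 1L,
                              level = 0.95) {
  labels <- as_binary_labels(labels)
  ra <- roc_auc(scores, labels)
  if (identical(threshold, "optimal"))
    threshold <- optimal_threshold(ra$roc)$threshold
  cm <- confusion_counts(scores, labels, threshold)
  rates <- rates_with_ci(cm, rate_ci_method, level)
  lrs <- likelihood_ratios_with_ci(cm, level)
  or <- tryCatch(odds_ratio_with_ci(cm, level),
                 error = function(e) c(est = NA, lo = NA, hi = NA))
  auc_ci <- bootstrap_auc_ci(scores, labels, B = B, seed = seed, level = level)
  structure(list(
    confusion = cm, threshold = threshold,
    sensitivity = rates$sensitivity, specificity = rates$specificity,
    accuracy = rates$accuracy, lr_plus = lrs$lr_plus,
    lr_minus = lrs$lr_minus, odds_ratio = or,
    auc = c(est = unname(auc_ci["est"]), lo = unname(auc_ci["lo"]),
            hi = unname(auc_ci["hi"])),
    roc = ra$roc
  ), class = "diagnostic_report")
}
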