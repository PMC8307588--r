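#' Overlap between a detected lesion and an expert annotation
#'
#' Default `coverage` mode measures the fraction of the expert-annotated
#' region covered by the detection (`|detected intersect expert| / |expert|`):
#' clinically, did the system find the lesion the dentist marked. `iou` mode
#' is the symmetric intersection-over-union. A detection is accepted when the
#' overlap is strictly greater than the threshold (default 0.60).
#'
#' @param detected,expert binary 0/255 matrices of equal shape.
#' @param mode `"coverage"` (default) or `"iou"`.
#' @param threshold acceptance threshold on the overlap fraction.
#' @return one-row tibble: `overlap`, `mode`, `pass`.
#' @export
overlap_fraction <- function(detected, expert, mode = c("coverage", "iou"),
                             threshold = 0.6) {
  mode <- match.arg(mode)
  assert_same_shape(detected, expert)
  inter <- sum(detected == 255 & expert == 255)
  frac <- if (mode == "coverage") {
    ex <- fg_count(expert)
    if (ex == 0L) stop("no annotated lesion", call. = FALSE)
    inter / ex
  } else {
    uni <- sum(detected == 255 | expert == 255)
    if (uni == 0L) 0 else inter / uni
  }
  tibble::tibble(overlap = frac, mode = mode, pass = frac > threshold)
}

#' Per-image detection outcome
#'
#' Applies the study's correctness rule. VNC and C images form the positive
#' "Caries" category, NSC the negative "Non-Caries" category. A Caries image
#' counts as a true positive only when a lesion was detected *and* (when an
#' expert mask is supplied) the overlap criterion passes; otherwise it is a
#' false negative. A Non-Caries image with any detection is a false positive,
#' without one a true negative.
#'
#' @param det a `caries_detection` (or a logical `caries_detected` flag).
#' @param label3 class label: `"NSC"`, `"VNC"` or `"C"`.
#' @param expert_mask expert-annotated binary lesion mask; required for
#'   Caries-category images when `check_overlap = TRUE`.
#' @param check_overlap validate detections against the expert mask?
#' @param mode,threshold passed to [overlap_fraction()].
#' @return one of `"tp"`, `"fp"`, `"fn"`, `"tn"`.
#' @export
detection_outcome <- function(det, label3, expert_mask = NULL,
                              check_overlap = !is.null(expert_mask),
                              mode = "coverage", threshold = 0.6) {
  label3 <- match.arg(label3, c("NSC", "VNC", "C"))
  detected <- if (is.logical(det)) det else det$caries_detected
  if (label3 == "NSC") return(if (detected) "fp" else "tn")
  if (!detected) return("fn")
  if (check_overlap) {
    if (is.null(expert_mask)) stop("expert mask required", call. = FALSE)
    ov <- overlap_fraction(det$lesion_mask, expert_mask, mode = mode,
                           threshold = threshold)
    if (!ov$pass) return("fn")
  }
  "tp"
}

#' 2x2 confusion matrix
#'
#' @param tp,fp,fn,tn non-negative outcome counts.
#' @param positive name of the positive class.
#' @return object of class `caries_confusion`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn, positive = "Caries") {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 total = tp + fp + fn + tn, positive = positive),
            class = "caries_confusion")
}

#' @export
print.caries_confusion <- function(x, ...) {
  cat("<caries_confusion> positive =", x$positive, "\n")
  print(matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
               dimnames = list(predicted = c("pos", "neg"),
                               truth = c("pos", "neg"))))
  invisible(x)
}

#' Build a confusion matrix from per-image outcomes
#'
#' @param outcomes character vector of `"tp"/"fp"/"fn"/"tn"`.
#' @param positive positive-class name.
#' @return a `caries_confusion`.
#' @export
tally_outcomes <- function(outcomes, positive = "Caries") {
  stopifnot(all(outcomes %in% c("tp", "fp", "fn", "tn")))
  confusion_matrix(sum(outcomes == "tp"), sum(outcomes == "fp"),
                   sum(outcomes == "fn"), sum(outcomes == "tn"),
                   positive = positive)
}

#' Metrics from a confusion matrix
#'
#' Accuracy `(tp+tn)/total`, sensitivity `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)`, precision `tp/(tp+fp)`, recall (= sensitivity) and F1
#' (harmonic mean of precision and recall), all as percentages. Full
#' precision is kept internally; use `round2()` (half-up, 2 decimals) for
#' display. A metric with a zero denominator is returned as `NA` with a
#' warning, never as a silent 0.
#'
#' @param cm a `caries_confusion` (or a list with `tp`, `fp`, `fn`, `tn`).
#' @return one-row tibble: `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, `recall`, `f1`, in percent.
#' @export
metrics_from_confusion <- function(cm) {
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  total <- tp + fp + fn + tn
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator")
      return(NA_real_)
    }
    num / den
  }
  accuracy <- 100 * (tp + tn) / total
  sensitivity <- 100 * safe_div(tp, tp + fn, "sensitivity")
  specificity <- 100 * safe_div(tn, tn + fp, "specificity")
  precision <- 100 * safe_div(tp, tp + fp, "precision")
  recall <- sensitivity
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  tibble::tibble(accuracy = accuracy, sensitivity = sensitivity,
                 specificity = specificity, precision = precision,
                 recall = recall, f1 = f1)
}

#' Round half-up to a fixed number of decimals
#'
#' Metric tables are printed at two decimals with ties rounded up
#' (so 87.385 prints as 87.39), unlike base R's round-half-even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @export
round2 <- function(x, digits = 2) {
  pow <- 10^digits
  sign(x) * floor(abs(x) * pow + 0.5) / pow
}

#' Area under the ROC curve
#'
#' Rank-statistic formulation: the probability that a randomly chosen
#' positive outscores a randomly chosen negative, ties counting one half
#' (equivalent to the Wilcoxon/Mann-Whitney statistic).
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels logical (or 0/1) vector, `TRUE` = positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch", call. = FALSE)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)  # midranks: ties count one half
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
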