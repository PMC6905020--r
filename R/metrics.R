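#' Confusion counts from truth and prediction
#'
#' @param truth,pred label vectors in \{+1, -1\}.
#' @return a \code{confusion_counts} list with TP, FN, TN, FP.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- .as_pm1(truth); pred <- .as_pm1(pred)
  if (length(truth) != length(pred)) stop("length mismatch")
  structure(list(TP = sum(truth == 1 & pred == 1),
                 FN = sum(truth == 1 & pred == -1),
                 TN = sum(truth == -1 & pred == -1),
                 FP = sum(truth == -1 & pred == 1)),
            class = "confusion_counts")
}

#' Sensitivity, specificity, accuracy and MCC
#'
#' \deqn{S_n = 100\,TP/(TP+FN),\quad S_p = 100\,TN/(TN+FP),}
#' \deqn{Acc = 100\,(TP+TN)/(TP+TN+FP+FN),}
#' \deqn{MCC = \frac{TP\cdot TN - FP\cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.}
#' Sn and Sp are percentages; when their denominator is zero they are
#' reported as NA. When any factor of the MCC denominator is zero, MCC is
#' defined as 0 (with a warning) — the usual convention for degenerate
#' confusion tables.
#'
#' @param counts a \code{confusion_counts}, or a list/vector with elements
#'   TP, FN, TN, FP.
#' @return an \code{ion_metrics} list: \code{sn}, \code{sp}, \code{acc}
#'   (percent), \code{mcc}, and the counts.
#' @export
compute_metrics <- function(counts) {
  cc <- as.list(counts)[c("TP", "FN", "TN", "FP")]
  if (anyNA(match(c("TP", "FN", "TN", "FP"), names(as.list(counts)))))
    stop("counts must provide TP, FN, TN, FP")
  # doubles: the MCC denominator product overflows 32-bit integers easily
  TP <- as.numeric(cc$TP); FN <- as.numeric(cc$FN)
  TN <- as.numeric(cc$TN); FP <- as.numeric(cc$FP)
  if (any(c(TP, FN, TN, FP) < 0)) stop("negative confusion counts")
  sn <- if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_
  sp <- if (TN + FP > 0) 100 * TN / (TN + FP) else NA_real_
  total <- TP + FN + TN + FP
  acc <- if (total > 0) 100 * (TP + TN) / total else NA_real_
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (den > 0) (TP * TN - FP * FN) / sqrt(den) else {
    warning("zero factor in MCC denominator; MCC set to 0")
    0
  }
  structure(list(sn = sn, sp = sp, acc = acc, mcc = mcc,
                 counts = structure(cc, class = "confusion_counts")),
            class = "ion_metrics")
}

#' @export
print.ion_metrics <- function(x, digits = 3, ...) {
  cat(sprintf("Sn %.1f%%  Sp %.1f%%  Acc %.1f%%  MCC %s\n",
              x$sn, x$sp, x$acc, format(round(x$mcc, digits))))
  invisible(x)
}
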