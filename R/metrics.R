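#' Confusion counts for a binary evaluation
#'
#' Positive class is the `+1` (early-stage) label.
#'
#' @param truth,predicted vectors of `+1`/`-1` labels, or give counts
#'   directly via `tp`, `fp`, `tn`, `fn`.
#' @param tp,fp,tn,fn direct counts (used when `truth` is missing).
#' @return A `ConfusionCounts` list with fields `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth = NULL, predicted = NULL,
                             tp = 0L, fp = 0L, tn = 0L, fn = 0L) {
  if (!is.null(truth)) {
    stopifnot(length(truth) == length(predicted))
    tp <- sum(truth == 1L & predicted == 1L)
    fp <- sum(truth == -1L & predicted == 1L)
    tn <- sum(truth == -1L & predicted == -1L)
    fn <- sum(truth == 1L & predicted == -1L)
  }
  if (any(c(tp, fp, tn, fn) < 0)) stop("counts must be non-negative",
                                       call. = FALSE)
  structure(list(tp = as.numeric(tp), fp = as.numeric(fp),
                 tn = as.numeric(tn), fn = as.numeric(fn)),
            class = "ConfusionCounts")
}

#' Matthews correlation coefficient
#'
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' in `[-1, 1]`; 1 = perfect, 0 = random, -1 = total disagreement. Any zero
#' factor in the denominator makes the value 0 by convention.
#'
#' @param c a `ConfusionCounts`.
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(c) {
  stopifnot(inherits(c, "ConfusionCounts"))
  denom <- (c$tp + c$fp) * (c$tp + c$fn) * (c$tn + c$fp) * (c$tn + c$fn)
  if (denom == 0) return(0)
  ((c$tp * c$tn) - (c$fp * c$fn)) / sqrt(denom)
}

#' Rank-based AUC (area under the ROC curve)
#'
#' Mann-Whitney formulation with midrank tie handling: the probability that a
#' random positive sample outscores a random negative one, counting ties as
#' one half. Constant scores give 0.5.
#'
#' @param scores continuous scores, larger = more positive-class.
#' @param labels `+1`/`-1` labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == -1L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC needs both classes present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
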