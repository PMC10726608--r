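#' ROC curve and AUC for a single-marker diagnostic model
#'
#' The curve is traced over all distinct score thresholds, from (0, 0) to
#' (1, 1); AUC is the trapezoid area, which equals the midrank Mann-Whitney
#' identity `U / (n1 * n0)` (positives vs negatives) exactly, including
#' under ties.
#'
#' @param scores Numeric marker values.
#' @param labels Logical or 0/1 vector; `TRUE`/1 marks the positive class
#'   (tumor).
#' @return An object of class `pc_roc`: a tibble of `(fpr, tpr)` points with
#'   attributes `auc`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))
roc_auc <- function(scores, labels) {
  scores <- as.numeric(scores)
  pos <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(pos)
  scores <- scores[keep]; pos <- pos[keep]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present", call. = FALSE)
  # sweep thresholds from high to low; ties move as a block
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) sum(pos & scores >= t), numeric(1)) / n1)
  fpr <- c(0, vapply(thr, function(t) sum(!pos & scores >= t), numeric(1)) / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  res <- tibble::tibble(fpr = fpr, tpr = tpr)
  attr(res, "auc") <- auc
  attr(res, "n_pos") <- n1
  attr(res, "n_neg") <- n0
  class(res) <- c("pc_roc", class(res))
  res
}
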