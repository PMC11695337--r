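#' Support-weighted F1 evaluation
#'
#' Per-class precision `TP / (TP + FP)`, recall `TP / (TP + FN)`, their
#' harmonic mean F1, and the support-weighted average
#' `F1 = sum(W_i * F1_i) / sum(W_i)` with `W_i` the number of true samples of
#' class i. Classes absent from `y_true` carry zero weight; a class never
#' predicted gets precision 0 (and hence F1 0). These zero-division
#' conventions make the score well defined for degenerate predictors.
#'
#' @param y_true,y_pred label vectors of equal length (any atomic type).
#' @param classes optional class universe; defaults to the union of observed
#'   labels.
#' @return object of class `eval_report`: list with `per_class` data.frame
#'   (class, precision, recall, f1, support) and `weighted_f1`.
#' @export
weighted_f1 <- function(y_true, y_pred, classes = NULL) {
  if (length(y_true) != length(y_pred)) stop("y_true and y_pred lengths differ")
  if (length(y_true) == 0) stop("empty input")
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  prec <- rec <- f1 <- supp <- numeric(length(classes))
  for (i in seq_along(classes)) {
    cl <- classes[i]
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[i] <- if (prec[i] + rec[i] > 0) 2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
    supp[i] <- tp + fn
  }
  structure(list(
    per_class = data.frame(class = classes, precision = prec, recall = rec,
                           f1 = f1, support = supp),
    weighted_f1 = sum(supp * f1) / sum(supp)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  print(x$per_class, row.names = FALSE)
  cat(sprintf("weighted F1: %.4f\n", x$weighted_f1))
  invisible(x)
}

#' Expected weighted F1 of the prior-sampling dummy baseline
#'
#' For a baseline that samples predictions from the class prior independently
#' of the features, expected per-class precision, recall and F1 all equal the
#' class proportion p_i, so the expected support-weighted F1 is
#' `sum(p_i^2)`. Finite test sets give slightly lower simulated means (the
#' per-class F1 is a concave ratio of binomial counts).
#'
#' @param class_proportions probability vector (positive, sums to 1).
#' @return expected weighted F1.
#' @export
expected_dummy_f1 <- function(class_proportions) {
  p <- class_proportions
  if (any(p <= 0) || abs(sum(p) - 1) > 1e-8) {
    stop("class_proportions must be positive and sum to 1")
  }
  sum(p^2)
}
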