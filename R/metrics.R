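#' Agresti-Coull binomial confidence interval
#'
#' Adjusted-count interval: with `z` the normal quantile for the confidence
#' level, `n~ = n + z^2`, `p~ = (x + z^2/2) / n~`, and half-width
#' `z * sqrt(p~ (1 - p~) / n~)`; the interval is truncated to \[0, 1\].
#'
#' @param x Number of successes (0 <= x <= n).
#' @param n Number of trials (>= 1).
#' @param conf Confidence level (default 0.95).
#' @return Named vector `c(low, high)`.
#' @export
agresti_coull_interval <- function(x, n, conf = 0.95) {
  if (!is.finite(x) || !is.finite(n) || n < 1 || x < 0) {
    stop("need 0 <= x <= n with n >= 1")
  }
  if (x > n) stop("x exceeds n (", x, " > ", n, ")")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  n_tilde <- n + z^2
  p_tilde <- (x + z^2 / 2) / n_tilde
  hw <- z * sqrt(p_tilde * (1 - p_tilde) / n_tilde)
  c(low = max(0, p_tilde - hw), high = min(1, p_tilde + hw))
}

#' Sensitivity and specificity with Agresti-Coull intervals
#'
#' Sensitivity is the true-positive rate `tp / (tp + fn)` and specificity
#' the true-negative rate `tn / (tn + fp)` for the designated positive
#' class; both carry Agresti-Coull confidence intervals.
#'
#' @param predicted,truth Aligned class-call vectors.
#' @param positive The positive class (must be present in `truth`).
#' @param conf Confidence level.
#' @return A `binary_metrics` list: `sensitivity`, `specificity`, `ci_sens`,
#'   `ci_spec`, `counts` (tp, fn, tn, fp).
#' @export
binary_metrics <- function(predicted, truth, positive, conf = 0.95) {
  if (length(predicted) != length(truth)) stop("predicted and truth differ in length")
  pos <- truth == positive
  if (!any(pos)) stop("positive class '", positive, "' absent from truth")
  if (all(pos)) stop("truth contains only the positive class")
  pred_pos <- predicted == positive
  tp <- sum(pred_pos & pos); fn <- sum(!pred_pos & pos)
  tn <- sum(!pred_pos & !pos); fp <- sum(pred_pos & !pos)
  structure(list(
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ci_sens = agresti_coull_interval(tp, tp + fn, conf),
    ci_spec = agresti_coull_interval(tn, tn + fp, conf),
    counts = c(tp = tp, fn = fn, tn = tn, fp = fp)
  ), class = "binary_metrics")
}

as_binary_truth <- function(truth, positive = NULL) {
  if (is.logical(truth)) return(truth)
  if (is.numeric(truth) && all(truth %in% c(0, 1))) return(truth == 1)
  if (is.null(positive)) {
    stop("truth must be logical or 0/1, or supply `positive =`")
  }
  truth == positive
}

#' ROC area under the curve (midrank / Mann-Whitney)
#'
#' AUC computed as the Mann-Whitney probability that a positive sample's
#' score exceeds a negative sample's, ties counted half:
#' `P(s+ > s-) + P(s+ = s-) / 2`, via the rank-sum identity.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param truth Logical / 0-1 vector, or class vector with `positive` given.
#' @param positive Positive class when `truth` is categorical.
#' @return The AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, truth, positive = NULL) {
  pos <- as_binary_truth(truth, positive)
  if (length(scores) != length(pos)) stop("scores and truth differ in length")
  keep <- is.finite(scores) & !is.na(pos)
  scores <- scores[keep]; pos <- pos[keep]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present in truth")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap confidence interval for an AUC
#'
#' Nonparametric bootstrap stratified within each truth class (so every
#' resample contains both classes even at small n), with an equi-tailed
#' percentile interval of the bootstrap AUC distribution. The default 100
#' iterations matches the study's evaluation protocol.
#'
#' @param scores,truth,positive As in [roc_auc()].
#' @param R Bootstrap iterations (>= 1).
#' @param conf Confidence level.
#' @param seed RNG seed.
#' @return Named vector `c(low, high)`.
#' @export
bootstrap_auc_ci <- function(scores, truth, R = 100, conf = 0.95, seed = 1L,
                             positive = NULL) {
  if (!is.numeric(R) || R < 1) stop("R must be >= 1")
  pos <- as_binary_truth(truth, positive)
  i_pos <- which(pos); i_neg <- which(!pos)
  if (length(i_pos) == 0 || length(i_neg) == 0) stop("both classes must be present")
  set.seed(seed)
  aucs <- vapply(seq_len(R), function(b) {
    idx <- c(sample(i_pos, replace = TRUE), sample(i_neg, replace = TRUE))
    roc_auc(scores[idx], pos[idx])
  }, numeric(1))
  a <- (1 - conf) / 2
  q <- stats::quantile(aucs, c(a, 1 - a), names = FALSE)
  c(low = q[1], high = q[2])
}

#' Multiclass one-vs-rest AUC report
#'
#' Per-class one-vs-rest AUCs from each class's probability column, their
#' unweighted mean (macro-AUC), and the AUC of the pooled (sample x class)
#' binary expansion (micro-AUC).
#'
#' @param probs Probability matrix / data.frame with one column per class.
#' @param truth Class calls; every class in `levels` must occur.
#' @param levels Classes to evaluate; defaults to the observed truth classes
#'   (in `SUBTYPES` order when applicable).
#' @return A `multiclass_auc` list: `auc_per_class`, `macro_auc`,
#'   `micro_auc`.
#' @export
multiclass_auc <- function(probs, truth, levels = NULL) {
  probs <- as.matrix(probs)
  truth <- as.character(truth)
  levels <- levels %||% {
    obs <- unique(truth)
    if (all(obs %in% SUBTYPES)) SUBTYPES[SUBTYPES %in% obs] else sort(obs)
  }
  missing_cols <- setdiff(levels, colnames(probs))
  if (length(missing_cols) > 0) {
    stop("missing probability column(s): ", paste(missing_cols, collapse = ", "))
  }
  absent <- setdiff(levels, unique(truth))
  if (length(absent) > 0) {
    stop("class(es) absent from truth: ", paste(absent, collapse = ", "))
  }
  per_class <- vapply(levels, function(cl) roc_auc(probs[, cl], truth == cl),
                      numeric(1))
  pooled_scores <- as.vector(probs[, levels])
  pooled_truth <- as.vector(vapply(levels, function(cl) truth == cl,
                                   logical(length(truth))))
  structure(list(
    auc_per_class = per_class,
    macro_auc = mean(per_class),
    micro_auc = roc_auc(pooled_scores, pooled_truth)
  ), class = "multiclass_auc")
}

#' @export
print.multiclass_auc <- function(x, ...) {
  cat("one-vs-rest AUC:",
      paste(sprintf("%s %.3f", names(x$auc_per_class), x$auc_per_class),
            collapse = " | "),
      sprintf("\nmacro-AUC %.3f  micro-AUC %.3f\n", x$macro_auc, x$micro_auc))
  invisible(x)
}
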