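# Mann-Whitney AUC via midranks: ties between a case and a control count
# half. Equivalent to the exhaustive concordance fraction.
auc_mann_whitney <- function(truth, score) {
  r <- rank(score)
  n1 <- as.numeric(sum(truth))
  n0 <- as.numeric(sum(!truth))
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Hanley-McNeil standard error of the AUC
auc_se_hanley <- function(auc, n1, n0) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) + (n0 - 1) * (q2 - auc^2)) /
         (n1 * n0))
}

roc_from_vectors <- function(truth, score, conf_level = 0.95,
                             ci_method = c("hanley-mcneil", "delong")) {
  ci_method <- match.arg(ci_method)
  keep <- !is.na(truth) & is.finite(score)
  truth <- as.logical(truth)[keep]
  score <- score[keep]
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L) {
    abort("both outcome classes must be present to compute a ROC curve")
  }
  auc <- auc_mann_whitney(truth, score)
  if (ci_method == "hanley-mcneil") {
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    se <- auc_se_hanley(auc, n1, n0)
    ci <- c(max(0, auc - z * se), min(1, auc + z * se))
  } else {
    if (!requireNamespace("pROC", quietly = TRUE)) {
      abort("ci_method = \"delong\" requires the pROC package")
    }
    r <- pROC::roc(response = truth, predictor = score, quiet = TRUE,
                   direction = "<", levels = c(FALSE, TRUE))
    ci <- as.numeric(pROC::ci.auc(r, conf.level = conf_level, method = "delong"))[c(1, 3)]
  }
  thresholds <- c(-Inf, sort(unique(score)), Inf)
  curve <- tibble::tibble(
    threshold = thresholds,
    sensitivity = vapply(thresholds, function(t) mean(score[truth] >= t), numeric(1)),
    specificity = vapply(thresholds, function(t) mean(score[!truth] < t), numeric(1))
  )
  structure(
    list(auc = auc, ci = ci, conf_level = conf_level, ci_method = ci_method,
         n_pos = n1, n_neg = n0, curve = curve),
    class = "mohi_roc"
  )
}

#' ROC curve and AUC of a risk score
#'
#' Computes the area under the receiver-operating-characteristic curve as
#' the Mann-Whitney concordance of the score between cases and controls
#' (ties count half), with a Hanley-McNeil normal-approximation confidence
#' interval by default (DeLong via pROC optional), plus the full
#' sensitivity/specificity operating-point sequence.
#'
#' @param data A data frame.
#' @param truth <[`data-masking`][rlang::args_data_masking]> logical (or
#'   0/1) outcome column.
#' @param estimate <[`data-masking`][rlang::args_data_masking]> numeric
#'   score or predicted probability column.
#' @param conf_level Confidence level of the AUC interval.
#' @param ci_method `"hanley-mcneil"` (default) or `"delong"`.
#' @return A `mohi_roc` object with elements `auc`, `ci`, `curve`;
#'   [autoplot.mohi_roc()] draws the curve.
#' @export
#' @examples
#' d <- data.frame(y = c(TRUE, TRUE, FALSE, FALSE), p = c(.9, .6, .4, .2))
#' roc_auc(d, y, p)$auc
roc_auc <- function(data, truth, estimate, conf_level = 0.95,
                    ci_method = c("hanley-mcneil", "delong")) {
  truth <- rlang::eval_tidy(rlang::enquo(truth), data)
  score <- rlang::eval_tidy(rlang::enquo(estimate), data)
  roc_from_vectors(truth, score, conf_level, ci_method)
}

#' @export
print.mohi_roc <- function(x, ...) {
  cat(sprintf("AUC = %.3f (%d%% CI %.3f-%.3f, %s; %d cases / %d controls)\n",
              x$auc, round(100 * x$conf_level), x$ci[1], x$ci[2],
              x$ci_method, x$n_pos, x$n_neg))
  invisible(x)
}

#' Tidy methods for ROC results
#'
#' `tidy()` returns the operating points (threshold, sensitivity,
#' specificity); `glance()` the one-row AUC summary.
#'
#' @param x A `mohi_roc`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mohi_roc
#' @export
tidy.mohi_roc <- function(x, ...) x$curve

#' @rdname tidy.mohi_roc
#' @method glance mohi_roc
#' @export
glance.mohi_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, conf.low = x$ci[1], conf.high = x$ci[2],
                 conf.level = x$conf_level, ci_method = x$ci_method,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}
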