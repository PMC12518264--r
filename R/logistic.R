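#' Candidate predictors of the oral-health risk models
#'
#' The candidate set of the degraded-oral-health model: age (continuous,
#' per-year effect), sex (ref male), education (ref higher), smoking status
#' (ref never), self-reported periodontitis (ref no), employment and
#' marital status.
#' @export
MOHI_CANDIDATE_PREDICTORS <- c(
  "age", "sex", "education", "smoking_status",
  "self_reported_periodontitis", "employment", "marital"
)

check_converged <- function(fit) {
  if (!fit$converged || any(abs(stats::coef(fit)[-1L]) > 15, na.rm = TRUE)) {
    abort(paste0(
      "logistic fit did not converge (possible complete separation); ",
      "check for predictors perfectly splitting the outcome"))
  }
  invisible(fit)
}

fit_logit <- function(formula, data) {
  # anchor the formula here so drop1()/add1() refits can find `data`
  environment(formula) <- environment()
  fit <- suppressWarnings(stats::glm(formula, data = data, family = stats::binomial()))
  check_converged(fit)
}

#' Stepwise binary logistic regression
#'
#' Fits a logistic model of a binary outcome and reduces it by backward
#' elimination on likelihood-ratio tests: starting from the full candidate
#' set, the term with the largest LR p-value is dropped while that p-value
#' is at or above `p_remove` (default 0.10); after each removal round,
#' dropped terms are rechecked and re-entered if their LR p-value falls
#' below `p_enter` (default 0.05). Categorical predictors enter and leave
#' as whole terms.
#'
#' @param data A scored cohort data frame (see [score_cohort()]).
#' @param outcome <[`data-masking`][rlang::args_data_masking]> logical (or
#'   0/1) outcome column, e.g. `degraded` or `high_caries`.
#' @param predictors Character vector of candidate predictor columns;
#'   defaults to [MOHI_CANDIDATE_PREDICTORS].
#' @param p_remove Removal threshold for backward elimination.
#' @param p_enter Re-entry threshold.
#' @param conf_level Confidence level of the Wald odds-ratio intervals.
#' @return A `mohi_logit` object: the reduced [stats::glm] fit plus the
#'   elimination trace. Use [tidy.mohi_logit()] for the odds-ratio table
#'   and [glance.mohi_logit()] for model-level statistics (likelihood-ratio
#'   chi-square, Nagelkerke R-squared, classification accuracy at the 0.5
#'   probability cutoff, AUC).
#' @export
#' @examples
#' cohort <- score_cohort(simulate_cohort(400, seed = 7))
#' fit <- stepwise_logistic(cohort, degraded,
#'                          predictors = c("age", "smoking_status"))
#' tidy(fit)
stepwise_logistic <- function(data, outcome,
                              predictors = MOHI_CANDIDATE_PREDICTORS,
                              p_remove = 0.10, p_enter = 0.05,
                              conf_level = 0.95) {
  data <- tibble::as_tibble(data)
  outcome_name <- rlang::as_name(rlang::enquo(outcome))
  y <- as.logical(rlang::eval_tidy(rlang::enquo(outcome), data))
  if (anyNA(y)) abort("outcome contains missing values")
  if (length(unique(y)) < 2L) {
    abort(sprintf("outcome %s has a single class; cannot fit", outcome_name))
  }
  missing_cols <- setdiff(predictors, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing predictor columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (p_enter > p_remove) {
    abort("p_enter must not exceed p_remove (would cycle)")
  }
  df <- data[predictors]
  df$.outcome <- y
  # constant predictors carry no information and would break drop1
  constant <- vapply(df[predictors], function(x) length(unique(x)) < 2L, logical(1))
  dropped_constant <- predictors[constant]
  current <- predictors[!constant]
  removed <- character()
  trace <- character()

  fit <- fit_logit(make_formula(current), df)
  # p_enter <= p_remove rules out the trivial remove/re-enter cycle; the
  # iteration cap guards the exotic multi-term ones
  for (iteration in seq_len(10L * max(1L, length(predictors)))) {
    while (length(current)) {
      d1 <- stats::drop1(fit, test = "LRT")
      p_vals <- d1[["Pr(>Chi)"]][-1L]
      terms <- rownames(d1)[-1L]
      worst <- which.max(p_vals)
      if (!length(worst) || p_vals[worst] < p_remove) break
      trace <- c(trace, sprintf("removed %s (LR p = %.3f)", terms[worst], p_vals[worst]))
      removed <- c(removed, terms[worst])
      current <- setdiff(current, terms[worst])
      fit <- fit_logit(make_formula(current), df)
    }
    re_entered <- FALSE
    if (length(removed)) {
      a1 <- stats::add1(fit, scope = make_formula(union(current, removed)), test = "LRT")
      p_vals <- a1[["Pr(>Chi)"]][-1L]
      terms <- rownames(a1)[-1L]
      best <- which.min(p_vals)
      if (length(best) && p_vals[best] < p_enter) {
        trace <- c(trace, sprintf("re-entered %s (LR p = %.3f)", terms[best], p_vals[best]))
        current <- c(current, terms[best])
        removed <- setdiff(removed, terms[best])
        fit <- fit_logit(make_formula(current), df)
        re_entered <- TRUE
      }
    }
    if (!re_entered) break
  }

  null_fit <- fit_logit(stats::as.formula(".outcome ~ 1"), df)
  structure(
    list(fit = fit, null_fit = null_fit, outcome = outcome_name,
         candidates = predictors, retained = current,
         removed = c(removed, dropped_constant), trace = trace,
         p_remove = p_remove, p_enter = p_enter, conf_level = conf_level),
    class = "mohi_logit"
  )
}

make_formula <- function(terms) {
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  stats::as.formula(paste(".outcome ~", rhs))
}

#' Fit the degraded-oral-health risk model
#'
#' [stepwise_logistic()] with outcome `degraded` (MOHi >= 1.5) and the
#' standard candidate set.
#'
#' @inheritParams stepwise_logistic
#' @param ... Passed on to [stepwise_logistic()].
#' @return A `mohi_logit`.
#' @export
fit_degraded_model <- function(data, predictors = MOHI_CANDIDATE_PREDICTORS, ...) {
  stepwise_logistic(data, !!rlang::sym("degraded"), predictors = predictors, ...)
}

#' Fit the alternative high-caries risk model
#'
#' The same stepwise machinery with the single-index outcome `high_caries`
#' (DMFT >= 14), for comparing which predictors the caries-only outcome
#' retains against the multidimensional one.
#'
#' @inheritParams fit_degraded_model
#' @return A `mohi_logit`.
#' @export
fit_high_caries_model <- function(data, predictors = MOHI_CANDIDATE_PREDICTORS, ...) {
  stepwise_logistic(data, !!rlang::sym("high_caries"), predictors = predictors, ...)
}

#' Nagelkerke pseudo R-squared
#'
#' Cox-Snell R-squared rescaled by its maximum attainable value, giving a
#' 0-1 measure of explained variation for logistic models:
#' `R2_CS = 1 - exp(-(2/n) (llik_full - llik_null))`,
#' `R2_N = R2_CS / (1 - exp((2/n) llik_null))`.
#'
#' @param fit A `mohi_logit` or a fitted binomial [stats::glm].
#' @param null_fit The intercept-only model on the same data; derived
#'   automatically for a `mohi_logit`.
#' @return A single number in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(fit, null_fit = NULL) {
  if (inherits(fit, "mohi_logit")) {
    null_fit <- null_fit %||% fit$null_fit
    fit <- fit$fit
  }
  if (is.null(null_fit)) {
    # refit on the stored response rather than update(), so the original
    # data frame need not be in scope
    y <- fit$y
    null_fit <- stats::glm(y ~ 1, family = stats::binomial())
  }
  n <- stats::nobs(fit)
  if (n != stats::nobs(null_fit) ||
      !isTRUE(all.equal(sum(fit$y), sum(null_fit$y)))) {
    abort("fitted and null models must be fitted on identical data")
  }
  ll_full <- as.numeric(stats::logLik(fit))
  ll_null <- as.numeric(stats::logLik(null_fit))
  r2_cs <- 1 - exp(-2 * (ll_full - ll_null) / n)
  r2_max <- 1 - exp(2 * ll_null / n)
  max(0, min(1, r2_cs / r2_max))
}

#' Classification accuracy at a probability cutoff
#'
#' Fraction of observations whose outcome is correctly classified when
#' predicted probability >= `cutoff` is called positive (default 0.5).
#'
#' @inheritParams nagelkerke_r2
#' @param cutoff Probability cutoff.
#' @return A fraction in `[0, 1]`.
#' @export
classification_accuracy <- function(fit, cutoff = 0.5) {
  if (inherits(fit, "mohi_logit")) fit <- fit$fit
  mean((stats::fitted(fit) >= cutoff) == (fit$y == 1))
}

#' @export
print.mohi_logit <- function(x, ...) {
  cat(sprintf("Stepwise logistic model of %s (n = %d)\n",
              x$outcome, stats::nobs(x$fit)))
  cat(sprintf("retained: %s\n",
              if (length(x$retained)) paste(x$retained, collapse = ", ") else "(none)"))
  if (length(x$removed)) cat(sprintf("removed:  %s\n", paste(x$removed, collapse = ", ")))
  print(tidy(x))
  g <- glance(x)
  cat(sprintf(
    "chi2(%d) = %.3f, p = %.3g | Nagelkerke R2 = %.3f | accuracy = %.3f | AUC = %.3f\n",
    g$df, g$statistic, g$p.value, g$nagelkerke_r2, g$accuracy, g$auc))
  invisible(x)
}

#' Tidy methods for stepwise logistic fits
#'
#' `tidy()` returns one row per model term with the log-odds estimate, Wald
#' statistics, and the odds ratio with its Wald confidence interval.
#' `glance()` returns the one-row model summary: likelihood-ratio
#' chi-square against the null model with its df and p-value, Nagelkerke
#' R-squared, classification accuracy at the 0.5 cutoff, and the AUC of the
#' fitted probabilities.
#'
#' @param x A `mohi_logit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mohi_logit
#' @export
tidy.mohi_logit <- function(x, ...) {
  z <- stats::qnorm(1 - (1 - x$conf_level) / 2)
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "z value"],
    p.value = s[, "Pr(>|z|)"],
    odds.ratio = exp(s[, "Estimate"]),
    or.conf.low = exp(s[, "Estimate"] - z * s[, "Std. Error"]),
    or.conf.high = exp(s[, "Estimate"] + z * s[, "Std. Error"])
  )
}

#' @rdname tidy.mohi_logit
#' @method glance mohi_logit
#' @export
glance.mohi_logit <- function(x, ...) {
  chisq <- x$fit$null.deviance - x$fit$deviance
  df <- x$fit$df.null - x$fit$df.residual
  roc <- roc_from_vectors(x$fit$y == 1, stats::fitted(x$fit))
  tibble::tibble(
    statistic = chisq,
    df = df,
    p.value = if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else NA_real_,
    nagelkerke_r2 = nagelkerke_r2(x),
    accuracy = classification_accuracy(x),
    auc = roc$auc,
    nobs = stats::nobs(x$fit)
  )
}
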