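group_summary <- function(values, groups, conf_level = 0.95) {
  tibble::tibble(value = values, group = groups) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = stats::sd(.data$value),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      se = .data$sd / sqrt(.data$n),
      ci_low = .data$mean - stats::qt(1 - (1 - conf_level) / 2, .data$n - 1) * .data$se,
      ci_high = .data$mean + stats::qt(1 - (1 - conf_level) / 2, .data$n - 1) * .data$se
    ) |>
    dplyr::select(-"se")
}

new_comparison <- function(variable, groups, p_value, method, letters = NULL, fit = NULL) {
  if (!is.null(letters)) groups$subset <- unname(letters[as.character(groups$group)])
  structure(
    list(variable = variable, groups = groups, p_value = p_value,
         method = method, fit = fit),
    class = "mohi_comparison"
  )
}

#' Two-group mean comparison
#'
#' Independent-samples t test of a continuous score (typically MOHi)
#' between the two levels of a binary factor, with per-group n, mean, SD
#' and t-based 95% confidence intervals for the means.
#'
#' @param data A data frame.
#' @param value <[`data-masking`][rlang::args_data_masking]> the continuous
#'   column to compare.
#' @param group <[`data-masking`][rlang::args_data_masking]> the grouping
#'   column (exactly 2 observed levels, each with n >= 2).
#' @param var_equal Assume equal variances (classical Student t, the
#'   default); `FALSE` gives the Welch test.
#' @param conf_level Confidence level for the group-mean intervals.
#' @return A `mohi_comparison` object; see [tidy.mohi_comparison()] and
#'   [glance.mohi_comparison()].
#' @export
compare_two_groups <- function(data, value, group, var_equal = TRUE,
                               conf_level = 0.95) {
  values <- rlang::eval_tidy(rlang::enquo(value), data)
  groups <- droplevels(as.factor(rlang::eval_tidy(rlang::enquo(group), data)))
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- groups[keep]
  lev <- levels(groups)
  if (length(lev) != 2L) {
    abort(sprintf("grouping must have exactly 2 levels, got %d", length(lev)))
  }
  counts <- table(groups)
  if (any(counts < 2L)) {
    abort(sprintf("group %s has fewer than 2 observations",
                  names(counts)[which(counts < 2L)[1L]]))
  }
  tt <- stats::t.test(values ~ groups, var.equal = var_equal)
  new_comparison(
    variable = rlang::as_label(rlang::enquo(group)),
    groups = group_summary(values, groups, conf_level),
    p_value = tt$p.value,
    method = if (var_equal) "t-test (pooled)" else "t-test (Welch)",
    fit = tt
  )
}

# Homogeneous-subset letters: maximal sets of mutually non-significant
# groups get one letter each; a group's label joins the letters of every
# subset containing it (e.g. "a,b" for a group bridging two subsets).
subset_letters <- function(group_names, p_matrix, alpha = 0.05) {
  k <- length(group_names)
  if (k > 15L) abort("homogeneous-subset letters support at most 15 groups")
  nonsig <- p_matrix >= alpha
  diag(nonsig) <- TRUE
  subsets <- list()
  for (code in seq_len(2^k) - 1L) {
    members <- which(bitwAnd(code, 2^(seq_len(k) - 1L)) > 0L)
    if (!length(members)) next
    if (all(nonsig[members, members])) subsets[[length(subsets) + 1L]] <- members
  }
  is_maximal <- vapply(subsets, function(s) {
    !any(vapply(subsets, function(t) length(t) > length(s) && all(s %in% t), logical(1)))
  }, logical(1))
  subsets <- subsets[is_maximal]
  # letter order follows the group order of the factor
  ord <- order(vapply(subsets, min, integer(1)),
               vapply(subsets, function(s) sum(2^s), numeric(1)))
  subsets <- subsets[ord]
  labels <- vapply(seq_len(k), function(g) {
    paste(letters[which(vapply(subsets, function(s) g %in% s, logical(1)))],
          collapse = ",")
  }, character(1))
  stats::setNames(labels, group_names)
}

#' Multi-group mean comparison with homogeneous subsets
#'
#' One-way ANOVA of a continuous score across a k-level factor, followed by
#' pairwise post-hoc comparisons converted to homogeneous-subset letters:
#' groups sharing a letter are not significantly different pairwise, groups
#' sharing no letter are. A group bridging two subsets gets both letters
#' ("a,b").
#'
#' @inheritParams compare_two_groups
#' @param group <[`data-masking`][rlang::args_data_masking]> the grouping
#'   column (>= 3 observed levels, each with n >= 2).
#' @param posthoc Pairwise post-hoc method for the letters: Tukey HSD
#'   (default) or Bonferroni-adjusted pairwise t tests.
#' @param alpha Significance level for the subset letters.
#' @return A `mohi_comparison` object with a `subset` letter per group.
#' @export
compare_k_groups <- function(data, value, group,
                             posthoc = c("tukey", "bonferroni"),
                             alpha = 0.05, conf_level = 0.95) {
  posthoc <- match.arg(posthoc)
  values <- rlang::eval_tidy(rlang::enquo(value), data)
  groups <- droplevels(as.factor(rlang::eval_tidy(rlang::enquo(group), data)))
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- groups[keep]
  lev <- levels(groups)
  if (length(lev) < 3L) abort("need at least 3 groups; use compare_two_groups()")
  counts <- table(groups)
  if (any(counts < 2L)) {
    abort(sprintf("group %s has fewer than 2 observations",
                  names(counts)[which(counts < 2L)[1L]]))
  }
  fit <- stats::aov(values ~ groups)
  p_global <- summary(fit)[[1]][["Pr(>F)"]][1L]

  k <- length(lev)
  p_mat <- matrix(1, k, k, dimnames = list(lev, lev))
  if (posthoc == "tukey") {
    tk <- stats::TukeyHSD(fit, conf.level = conf_level)$groups
    # rows follow combn(levels, 2) order, named "b-a"; map positionally so
    # level labels containing "-" (age bands) parse correctly
    pairs <- utils::combn(lev, 2L)
    stopifnot(nrow(tk) == ncol(pairs),
              all(rownames(tk) == paste(pairs[2L, ], pairs[1L, ], sep = "-")))
    for (i in seq_len(ncol(pairs))) {
      p_mat[pairs[1L, i], pairs[2L, i]] <-
        p_mat[pairs[2L, i], pairs[1L, i]] <- tk[i, "p adj"]
    }
  } else {
    pw <- stats::pairwise.t.test(values, groups, p.adjust.method = "bonferroni")$p.value
    for (a in rownames(pw)) for (b in colnames(pw)) {
      if (!is.na(pw[a, b])) p_mat[a, b] <- p_mat[b, a] <- pw[a, b]
    }
  }
  new_comparison(
    variable = rlang::as_label(rlang::enquo(group)),
    groups = group_summary(values, groups, conf_level),
    p_value = p_global,
    method = sprintf("one-way ANOVA + %s letters",
                     if (posthoc == "tukey") "Tukey HSD" else "Bonferroni"),
    letters = subset_letters(lev, p_mat, alpha),
    fit = fit
  )
}

#' @export
print.mohi_comparison <- function(x, ...) {
  cat(sprintf("Group comparison of %s (%s)\n", x$variable, x$method))
  print(x$groups)
  cat(sprintf("p = %.4g\n", x$p_value))
  invisible(x)
}

#' Tidy a group comparison
#'
#' `tidy()` returns the per-group table (n, mean, sd, CI and, for k-group
#' comparisons, the homogeneous-subset letter); `glance()` returns the
#' one-row test summary.
#'
#' @param x A `mohi_comparison`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mohi_comparison
#' @export
tidy.mohi_comparison <- function(x, ...) {
  dplyr::mutate(x$groups, variable = x$variable, .before = 1L)
}

#' @rdname tidy.mohi_comparison
#' @method glance mohi_comparison
#' @export
glance.mohi_comparison <- function(x, ...) {
  tibble::tibble(variable = x$variable, method = x$method,
                 n = sum(x$groups$n), p.value = x$p_value)
}
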