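moment_about_mean <- function(x, k) mean((x - mean(x))^k)

# Adjusted Fisher-Pearson (bias-corrected) skewness, the convention of the
# major commercial statistics packages: G1 = g1 * sqrt(n(n-1)) / (n-2).
sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m2 <- moment_about_mean(x, 2)
  if (m2 == 0) return(NA_real_)
  g1 <- moment_about_mean(x, 3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

# Bias-corrected excess kurtosis (normal -> 0):
# G2 = ((n+1) g2 + 6) (n-1) / ((n-2)(n-3)), g2 = m4/m2^2 - 3.
sample_kurtosis <- function(x) {
  n <- length(x)
  if (n < 4L) return(NA_real_)
  m2 <- moment_about_mean(x, 2)
  if (m2 == 0) return(NA_real_)
  g2 <- moment_about_mean(x, 4) / m2^2 - 3
  ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
}

#' Distribution descriptives
#'
#' Summarizes the selected numeric columns the way cohort score
#' distributions are conventionally reported: mean, sample SD (denominator
#' n-1), median, min-max, adjusted Fisher-Pearson skewness and
#' bias-corrected excess kurtosis (both 0 for a normal distribution in
#' expectation). Higher moments that are undefined at the available n (or
#' for a constant variable) are returned as `NA` and flagged in `note`.
#'
#' @param data A data frame.
#' @param ... <[`tidy-select`][dplyr::dplyr_tidy_select]> columns to
#'   summarize; defaults to all numeric columns.
#' @return A tibble with one row per variable: `variable`, `n`, `mean`,
#'   `sd`, `median`, `min`, `max`, `skewness`, `kurtosis`, `note`.
#' @export
#' @examples
#' describe(data.frame(x = c(1, 2, 3)))
describe <- function(data, ...) {
  data <- tibble::as_tibble(data)
  sel <- rlang::enquos(...)
  if (length(sel)) {
    cols <- names(dplyr::select(data, !!!sel))
  } else {
    cols <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  if (!length(cols)) abort("no numeric columns to describe")
  purrr::map_dfr(cols, function(nm) describe_vector(data[[nm]], nm))
}

describe_vector <- function(x, name) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 1L) abort(sprintf("variable %s has no finite values", name))
  notes <- character()
  sd_ <- if (n >= 2L) stats::sd(x) else { notes <- c(notes, "sd undefined (n < 2)"); NA_real_ }
  skw <- sample_skewness(x)
  krt <- sample_kurtosis(x)
  if (is.na(skw)) notes <- c(notes, "skewness undefined (n < 3 or constant)")
  if (is.na(krt)) notes <- c(notes, "kurtosis undefined (n < 4 or constant)")
  tibble::tibble(
    variable = name, n = n, mean = mean(x), sd = sd_,
    median = stats::median(x), min = min(x), max = max(x),
    skewness = skw, kurtosis = krt,
    note = if (length(notes)) paste(notes, collapse = "; ") else NA_character_
  )
}
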