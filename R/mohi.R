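OHVS_MIN <- 12L; OHVS_MAX <- 60L
OHIP_MIN <- 0L;  OHIP_MAX <- 56L
DMFT_MIN <- 0L;  DMFT_MAX <- 32L

#' MOHi thresholds
#'
#' `MOHI_DEGRADED_CUTOFF` is the MOHi score at or above which oral health is
#' classed as degraded (the binary outcome of the risk model);
#' `DMFT_HIGH_CARIES_CUTOFF` is the DMFT count at or above which caries
#' experience is classed as high (the alternative model's outcome). Both
#' comparisons are inclusive.
#' @name mohi-thresholds
#' @export
MOHI_DEGRADED_CUTOFF <- 1.5
#' @rdname mohi-thresholds
#' @export
DMFT_HIGH_CARIES_CUTOFF <- 14L

check_range <- function(x, lo, hi, what) {
  bad <- which(is.na(x) | x < lo | x > hi)
  if (length(bad)) {
    abort(sprintf("%s out of range [%s, %s] at position %d (value %s)",
                  what, lo, hi, bad[1L], deparse(x[bad[1L]])))
  }
  invisible(x)
}

#' MOHi normalized components
#'
#' The MOHi composite is the equally weighted sum of three components, each
#' normalized to `[0, 1]` by the theoretical bounds of its instrument (not
#' the sample range):
#' \describe{
#'   \item{A}{`1 - (OHVS - 12) / 48` -- reversed so that a low value placed
#'     on oral health contributes to a high (worse) MOHi.}
#'   \item{B}{`OHIP-14 / 56` -- impact on quality of life.}
#'   \item{C}{`DMFT / 32` -- caries experience.}
#' }
#' Each component contributes exactly one unit of the 0-3 MOHi range.
#'
#' @param ohvs_total OHVS total(s) in `[12, 60]`.
#' @param ohip_total OHIP-14 total(s) in `[0, 56]`.
#' @param dmft_total DMFT total(s) in `[0, 32]`.
#' @return A numeric vector in `[0, 1]`.
#' @name mohi-components
#' @export
#' @examples
#' mohi_component_a(c(12, 36, 60))
mohi_component_a <- function(ohvs_total) {
  check_range(ohvs_total, OHVS_MIN, OHVS_MAX, "OHVS total")
  1 - (ohvs_total - OHVS_MIN) / (OHVS_MAX - OHVS_MIN)
}

#' @rdname mohi-components
#' @export
mohi_component_b <- function(ohip_total) {
  check_range(ohip_total, OHIP_MIN, OHIP_MAX, "OHIP-14 total")
  ohip_total / OHIP_MAX
}

#' @rdname mohi-components
#' @export
mohi_component_c <- function(dmft_total) {
  check_range(dmft_total, DMFT_MIN, DMFT_MAX, "DMFT total")
  dmft_total / DMFT_MAX
}

#' Compute the Multidimensional Oral Health indicator (MOHi)
#'
#' MOHi = A + B + C, the equally weighted sum of the normalized OHVS,
#' OHIP-14 and DMFT scores (see [mohi_component_a()]). It lives on a
#' continuous 0-3 scale where higher values represent a more degraded oral
#' health condition: 0 only for OHVS 60 / OHIP 0 / DMFT 0, and 3 only for
#' OHVS 12 / OHIP 56 / DMFT 32. Components are never rounded before
#' summation.
#'
#' @inheritParams mohi-components
#' @return A tibble with columns `mohi_a`, `mohi_b`, `mohi_c`, `mohi`,
#'   `degraded` (MOHi >= 1.5) and `high_caries` (DMFT >= 14).
#' @export
#' @examples
#' compute_mohi(60, 0, 0)$mohi   # best possible oral health: 0
#' compute_mohi(12, 56, 32)$mohi # worst possible: 3
compute_mohi <- function(ohvs_total, ohip_total, dmft_total) {
  a <- mohi_component_a(ohvs_total)
  b <- mohi_component_b(ohip_total)
  c <- mohi_component_c(dmft_total)
  score <- a + b + c
  tibble::tibble(
    mohi_a = a, mohi_b = b, mohi_c = c, mohi = score,
    degraded = classify_degraded(score),
    high_caries = classify_high_caries(dmft_total)
  )
}

#' Degraded oral health classification
#'
#' TRUE when the MOHi score is at or above 1.5, the cutoff defining the
#' degraded oral health condition modelled by [fit_degraded_model()]. The
#' boundary is included.
#'
#' @param score MOHi score(s) in `[0, 3]`.
#' @return A logical vector.
#' @export
classify_degraded <- function(score) {
  check_range(score, 0, 3, "MOHi score")
  score >= MOHI_DEGRADED_CUTOFF
}

#' High caries experience classification
#'
#' TRUE when the DMFT total is 14 or higher, the cutoff of the alternative
#' single-index risk model ([fit_high_caries_model()]).
#'
#' @inheritParams mohi-components
#' @return A logical vector.
#' @export
classify_high_caries <- function(dmft_total) {
  check_range(dmft_total, DMFT_MIN, DMFT_MAX, "DMFT total")
  dmft_total >= DMFT_HIGH_CARIES_CUTOFF
}

#' Append MOHi columns to a scored cohort
#'
#' Requires the instrument totals produced by [score_instruments()]
#' (`ohvs_total`, `ohip_total`, `dmft_total`) and appends the normalized
#' components, the MOHi score and the two outcome flags.
#'
#' @param data A data frame with instrument total columns.
#' @return `data` as a tibble with `mohi_a`, `mohi_b`, `mohi_c`, `mohi`,
#'   `degraded`, `high_caries` appended.
#' @export
add_mohi <- function(data) {
  data <- tibble::as_tibble(data)
  data <- data[setdiff(names(data), c("mohi_a", "mohi_b", "mohi_c", "mohi",
                                      "degraded", "high_caries"))]
  need <- c("ohvs_total", "ohip_total", "dmft_total")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("add_mohi() needs columns ", paste(missing_cols, collapse = ", "),
                 "; run score_instruments() first"))
  }
  dplyr::bind_cols(data, compute_mohi(data$ohvs_total, data$ohip_total, data$dmft_total))
}

#' Score a raw cohort end to end
#'
#' Convenience wrapper: [score_instruments()] then [add_mohi()].
#'
#' @inheritParams score_instruments
#' @return A fully scored cohort tibble.
#' @export
score_cohort <- function(data) {
  add_mohi(score_instruments(data))
}
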