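#' @importFrom rlang .data abort
#' @importFrom stats qlogis qnorm plogis pnorm quantile
NULL

OHVS_N_ITEMS <- 12L
OHIP_N_ITEMS <- 14L
N_TEETH <- 32L
TOOTH_CODES <- c("S", "D", "M", "F")

# OHVS subdomain item indices (1-based)
OHVS_SUBDOMAINS <- list(
  professional_dental_care = c(4L, 8L, 11L),
  appearance_and_health    = c(3L, 7L, 12L),
  flossing                 = c(2L, 5L, 10L),
  retaining_natural_teeth  = c(1L, 6L, 9L)
)

# Coerce a single response vector or an n x k matrix/data frame to a matrix,
# validating length/width, integrality and range. Errors name the first
# offending item so a bad record can be traced back to its questionnaire item.
as_item_matrix <- function(items, n_items, lo, hi, what) {
  if (is.data.frame(items)) items <- as.matrix(items)
  if (!is.matrix(items)) {
    if (length(items) != n_items) {
      abort(sprintf("%s must have exactly %d items, got %d",
                    what, n_items, length(items)))
    }
    items <- matrix(items, nrow = 1L)
  }
  if (ncol(items) != n_items) {
    abort(sprintf("%s must have exactly %d items, got %d columns",
                  what, n_items, ncol(items)))
  }
  storage.mode(items) <- "double"
  bad <- which(is.na(items) | items < lo | items > hi | items != round(items))
  if (length(bad)) {
    item_idx <- ((bad[1L] - 1L) %/% nrow(items)) + 1L
    row_idx <- ((bad[1L] - 1L) %% nrow(items)) + 1L
    abort(sprintf(
      "%s item %d (row %d) is missing or outside [%d, %d]",
      what, item_idx, row_idx, lo, hi))
  }
  items
}

#' Score the Oral Health Value Scale (OHVS)
#'
#' The OHVS is a 12-item instrument measuring how much an individual values
#' oral health, each item rated on a 5-point Likert scale (1 = strongly
#' disagree to 5 = strongly agree). The total is the plain item sum, ranging
#' 12 (lowest possible value placed on oral health) to 60 (highest).
#'
#' Records with missing or out-of-range items are rejected rather than
#' imputed; cohort-level filtering of incomplete questionnaires is handled by
#' [load_cohort()].
#'
#' @param items An integer vector of length 12 (one respondent), or an
#'   `n x 12` matrix/data frame (one row per respondent), values in 1..5.
#' @return An integer vector of OHVS totals in `[12, 60]`.
#' @seealso [ohvs_subdomains()], [score_ohip()], [mohi_component_a()]
#' @export
#' @examples
#' score_ohvs(rep(3, 12))
score_ohvs <- function(items) {
  m <- as_item_matrix(items, OHVS_N_ITEMS, 1L, 5L, "OHVS response")
  as.integer(rowSums(m))
}

#' OHVS subdomain sums
#'
#' The 12 OHVS items partition into four 3-item subdomains: professional
#' dental care (items 4, 8, 11), appearance and health (3, 7, 12), flossing
#' (2, 5, 10) and retaining natural teeth (1, 6, 9). Each subdomain sum
#' ranges 3-15 and the four sums add up to the OHVS total.
#'
#' @inheritParams score_ohvs
#' @return A tibble with one row per respondent and one column per subdomain.
#' @export
ohvs_subdomains <- function(items) {
  m <- as_item_matrix(items, OHVS_N_ITEMS, 1L, 5L, "OHVS response")
  out <- lapply(OHVS_SUBDOMAINS, function(idx) as.integer(rowSums(m[, idx, drop = FALSE])))
  tibble::as_tibble(out)
}

#' Score the Oral Health Impact Profile short form (OHIP-14)
#'
#' The OHIP-14 asks how often 14 oral-health problems interfered with daily
#' life, each on a 5-point frequency scale coded 0 (never) to 4 (very often).
#' The total is the item sum, 0-56, higher meaning worse oral-health-related
#' quality of life.
#'
#' @param items An integer vector of length 14, or an `n x 14` matrix/data
#'   frame, values in 0..4.
#' @return An integer vector of OHIP-14 totals in `[0, 56]`.
#' @export
#' @examples
#' score_ohip(rep(0, 14))
score_ohip <- function(items) {
  m <- as_item_matrix(items, OHIP_N_ITEMS, 0L, 4L, "OHIP-14 response")
  as.integer(rowSums(m))
}

as_tooth_matrix <- function(statuses) {
  if (is.data.frame(statuses)) statuses <- as.matrix(statuses)
  if (!is.matrix(statuses)) {
    if (length(statuses) != N_TEETH) {
      abort(sprintf("tooth chart must have exactly %d teeth, got %d",
                    N_TEETH, length(statuses)))
    }
    statuses <- matrix(statuses, nrow = 1L)
  }
  if (ncol(statuses) != N_TEETH) {
    abort(sprintf("tooth chart must have exactly %d teeth, got %d columns",
                  N_TEETH, ncol(statuses)))
  }
  statuses[] <- toupper(as.character(statuses))
  bad <- which(!(statuses %in% TOOTH_CODES))
  if (length(bad)) {
    tooth_idx <- ((bad[1L] - 1L) %/% nrow(statuses)) + 1L
    abort(sprintf(
      "tooth %d has unknown status %s (expected one of S, D, M, F)",
      tooth_idx, deparse(statuses[bad[1L]])))
  }
  statuses
}

#' Decayed, Missing and Filled Teeth (DMFT) index
#'
#' Counts decayed (D), missing (M) and filled (F) teeth on a 32-tooth chart
#' (full permanent dentition including third molars); sound (S) teeth
#' contribute nothing. The DMFT total is D + M + F, the standard
#' caries-experience index, 0-32 here.
#'
#' @param statuses A character vector of length 32 with codes
#'   `"S"`, `"D"`, `"M"`, `"F"` (case-insensitive), or an `n x 32`
#'   matrix/data frame of such codes. Tooth position carries no weight, so
#'   no FDI/universal numbering convention is assumed.
#' @return A tibble with columns `dmft_d`, `dmft_m`, `dmft_f`, `dmft_total`.
#' @export
#' @examples
#' compute_dmft(c(rep("S", 20), rep("D", 3), rep("M", 6), rep("F", 3)))
compute_dmft <- function(statuses) {
  m <- as_tooth_matrix(statuses)
  tibble::tibble(
    dmft_d = as.integer(rowSums(m == "D")),
    dmft_m = as.integer(rowSums(m == "M")),
    dmft_f = as.integer(rowSums(m == "F")),
    dmft_total = as.integer(rowSums(m != "S"))
  )
}

#' Severe tooth loss
#'
#' A participant has severe tooth loss when fewer than 10 teeth remain,
#' i.e. the count of non-missing teeth on the 32-tooth chart is below 10.
#'
#' @inheritParams compute_dmft
#' @return A logical vector.
#' @export
severe_tooth_loss <- function(statuses) {
  m <- as_tooth_matrix(statuses)
  as.vector(rowSums(m != "M") < 10L)
}

#' NHANES smoking-status classification
#'
#' Classifies smoking history into never (smoked fewer than 100 cigarettes
#' in their lifetime), former (at least 100 lifetime cigarettes, not a
#' current smoker) and active (at least 100 lifetime cigarettes and
#' currently smoking), following the NHANES convention.
#'
#' @param lifetime_at_least_100 Logical: smoked >= 100 cigarettes lifetime.
#' @param currently_smokes Logical: currently smokes.
#' @return A factor with levels `never`, `former`, `active` (never first,
#'   the reference category of the risk models).
#' @export
classify_smoking <- function(lifetime_at_least_100, currently_smokes) {
  lifetime <- as.logical(lifetime_at_least_100)
  current <- as.logical(currently_smokes)
  if (anyNA(lifetime) || anyNA(current)) {
    abort("smoking history fields must be present (0/1 or TRUE/FALSE)")
  }
  if (length(lifetime) != length(current)) {
    abort("smoking history fields must have equal length")
  }
  out <- ifelse(!lifetime, "never", ifelse(current, "active", "former"))
  factor(out, levels = c("never", "former", "active"))
}

#' Score all instruments on a raw cohort table
#'
#' Takes a cohort in the raw column schema (`ohvs_01`..`ohvs_12`,
#' `ohip_01`..`ohip_14`, `tooth_01`..`tooth_32`, `smoked_100_lifetime`,
#' `smokes_now`, ...) and appends the derived instrument scores: OHVS total
#' and subdomains, OHIP-14 total, the DMFT triple and total, the severe
#' tooth loss flag and the NHANES smoking status.
#'
#' @param data A data frame in the raw cohort schema (see [load_cohort()]).
#' @return `data` as a tibble with derived score columns appended.
#' @seealso [add_mohi()], [score_cohort()]
#' @export
score_instruments <- function(data) {
  data <- tibble::as_tibble(data)
  # recomputing on an already-scored table overwrites the derived columns
  derived <- c("ohvs_total", names(OHVS_SUBDOMAINS), "ohip_total",
               "dmft_d", "dmft_m", "dmft_f", "dmft_total",
               "severe_tooth_loss", "smoking_status")
  data <- data[setdiff(names(data), derived)]
  ohvs_cols <- sprintf("ohvs_%02d", 1:OHVS_N_ITEMS)
  ohip_cols <- sprintf("ohip_%02d", 1:OHIP_N_ITEMS)
  tooth_cols <- sprintf("tooth_%02d", 1:N_TEETH)
  missing_cols <- setdiff(c(ohvs_cols, ohip_cols, tooth_cols,
                            "smoked_100_lifetime", "smokes_now"), names(data))
  if (length(missing_cols)) {
    abort(paste0("cohort table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  ohvs <- as.matrix(data[ohvs_cols])
  ohip <- as.matrix(data[ohip_cols])
  teeth <- as.matrix(data[tooth_cols])
  dmft <- compute_dmft(teeth)
  dplyr::bind_cols(
    data,
    tibble::tibble(ohvs_total = score_ohvs(ohvs)),
    ohvs_subdomains(ohvs),
    tibble::tibble(ohip_total = score_ohip(ohip)),
    dmft,
    tibble::tibble(
      severe_tooth_loss = severe_tooth_loss(teeth),
      smoking_status = classify_smoking(data$smoked_100_lifetime, data$smokes_now)
    )
  )
}
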