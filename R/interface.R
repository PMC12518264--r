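RAW_REQUIRED_COLS <- c(
  sprintf("ohvs_%02d", 1:12), sprintf("ohip_%02d", 1:14),
  sprintf("tooth_%02d", 1:32),
  "age", "sex", "education", "employment", "marital",
  "smoked_100_lifetime", "smokes_now", "self_reported_periodontitis"
)

is_int_in <- function(x, lo, hi) {
  suppressWarnings(v <- as.numeric(x))
  !is.na(v) & v >= lo & v <= hi & v == round(v)
}

# Per-row completeness/validity in the raw schema; returns a logical vector
row_is_valid <- function(data) {
  ok <- rep(TRUE, nrow(data))
  for (col in sprintf("ohvs_%02d", 1:12)) ok <- ok & is_int_in(data[[col]], 1, 5)
  for (col in sprintf("ohip_%02d", 1:14)) ok <- ok & is_int_in(data[[col]], 0, 4)
  for (col in sprintf("tooth_%02d", 1:32)) {
    ok <- ok & toupper(as.character(data[[col]])) %in% TOOTH_CODES
  }
  suppressWarnings(age <- as.numeric(data$age))
  ok <- ok & !is.na(age) & age >= 18 & age <= 120
  ok <- ok & toupper(as.character(data$sex)) %in% c("F", "M", "FEMALE", "MALE")
  ok <- ok & as.character(data$education) %in% c("elementary", "middle", "higher")
  ok <- ok & as.character(data$employment) %in%
    c("student", "employed", "unemployed", "retired")
  ok <- ok & as.character(data$marital) %in%
    c("single", "married", "divorced", "widowed")
  for (col in c("smoked_100_lifetime", "smokes_now", "self_reported_periodontitis")) {
    ok <- ok & is_int_in(data[[col]], 0, 1)
  }
  ok & !is.na(ok)
}

normalize_raw_cohort <- function(data) {
  data$age <- as.numeric(data$age)
  sex <- toupper(as.character(data$sex))
  data$sex <- factor(ifelse(sex %in% c("F", "FEMALE"), "female", "male"),
                     levels = c("male", "female"))
  data$education <- factor(data$education, levels = c("higher", "middle", "elementary"))
  data$employment <- factor(data$employment,
                            levels = c("employed", "student", "unemployed", "retired"))
  data$marital <- factor(data$marital,
                         levels = c("single", "married", "divorced", "widowed"))
  for (col in c("smoked_100_lifetime", "smokes_now", "self_reported_periodontitis")) {
    data[[col]] <- as.integer(data[[col]])
  }
  for (col in c(sprintf("ohvs_%02d", 1:12), sprintf("ohip_%02d", 1:14))) {
    data[[col]] <- as.integer(data[[col]])
  }
  for (col in sprintf("tooth_%02d", 1:32)) {
    data[[col]] <- toupper(as.character(data[[col]]))
  }
  data
}

#' Load a cohort file with the inclusion filter
#'
#' Reads a comma-separated cohort table in the raw schema
#' (`ohvs_01..ohvs_12` in 1-5, `ohip_01..ohip_14` in 0-4,
#' `tooth_01..tooth_32` coded S/D/M/F, sociodemographics, the two NHANES
#' smoking items and the periodontitis flag) and applies the study-style
#' inclusion flow: rows flagged in an optional `refused` column are counted
#' as refusals; remaining rows failing validation (missing items,
#' out-of-range codes) are counted as incomplete and excluded; the clean
#' rows form the analyzed cohort. The resulting counts (invited, refused,
#' incomplete, included) are attached as the inclusion ledger, retrievable
#' with [inclusion_ledger()].
#'
#' @param path Path to a CSV file (UTF-8, header row).
#' @return A tibble of included participants with typed columns (sex,
#'   education, employment, marital as factors with the risk-model
#'   reference levels first) and an `inclusion_ledger` attribute.
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) abort(sprintf("cohort file not found: %s", path))
  data <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_character())),
    error = function(e) abort(sprintf("cannot read cohort file %s: %s",
                                      path, conditionMessage(e)))
  )
  missing_cols <- setdiff(RAW_REQUIRED_COLS, names(data))
  if (length(missing_cols)) {
    abort(paste0("malformed cohort header; missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  invited <- nrow(data)
  if ("refused" %in% names(data)) {
    refused_flag <- !is.na(data$refused) & as.character(data$refused) %in% c("1", "TRUE")
  } else {
    refused_flag <- rep(FALSE, invited)
  }
  refused <- sum(refused_flag)
  data <- data[!refused_flag, , drop = FALSE]
  valid <- row_is_valid(data)
  incomplete <- sum(!valid)
  clean <- normalize_raw_cohort(tibble::as_tibble(data[valid, , drop = FALSE]))
  clean$refused <- NULL
  # extra (e.g. previously derived) columns were read as character; re-type
  for (col in setdiff(names(clean), RAW_REQUIRED_COLS)) {
    clean[[col]] <- utils::type.convert(clean[[col]], as.is = TRUE)
  }
  ledger <- tibble::tibble(invited = invited, refused = refused,
                           incomplete = incomplete,
                           included = invited - refused - incomplete)
  stopifnot(ledger$included == nrow(clean))
  attr(clean, "inclusion_ledger") <- ledger
  clean
}

#' Inclusion ledger of a loaded cohort
#'
#' @param data A cohort loaded with [load_cohort()].
#' @return A one-row tibble: `invited`, `refused`, `incomplete`, `included`
#'   (with included = invited - refused - incomplete).
#' @export
inclusion_ledger <- function(data) {
  ledger <- attr(data, "inclusion_ledger")
  if (is.null(ledger)) {
    ledger <- tibble::tibble(invited = nrow(data), refused = 0L,
                             incomplete = 0L, included = nrow(data))
  }
  ledger
}

#' Write a cohort table in the raw CSV schema
#'
#' Serializes an in-memory cohort (simulated or loaded) to the raw
#' comma-separated schema, mapping sex back to the `F`/`M` codes. Derived
#' score columns, if present, are written as-is, so a scored cohort
#' round-trips through [load_cohort()] + [score_cohort()] to identical
#' derived values.
#'
#' @param data A cohort tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  out <- tibble::as_tibble(data)
  if ("sex" %in% names(out)) {
    out$sex <- ifelse(as.character(out$sex) %in% c("female", "F"), "F", "M")
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Age bands used in the group comparisons
#'
#' 18-44, 45-64 and 65+ years.
#'
#' @param age Numeric vector of ages.
#' @return An ordered-level factor.
#' @export
age_bands <- function(age) {
  cut(age, breaks = c(18, 45, 65, Inf), right = FALSE,
      labels = c("18-44", "45-64", "65+"), include.lowest = TRUE)
}

#' Run the full cohort analysis
#'
#' The complete analysis stack on a scored cohort: distribution
#' descriptives of OHVS, OHIP-14, DMFT and MOHi; MOHi mean comparisons
#' across periodontitis status, sex, age bands, education, smoking,
#' employment and marital status (t tests for 2-level factors, one-way
#' ANOVA with homogeneous-subset letters otherwise); the stepwise logistic
#' model of the degraded outcome with its ROC; and the alternative
#' high-caries (DMFT >= 14) model.
#'
#' @param data A cohort; raw tables are scored automatically.
#' @param posthoc Post-hoc method for subset letters, see
#'   [compare_k_groups()].
#' @param p_remove,p_enter Stepwise thresholds, see [stepwise_logistic()].
#' @return A `mohi_analysis` list: `descriptives`, `comparisons` (named
#'   list of `mohi_comparison`), `model`, `roc`, `model_dmft`, `roc_dmft`,
#'   `settings`, `ledger`.
#' @export
analyze_cohort <- function(data, posthoc = c("tukey", "bonferroni"),
                           p_remove = 0.10, p_enter = 0.05) {
  posthoc <- match.arg(posthoc)
  ledger <- inclusion_ledger(data)
  if (nrow(data) == 0L) abort("cohort is empty after filtering; nothing to analyze")
  if (all(RAW_REQUIRED_COLS %in% names(data))) {
    data <- score_cohort(data) # (re)score from the raw items
  } else if (!all(c("mohi", "degraded") %in% names(data))) {
    abort("data has neither the raw item columns nor scored MOHi columns")
  }
  data$age_band <- age_bands(data$age)
  data$periodontitis <- factor(ifelse(data$self_reported_periodontitis == 1, "yes", "no"),
                               levels = c("no", "yes"))

  descriptives <- describe(data, dplyr::all_of(c("ohvs_total", "ohip_total",
                                                 "dmft_total", "mohi")))
  two_level <- c("periodontitis", "sex")
  k_level <- c("age_band", "education", "smoking_status", "employment", "marital")
  comparisons <- c(
    lapply(rlang::set_names(two_level), function(v) {
      compare_two_groups(data, !!rlang::sym("mohi"), !!rlang::sym(v))
    }),
    lapply(rlang::set_names(k_level), function(v) {
      compare_k_groups(data, !!rlang::sym("mohi"), !!rlang::sym(v), posthoc = posthoc)
    })
  )
  model <- fit_degraded_model(data, p_remove = p_remove, p_enter = p_enter)
  roc <- roc_from_vectors(model$fit$y == 1, stats::fitted(model$fit))
  model_dmft <- tryCatch(
    fit_high_caries_model(data, p_remove = p_remove, p_enter = p_enter),
    error = function(e) e
  )
  roc_dmft <- if (inherits(model_dmft, "mohi_logit")) {
    roc_from_vectors(model_dmft$fit$y == 1, stats::fitted(model_dmft$fit))
  }
  structure(
    list(descriptives = descriptives, comparisons = comparisons,
         model = model, roc = roc, model_dmft = model_dmft, roc_dmft = roc_dmft,
         ledger = ledger,
         settings = list(stepwise = "backward elimination on LR tests with re-entry",
                         p_remove = p_remove, p_enter = p_enter,
                         posthoc = posthoc,
                         degraded_cutoff = MOHI_DEGRADED_CUTOFF,
                         high_caries_cutoff = DMFT_HIGH_CARIES_CUTOFF,
                         accuracy_cutoff = 0.5)),
    class = "mohi_analysis"
  )
}

comparison_table <- function(comparisons) {
  purrr::map_dfr(comparisons, function(cmp) {
    tb <- tidy(cmp)
    if (!"subset" %in% names(tb)) tb$subset <- NA_character_
    tb$p.value <- cmp$p_value
    tb$method <- cmp$method
    tb
  })
}

round_cols <- function(df, digits, cols = NULL) {
  cols <- cols %||% names(df)[vapply(df, is.numeric, logical(1))]
  for (col in intersect(cols, names(df))) df[[col]] <- round(df[[col]], digits)
  df
}

#' Run the end-to-end pipeline and write the report bundle
#'
#' Loads (or simulates) a cohort, scores the instruments, computes MOHi,
#' runs [analyze_cohort()] and writes the result bundle to `out_dir`:
#' the scored cohort, the inclusion ledger, descriptives, group
#' comparisons, the two model term tables with a model-summary table, the
#' ROC operating points, and a plain-text report logging every analysis
#' setting in effect. Output is deterministic given `seed`. Numbers are
#' rounded only at serialization (2 decimals for scores, 1 for
#' percentages).
#'
#' @param input Path to a raw cohort CSV, or `NULL` to simulate.
#' @param out_dir Output directory (created if needed).
#' @param n,seed,config Simulation arguments when `input` is `NULL`
#'   (see [simulate_cohort()]); `config` may be a [mohi_sim_config()] or a
#'   path to a YAML configuration.
#' @param ... Passed to [analyze_cohort()].
#' @return The `mohi_analysis`, invisibly.
#' @export
run_pipeline <- function(input = NULL, out_dir, n = 1000, seed = 1,
                         config = NULL, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(input)) {
    if (is.character(config)) config <- read_sim_config(config)
    cohort <- simulate_cohort(n, seed, config %||% mohi_sim_config())
    source_desc <- sprintf("simulated cohort (n = %d, seed = %d)", n, as.integer(seed))
  } else {
    cohort <- load_cohort(input)
    source_desc <- sprintf("loaded cohort from %s", input)
  }
  ledger <- inclusion_ledger(cohort)
  readr::write_csv(ledger, file.path(out_dir, "inclusion_ledger.csv"), progress = FALSE)
  if (nrow(cohort) == 0L) {
    abort(sprintf(
      "cohort is empty after filtering (invited %d, refused %d, incomplete %d); ledger written to %s",
      ledger$invited, ledger$refused, ledger$incomplete, out_dir))
  }
  scored <- score_cohort(cohort)
  attr(scored, "inclusion_ledger") <- ledger
  analysis <- analyze_cohort(scored, ...)

  write_cohort(scored, file.path(out_dir, "cohort_scored.csv"))
  readr::write_csv(round_cols(analysis$descriptives, 2L),
                   file.path(out_dir, "descriptives.csv"), progress = FALSE)
  readr::write_csv(round_cols(comparison_table(analysis$comparisons), 2L,
                              c("mean", "sd", "ci_low", "ci_high")),
                   file.path(out_dir, "group_comparisons.csv"), progress = FALSE)
  readr::write_csv(round_cols(tidy(analysis$model), 2L,
                              c("odds.ratio", "or.conf.low", "or.conf.high")),
                   file.path(out_dir, "model_mohi.csv"), progress = FALSE)
  summaries <- dplyr::bind_rows(
    dplyr::mutate(glance(analysis$model), model = "degraded (MOHi >= 1.5)", .before = 1L),
    if (inherits(analysis$model_dmft, "mohi_logit")) {
      dplyr::mutate(glance(analysis$model_dmft),
                    model = "high caries (DMFT >= 14)", .before = 1L)
    }
  )
  readr::write_csv(round_cols(summaries, 3L),
                   file.path(out_dir, "model_summary.csv"), progress = FALSE)
  if (inherits(analysis$model_dmft, "mohi_logit")) {
    readr::write_csv(round_cols(tidy(analysis$model_dmft), 2L,
                                c("odds.ratio", "or.conf.low", "or.conf.high")),
                     file.path(out_dir, "model_dmft.csv"), progress = FALSE)
  }
  readr::write_csv(round_cols(tidy(analysis$roc), 3L),
                   file.path(out_dir, "roc_mohi.csv"), progress = FALSE)
  writeLines(pipeline_report(analysis, source_desc, seed),
             file.path(out_dir, "report.txt"))
  invisible(analysis)
}

pipeline_report <- function(analysis, source_desc, seed) {
  s <- analysis$settings
  g <- glance(analysis$model)
  pct <- function(x) sprintf("%.1f%%", 100 * x)
  c(
    "MOHi cohort analysis report",
    "===========================",
    sprintf("input: %s", source_desc),
    sprintf("seed: %d", as.integer(seed)),
    "",
    "inclusion flow:",
    sprintf("  invited %d | refused %d | incomplete %d | included %d",
            analysis$ledger$invited, analysis$ledger$refused,
            analysis$ledger$incomplete, analysis$ledger$included),
    "",
    "settings in effect:",
    sprintf("  stepwise variant: %s (remove at p >= %.2f, re-enter at p < %.2f)",
            s$stepwise, s$p_remove, s$p_enter),
    sprintf("  post-hoc subsets: %s at alpha = 0.05", s$posthoc),
    sprintf("  degraded outcome: MOHi >= %.1f; high caries: DMFT >= %d",
            s$degraded_cutoff, s$high_caries_cutoff),
    sprintf("  classification cutoff: probability >= %.1f", s$accuracy_cutoff),
    "  group-comparison p-values are unadjusted across variables",
    "",
    "degraded-oral-health model:",
    sprintf("  retained: %s", paste(analysis$model$retained, collapse = ", ")),
    sprintf("  chi2(%d) = %.3f, p = %.3g; Nagelkerke R2 = %s; accuracy = %s",
            g$df, g$statistic, g$p.value, pct(g$nagelkerke_r2), pct(g$accuracy)),
    sprintf("  AUC = %.2f (95%% CI %.2f-%.2f)",
            analysis$roc$auc, analysis$roc$ci[1], analysis$roc$ci[2]),
    "",
    if (inherits(analysis$model_dmft, "mohi_logit")) {
      sprintf("high-caries model retained: %s",
              paste(analysis$model_dmft$retained, collapse = ", "))
    } else {
      sprintf("high-caries model not fitted: %s", conditionMessage(analysis$model_dmft))
    }
  )
}
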