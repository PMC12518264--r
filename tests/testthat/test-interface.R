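write_temp_cohort <- function(data, ...) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  write_cohort(data, path)
  path
}

test_that("a fully valid file is included in full", {
  cohort <- simulate_cohort(5, seed = 80)
  path <- write_temp_cohort(cohort)
  loaded <- load_cohort(path)
  ledger <- inclusion_ledger(loaded)
  expect_equal(ledger, tibble::tibble(invited = 5L, refused = 0L,
                                      incomplete = 0L, included = 5L))
  expect_equal(nrow(loaded), 5)
})

test_that("rows with missing or invalid items count as incomplete", {
  cohort <- simulate_cohort(5, seed = 81)
  cohort$ohvs_03[2] <- NA
  cohort$ohvs_07[4] <- 9
  path <- write_temp_cohort(cohort)
  loaded <- load_cohort(path)
  ledger <- inclusion_ledger(loaded)
  expect_equal(ledger$incomplete, 2L)
  expect_equal(ledger$included, 3L)
  expect_equal(nrow(loaded), 3)
})

test_that("the refusal flag is honoured and the ledger balances", {
  cohort <- simulate_cohort(60, seed = 82)
  cohort$refused <- rep(c(1, 0), c(7, 53))
  # corrupt 4 of the non-refused rows
  cohort$ohip_01[10:13] <- -1
  path <- write_temp_cohort(cohort)
  loaded <- load_cohort(path)
  ledger <- inclusion_ledger(loaded)
  expect_equal(ledger$invited, 60L)
  expect_equal(ledger$refused, 7L)
  expect_equal(ledger$incomplete, 4L)
  expect_equal(ledger$included, 60L - 7L - 4L)
  expect_equal(ledger$included, nrow(loaded))
  expect_false("refused" %in% names(loaded))
})

test_that("malformed files fail fast with diagnostics", {
  expect_error(load_cohort("no/such/file.csv"), "not found")
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(data.frame(a = 1, b = 2), path)
  expect_error(load_cohort(path), "missing columns")
})

test_that("a scored cohort round-trips with identical derived columns", {
  scored <- score_cohort(simulate_cohort(30, seed = 83))
  path <- write_temp_cohort(scored)
  reloaded <- score_cohort(load_cohort(path))
  for (col in c("ohvs_total", "ohip_total", "dmft_d", "dmft_m", "dmft_f",
                "dmft_total", "mohi_a", "mohi_b", "mohi_c", "mohi",
                "degraded", "high_caries", "severe_tooth_loss")) {
    expect_equal(reloaded[[col]], scored[[col]], info = col)
  }
  expect_equal(as.character(reloaded$smoking_status),
               as.character(scored$smoking_status))
})

test_that("analyze_cohort assembles every analysis stage", {
  sc <- score_cohort(simulate_cohort(600, seed = 84))
  an <- analyze_cohort(sc)
  expect_s3_class(an$descriptives, "tbl_df")
  expect_equal(an$descriptives$variable,
               c("ohvs_total", "ohip_total", "dmft_total", "mohi"))
  expect_named(an$comparisons, c("periodontitis", "sex", "age_band",
                                 "education", "smoking_status",
                                 "employment", "marital"))
  expect_s3_class(an$model, "mohi_logit")
  expect_s3_class(an$roc, "mohi_roc")
  # analyzed N matches the ledger in every group table
  for (cmp in an$comparisons) expect_equal(sum(tidy(cmp)$n), 600)
  expect_equal(glance(an$model)$nobs, 600)
})

test_that("the pipeline writes a complete, deterministic bundle", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  an <- run_pipeline(input = NULL, out_dir = out1, n = 500, seed = 85)
  expected <- c("cohort_scored.csv", "descriptives.csv", "group_comparisons.csv",
                "inclusion_ledger.csv", "model_mohi.csv", "model_summary.csv",
                "report.txt", "roc_mohi.csv")
  expect_true(all(expected %in% list.files(out1)))
  report <- readLines(file.path(out1, "report.txt"))
  expect_true(any(grepl("stepwise variant", report)))
  expect_true(any(grepl("seed: 85", report)))
  run_pipeline(input = NULL, out_dir = out2, n = 500, seed = 85)
  for (f in list.files(out1)) {
    expect_identical(readLines(file.path(out1, f)), readLines(file.path(out2, f)),
                     info = f)
  }
})

test_that("an emptied cohort aborts cleanly with the ledger emitted", {
  cohort <- simulate_cohort(4, seed = 86)
  cohort$age <- NA
  path <- write_temp_cohort(cohort)
  out <- withr::local_tempdir()
  expect_error(run_pipeline(input = path, out_dir = out), "empty after filtering")
  ledger <- readr::read_csv(file.path(out, "inclusion_ledger.csv"),
                            show_col_types = FALSE)
  expect_equal(ledger$invited, 4)
  expect_equal(ledger$incomplete, 4)
  expect_equal(ledger$included, 0)
})

test_that("the pipeline accepts a file input end to end", {
  cohort <- simulate_cohort(250, seed = 87)
  path <- write_temp_cohort(cohort)
  out <- withr::local_tempdir()
  an <- run_pipeline(input = path, out_dir = out)
  expect_equal(an$ledger$included, 250)
  expect_s3_class(an$model, "mohi_logit")
  comparisons <- readr::read_csv(file.path(out, "group_comparisons.csv"),
                                 show_col_types = FALSE)
  expect_equal(sum(comparisons$n[comparisons$variable == "sex"]), 250)
})
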