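test_that("simulation is deterministic and row-stable in n", {
  a <- simulate_cohort(25, seed = 101)
  b <- simulate_cohort(25, seed = 101)
  expect_identical(a, b)
  big <- simulate_cohort(200, seed = 101)
  expect_identical(a, big[1:25, ])
  one <- simulate_cohort(1, seed = 101)
  expect_identical(one, big[1, ])
  expect_false(identical(a, simulate_cohort(25, seed = 102)))
  # severity is bitwise-identical across calls
  cov <- simulate_covariates(50, 101)
  expect_identical(simulate_severity(cov, 101), simulate_severity(cov, 101))
})

test_that("covariate marginals match the emulated population", {
  cov <- simulate_covariates(10000, seed = 5)
  se3 <- function(p) 3 * sqrt(p * (1 - p) / 10000)
  expect_lt(abs(mean(cov$sex == "female") - 0.581), se3(0.581))
  expect_lt(abs(mean(cov$self_reported_periodontitis) - 0.42), se3(0.42))
  smoking <- classify_smoking(cov$smoked_100_lifetime, cov$smokes_now)
  expect_lt(abs(mean(smoking == "never") - 0.532), se3(0.532))
  expect_lt(abs(mean(smoking == "active") - 0.231), se3(0.231))
  expect_lt(abs(mean(cov$education == "elementary") - 0.327), se3(0.327))
  expect_true(all(cov$age >= 18 & cov$age <= 95))
  # truncation to [18, 95] lifts the realized mean slightly above 46.8
  expect_gt(mean(cov$age), 46)
  expect_lt(mean(cov$age), 50)
  # age-linked structure: students are young, retirees and widowhood old
  expect_lt(mean(cov$age[cov$employment == "student"]), 32)
  expect_gt(mean(cov$age[cov$employment == "retired"]), 60)
  expect_gt(mean(cov$age[cov$marital == "widowed"]),
            mean(cov$age[cov$marital == "single"]))
})

test_that("severity follows the configured effects and noise", {
  null_cfg <- mohi_sim_config(effect_params = null_effects,
                              noise_params = list(severity_sd = 1))
  cov <- simulate_covariates(10000, seed = 6, null_cfg)
  sev <- simulate_severity(cov, 6, null_cfg)
  expect_lt(abs(mean(sev)), 3 / sqrt(10000))
  expect_lt(abs(sd(sev) - 1), 3 / sqrt(10000))
  # a positive periodontitis effect raises severity in the flagged group
  cfg <- mohi_sim_config(effect_params = c(null_effects[names(null_effects) !=
                                                          "periodontitis"],
                                           list(periodontitis = 1)))
  cov2 <- simulate_covariates(10000, seed = 7, cfg)
  sev2 <- simulate_severity(cov2, 7, cfg)
  expect_gt(mean(sev2[cov2$self_reported_periodontitis == 1]),
            mean(sev2[cov2$self_reported_periodontitis == 0]))
  expect_error(simulate_severity(cov2[, 1:2], 7, cfg), "missing")
})

test_that("generated items always satisfy the instrument invariants", {
  set.seed(30)
  for (i in 1:5) {
    cfg <- mohi_sim_config(
      noise_params = list(severity_sd = runif(1, 0.5, 3),
                          ohvs_item_scale = runif(1, 0.1, 1),
                          ohip_item_scale = runif(1, 0.1, 1)),
      item_params = list(ohvs_slope = runif(1, 0, 0.5),
                         ohip_slope = runif(1, 0, 0.5))
    )
    co <- simulate_cohort(300, seed = i, cfg)
    sc <- score_cohort(co) # score_* validate all ranges internally
    expect_true(all(sc$ohvs_total >= 12 & sc$ohvs_total <= 60))
    expect_true(all(sc$ohip_total >= 0 & sc$ohip_total <= 56))
    expect_true(all(sc$dmft_total >= 0 & sc$dmft_total <= 32))
  }
})

test_that("extreme severity drives MOHi to its bounds", {
  cfg <- mohi_sim_config(noise_params = list(ohvs_item_scale = 1e-6,
                                             ohip_item_scale = 1e-6))
  healthy <- simulate_items(rep(-60, 20), rep(40, 20), seed = 8, cfg)
  sc_h <- score_cohort(cbind(healthy,
                             make_raw_row()[rep(1, 20), c("age", "sex", "education",
                                                          "employment", "marital",
                                                          "smoked_100_lifetime", "smokes_now",
                                                          "self_reported_periodontitis")]))
  expect_true(all(sc_h$mohi == 0))
  sick <- simulate_items(rep(60, 20), rep(40, 20), seed = 8, cfg)
  sc_s <- score_cohort(cbind(sick,
                             make_raw_row()[rep(1, 20), c("age", "sex", "education",
                                                          "employment", "marital",
                                                          "smoked_100_lifetime", "smokes_now",
                                                          "self_reported_periodontitis")]))
  expect_true(all(sc_s$mohi == 3))
})

test_that("severity and MOHi are strongly correlated under defaults", {
  co <- simulate_cohort(10000, seed = 9, keep_latent = TRUE)
  sc <- score_cohort(co)
  expect_gt(cor(sc$latent_severity, sc$mohi), 0.5)
})

test_that("null effects give nominal type-I error for downstream contrasts", {
  null_cfg <- mohi_sim_config(effect_params = null_effects)
  reject <- logical(1000)
  for (r in seq_len(1000)) {
    sc <- score_cohort(simulate_cohort(200, seed = 5000 + r, null_cfg))
    sc$perio <- factor(sc$self_reported_periodontitis)
    reject[r] <- compare_two_groups(sc, mohi, perio)$p_value < 0.05
  }
  rate <- mean(reject)
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / 1000))
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("configuration validation and YAML round-trip work", {
  expect_error(mohi_sim_config(demographic_params = list(
    p_education = c(elementary = 0.5, middle = 0.4, higher = 0.2))), "sum to 1")
  expect_error(mohi_sim_config(noise_params = list(severity_sd = 0)), "> 0")
  expect_error(simulate_covariates(0, 1), ">= 1")
  expect_error(simulate_covariates(10, "a"), "seed")
  cfg <- mohi_sim_config(effect_params = list(female = 0.3))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2$effect_params$female, 0.3)
  expect_identical(simulate_cohort(10, 1, cfg), simulate_cohort(10, 1, cfg2))
})
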