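test_that("Nagelkerke R2 matches a brute-force likelihood computation", {
  set.seed(70)
  d <- data.frame(x = rnorm(40))
  d$y <- rbinom(40, 1, plogis(0.8 * d$x)) == 1
  fit <- glm(y ~ x, family = binomial(), data = d)
  null_fit <- glm(y ~ 1, family = binomial(), data = d)
  expect_equal(nagelkerke_r2(fit, null_fit),
               oracle_nagelkerke(d$y, fitted(fit)), tolerance = 1e-10)
  # the null model explains nothing of itself
  expect_equal(nagelkerke_r2(null_fit, null_fit), 0)
  # invariant to predictor rescaling
  d$x1000 <- d$x * 1000
  fit2 <- glm(y ~ x1000, family = binomial(), data = d)
  expect_equal(nagelkerke_r2(fit, null_fit), nagelkerke_r2(fit2, null_fit),
               tolerance = 1e-8)
  # mismatched data is refused
  fit_sub <- glm(y ~ x, family = binomial(), data = d[1:30, ])
  expect_error(nagelkerke_r2(fit_sub, null_fit), "identical data")
})

test_that("near-separable data drives Nagelkerke R2 toward 1", {
  set.seed(71)
  x <- c(rnorm(60, -2, 0.3), rnorm(60, 2, 0.3))
  y <- rep(c(FALSE, TRUE), each = 60)
  # steep but finite coefficient: keep the fit convergent
  d <- data.frame(x = x, y = y)
  # the near-boundary fit legitimately warns about fitted 0/1 probabilities
  fit <- suppressWarnings(glm(y ~ x, family = binomial(), data = d,
                              control = list(maxit = 100)))
  expect_gt(nagelkerke_r2(fit), 0.9)
})

test_that("stepwise elimination keeps signal and drops noise", {
  set.seed(72)
  n <- 1500
  d <- tibble::tibble(
    signal = rnorm(n),
    noise1 = rnorm(n),
    noise2 = factor(sample(c("u", "v", "w"), n, replace = TRUE)),
    constant = 1
  )
  d$y <- rbinom(n, 1, plogis(d$signal)) == 1
  fit <- stepwise_logistic(d, y, predictors = c("signal", "noise1",
                                                "noise2", "constant"))
  expect_true("signal" %in% fit$retained)
  # a constant predictor can never be retained
  expect_false("constant" %in% fit$retained)
  expect_true("constant" %in% fit$removed)
  td <- tidy(fit)
  expect_true(all(td$odds.ratio > 0))
  expect_true(all(td$or.conf.low < td$odds.ratio & td$odds.ratio < td$or.conf.high))
  g <- glance(fit)
  expect_gte(g$nagelkerke_r2, 0)
  expect_lte(g$nagelkerke_r2, 1)
  expect_equal(g$accuracy, mean((fitted(fit$fit) >= 0.5) == d$y))
})

test_that("single-class outcomes and separation raise explicit errors", {
  d <- tibble::tibble(x = rnorm(50), y = rep(TRUE, 50))
  expect_error(stepwise_logistic(d, y, predictors = "x"), "single class")
  d2 <- tibble::tibble(x = c(rep(0, 30), rep(1, 30)),
                       y = rep(c(FALSE, TRUE), each = 30))
  expect_error(stepwise_logistic(d2, y, predictors = "x"), "converge")
  expect_error(stepwise_logistic(d2, y, predictors = "missing_col"),
               "missing predictor")
  expect_error(stepwise_logistic(d2, y, predictors = "x",
                                 p_remove = 0.05, p_enter = 0.10),
               "p_enter")
})

test_that("planted odds ratio is recovered within its confidence interval", {
  set.seed(73)
  n <- 4000
  d <- tibble::tibble(x = rnorm(n), z = rnorm(n))
  d$y <- rbinom(n, 1, plogis(-0.5 + 1 * d$x)) == 1 # true OR = e
  fit <- stepwise_logistic(d, y, predictors = c("x", "z"))
  expect_true("x" %in% fit$retained)
  row <- tidy(fit)[tidy(fit)$term == "x", ]
  expect_true(row$or.conf.low < exp(1) && exp(1) < row$or.conf.high)
})

test_that("the degraded and high-caries wrappers use their outcome columns", {
  sc <- score_cohort(simulate_cohort(1200, seed = 74))
  fit <- fit_degraded_model(sc)
  expect_equal(fit$outcome, "degraded")
  expect_true("age" %in% fit$retained)
  age_or <- tidy(fit)$odds.ratio[tidy(fit)$term == "age"]
  expect_gt(age_or, 1)
  fit2 <- fit_high_caries_model(sc)
  expect_equal(fit2$outcome, "high_caries")
  # DMFT >= 14 is driven by the same severity: age must persist with OR > 1
  expect_true("age" %in% fit2$retained)
  # all-false outcome is a single class
  sc$high_caries <- FALSE
  expect_error(fit_high_caries_model(sc), "single class")
})

test_that("education is not retained for caries when it has no effect", {
  # generator with education decoupled from severity
  cfg <- mohi_sim_config(effect_params = list(education_middle = 0,
                                              education_elementary = 0))
  retained <- vapply(1:10, function(r) {
    sc <- score_cohort(simulate_cohort(800, seed = 7500 + r, cfg))
    "education" %in% fit_high_caries_model(sc)$retained
  }, logical(1))
  # null term: retention should be the exception, not the rule
  expect_lte(mean(retained), 0.3)
})
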