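# Per-participant uniform stream layout. Each participant consumes a fixed
# block of 131 uniforms, so participant i's draws are identical whatever n
# is (single-row reproducibility) and the whole cohort is generated from
# one vectorized runif() call.
STREAM_COLS <- list(
  age = 1L, sex = 2L, education = 3L, employment = 4L, marital = 5L,
  smoked_100 = 6L, smokes_now = 7L, periodontitis = 8L, severity = 9L,
  ohvs = 10:21, ohip = 22:35,
  tooth_affected = 36:67, tooth_missing = 68:99, tooth_decay = 100:131
)
STREAM_WIDTH <- 131L

participant_uniforms <- function(seed, n) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("seed must be a single integer")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  matrix(stats::runif(n * STREAM_WIDTH), nrow = n, byrow = TRUE)
}

#' Simulation configuration for synthetic cohorts
#'
#' Bundles and validates every parameter of the synthetic cohort generator.
#' Defaults emulate the study population of a university dental clinic
#' cohort of first-appointment adults: age truncated-normal 46.8 (SD 18.6)
#' on 18-95 years, 58.1% female, roughly equal thirds of
#' elementary/middle/higher education, smoking never/former/active at
#' 53.2/23.7/23.1%, and 42% self-reported periodontitis. Effect sizes link
#' the covariates to a latent oral-health severity with log-odds of
#' published-risk-model magnitude (per-year age OR 1.05, periodontitis
#' 1.94, female 1.80, middle/elementary education 2.27/2.94, former/active
#' smoking 1.62/3.12), so the generated degraded-oral-health outcome follows
#' a logistic model with those odds ratios as the truth.
#'
#' The severity noise is logistic, parameterized by its standard deviation.
#' The default (1.719) is chosen so that the severity noise plus the
#' item-level measurement noise propagated through the MOHi mapping has, in
#' total, the standard-logistic scale at the degraded margin; this is what
#' makes the configured odds ratios exact rather than attenuated. See the
#' methods vignette for the derivation and for how the item parameters were
#' calibrated against the emulated cohort's instrument means.
#'
#' @param demographic_params Named list of marginal parameters (see
#'   defaults in the function definition); probability vectors must sum
#'   to 1 (tolerance 1e-9).
#' @param effect_params Named list of log-odds effects of each covariate on
#'   latent severity. Set all to 0 for a null cohort.
#' @param noise_params Named list: `severity_sd` (SD of the logistic
#'   severity noise, > 0), `ohvs_item_scale`, `ohip_item_scale` (logistic
#'   scales of per-item noise, > 0).
#' @param item_params Named list controlling the severity-to-instrument
#'   mapping (item latent centers and per-severity-unit slopes; tooth-state
#'   logit intercepts and slopes).
#' @return A validated list of class `mohi_sim_config`.
#' @export
mohi_sim_config <- function(demographic_params = list(),
                            effect_params = list(),
                            noise_params = list(),
                            item_params = list()) {
  demo <- utils::modifyList(list(
    age_mean = 46.8, age_sd = 18.6, age_min = 18, age_max = 95,
    p_female = 0.581,
    # elementary/middle/higher
    p_education = c(elementary = 0.327, middle = 0.335, higher = 0.338),
    p_employment = c(student = 0.112, employed = 0.679,
                     unemployed = 0.040, retired = 0.169),
    p_marital = c(single = 0.388, married = 0.451,
                  divorced = 0.116, widowed = 0.045),
    # never/former/active 0.532/0.237/0.231 via the two NHANES booleans
    p_smoked_100 = 0.468, p_current_given_100 = 0.4936,
    p_periodontitis = 0.42,
    # dependence of periodontitis on age (per age-SD) and smoking (per
    # never/former/active step), on the logit scale; the intercept is
    # rescaled so the marginal prevalence stays at p_periodontitis
    periodontitis_age_logit = 0.55, periodontitis_smoking_logit = 0.35,
    # age-linked sociodemographic structure (cohort effects): education
    # odds tilt with age (elderly more often elementary-educated), and
    # employment / marital status follow age bands (students young,
    # retirees old, widowhood late in life). Set education_age_logit = 0
    # and the *_by_age entries to NULL for fully independent covariates.
    education_age_logit = 0.9,
    life_stage_breaks = c(30, 65),
    employment_by_age = list(
      young = c(student = 0.58, employed = 0.38, unemployed = 0.04, retired = 0.00),
      mid   = c(student = 0.02, employed = 0.86, unemployed = 0.045, retired = 0.075),
      old   = c(student = 0.00, employed = 0.10, unemployed = 0.02, retired = 0.88)
    ),
    marital_by_age = list(
      young = c(single = 0.86, married = 0.13, divorced = 0.01, widowed = 0.00),
      mid   = c(single = 0.33, married = 0.54, divorced = 0.12, widowed = 0.01),
      old   = c(single = 0.09, married = 0.50, divorced = 0.16, widowed = 0.25)
    )
  ), demographic_params)
  eff <- utils::modifyList(list(
    age_per_year = log(1.05),
    periodontitis = log(1.94),
    female = log(1.80),
    education_middle = log(2.27),
    education_elementary = log(2.94),
    smoking_former = log(1.62),
    smoking_active = log(3.12)
  ), effect_params)
  noise <- utils::modifyList(list(
    severity_sd = 1.719,
    ohvs_item_scale = 0.25,
    ohip_item_scale = 0.35
  ), noise_params)
  items <- utils::modifyList(list(
    ohvs_center = 2.614, ohvs_slope = 0.202,
    ohip_center = 0.770, ohip_slope = 0.256,
    tooth_affected_logit = -0.503, tooth_affected_slope = 0.369,
    tooth_missing_logit = -0.58, tooth_missing_slope = 0.25,
    tooth_missing_age_slope = 1.2,
    tooth_decay_share = 0.484
  ), item_params)

  # YAML deserialization yields lists where vectors are expected
  for (p in c("p_education", "p_employment", "p_marital")) demo[[p]] <- unlist(demo[[p]])
  demo$life_stage_breaks <- unlist(demo$life_stage_breaks)
  for (p in c("employment_by_age", "marital_by_age")) {
    if (!is.null(demo[[p]])) demo[[p]] <- lapply(demo[[p]], unlist)
  }
  for (p in c("p_education", "p_employment", "p_marital")) {
    if (abs(sum(demo[[p]]) - 1) > 1e-9) {
      abort(sprintf("%s probabilities must sum to 1", p))
    }
    if (any(demo[[p]] < 0)) abort(sprintf("%s probabilities must be >= 0", p))
  }
  for (p in c("p_female", "p_smoked_100", "p_current_given_100", "p_periodontitis")) {
    if (demo[[p]] < 0 || demo[[p]] > 1) abort(sprintf("%s must be in [0, 1]", p))
  }
  if (demo$age_min >= demo$age_max || demo$age_sd <= 0) {
    abort("age distribution parameters invalid")
  }
  for (p in c("severity_sd", "ohvs_item_scale", "ohip_item_scale")) {
    if (noise[[p]] <= 0) abort(sprintf("%s must be > 0", p))
  }
  structure(list(demographic_params = demo, effect_params = eff,
                 noise_params = noise, item_params = items),
            class = "mohi_sim_config")
}

as_sim_config <- function(config) {
  if (inherits(config, "mohi_sim_config")) return(config)
  if (is.null(config)) return(mohi_sim_config())
  if (is.list(config)) {
    return(mohi_sim_config(
      demographic_params = config$demographic_params %||% list(),
      effect_params = config$effect_params %||% list(),
      noise_params = config$noise_params %||% list(),
      item_params = config$item_params %||% list()
    ))
  }
  abort("config must be a mohi_sim_config or a named list")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a simulation configuration
#'
#' Configurations are stored as YAML with the four sections of
#' [mohi_sim_config()]; absent keys fall back to the defaults.
#'
#' @param path File path.
#' @param config A `mohi_sim_config`.
#' @return `read_sim_config()` returns a `mohi_sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  as_sim_config(yaml::read_yaml(path))
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  config <- as_sim_config(config)
  # named vectors become YAML maps so the names survive the round trip
  namedify <- function(x) {
    if (is.list(x)) lapply(x, namedify)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(namedify(unclass(config)), path)
  invisible(path)
}

cut_categorical <- function(u, probs) {
  labels <- names(probs)
  idx <- findInterval(u, cumsum(probs), left.open = TRUE) + 1L
  idx[idx > length(labels)] <- length(labels)
  labels[idx]
}

# quadrature grid over the standardized truncated-normal age distribution
age_c_grid <- function(d, m = 401L) {
  f_lo <- pnorm(d$age_min, d$age_mean, d$age_sd)
  f_hi <- pnorm(d$age_max, d$age_mean, d$age_sd)
  q <- f_lo + ((seq_len(m) - 0.5) / m) * (f_hi - f_lo)
  (qnorm(q, d$age_mean, d$age_sd) - d$age_mean) / d$age_sd
}

# baseline education weights such that the age-tilted softmax realizes the
# configured marginals (fixed point over the age quadrature)
education_weights <- function(d) {
  target <- d$p_education[c("elementary", "middle", "higher")]
  if (d$education_age_logit == 0) return(target)
  a <- age_c_grid(d)
  tilt <- cbind(exp(d$education_age_logit * a), 1, exp(-d$education_age_logit * a))
  b <- target
  for (i in seq_len(60L)) {
    w <- sweep(tilt, 2L, b, `*`)
    realized <- colMeans(w / rowSums(w))
    b <- b * target / realized
    b <- b / sum(b)
  }
  stats::setNames(b, names(target))
}

# intercept making the periodontitis marginal equal p_periodontitis under
# the configured age/smoking dependence
periodontitis_intercept <- function(d) {
  if (d$periodontitis_age_logit == 0 && d$periodontitis_smoking_logit == 0) {
    return(qlogis(d$p_periodontitis))
  }
  a <- age_c_grid(d)
  step <- c(0, 1, 2)
  p_step <- c(1 - d$p_smoked_100,
              d$p_smoked_100 * (1 - d$p_current_given_100),
              d$p_smoked_100 * d$p_current_given_100)
  step_mean <- sum(step * p_step)
  marginal <- function(c0) {
    z <- outer(d$periodontitis_age_logit * a,
               d$periodontitis_smoking_logit * (step - step_mean), `+`)
    sum(plogis(c0 + z) %*% p_step) / length(a) - d$p_periodontitis
  }
  stats::uniroot(marginal, c(-8, 8), tol = 1e-10)$root
}

#' Simulate cohort covariates
#'
#' Draws `n` participants' sociodemographics, smoking history and
#' self-reported periodontitis from the configured marginals: truncated
#' normal age, independent categorical draws for sex, education, employment
#' and marital status, the two NHANES smoking booleans, and a periodontitis
#' flag whose logit may optionally depend on age and smoking.
#'
#' @param n Number of participants.
#' @param seed Integer seed. Participant `i`'s draws depend only on
#'   `(seed, i)`, so row `i` is identical for any `n >= i`.
#' @param config A [mohi_sim_config()] (or named list merged into defaults).
#' @return A tibble with columns `age`, `sex`, `education`, `employment`,
#'   `marital`, `smoked_100_lifetime`, `smokes_now`,
#'   `self_reported_periodontitis`. Factor reference levels are the risk
#'   model's: male, higher education, never smoker.
#' @export
simulate_covariates <- function(n, seed, config = mohi_sim_config()) {
  config <- as_sim_config(config)
  if (!is.numeric(n) || n < 1) abort("n must be >= 1")
  n <- as.integer(n)
  d <- config$demographic_params
  u <- participant_uniforms(seed, n)

  f_lo <- pnorm(d$age_min, d$age_mean, d$age_sd)
  f_hi <- pnorm(d$age_max, d$age_mean, d$age_sd)
  age <- qnorm(f_lo + u[, STREAM_COLS$age] * (f_hi - f_lo), d$age_mean, d$age_sd)

  age_c <- (age - d$age_mean) / d$age_sd
  sex <- factor(ifelse(u[, STREAM_COLS$sex] < d$p_female, "female", "male"),
                levels = c("male", "female"))

  # education: per-participant probabilities tilt with age (elderly toward
  # elementary, young toward higher); baseline weights are solved so the
  # realized marginals equal the configured p_education
  g <- d$education_age_logit
  base <- education_weights(d)
  w <- cbind(elementary = base[["elementary"]] * exp(g * age_c),
             middle = base[["middle"]],
             higher = base[["higher"]] * exp(-g * age_c))
  w <- w / rowSums(w)
  edu_idx <- 1L + (u[, STREAM_COLS$education] > w[, 1L]) +
    (u[, STREAM_COLS$education] > w[, 1L] + w[, 2L])
  education <- factor(colnames(w)[edu_idx], levels = c("higher", "middle", "elementary"))

  # employment and marital status by life stage (age bands)
  stage <- cut(age, breaks = c(-Inf, d$life_stage_breaks, Inf),
               labels = c("young", "mid", "old"))
  pick_by_stage <- function(u_col, tables) {
    out <- character(length(u_col))
    for (s in levels(stage)) {
      idx <- stage == s
      if (any(idx)) out[idx] <- cut_categorical(u_col[idx], tables[[s]])
    }
    out
  }
  if (is.null(d$employment_by_age)) {
    employment <- cut_categorical(u[, STREAM_COLS$employment], d$p_employment)
  } else {
    employment <- pick_by_stage(u[, STREAM_COLS$employment], d$employment_by_age)
  }
  employment <- factor(employment,
                       levels = c("employed", "student", "unemployed", "retired"))
  if (is.null(d$marital_by_age)) {
    marital <- cut_categorical(u[, STREAM_COLS$marital], d$p_marital)
  } else {
    marital <- pick_by_stage(u[, STREAM_COLS$marital], d$marital_by_age)
  }
  marital <- factor(marital, levels = c("single", "married", "divorced", "widowed"))

  smoked_100 <- u[, STREAM_COLS$smoked_100] < d$p_smoked_100
  smokes_now <- smoked_100 & (u[, STREAM_COLS$smokes_now] < d$p_current_given_100)

  # periodontitis: logit-linear in age and smoking, centered; the
  # intercept is solved so the marginal prevalence is exact
  smoking_step <- as.integer(smoked_100) + as.integer(smokes_now)
  step_mean <- d$p_smoked_100 * (1 + d$p_current_given_100)
  perio_logit <- periodontitis_intercept(d) +
    d$periodontitis_age_logit * age_c +
    d$periodontitis_smoking_logit * (smoking_step - step_mean)
  periodontitis <- u[, STREAM_COLS$periodontitis] < plogis(perio_logit)

  tibble::tibble(
    age = age, sex = sex, education = education, employment = employment,
    marital = marital,
    smoked_100_lifetime = as.integer(smoked_100),
    smokes_now = as.integer(smokes_now),
    self_reported_periodontitis = as.integer(periodontitis)
  )
}

# Centered linear predictor of latent severity; centering at the marginal
# covariate means keeps E[severity] ~ 0 under the default marginals.
severity_linear_predictor <- function(covariates, config) {
  d <- config$demographic_params
  e <- config$effect_params
  smoking <- classify_smoking(covariates$smoked_100_lifetime, covariates$smokes_now)
  p_former <- d$p_smoked_100 * (1 - d$p_current_given_100)
  p_active <- d$p_smoked_100 * d$p_current_given_100
  e$age_per_year * (covariates$age - d$age_mean) +
    e$periodontitis * (covariates$self_reported_periodontitis - d$p_periodontitis) +
    e$female * ((covariates$sex == "female") - d$p_female) +
    e$education_middle * ((covariates$education == "middle") - d$p_education[["middle"]]) +
    e$education_elementary * ((covariates$education == "elementary") - d$p_education[["elementary"]]) +
    e$smoking_former * ((smoking == "former") - p_former) +
    e$smoking_active * ((smoking == "active") - p_active)
}

#' Simulate latent oral-health severity
#'
#' Severity is the centered linear predictor of the configured covariate
#' effects plus logistic noise with SD `noise_params$severity_sd`. It is the
#' single shared factor that induces the correlations among OHVS, OHIP-14
#' and DMFT which the MOHi composite assumes; higher severity means worse
#' oral health on every instrument.
#'
#' @param covariates A covariate tibble from [simulate_covariates()],
#'   generated with the same `seed`.
#' @inheritParams simulate_covariates
#' @return A numeric vector of length `nrow(covariates)`.
#' @export
simulate_severity <- function(covariates, seed, config = mohi_sim_config()) {
  config <- as_sim_config(config)
  need <- c("age", "sex", "education", "smoked_100_lifetime", "smokes_now",
            "self_reported_periodontitis")
  missing_cols <- setdiff(need, names(covariates))
  if (length(missing_cols)) {
    abort(paste0("covariates are missing: ", paste(missing_cols, collapse = ", ")))
  }
  if (!all(as.character(covariates$education) %in% c("higher", "middle", "elementary"))) {
    abort("unknown education level in covariates")
  }
  if (!all(as.character(covariates$sex) %in% c("male", "female"))) {
    abort("unknown sex level in covariates")
  }
  u <- participant_uniforms(seed, nrow(covariates))
  eta <- severity_linear_predictor(covariates, config)
  noise_scale <- config$noise_params$severity_sd * sqrt(3) / pi
  as.vector(eta + qlogis(u[, STREAM_COLS$severity]) * noise_scale)
}

# item = 1 + number of equal-interval thresholds (1.5, 2.5, 3.5, 4.5)
# exceeded by a logistic latent -> 1..5; for OHIP, thresholds .5..3.5 -> 0..4.
threshold_items <- function(center, slope, severity, u, scale, lo, hi) {
  n <- length(severity)
  k <- ncol(u)
  latent <- matrix(center + slope * severity, n, k) + qlogis(u) * scale
  items <- floor(latent - (lo - 0.5)) + lo
  items[items < lo] <- lo
  items[items > hi] <- hi
  storage.mode(items) <- "integer"
  items
}

#' Simulate instrument responses and tooth charts
#'
#' Given latent severities (and ages, which influence which affected teeth
#' end up missing), generates per-item OHVS and OHIP-14 responses and a
#' 32-tooth chart. Ordinal items come from equal-interval thresholds on a
#' logistic latent whose mean decreases with severity for OHVS (worse oral
#' health, lower value placed on it) and increases for OHIP-14. Each tooth
#' is independently affected with probability increasing in severity;
#' affected teeth are missing with probability increasing in severity and
#' age, else decayed or filled.
#'
#' @param severity Numeric vector from [simulate_severity()].
#' @param age Numeric vector of ages (same length), used only for the
#'   missing-tooth split.
#' @inheritParams simulate_covariates
#' @return A tibble with columns `ohvs_01`..`ohvs_12`, `ohip_01`..`ohip_14`,
#'   `tooth_01`..`tooth_32`.
#' @export
simulate_items <- function(severity, age, seed, config = mohi_sim_config()) {
  config <- as_sim_config(config)
  if (length(age) != length(severity)) abort("age and severity lengths differ")
  n <- length(severity)
  u <- participant_uniforms(seed, n)
  it <- config$item_params
  no <- config$noise_params
  d <- config$demographic_params

  ohvs <- threshold_items(it$ohvs_center, -it$ohvs_slope, severity,
                          u[, STREAM_COLS$ohvs, drop = FALSE],
                          no$ohvs_item_scale, 1L, 5L)
  ohip <- threshold_items(it$ohip_center, it$ohip_slope, severity,
                          u[, STREAM_COLS$ohip, drop = FALSE],
                          no$ohip_item_scale, 0L, 4L)

  age_c <- (age - d$age_mean) / d$age_sd
  p_aff <- plogis(it$tooth_affected_logit + it$tooth_affected_slope * severity)
  p_mis <- plogis(it$tooth_missing_logit + it$tooth_missing_slope * severity +
                    it$tooth_missing_age_slope * age_c)
  affected <- u[, STREAM_COLS$tooth_affected, drop = FALSE] < p_aff
  missing_ <- u[, STREAM_COLS$tooth_missing, drop = FALSE] < p_mis
  decayed <- u[, STREAM_COLS$tooth_decay, drop = FALSE] < it$tooth_decay_share
  teeth <- matrix("S", n, N_TEETH)
  teeth[affected & missing_] <- "M"
  teeth[affected & !missing_ & decayed] <- "D"
  teeth[affected & !missing_ & !decayed] <- "F"

  out <- cbind(
    tibble::as_tibble(as.data.frame(ohvs)),
    tibble::as_tibble(as.data.frame(ohip)),
    tibble::as_tibble(as.data.frame(teeth), .name_repair = "minimal")
  )
  names(out) <- c(sprintf("ohvs_%02d", 1:OHVS_N_ITEMS),
                  sprintf("ohip_%02d", 1:OHIP_N_ITEMS),
                  sprintf("tooth_%02d", 1:N_TEETH))
  tibble::as_tibble(out)
}

#' Simulate a complete synthetic cohort
#'
#' Covariates, latent severity and item-level responses in one call, bound
#' into the raw cohort schema consumed by [score_cohort()] and
#' [load_cohort()]. Fully deterministic given `seed`; participant `i`'s row
#' does not depend on `n`.
#'
#' @inheritParams simulate_covariates
#' @param keep_latent Keep the latent severity as column `latent_severity`
#'   (useful for generator diagnostics; dropped by default since real
#'   cohorts have no such column).
#' @return A raw cohort tibble (covariates + `ohvs_*`, `ohip_*`, `tooth_*`).
#' @export
#' @examples
#' cohort <- simulate_cohort(50, seed = 1)
#' scored <- score_cohort(cohort)
#' mean(scored$mohi)
simulate_cohort <- function(n, seed, config = mohi_sim_config(), keep_latent = FALSE) {
  config <- as_sim_config(config)
  covariates <- simulate_covariates(n, seed, config)
  severity <- simulate_severity(covariates, seed, config)
  items <- simulate_items(severity, covariates$age, seed, config)
  out <- dplyr::bind_cols(covariates, items)
  if (keep_latent) out$latent_severity <- severity
  out
}
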