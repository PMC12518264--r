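# Independent brute-force oracles, deliberately written from the defining
# formulas rather than reusing any package internals.

# moments from first principles
oracle_moments <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  dev <- x - m
  m2 <- sum(dev^2) / n
  m3 <- sum(dev^3) / n
  m4 <- sum(dev^4) / n
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3
  list(
    mean = m,
    sd = sqrt(sum(dev^2) / (n - 1)),
    skewness = g1 * sqrt(n * (n - 1)) / (n - 2),
    kurtosis = ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  )
}

# exhaustive pairwise concordance AUC (ties count 1/2)
oracle_auc <- function(truth, score) {
  pos <- score[truth]
  neg <- score[!truth]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Nagelkerke R2 from raw per-observation likelihood products
oracle_nagelkerke <- function(y, p_full) {
  n <- length(y)
  p_null <- rep(mean(y), n)
  lik <- function(p) prod(ifelse(y, p, 1 - p))
  r2_cs <- 1 - (lik(p_null) / lik(p_full))^(2 / n)
  r2_cs / (1 - lik(p_null)^(2 / n))
}

# two-sided pooled-variance t-test p-value from the textbook formulas
oracle_t_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(tstat), df = nx + ny - 2)
}

# a minimal valid raw cohort row as a one-row data frame
make_raw_row <- function(ohvs = rep(3, 12), ohip = rep(1, 14),
                         teeth = rep("S", 32), age = 40, sex = "F",
                         education = "higher", employment = "employed",
                         marital = "single", smoked = 0, smokes = 0,
                         perio = 0) {
  row <- c(as.list(setNames(ohvs, sprintf("ohvs_%02d", 1:12))),
           as.list(setNames(ohip, sprintf("ohip_%02d", 1:14))),
           as.list(setNames(teeth, sprintf("tooth_%02d", 1:32))),
           list(age = age, sex = sex, education = education,
                employment = employment, marital = marital,
                smoked_100_lifetime = smoked, smokes_now = smokes,
                self_reported_periodontitis = perio))
  tibble::as_tibble(row)
}

null_effects <- list(age_per_year = 0, periodontitis = 0, female = 0,
                     education_middle = 0, education_elementary = 0,
                     smoking_former = 0, smoking_active = 0)
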