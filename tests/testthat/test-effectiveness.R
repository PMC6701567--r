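published <- trial_abstinence_model()

test_that("linear predictor reproduces hand-computed logits", {
  # age 0 is an extrapolation by construction: intercept-only check
  expect_warning(lp0 <- linear_predictor(published, 0, 0, 0), "extrapolating")
  expect_equal(lp0, -3.124)
  expect_equal(linear_predictor(published, 1, 1, 20), -2.100)
  expect_equal(linear_predictor(published, 1, 0, 40), -1.923)
  expect_warning(linear_predictor(published, 1, 0, 80), "extrapolating")
  expect_error(linear_predictor(published, 2, 0, 40), "coded 0/1")
})

test_that("abstinence_probability is the logistic function", {
  expect_equal(abstinence_probability(0), 0.5)
  expect_equal(abstinence_probability(-2.100), exp(-2.1) / (1 + exp(-2.1)))
  expect_equal(round(abstinence_probability(-2.100), 3), 0.109)
  x <- seq(-5, 5, by = 0.25)
  p <- abstinence_probability(x)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0 & p < 1))
  expect_error(abstinence_probability(NA), "finite")
})

test_that("HIT probabilities over the trial age range span ~0.11-0.14", {
  p_men <- abstinence_probability(linear_predictor(published, 1, 1, 19:71))
  expect_equal(min(p_men), 0.109, tolerance = 0.005)
  expect_true(all(diff(p_men) > 0))   # monotone in age (positive beta)
  expect_lt(max(p_men), 0.14)
  p_women <- abstinence_probability(linear_predictor(published, 1, 0, 19:71))
  expect_true(all(p_women > p_men))   # negative male coefficient
})

test_that("odds ratios match the published table and invert the log scale", {
  expect_equal(round(odds_ratio(published, "programme")$or, 2), 2.72)
  expect_equal(round(odds_ratio(published, "gender")$or, 2), 0.93)
  expect_equal(odds_ratio(abstinence_model(0, 0, 0, 0), "programme")$or, 1)
  expect_error(odds_ratio(published, "education"), "unknown term")
  # exp and log are mutual inverses across the coefficient set
  for (term in names(published$coefficients)) {
    expect_equal(log(odds_ratio(published, term)$or),
                 published$coefficients[[term]])
  }
})

test_that("Wald CIs use exp(coef +/- z se)", {
  m <- abstinence_model(-3, 1, 0, 0, se = c(programme = 0.4))
  ci <- odds_ratio(m, "programme")$ci
  expect_equal(ci, exp(1 + c(-1, 1) * qnorm(0.975) * 0.4))
  expect_null(odds_ratio(m, "gender")$ci)
})

test_that("simulated trials are reproducible and respect the null", {
  a <- simulate_trial(500, seed = 11)
  b <- simulate_trial(500, seed = 11)
  expect_identical(a, b)
  expect_equal(nrow(a), 1000L)
  expect_true(all(a$age >= 19 & a$age <= 71))
  null <- abstinence_model(-2, 0, 0, 0)
  rec <- simulate_trial(20000, model = null, seed = 4)
  rates <- tapply(rec$abstinent, rec$programme, mean)
  se <- sqrt(2 * 0.12 * 0.88 / 20000)
  expect_lt(abs(rates[["1"]] - rates[["0"]]), 4 * se)
})

test_that("the empirical arm difference matches the integrated expectation", {
  n <- 20000L
  rec <- simulate_trial(n, model = published, age_distribution = function(k) {
    runif(k, 19, 71)
  }, p_male = 0.22, seed = 8)
  emp <- mean(rec$abstinent[rec$programme == 1]) -
    mean(rec$abstinent[rec$programme == 0])
  # analytic expectation over uniform ages and the gender mix
  grid <- expand.grid(age = seq(19, 71, length.out = 2001), gender = c(0, 1))
  w <- ifelse(grid$gender == 1, 0.22, 0.78)
  dp <- abstinence_probability(linear_predictor(published, 1, grid$gender, grid$age)) -
    abstinence_probability(linear_predictor(published, 0, grid$gender, grid$age))
  expected <- sum(w * dp) / sum(w)
  mc_se <- sqrt(0.13 * 0.87 / n + 0.05 * 0.95 / n)
  expect_lt(abs(emp - expected), 3 * mc_se)
  # the published per-person derivation puts the arm gap near 7 points
  expect_gt(expected, 0.06)
  expect_lt(expected, 0.09)
})

test_that("fitting recovers generating coefficients from synthetic records", {
  rec <- simulate_trial(5000, model = published, seed = 21)
  fit <- fit_abstinence_model(rec)
  truth <- published$coefficients
  for (term in names(truth)) {
    ci <- fit$coefficients[[term]] +
      c(-1, 1) * qnorm(0.975) * fit$se[[term]]
    expect_gte(truth[[term]], ci[1])
    expect_lte(truth[[term]], ci[2])
  }
})

test_that("programme-only data drive gender and age estimates to zero", {
  gen <- abstinence_model(-2.5, 1.2, 0, 0)
  rec <- simulate_trial(30000, model = gen, seed = 5)
  fit <- fit_abstinence_model(rec)
  expect_lt(abs(fit$coefficients[["gender"]]), 3 * fit$se[["gender"]])
  expect_lt(abs(fit$coefficients[["age"]]), 3 * fit$se[["age"]])
  expect_gt(fit$coefficients[["programme"]], 1.2 - 3 * fit$se[["programme"]])
})

test_that("degenerate inputs raise fitting errors", {
  rec <- simulate_trial(100, seed = 1)
  rec$abstinent <- 0L
  expect_error(fit_abstinence_model(rec), "outcome class")
  sep <- data.frame(programme = rep(c(1, 0), each = 50),
                    gender = rep(c(1, 0), 50),
                    age = rep(30:39, 10),
                    abstinent = rep(c(1, 0), each = 50))
  expect_error(fit_abstinence_model(sep), "separation|converge")
  expect_error(fit_abstinence_model(data.frame(x = 1)), "columns")
})

test_that("records and fitted models round-trip through their text formats", {
  rec <- simulate_trial(200, seed = 2)
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_records(rec, p1)
  expect_equal(read_records(p1), rec, ignore_attr = TRUE)
  fit <- fit_abstinence_model(simulate_trial(2000, seed = 3))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_abstinence_model(fit, p2)
  back <- read_abstinence_model(p2)
  expect_equal(back$coefficients, fit$coefficients)
  expect_equal(back$se[names(fit$se)], fit$se)
})
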