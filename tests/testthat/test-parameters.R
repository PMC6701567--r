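test_that("generated parameter sets satisfy every invariant across seeds", {
  for (seed in c(1, 7, 23, 101, 4096)) {
    p <- generate_synthetic_parameters(seed = seed)
    expect_silent(validate_parameters(p))
    # incidence curves rise with age, never-smoker <= smoker everywhere
    for (d in p$diseases) {
      for (sx in p$sexes) {
        expect_true(all(diff(p$incidence_never[d, sx, ]) >= 0))
        expect_true(all(diff(p$incidence_smoker[d, sx, ]) >= 0))
      }
    }
    expect_true(all(p$incidence_smoker >= p$incidence_never))
    expect_true(all(abs(p$decay_fraction[, 1] - 1) < 1e-12))
  }
})

test_that("generator is deterministic and respects overrides", {
  expect_identical(generate_synthetic_parameters(seed = 1),
                   generate_synthetic_parameters(seed = 1))
  p_rr1 <- generate_synthetic_parameters(seed = 1, config = list(rr = 1))
  expect_equal(p_rr1$incidence_smoker, p_rr1$incidence_never)
  p2 <- generate_synthetic_parameters(
    seed = 1, config = list(rr = c(chd = 3), discount_rate = 0, max_age = 80))
  expect_equal(p2$discount_rate, 0)
  expect_equal(p2$max_age, 80L)
  expect_equal(p2$incidence_smoker["chd", , ], 3 * p2$incidence_never["chd", , ],
               tolerance = 1e-12)
})

test_that("invalid generator overrides name the offending field", {
  expect_error(generate_synthetic_parameters(seed = 1, config = list(rr = 0.5)),
               "rr")
  expect_error(generate_synthetic_parameters(seed = 1,
                                             config = list(decay_tau = -1)),
               "decay_tau")
  expect_error(generate_synthetic_parameters(
    seed = 1, config = list(rr = c(diabetes = 2))), "diabetes")
})

test_that("identity scenario leaves parameters unchanged and is idempotent", {
  p <- generate_synthetic_parameters(seed = 3)
  id <- sensitivity_scenario()
  once <- apply_scenario(p, id)
  expect_equal(once, p)
  expect_equal(apply_scenario(once, id), p)
})

test_that("the low cost/low risk scenario transforms each field as specified", {
  p <- generate_synthetic_parameters(seed = 5)
  s <- apply_scenario(p, low_cost_low_risk_scenario())
  expect_equal(s$disease_cost, 0.75 * p$disease_cost)
  expect_equal(s$incidence_smoker - s$incidence_never,
               0.5 * (p$incidence_smoker - p$incidence_never), tolerance = 1e-12)
  expect_equal(s$incidence_never, p$incidence_never)
  expect_equal(s$case_fatality, 0.9 * p$case_fatality)
  expect_equal(s$background_mortality, 0.9 * p$background_mortality)
  expect_equal(s$decay_fraction[, -1], pmax(p$decay_fraction[, -1] - 0.1, 0))
  expect_true(all(s$decay_fraction[, 1] == 1))
  # original untouched
  expect_equal(p, generate_synthetic_parameters(seed = 5))
})

test_that("decay delta floors at zero", {
  p <- toy_params(decay = c(1, rep(0.05, 76)))
  s <- apply_scenario(p, sensitivity_scenario(decay_fraction_delta = 0.1))
  expect_true(all(s$decay_fraction[, -1] == 0))
})

test_that("cost and death multipliers commute", {
  p <- generate_synthetic_parameters(seed = 9)
  cost_only <- sensitivity_scenario(cost_multiplier = 0.75)
  death_only <- sensitivity_scenario(death_risk_multiplier = 0.9)
  ab <- apply_scenario(apply_scenario(p, cost_only), death_only)
  ba <- apply_scenario(apply_scenario(p, death_only), cost_only)
  expect_equal(ab, ba)
})

test_that("scenario constructor validates its inputs", {
  expect_error(sensitivity_scenario(cost_multiplier = 0), "cost_multiplier")
  expect_error(sensitivity_scenario(death_risk_multiplier = 1.2),
               "death_risk_multiplier")
  expect_error(sensitivity_scenario(decay_fraction_delta = 1.5),
               "decay_fraction_delta")
})

test_that("parameter sets round-trip through CSV", {
  p <- generate_synthetic_parameters(seed = 11)
  dir <- withr::local_tempdir()
  write_parameters(p, dir)
  expect_equal(read_parameters(dir), p, tolerance = 1e-12)
})

test_that("validator rejects broken parameter sets", {
  p <- generate_synthetic_parameters(seed = 1)
  bad <- p
  bad$incidence_smoker["chd", "male", "40"] <-
    bad$incidence_never["chd", "male", "40"] / 2
  expect_error(validate_parameters(bad), "incidence_smoker")
  bad <- p
  bad$utility[["dead"]] <- 0.1
  expect_error(validate_parameters(bad), "dead")
  bad <- p
  bad$decay_fraction[1, 2] <- 2 # also violates [0,1]
  expect_error(validate_parameters(bad), "decay_fraction")
})
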