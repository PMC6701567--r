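test_that("discount_factor has the closed form (1+r)^-t", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(0:10, 0), rep(1, 11))
  expect_equal(discount_factor(1, 0.03), 1 / 1.03)
  expect_equal(discount_factor(7, 0.03), 1.03^-7)
  expect_error(discount_factor(-1, 0.03), "year_index")
})

test_that("a riskless cohort accrues exactly its well-years", {
  p <- toy_params(inc_never = 0, inc_smoker = 0, case_fatality = 0,
                  bg_mortality = 0, utility_well = 1, discount_rate = 0,
                  start_age = 90, max_age = 95)
  out <- simulate_cohort("female", 90, "smoker", p)
  expect_equal(out$discounted_qalys, 5)
  expect_equal(out$discounted_cost, 0)
})

test_that("engine totals equal brute-force path enumeration on small chains", {
  # sweep toy chains: 1 or 2 diseases (3/4 states), <= 5 cycles, both
  # statuses, with and without discounting
  set.seed(42)
  cases <- expand.grid(nd = 1:2, status = c("smoker", "quitter"),
                       rate = c(0, 0.03), stringsAsFactors = FALSE)
  for (k in seq_len(nrow(cases))) {
    nd <- cases$nd[k]
    p <- toy_params(
      diseases = c("copd", "lung_cancer")[seq_len(nd)],
      inc_never = runif(nd, 0, 0.05), inc_smoker = runif(nd, 0.1, 0.3),
      case_fatality = runif(nd, 0.1, 0.4), bg_mortality = runif(1, 0, 0.1),
      cost = c(10000, 40000)[seq_len(nd)],
      utility_disease = c(0.6, 0.5)[seq_len(nd)],
      discount_rate = cases$rate[k], start_age = 90, max_age = 95)
    out <- simulate_cohort("male", 90, cases$status[k], p)
    mats <- transition_matrices("male", 90, cases$status[k], p)
    states <- rownames(mats[[1]])
    cost_r <- setNames(numeric(length(states)), states)
    cost_r[p$diseases] <- p$disease_cost
    util_r <- setNames(numeric(length(states)), states)
    util_r["well"] <- p$utility[["well"]]
    util_r[p$diseases] <- p$utility[p$diseases]
    expect_equal(out$discounted_cost,
                 enumerate_expected_reward(mats, cost_r, cases$rate[k]),
                 tolerance = 1e-10)
    expect_equal(out$discounted_qalys,
                 enumerate_expected_reward(mats, util_r, cases$rate[k]),
                 tolerance = 1e-10)
  }
})

test_that("discounting strictly reduces totals that accrue after year 0", {
  p0 <- toy_params(discount_rate = 0)
  p3 <- toy_params(discount_rate = 0.03)
  o0 <- simulate_cohort("female", 90, "smoker", p0)
  o3 <- simulate_cohort("female", 90, "smoker", p3)
  expect_lt(o3$discounted_cost, o0$discounted_cost)
  expect_lt(o3$discounted_qalys, o0$discounted_qalys)
})

test_that("occupancy is conserved every cycle", {
  p <- generate_synthetic_parameters(seed = 2)
  for (profile in list(c("male", 25), c("female", 40), c("male", 80))) {
    out <- simulate_cohort(profile[1], as.integer(profile[2]), "quitter", p)
    occ <- out$trace[, !(names(out$trace) %in% c("cycle", "age"))]
    expect_true(all(abs(rowSums(occ) - 1) < 1e-9))
    expect_equal(nrow(occ), p$max_age - as.integer(profile[2]) + 1L)
  }
})

test_that("no excess risk or no risk reversal means no quit benefit", {
  p_rr1 <- generate_synthetic_parameters(seed = 1, config = list(rr = 1))
  qb <- quit_benefit("female", 40, p_rr1)
  expect_equal(qb$costs_avoided, 0)
  expect_equal(qb$qalys_gained, 0)
  p_nodecay <- generate_synthetic_parameters(
    seed = 1, config = list(decay_residual = 1))
  qb2 <- quit_benefit("male", 55, p_nodecay)
  expect_equal(qb2$costs_avoided, 0)
  expect_equal(qb2$qalys_gained, 0)
})

test_that("quitting dominates smoking under excess risk that decays", {
  for (seed in c(1, 13, 77)) {
    p <- generate_synthetic_parameters(seed = seed)
    for (age in c(30, 50, 70)) {
      qb <- quit_benefit("female", age, p)
      expect_gte(qb$costs_avoided, 0)
      expect_gte(qb$qalys_gained, 0)
    }
  }
})

test_that("QALY gains decline with quit age on the synthetic defaults", {
  p <- generate_synthetic_parameters(seed = 1)
  q40 <- quit_benefit("female", 40, p)
  q60 <- quit_benefit("female", 60, p)
  expect_gte(q40$qalys_gained, q60$qalys_gained)
})

test_that("the low cost/low risk scenario weakly shrinks quit benefits", {
  for (seed in c(1, 13, 77)) {
    p <- generate_synthetic_parameters(seed = seed)
    ps <- apply_scenario(p, low_cost_low_risk_scenario())
    for (prof in list(list("female", 40), list("male", 60))) {
      base <- quit_benefit(prof[[1]], prof[[2]], p)
      scen <- quit_benefit(prof[[1]], prof[[2]], ps)
      expect_lte(scen$costs_avoided, base$costs_avoided)
      expect_lte(scen$qalys_gained, base$qalys_gained)
    }
  }
})

test_that("quit_benefit_table sweeps bands keyed by midpoint", {
  p <- generate_synthetic_parameters(seed = 1)
  tab <- quit_benefit_table(p, band_starts = c(40, 60), sexes = "female")
  expect_equal(tab$age_group, c("40-44", "60-64"))
  expect_equal(tab$sex, c("women", "women"))
  mid <- quit_benefit("female", 42, p)
  expect_equal(tab$costs_avoided[1], mid$costs_avoided)
})

test_that("invalid cohort profiles are rejected", {
  p <- generate_synthetic_parameters(seed = 1)
  expect_error(simulate_cohort("female", 95, "smoker", p), "start_age")
  expect_error(simulate_cohort("female", 10, "smoker", p), "start_age")
})
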