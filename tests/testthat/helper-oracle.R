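# Independent oracles and toy-model builders for the test suite.
# Nothing here calls into the package's accumulation machinery: the path
# enumerator works directly on transition matrices, and the CEAC closed
# form is written from the truncated-normal survival function.

# Brute-force expectation of discounted rewards by literal enumeration of
# every state path. `mats`: list of row-stochastic matrices (one per
# cycle); rewards accrue at cycle start for cycles 0..n-1, discounted at
# `rate` with year 0 undiscounted.
enumerate_expected_reward <- function(mats, reward, rate, start_state = 1L) {
  n <- length(mats)
  states <- seq_len(nrow(mats[[1]]))
  paths <- as.matrix(expand.grid(rep(list(states), n)))
  total <- 0
  for (k in seq_len(nrow(paths))) {
    path <- c(start_state, paths[k, ])
    prob <- 1
    for (t in seq_len(n)) prob <- prob * mats[[t]][path[t], path[t + 1L]]
    if (prob == 0) next
    value <- sum(reward[path[seq_len(n)]] * (1 + rate)^(-(seq_len(n) - 1L)))
    total <- total + prob * value
  }
  total
}

# Minimal parameter set with constant (age-flat) inputs; defaults give a
# well -> disease -> dead toy chain with a single disease.
toy_params <- function(diseases = "copd",
                       inc_never = 0.02, inc_smoker = 0.10,
                       case_fatality = 0.20, bg_mortality = 0.05,
                       decay = NULL, cost = 10000, utility_disease = 0.6,
                       utility_well = 1, discount_rate = 0,
                       start_age = 90, max_age = 95) {
  ages <- 19:max_age
  nd <- length(diseases)
  dn <- list(diseases, c("male", "female"), as.character(ages))
  const_arr <- function(x) {
    array(rep(rep(x, length.out = nd), times = 2 * length(ages)),
          dim = c(nd, 2, length(ages)), dimnames = dn)
  }
  tmax <- max_age - 19
  if (is.null(decay)) decay <- exp(-(0:tmax) / 3)
  dk <- matrix(rep(decay, each = nd), nrow = nd,
               dimnames = list(diseases, as.character(0:tmax)))
  dk[, 1] <- 1
  model_parameters(
    incidence_never = const_arr(inc_never),
    incidence_smoker = const_arr(inc_smoker),
    case_fatality = const_arr(case_fatality),
    background_mortality = matrix(bg_mortality, 2, length(ages),
                                  dimnames = list(c("male", "female"),
                                                  as.character(ages))),
    decay_fraction = dk,
    disease_cost = setNames(rep(cost, length.out = nd), diseases),
    utility = c(setNames(rep(utility_disease, length.out = nd), diseases),
                well = utility_well, dead = 0),
    discount_rate = discount_rate, max_age = max_age, ages = ages
  )
}

# Closed-form CEAC for the package's default PSA framing: draws q from a
# normal(mu, sigma) truncated to [0, 1]; HIT is cost-effective at lambda
# iff q exceeds lit + cost_diff / (qaly * lambda + cost_per_quitter).
ceac_closed_form <- function(wtp, lit, ci, cost_diff, per_quitter) {
  mu <- mean(ci)
  sigma <- diff(ci) / (2 * qnorm(0.975))
  za <- pnorm((0 - mu) / sigma)
  zb <- pnorm((1 - mu) / sigma)
  thr <- lit + cost_diff / (per_quitter[["qaly"]] * wtp + per_quitter[["cost"]])
  z <- pmin(pmax((thr - mu) / sigma, (0 - mu) / sigma), (1 - mu) / sigma)
  (zb - pnorm(z)) / (zb - za)
}
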