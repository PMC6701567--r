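#' Discount factor
#'
#' `(1 + rate)^(-year_index)`, with year 0 undiscounted. Vectorised over
#' `year_index`.
#'
#' @param year_index non-negative integer cycle index (0 = intervention year).
#' @param rate annual discount rate.
#' @export
discount_factor <- function(year_index, rate) {
  if (any(year_index < 0)) stop("`year_index` must be >= 0", call. = FALSE)
  if (rate < 0) stop("`rate` must be >= 0", call. = FALSE)
  (1 + rate)^(-year_index)
}

# Annual transition matrices for one cohort profile. States are
# well, one absorbing-except-death state per disease, and death; death is
# optionally split into disease-attributable and other-cause (used for the
# occupancy trace; rewards are zero in both, so the split never affects
# cost/QALY totals). Competing outflows exceeding probability 1 are
# resolved by proportional allocation.
.build_transitions <- function(sex, start_age, status, params,
                               split_dead = FALSE) {
  diseases <- params$diseases
  dead_states <- if (split_dead) c("dead_disease", "dead_other") else "dead"
  states <- c("well", diseases, dead_states)
  n_cycles <- params$max_age - start_age
  tmax <- ncol(params$decay_fraction) - 1L
  lapply(seq_len(n_cycles) - 1L, function(t) {
    age <- as.character(start_age + t)
    M <- matrix(0, length(states), length(states),
                dimnames = list(states, states))
    bg <- params$background_mortality[sex, age]
    inc <- vapply(diseases, function(d) {
      i_n <- params$incidence_never[d, sex, age]
      i_s <- params$incidence_smoker[d, sex, age]
      if (status == "smoker") i_s
      else i_n + params$decay_fraction[d, as.character(min(t, tmax))] * (i_s - i_n)
    }, numeric(1))
    out <- sum(inc) + bg
    if (out > 1) {  # proportional allocation of competing outflows
      inc <- inc / out
      bg <- bg / out
      out <- 1
    }
    M["well", diseases] <- inc
    M["well", dead_states[length(dead_states)]] <- bg
    M["well", "well"] <- 1 - out
    for (d in diseases) {
      cf_d <- params$case_fatality[d, sex, age]
      bg_d <- params$background_mortality[sex, age]
      dth <- cf_d + bg_d
      if (dth > 1) {
        cf_d <- cf_d / dth
        bg_d <- bg_d / dth
        dth <- 1
      }
      if (split_dead) {
        M[d, "dead_disease"] <- cf_d
        M[d, "dead_other"] <- bg_d
      } else {
        M[d, "dead"] <- cf_d + bg_d
      }
      M[d, d] <- 1 - dth
    }
    for (s in dead_states) M[s, s] <- 1
    rs <- rowSums(M)
    if (any(abs(rs - 1) > 1e-9)) {
      stop("internal consistency error: transition row sums deviate from 1",
           call. = FALSE)
    }
    M
  })
}

#' Transition matrices for a cohort profile
#'
#' One annual matrix per cycle from `start_age` to the model horizon, over
#' states `well`, each disease, `dead`. Quitter incidence of disease `d`
#' at `t` years after quitting is
#' `incidence_never + decay_fraction(d, t) * (incidence_smoker - incidence_never)`;
#' there is no relapse. Exposed mainly so the engine can be cross-checked
#' against independent path enumeration.
#'
#' @inheritParams simulate_cohort
#' @return a list of row-stochastic matrices.
#' @export
transition_matrices <- function(sex = c("male", "female"), start_age,
                                status = c("smoker", "quitter"), params) {
  sex <- match.arg(sex)
  status <- match.arg(status)
  validate_parameters(params)
  .build_transitions(sex, start_age, status, params, split_dead = FALSE)
}

#' Simulate a cohort of one smoking status to the model horizon
#'
#' Annual-cycle deterministic cohort simulation from `start_age` to
#' `max_age` (default 95). The cohort starts well; each cycle it can
#' develop one of the modelled diseases (absorbing except for death) or
#' die of other causes. Societal costs (`disease_cost` per year in state)
#' and QALYs (`utility` per year in state) accrue at cycle start — no
#' half-cycle correction — and are discounted at `discount_rate`, year 0
#' undiscounted.
#'
#' @param sex `"male"` or `"female"`.
#' @param start_age integer age at model entry, in `[min(ages), max_age - 1]`.
#' @param status `"smoker"` (lifelong continuing smoker) or `"quitter"`
#'   (quit at `start_age`; the post-quit clock starts at 0).
#' @param params a [model_parameters()] object.
#' @return `lifetime_outcome`: list with `discounted_cost`,
#'   `discounted_qalys`, and `trace`, a data.frame of state occupancy at
#'   each cycle start (death split into disease-attributable and
#'   other-cause columns; each row sums to 1).
#' @examples
#' p <- generate_synthetic_parameters(seed = 1)
#' simulate_cohort("female", 40, "quitter", p)$discounted_qalys
#' @export
simulate_cohort <- function(sex = c("male", "female"), start_age,
                            status = c("smoker", "quitter"), params) {
  sex <- match.arg(sex)
  status <- match.arg(status)
  validate_parameters(params)
  if (start_age < min(params$ages) || start_age >= params$max_age) {
    stop(sprintf("`start_age` must lie in [%d, %d]", min(params$ages),
                 params$max_age - 1L), call. = FALSE)
  }
  mats <- .build_transitions(sex, start_age, status, params, split_dead = TRUE)
  states <- rownames(mats[[1]])
  reward_cost <- setNames(numeric(length(states)), states)
  reward_cost[params$diseases] <- params$disease_cost[params$diseases]
  reward_util <- setNames(numeric(length(states)), states)
  reward_util["well"] <- params$utility[["well"]]
  reward_util[params$diseases] <- params$utility[params$diseases]
  n_cycles <- length(mats)
  occ <- setNames(numeric(length(states)), states)
  occ["well"] <- 1
  trace <- matrix(NA_real_, n_cycles + 1L, length(states),
                  dimnames = list(NULL, states))
  cost <- 0
  qaly <- 0
  for (t in seq_len(n_cycles) - 1L) {
    trace[t + 1L, ] <- occ
    if (abs(sum(occ) - 1) > 1e-9) {
      stop("internal consistency error: occupancy not conserved", call. = FALSE)
    }
    df <- discount_factor(t, params$discount_rate)
    cost <- cost + df * sum(occ * reward_cost)
    qaly <- qaly + df * sum(occ * reward_util)
    occ <- drop(occ %*% mats[[t + 1L]])
  }
  trace[n_cycles + 1L, ] <- occ
  trace <- data.frame(cycle = 0:n_cycles, age = start_age + 0:n_cycles, trace)
  structure(list(discounted_cost = cost, discounted_qalys = qaly,
                 sex = sex, start_age = start_age, status = status,
                 trace = trace),
            class = "lifetime_outcome")
}

#' @export
print.lifetime_outcome <- function(x, ...) {
  cat(sprintf("<lifetime_outcome> %s %s, start age %d\n", x$sex, x$status,
              x$start_age))
  cat(sprintf("  discounted societal cost: %.0f EUR\n", x$discounted_cost))
  cat(sprintf("  discounted QALYs:         %.3f\n", x$discounted_qalys))
  invisible(x)
}

#' Per-person benefit of quitting at a given age
#'
#' Runs [simulate_cohort()] for a lifelong smoker and for a quitter with
#' the same sex and start age, and differences the discounted totals
#' outside the model: `costs_avoided = smoker cost - quitter cost`,
#' `qalys_gained = quitter QALYs - smoker QALYs`.
#'
#' @inheritParams simulate_cohort
#' @return `quit_benefit`: list with `costs_avoided`, `qalys_gained` and
#'   the two underlying `lifetime_outcome` objects.
#' @export
quit_benefit <- function(sex = c("male", "female"), start_age, params) {
  sex <- match.arg(sex)
  smoker <- simulate_cohort(sex, start_age, "smoker", params)
  quitter <- simulate_cohort(sex, start_age, "quitter", params)
  structure(list(
    costs_avoided = smoker$discounted_cost - quitter$discounted_cost,
    qalys_gained = quitter$discounted_qalys - smoker$discounted_qalys,
    smoker = smoker, quitter = quitter
  ), class = "quit_benefit")
}

#' @export
print.quit_benefit <- function(x, ...) {
  cat(sprintf("<quit_benefit> %s, quit at %d: %.0f EUR avoided, %.3f QALYs gained\n",
              x$smoker$sex, x$smoker$start_age, x$costs_avoided, x$qalys_gained))
  invisible(x)
}

#' Sweep quit benefits over sexes and 5-year age bands
#'
#' Engine runs are keyed by the band midpoint (e.g. age 42 for "40-44"),
#' matching how banded published estimates are compared to single-age
#' model output.
#'
#' @param params a [model_parameters()] object.
#' @param band_starts lower edges of 5-year bands (default 20 to 65).
#' @param sexes subset of `c("female", "male")`.
#' @return data.frame `(sex, age_group, costs_avoided, qalys_gained)` —
#'   the shape of the published per-person benefit table (sex labelled
#'   `women`/`men`).
#' @export
quit_benefit_table <- function(params, band_starts = seq(20, 65, by = 5),
                               sexes = c("female", "male")) {
  rows <- lapply(sexes, function(sx) {
    lab <- if (sx == "female") "women" else "men"
    do.call(rbind, lapply(band_starts, function(a0) {
      qb <- quit_benefit(sx, a0 + 2L, params)
      data.frame(sex = lab, age_group = sprintf("%d-%d", a0, a0 + 4L),
                 costs_avoided = qb$costs_avoided,
                 qalys_gained = qb$qalys_gained)
    }))
  })
  do.call(rbind, rows)
}
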