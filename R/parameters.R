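#' Model parameter container for the smoking-cessation Markov model
#'
#' Bundles every input the cohort engine needs: annual never-smoker and
#' current-smoker incidence by disease, sex and single year of age; the
#' remaining excess-risk fraction by years since quitting; annual case
#' fatality in each disease state; background (all-other-cause) mortality;
#' yearly societal cost per disease state; utility weights per state; the
#' annual discount rate and the model horizon (default age 95).
#'
#' Probabilities are annual transition probabilities, not rates. The
#' quitter's incidence of disease `d` at `t` years after quitting is
#' `incidence_never + decay_fraction(d, t) * (incidence_smoker -
#' incidence_never)`; there is no relapse back to smoking.
#'
#' @param incidence_never,incidence_smoker,case_fatality numeric arrays
#'   `[disease, sex, age]` of annual probabilities, with dimnames
#'   `diseases` x `c("male","female")` x `ages`.
#' @param background_mortality numeric matrix `[sex, age]` of annual
#'   all-other-cause death probabilities.
#' @param decay_fraction numeric matrix `[disease, t]`, columns named
#'   `"0","1",...`: the fraction of the smoker's excess incidence that
#'   remains `t` years after quitting; row-wise non-increasing with
#'   `decay_fraction[, "0"] == 1`.
#' @param disease_cost named numeric, euro per year spent in each disease
#'   state (the well state costs nothing).
#' @param utility named numeric QALY weights for `well`, each disease and
#'   `dead` (which must be 0), all in `[0, 1]`.
#' @param discount_rate annual discount rate (default 0.03).
#' @param max_age model horizon; cycles stop at this age (default 95).
#' @param ages integer vector of ages covered by the age-indexed inputs.
#'
#' @return An object of class `model_parameters`.
#' @seealso [generate_synthetic_parameters()], [validate_parameters()],
#'   [apply_scenario()], [write_parameters()]
#' @export
model_parameters <- function(incidence_never, incidence_smoker, case_fatality,
                             background_mortality, decay_fraction,
                             disease_cost, utility,
                             discount_rate = 0.03, max_age = 95,
                             ages = 19:95) {
  diseases <- dimnames(incidence_never)[[1]]
  p <- structure(
    list(
      diseases = diseases,
      sexes = c("male", "female"),
      ages = as.integer(ages),
      incidence_never = incidence_never,
      incidence_smoker = incidence_smoker,
      case_fatality = case_fatality,
      background_mortality = background_mortality,
      decay_fraction = decay_fraction,
      disease_cost = disease_cost,
      utility = utility,
      discount_rate = discount_rate,
      max_age = as.integer(max_age)
    ),
    class = "model_parameters"
  )
  validate_parameters(p)
  p
}

#' Validate a `model_parameters` object
#'
#' Checks every structural invariant: all probabilities in `[0, 1]`,
#' smoker incidence at least the never-smoker incidence everywhere,
#' decay fractions starting at 1 and non-increasing in time since quit,
#' `utility["dead"] == 0`, non-negative discount rate.
#'
#' @param params a [model_parameters()] object.
#' @return `params`, invisibly; errors name the offending field.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "model_parameters"))
  assert_prob(params$incidence_never, "incidence_never")
  assert_prob(params$incidence_smoker, "incidence_smoker")
  assert_prob(params$case_fatality, "case_fatality")
  assert_prob(params$background_mortality, "background_mortality")
  assert_prob(params$decay_fraction, "decay_fraction")
  if (any(params$incidence_smoker < params$incidence_never)) {
    stop("incidence_smoker must be >= incidence_never for every (disease, sex, age)",
         call. = FALSE)
  }
  if (any(abs(params$decay_fraction[, 1] - 1) > 1e-12)) {
    stop("decay_fraction must equal 1 at t = 0 for every disease", call. = FALSE)
  }
  if (ncol(params$decay_fraction) > 1) {
    d <- t(apply(params$decay_fraction, 1, diff))
    if (any(d > 1e-12)) {
      stop("decay_fraction must be non-increasing in time since quit", call. = FALSE)
    }
  }
  assert_prob(params$utility, "utility")
  if (!"dead" %in% names(params$utility) || params$utility[["dead"]] != 0) {
    stop("utility must include 'dead' with weight 0", call. = FALSE)
  }
  if (!"well" %in% names(params$utility)) {
    stop("utility must include a 'well' state weight", call. = FALSE)
  }
  if (!setequal(names(params$disease_cost), params$diseases)) {
    stop("disease_cost must name exactly the modelled diseases", call. = FALSE)
  }
  if (any(params$disease_cost < 0) || any(!is.finite(params$disease_cost))) {
    stop("disease_cost must be finite and non-negative", call. = FALSE)
  }
  if (!is.finite(params$discount_rate) || params$discount_rate < 0) {
    stop("discount_rate must be >= 0", call. = FALSE)
  }
  if (params$max_age > max(params$ages) + 1L) {
    stop("max_age exceeds the age range covered by the parameter tables",
         call. = FALSE)
  }
  invisible(params)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("<model_parameters>\n")
  cat("  diseases:     ", paste(x$diseases, collapse = ", "), "\n")
  cat("  ages:         ", min(x$ages), "-", max(x$ages),
      " (horizon ", x$max_age, ")\n", sep = "")
  cat("  discount rate:", x$discount_rate, "per year\n")
  rr <- range(x$incidence_smoker / pmax(x$incidence_never, .Machine$double.eps))
  cat(sprintf("  smoker/never relative risk range: %.2f-%.2f\n", rr[1], rr[2]))
  invisible(x)
}

# Anchors for the synthetic generator: annual probabilities and euro values
# calibrated to order of magnitude only (the study's own national parameter
# tables are unpublished). b0 = never-smoker incidence at age 19, k = log
# slope per year of age; rr = smoker relative risk; tau = e-folding time
# (years) of excess-risk decay after quitting; residual = excess fraction
# that never resolves.
.synth_anchor <- list(
  diseases = c("lung_cancer", "copd", "chd", "stroke"),
  b0       = c(lung_cancer = 1e-5, copd = 2e-5,  chd = 5e-4, stroke = 2e-4),
  slope    = c(lung_cancer = 0.055, copd = 0.06, chd = 0.045, stroke = 0.05),
  rr       = c(lung_cancer = 15,   copd = 10,    chd = 2,    stroke = 2),
  case_fatality = c(lung_cancer = 0.35, copd = 0.06, chd = 0.08, stroke = 0.10),
  decay_tau      = c(lung_cancer = 4, copd = 4, chd = 2, stroke = 2),
  decay_residual = c(lung_cancer = 0.10, copd = 0.10, chd = 0, stroke = 0),
  disease_cost = c(lung_cancer = 45000, copd = 12000, chd = 15000, stroke = 28000),
  utility = c(well = 0.88, lung_cancer = 0.55, copd = 0.65, chd = 0.72,
              stroke = 0.55, dead = 0),
  gompertz = c(level = 8.5e-6, slope = 0.0905),  # background mortality
  male_mortality_factor = 1.5,
  male_incidence_factor = c(lung_cancer = 1.3, copd = 1.2, chd = 1.4,
                            stroke = 1.1)
)

#' Generate a synthetic parameter set
#'
#' Stands in for the unpublished national parameter tables behind the
#' published analysis: produces a complete, internally consistent
#' [model_parameters()] set whose incidence curves rise with age, whose
#' smoker incidence is a disease-specific relative-risk multiple of the
#' never-smoker incidence, and whose excess risk after quitting decays
#' exponentially towards a disease-specific residual within 10-15 years.
#' Values are calibrated to epidemiological orders of magnitude only; they
#' do not reproduce any national estimates.
#'
#' Seeded jitter (lognormal, ~10%) perturbs levels so property tests sweep
#' a family of plausible models; the output is deterministic given `seed`
#' and passes [validate_parameters()] by construction.
#'
#' @param seed single non-negative integer.
#' @param config optional list of overrides: `rr` (scalar or per-disease
#'   named vector of relative risks, all >= 1), `decay_tau`,
#'   `decay_residual`, `disease_cost`, `utility`, `discount_rate`,
#'   `max_age`, `jitter` (set `FALSE` for the anchor values exactly).
#' @return a validated [model_parameters()] object.
#' @examples
#' p <- generate_synthetic_parameters(seed = 1)
#' p
#' @export
generate_synthetic_parameters <- function(seed = 1L, config = list()) {
  a <- .synth_anchor
  diseases <- a$diseases
  expand <- function(x, what, default) {
    if (is.null(x)) return(default)
    if (length(x) == 1L && is.null(names(x))) {
      return(setNames(rep(as.numeric(x), length(diseases)), diseases))
    }
    if (!all(names(x) %in% diseases)) {
      stop(sprintf("unknown disease in `%s` override: %s", what,
                   paste(setdiff(names(x), diseases), collapse = ", ")),
           call. = FALSE)
    }
    out <- default
    out[names(x)] <- as.numeric(x)
    out
  }
  rr <- expand(config$rr, "rr", a$rr)
  if (any(rr < 1)) stop("`rr`: relative risks must be >= 1", call. = FALSE)
  tau <- expand(config$decay_tau, "decay_tau", a$decay_tau)
  if (any(tau <= 0)) stop("`decay_tau` must be positive", call. = FALSE)
  residual <- expand(config$decay_residual, "decay_residual", a$decay_residual)
  assert_prob(residual, "decay_residual")
  cost <- expand(config$disease_cost, "disease_cost", a$disease_cost)
  utility <- a$utility
  if (!is.null(config$utility)) utility[names(config$utility)] <- config$utility
  assert_prob(utility, "utility")
  discount_rate <- config$discount_rate %||% 0.03
  if (discount_rate < 0) stop("`discount_rate` must be >= 0", call. = FALSE)
  max_age <- config$max_age %||% 95L
  jitter <- isTRUE(config$jitter %||% TRUE)

  ages <- 19:max(95L, max_age)
  sexes <- c("male", "female")
  dn <- list(diseases, sexes, as.character(ages))
  with_seed(seed, {
    jit <- function(n, sd = 0.1) if (jitter) exp(rnorm(n, 0, sd)) else rep(1, n)
    b0 <- a$b0[diseases] * jit(length(diseases))
    slope <- a$slope[diseases] * jit(length(diseases), 0.05)
    inc_never <- array(0, dim = lengths(dn), dimnames = dn)
    for (d in diseases) {
      curve <- pmin(b0[d] * exp(slope[d] * (ages - 19)), 0.05)
      inc_never[d, "male", ] <- pmin(curve * a$male_incidence_factor[d], 0.05)
      inc_never[d, "female", ] <- curve
    }
    inc_smoker <- inc_never
    for (d in diseases) inc_smoker[d, , ] <- pmin(inc_never[d, , ] * rr[d], 0.5)
    cf <- array(0, dim = lengths(dn), dimnames = dn)
    cf_base <- a$case_fatality[diseases] * jit(length(diseases), 0.05)
    for (d in diseases) {
      curve <- pmin(cf_base[d] * exp(0.01 * (ages - 19)), 0.8)
      cf[d, "male", ] <- curve
      cf[d, "female", ] <- curve
    }
    gl <- a$gompertz[["level"]] * (if (jitter) exp(rnorm(1, 0, 0.05)) else 1)
    bg <- rbind(
      male = pmin(a$male_mortality_factor * gl * exp(a$gompertz[["slope"]] * ages), 0.5),
      female = pmin(gl * exp(a$gompertz[["slope"]] * ages), 0.5)
    )
    colnames(bg) <- as.character(ages)
    tmax <- max_age - min(ages)
    tt <- 0:tmax
    decay <- t(vapply(diseases, function(d) {
      residual[d] + (1 - residual[d]) * exp(-tt / tau[d])
    }, numeric(length(tt))))
    decay[, 1] <- 1
    dimnames(decay) <- list(diseases, as.character(tt))
    cost_j <- cost * jit(length(cost), 0.05)

    model_parameters(
      incidence_never = inc_never, incidence_smoker = inc_smoker,
      case_fatality = cf, background_mortality = bg,
      decay_fraction = decay, disease_cost = cost_j, utility = utility,
      discount_rate = discount_rate, max_age = max_age, ages = ages
    )
  })
}

#' Multivariate sensitivity scenario
#'
#' A deterministic "what if" transformation of a parameter set: scale the
#' disease costs, scale the excess (smoker minus never-smoker) incidence,
#' scale all death probabilities, and subtract a constant from the
#' post-quit remaining-risk fractions (floored at zero).
#'
#' `low_cost_low_risk_scenario()` returns the published conservative
#' multivariate scenario: costs down 25%, disease risks down 50%, death
#' risks down 10%, post-quit risk fractions down by 0.1.
#'
#' @param cost_multiplier,disease_risk_multiplier,death_risk_multiplier
#'   fractions in `(0, 1]`.
#' @param decay_fraction_delta subtraction applied to `decay_fraction` for
#'   `t >= 1` (the `t = 0` fraction is pinned at 1), in `[0, 1]`.
#' @return an object of class `sensitivity_scenario`.
#' @export
sensitivity_scenario <- function(cost_multiplier = 1,
                                 disease_risk_multiplier = 1,
                                 death_risk_multiplier = 1,
                                 decay_fraction_delta = 0) {
  chk <- function(x, what) {
    if (!is.finite(x) || x <= 0 || x > 1) {
      stop(sprintf("`%s` must lie in (0, 1]", what), call. = FALSE)
    }
  }
  chk(cost_multiplier, "cost_multiplier")
  chk(disease_risk_multiplier, "disease_risk_multiplier")
  chk(death_risk_multiplier, "death_risk_multiplier")
  if (decay_fraction_delta < 0 || decay_fraction_delta > 1) {
    stop("`decay_fraction_delta` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(cost_multiplier = cost_multiplier,
                 disease_risk_multiplier = disease_risk_multiplier,
                 death_risk_multiplier = death_risk_multiplier,
                 decay_fraction_delta = decay_fraction_delta),
            class = "sensitivity_scenario")
}

#' @rdname sensitivity_scenario
#' @export
low_cost_low_risk_scenario <- function() {
  sensitivity_scenario(cost_multiplier = 0.75,
                       disease_risk_multiplier = 0.5,
                       death_risk_multiplier = 0.9,
                       decay_fraction_delta = 0.1)
}

#' Apply a sensitivity scenario to a parameter set
#'
#' Returns a new [model_parameters()] object; the input is unchanged.
#' Death probabilities that would leave `[0, 1]` after scaling are clamped
#' with a warning (cannot occur for multipliers `<= 1`).
#'
#' @param params a [model_parameters()] object.
#' @param scenario a [sensitivity_scenario()].
#' @return a validated, transformed [model_parameters()] object.
#' @export
apply_scenario <- function(params, scenario) {
  validate_parameters(params)
  stopifnot(inherits(scenario, "sensitivity_scenario"))
  out <- params
  out$disease_cost <- params$disease_cost * scenario$cost_multiplier
  excess <- params$incidence_smoker - params$incidence_never
  out$incidence_smoker <- params$incidence_never +
    excess * scenario$disease_risk_multiplier
  clamp <- function(x, what) {
    if (any(x > 1) || any(x < 0)) {
      warning(sprintf("%s clamped to [0, 1] after scenario scaling", what))
      x <- pmin(pmax(x, 0), 1)
    }
    x
  }
  out$case_fatality <- clamp(params$case_fatality * scenario$death_risk_multiplier,
                             "case_fatality")
  out$background_mortality <- clamp(
    params$background_mortality * scenario$death_risk_multiplier,
    "background_mortality")
  dk <- pmax(params$decay_fraction - scenario$decay_fraction_delta, 0)
  dk[, 1] <- 1  # t = 0: no time has elapsed since quitting
  out$decay_fraction <- dk
  validate_parameters(out)
}

# ---- CSV round trip -------------------------------------------------------

#' Write / read a parameter set as plain CSV
#'
#' Three files are written to `dir`: `rates.csv` with columns
#' `(disease, sex, age, incidence_never, incidence_smoker, case_fatality)`
#' (background mortality travels as pseudo-disease `background` in the
#' `case_fatality` column), `decay.csv` with
#' `(disease, years_since_quit, decay_fraction)`, and `values.csv` holding
#' disease costs, utilities, the discount rate and the horizon.
#'
#' @param params a [model_parameters()] object.
#' @param dir directory (created if needed).
#' @return `write_parameters()`: the directory, invisibly;
#'   `read_parameters()`: a validated [model_parameters()] object equal to
#'   the one written.
#' @export
write_parameters <- function(params, dir) {
  validate_parameters(params)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- expand.grid(disease = params$diseases, sex = params$sexes,
                   age = params$ages, stringsAsFactors = FALSE)
  idx <- cbind(g$disease, g$sex, as.character(g$age))
  rates <- data.frame(
    g,
    incidence_never = params$incidence_never[idx],
    incidence_smoker = params$incidence_smoker[idx],
    case_fatality = params$case_fatality[idx]
  )
  bg <- data.frame(disease = "background", sex = rep(params$sexes, each = length(params$ages)),
                   age = rep(params$ages, times = 2),
                   incidence_never = NA_real_, incidence_smoker = NA_real_,
                   case_fatality = as.vector(t(params$background_mortality)))
  write.csv(rbind(rates, bg), file.path(dir, "rates.csv"), row.names = FALSE)
  tt <- as.integer(colnames(params$decay_fraction))
  decay <- data.frame(
    disease = rep(params$diseases, each = length(tt)),
    years_since_quit = rep(tt, times = length(params$diseases)),
    decay_fraction = as.vector(t(params$decay_fraction))
  )
  write.csv(decay, file.path(dir, "decay.csv"), row.names = FALSE)
  vals <- rbind(
    data.frame(kind = "cost", state = names(params$disease_cost),
               value = unname(params$disease_cost)),
    data.frame(kind = "utility", state = names(params$utility),
               value = unname(params$utility)),
    data.frame(kind = "discount_rate", state = "", value = params$discount_rate),
    data.frame(kind = "max_age", state = "", value = params$max_age)
  )
  write.csv(vals, file.path(dir, "values.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(dir) {
  rates <- read.csv(file.path(dir, "rates.csv"))
  decay <- read.csv(file.path(dir, "decay.csv"))
  vals <- read.csv(file.path(dir, "values.csv"))
  diseases <- setdiff(unique(rates$disease), "background")
  sexes <- c("male", "female")
  ages <- sort(unique(rates$age))
  dn <- list(diseases, sexes, as.character(ages))
  arr <- function(col) {
    a <- array(NA_real_, dim = lengths(dn), dimnames = dn)
    sub <- rates[rates$disease != "background", ]
    a[cbind(sub$disease, sub$sex, as.character(sub$age))] <- sub[[col]]
    a
  }
  bg_rows <- rates[rates$disease == "background", ]
  bg <- matrix(NA_real_, 2, length(ages), dimnames = list(sexes, as.character(ages)))
  bg[cbind(bg_rows$sex, as.character(bg_rows$age))] <- bg_rows$case_fatality
  tt <- sort(unique(decay$years_since_quit))
  dk <- matrix(NA_real_, length(diseases), length(tt),
               dimnames = list(diseases, as.character(tt)))
  dk[cbind(decay$disease, as.character(decay$years_since_quit))] <- decay$decay_fraction
  costs <- vals[vals$kind == "cost", ]
  utils_ <- vals[vals$kind == "utility", ]
  model_parameters(
    incidence_never = arr("incidence_never"),
    incidence_smoker = arr("incidence_smoker"),
    case_fatality = arr("case_fatality"),
    background_mortality = bg,
    decay_fraction = dk,
    disease_cost = setNames(costs$value, costs$state),
    utility = setNames(utils_$value, utils_$state),
    discount_rate = vals$value[vals$kind == "discount_rate"],
    max_age = vals$value[vals$kind == "max_age"],
    ages = ages
  )
}
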