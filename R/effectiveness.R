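#' Logistic model of sustained abstinence
#'
#' Coefficients, on the logit scale, of the regression of sustained
#' abstinence on programme (1 = HIT, 0 = LIT), gender (1 = male,
#' 0 = female) and age in years (trial range 19-71).
#'
#' `trial_abstinence_model()` builds the model from the packaged
#' `"table2_logistic"` fixture — the published fit: intercept -3.124,
#' programme +1.001, gender -0.077, age +0.005.
#'
#' @param intercept,programme,gender,age coefficients (logit units; `age`
#'   per year).
#' @param se optional named numeric of standard errors
#'   (`programme`, `gender`, `age`, `intercept`), used for Wald CIs.
#' @return an object of class `abstinence_model`.
#' @export
abstinence_model <- function(intercept, programme, gender, age, se = NULL) {
  coefs <- c(intercept = intercept, programme = programme,
             gender = gender, age = age)
  if (any(!is.finite(coefs))) stop("coefficients must be finite", call. = FALSE)
  structure(list(coefficients = coefs, se = se), class = "abstinence_model")
}

#' @rdname abstinence_model
#' @export
trial_abstinence_model <- function() {
  tab <- load_fixture_table("table2_logistic")
  co <- setNames(tab$coefficient, tab$term)
  abstinence_model(intercept = co[["intercept"]],
                   programme = co[["programme"]],
                   gender = co[["gender"]], age = co[["age"]])
}

#' @export
print.abstinence_model <- function(x, ...) {
  cat("<abstinence_model> logit(P_abstinent) =\n  ")
  co <- x$coefficients
  cat(sprintf("%.3f %+.3f*programme %+.3f*gender %+.3f*age\n",
              co["intercept"], co["programme"], co["gender"], co["age"]))
  invisible(x)
}

#' Linear predictor (logit) of sustained abstinence
#'
#' Vectorised over the covariates. Ages outside the trial range 19-71
#' trigger an extrapolation warning, not an error.
#'
#' @param model an [abstinence_model()].
#' @param programme 1 = HIT, 0 = LIT.
#' @param gender 1 = male, 0 = female.
#' @param age years.
#' @export
linear_predictor <- function(model, programme, gender, age) {
  stopifnot(inherits(model, "abstinence_model"))
  if (!all(programme %in% c(0, 1)) || !all(gender %in% c(0, 1))) {
    stop("`programme` and `gender` must be coded 0/1", call. = FALSE)
  }
  if (any(age < 19 | age > 71)) {
    warning("age outside the trial range [19, 71]: extrapolating")
  }
  co <- model$coefficients
  co[["intercept"]] + co[["programme"]] * programme +
    co[["gender"]] * gender + co[["age"]] * age
}

#' Inverse-logit abstinence probability
#'
#' `exp(x) / (1 + exp(x))`, strictly in (0, 1) and monotone in `x`.
#' @param logit numeric logit value(s).
#' @export
abstinence_probability <- function(logit) {
  if (any(!is.finite(logit))) stop("`logit` must be finite", call. = FALSE)
  plogis(logit)
}

#' Odds ratio for one model term
#'
#' `exp(coefficient)`; when a standard error is available (from
#' [fit_abstinence_model()] or supplied to [abstinence_model()]) a Wald
#' `level` confidence interval `exp(coef +/- z * se)` is attached.
#'
#' @param model an [abstinence_model()].
#' @param term one of `"programme"`, `"gender"`, `"age"`, `"intercept"`.
#' @param level confidence level (default 0.95).
#' @return named list `or`, `ci` (NULL without a standard error).
#' @examples
#' odds_ratio(trial_abstinence_model(), "programme")$or  # 2.72
#' @export
odds_ratio <- function(model, term, level = 0.95) {
  stopifnot(inherits(model, "abstinence_model"))
  if (!term %in% names(model$coefficients)) {
    stop("unknown term '", term, "'; available: ",
         paste(names(model$coefficients), collapse = ", "), call. = FALSE)
  }
  or <- exp(model$coefficients[[term]])
  ci <- NULL
  if (!is.null(model$se) && term %in% names(model$se)) {
    z <- qnorm(1 - (1 - level) / 2)
    ci <- exp(model$coefficients[[term]] + c(-1, 1) * z * model$se[[term]])
  }
  list(or = or, ci = ci)
}

#' Fit the abstinence model to individual-level records
#'
#' Maximum-likelihood logistic regression (`stats::glm`, binomial logit)
#' of `abstinent` on `programme + gender + age`. Complete separation or
#' non-convergence raises an error with a diagnostic rather than
#' returning a silently useless fit.
#'
#' @param records data.frame with columns `programme`, `gender` (0/1),
#'   `age`, `abstinent` (0/1), as produced by [simulate_trial()].
#' @return an [abstinence_model()] carrying standard errors and, as
#'   attributes, the `glm` fit's variance-covariance matrix.
#' @export
fit_abstinence_model <- function(records) {
  req <- c("programme", "gender", "age", "abstinent")
  if (!all(req %in% names(records))) {
    stop("records need columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  tab <- table(records$abstinent)
  if (length(tab) < 2L || any(tab < 2L)) {
    stop("separation-prone input: need at least 2 records per outcome class",
         call. = FALSE)
  }
  fit <- withCallingHandlers(
    glm(abstinent ~ programme + gender + age, family = binomial(),
        data = records),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        stop("perfect or quasi-perfect separation detected in the logistic fit",
             call. = FALSE)
      }
      invokeRestart("muffleWarning")
    }
  )
  if (!fit$converged) {
    stop("logistic fit did not converge (", fit$iter, " iterations)",
         call. = FALSE)
  }
  if (any(abs(coef(fit)) > 15)) {
    # glm can "converge" under perfect separation without warning; logit
    # effects this large are never genuine in abstinence data
    stop("perfect or quasi-perfect separation detected: |coefficient| > 15 (",
         paste(sprintf("%s=%.1f", names(coef(fit)), coef(fit)), collapse = ", "),
         ")", call. = FALSE)
  }
  co <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  m <- abstinence_model(
    intercept = co[["(Intercept)"]], programme = co[["programme"]],
    gender = co[["gender"]], age = co[["age"]],
    se = c(intercept = se[["(Intercept)"]], programme = se[["programme"]],
           gender = se[["gender"]], age = se[["age"]])
  )
  attr(m, "vcov") <- vcov(fit)
  attr(m, "n") <- nrow(records)
  m
}

#' Simulate individual-level trial records
#'
#' Generates participant records shaped like the trial's: two arms of
#' `n_per_arm`, gender drawn with probability `p_male` of being male,
#' ages from `age_distribution`, and Bernoulli abstinence outcomes with
#' success probability from the logistic model. Defaults emulate the
#' trial cohort: ~78% women, ages normal(48.6, 10) truncated to [19, 71].
#'
#' @param n_per_arm participants per arm.
#' @param model an [abstinence_model()].
#' @param age_distribution function `n -> ages`; default truncated normal.
#' @param p_male probability a participant is male (default 0.22).
#' @param seed RNG seed.
#' @return data.frame `(programme, gender, age, abstinent)`.
#' @export
simulate_trial <- function(n_per_arm, model = trial_abstinence_model(),
                           age_distribution = NULL, p_male = 0.22,
                           seed = 1L) {
  stopifnot(n_per_arm >= 1)
  if (is.null(age_distribution)) {
    age_distribution <- function(n) rtrunc_norm(n, 48.6, 10, 19, 71)
  }
  with_seed(seed, {
    n <- 2L * as.integer(n_per_arm)
    rec <- data.frame(
      programme = rep(c(1L, 0L), each = n_per_arm),
      gender = rbinom(n, 1L, p_male),
      age = age_distribution(n)
    )
    p <- abstinence_probability(
      linear_predictor(model, rec$programme, rec$gender, rec$age))
    rec$abstinent <- rbinom(n, 1L, p)
    rec
  })
}

# Truncated normal via inverse-CDF; exact, no rejection loop.
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Read/write participant records CSV
#' @param records data.frame as from [simulate_trial()].
#' @param path CSV path.
#' @export
write_records <- function(records, path) {
  write.csv(records[, c("programme", "gender", "age", "abstinent")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) read.csv(path)

#' Serialise a fitted abstinence model to a small text file
#'
#' Plain `term,coefficient,se` CSV; round-trips through
#' [read_abstinence_model()].
#' @param model an [abstinence_model()].
#' @param path file path.
#' @export
write_abstinence_model <- function(model, path) {
  stopifnot(inherits(model, "abstinence_model"))
  se <- model$se %||% setNames(rep(NA_real_, 4), names(model$coefficients))
  write.csv(data.frame(term = names(model$coefficients),
                       coefficient = unname(model$coefficients),
                       se = unname(se[names(model$coefficients)])),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abstinence_model
#' @export
read_abstinence_model <- function(path) {
  tab <- read.csv(path)
  co <- setNames(tab$coefficient, tab$term)
  se <- setNames(tab$se, tab$term)
  if (all(is.na(se))) se <- NULL
  abstinence_model(intercept = co[["intercept"]], programme = co[["programme"]],
                   gender = co[["gender"]], age = co[["age"]], se = se)
}
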