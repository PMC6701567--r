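#' Configuration for the probabilistic sensitivity analysis
#'
#' The PSA varies only the HIT quit rate: LIT is fixed at its observed
#' quit rate and the HIT rate is drawn from a distribution matched to its
#' 95% CI. Each draw is converted to per-participant incremental cost and
#' QALYs using the per-quitter benefit of the reference group (the group
#' with the most quitters: women 40-44, 8 532 EUR / 0.71 QALYs) and the
#' per-participant intervention-cost difference (612 EUR).
#'
#' The sampling distribution is a normal with mean at the CI midpoint and
#' standard deviation `(high - low) / (2 * 1.96)`, truncated to `[0, 1]`;
#' a moment-matched beta is available via `distribution = "beta"`.
#'
#' @param n_runs number of Monte-Carlo draws (published analysis: 10 000).
#' @param seed RNG seed.
#' @param lit_quit_rate fixed LIT quit rate (default 0.07).
#' @param hit_ci `(low, high)` 95% CI for the HIT quit rate
#'   (default `c(0.09, 0.22)`).
#' @param per_quitter_benefit `(euro, QALY)` per quitter.
#' @param per_participant_cost_diff euro (default 612).
#' @param wtp_grid sorted non-negative willingness-to-pay values (EUR/QALY).
#' @param distribution `"truncnorm"` (default) or `"beta"`.
#' @return an object of class `psa_config`.
#' @export
psa_config <- function(n_runs = 10000L, seed = 1L, lit_quit_rate = 0.07,
                       hit_ci = c(0.09, 0.22),
                       per_quitter_benefit = c(cost = 8532, qaly = 0.71),
                       per_participant_cost_diff = 612,
                       wtp_grid = seq(0, 20000, by = 500),
                       distribution = c("truncnorm", "beta")) {
  distribution <- match.arg(distribution)
  if (n_runs < 1) stop("`n_runs` must be >= 1", call. = FALSE)
  if (lit_quit_rate <= 0 || lit_quit_rate >= 1) {
    stop("`lit_quit_rate` must lie in (0, 1)", call. = FALSE)
  }
  if (length(hit_ci) != 2 || hit_ci[1] < 0 || hit_ci[2] > 1 ||
      hit_ci[1] > hit_ci[2]) {
    stop("`hit_ci` must be (low, high) with 0 <= low <= high <= 1",
         call. = FALSE)
  }
  if (any(wtp_grid < 0) || is.unsorted(wtp_grid)) {
    stop("`wtp_grid` must be non-negative and sorted", call. = FALSE)
  }
  structure(list(n_runs = as.integer(n_runs), seed = seed,
                 lit_quit_rate = lit_quit_rate, hit_ci = hit_ci,
                 per_quitter_benefit = per_quitter_benefit,
                 per_participant_cost_diff = per_participant_cost_diff,
                 wtp_grid = wtp_grid, distribution = distribution),
            class = "psa_config")
}

#' Draw HIT quit rates
#'
#' Inverse-CDF sampling from the configured distribution; deterministic
#' given `config$seed`. A degenerate CI (`low == high`) returns constant
#' draws.
#'
#' @param config a [psa_config()].
#' @return numeric vector of length `n_runs`, values in `[0, 1]`.
#' @export
sample_hit_rate <- function(config) {
  stopifnot(inherits(config, "psa_config"))
  lo <- config$hit_ci[1]
  hi <- config$hit_ci[2]
  if (hi == lo) return(rep(lo, config$n_runs))
  mu <- (lo + hi) / 2
  sigma <- (hi - lo) / (2 * qnorm(0.975))
  with_seed(config$seed, {
    if (config$distribution == "truncnorm") {
      rtrunc_norm(config$n_runs, mu, sigma, 0, 1)
    } else {
      v <- sigma^2
      k <- mu * (1 - mu) / v - 1
      if (k <= 0) stop("beta moment match infeasible for this CI", call. = FALSE)
      stats::rbeta(config$n_runs, mu * k, (1 - mu) * k)
    }
  })
}

#' Run the probabilistic sensitivity analysis
#'
#' Per draw `q`: incremental QALYs `(q - lit_quit_rate) * per-quitter
#' QALYs`; incremental cost `per_participant_cost_diff -
#' (q - lit_quit_rate) * per-quitter costs avoided`.
#'
#' @param config a [psa_config()].
#' @return `psa_result`: data.frame `(hit_rate, inc_cost, inc_qaly)` with
#'   the config attached as attribute `"config"`.
#' @export
run_psa <- function(config = psa_config()) {
  q <- sample_hit_rate(config)
  dq <- q - config$lit_quit_rate
  out <- data.frame(
    hit_rate = q,
    inc_cost = config$per_participant_cost_diff -
      dq * config$per_quitter_benefit[[1]],
    inc_qaly = dq * config$per_quitter_benefit[[2]]
  )
  attr(out, "config") <- config
  class(out) <- c("psa_result", class(out))
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay `lambda`, the probability that HIT is
#' cost-effective versus LIT: the fraction of draws with strictly
#' positive net monetary benefit `lambda * inc_qaly - inc_cost` (ties
#' count as not cost-effective).
#'
#' @param draws a [run_psa()] result, or any data.frame with `inc_cost`
#'   and `inc_qaly`.
#' @param wtp_grid willingness-to-pay values; defaults to the config
#'   attached to `draws`, else 0-20 000 EUR/QALY in steps of 500.
#' @return data.frame `(wtp, probability_cost_effective)`.
#' @export
ceac <- function(draws, wtp_grid = NULL) {
  if (NROW(draws) < 1L) stop("`draws` must contain at least one draw",
                             call. = FALSE)
  if (is.null(wtp_grid)) {
    cfg <- attr(draws, "config")
    wtp_grid <- if (!is.null(cfg)) cfg$wtp_grid else seq(0, 20000, by = 500)
  }
  prob <- vapply(wtp_grid, function(lambda) {
    mean(lambda * draws$inc_qaly - draws$inc_cost > 0)
  }, numeric(1))
  data.frame(wtp = wtp_grid, probability_cost_effective = prob)
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param curve a [ceac()] data.frame.
#' @param file optional PNG path; when given, the plot is written there.
#' @param ... passed to [graphics::plot()].
#' @return `curve`, invisibly.
#' @export
plot_ceac <- function(curve, file = NULL, ...) {
  draw <- function() {
    plot(curve$wtp, curve$probability_cost_effective, type = "l",
         ylim = c(0, 1), xlab = "Willingness-to-pay (EUR/QALY)",
         ylab = "P(HIT cost-effective vs LIT)",
         main = "Cost-effectiveness acceptability curve", ...)
    abline(h = c(0.5, 0.95), lty = 3, col = "grey50")
  }
  if (!is.null(file)) {
    png(file, width = 800, height = 600)
    on.exit(dev.off())
    draw()
  } else {
    draw()
  }
  invisible(curve)
}
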