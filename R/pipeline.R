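#' Run configuration for the pipeline
#'
#' A validated bag of options for [run_pipeline()]. `options` depends on
#' the command:
#' * `"report"` — `horizon` (`"short"`/`"long"`), optional `scenario`
#'   (`"low_cost_low_risk"`): render the incremental CEA from the packaged
#'   published inputs, recomputing every derived row.
#' * `"cea"` — `horizon`: recompute the incremental CEA by aggregating the
#'   per-person benefit fixtures over the abstinent-count differentials.
#' * `"per_person"` — `gender`: population-level per-person CEA.
#' * `"psa"` — any [psa_config()] argument; writes draws, CEAC table and
#'   a CEAC PNG.
#' * `"synth"` — `what` (`"parameters"` and/or `"trial"`), `n_per_arm`;
#'   writes synthetic parameter tables / trial records.
#' * `"simulate"` — `sex`, `age`, `status`; writes the occupancy trace and
#'   a summary for one cohort on synthetic parameters.
#' * `"quit_benefit"` — sweep [quit_benefit_table()] on synthetic
#'   parameters.
#'
#' @param command one of the commands above.
#' @param output_dir directory for artifacts (created if needed).
#' @param seed integer; recorded in every output header and used for all
#'   randomness.
#' @param discount_rate annual discount rate for engine-backed commands.
#' @param options named list of command options.
#' @return an object of class `run_config`.
#' @export
run_config <- function(command = c("report", "cea", "per_person", "psa",
                                   "synth", "simulate", "quit_benefit"),
                       output_dir = ".", seed = 1L, discount_rate = 0.03,
                       options = list()) {
  command <- match.arg(command)
  structure(list(command = command, output_dir = output_dir,
                 seed = as.integer(seed), discount_rate = discount_rate,
                 options = options),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file with fields `command`, `output_dir`, `seed`,
#'   `discount_rate`, `options`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(command = x$command, output_dir = x$output_dir %||% ".",
             seed = x$seed %||% 1L,
             discount_rate = x$discount_rate %||% 0.03,
             options = as.list(x$options))
}

# Hash of the analytic configuration (output_dir excluded, so the same
# analysis written to two places is byte-identical).
config_hash <- function(config) {
  x <- unclass(config)
  x$output_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

# CSV with '#' provenance header lines; deterministic (no timestamps) so a
# repeated run is byte-identical. Read back with read_output_csv().
write_output_csv <- function(df, path, config, extra = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  meta <- c(
    sprintf("# quitcea %s", as.character(utils::packageVersion("quitcea"))),
    sprintf("# command: %s", config$command),
    sprintf("# seed: %d", config$seed),
    sprintf("# config_hash: %s", config_hash(config)),
    sprintf("# fixtures: %s", paste(fixture_names(), collapse = " ")),
    extra
  )
  writeLines(meta, con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname run_pipeline
#' @param path a CSV written by [run_pipeline()].
#' @export
read_output_csv <- function(path) read.csv(path, comment.char = "#")

table4_column <- function(res) {
  data.frame(
    quantity = c("intervention_cost_hit", "intervention_cost_lit",
                 "intervention_cost_diff", "societal_costs_avoided",
                 "incremental_cost", "incremental_qalys", "icer"),
    value = c(res$cost_hit, res$cost_lit,
              format(res$result)[c("delta_intervention_cost",
                                   "societal_costs_avoided",
                                   "incremental_net_cost",
                                   "incremental_qalys", "icer")])
  )
}

#' Run one pipeline command and write its artifacts
#'
#' Deterministic given the config (same config twice gives byte-identical
#' CSVs); every output carries a provenance header with the package
#' version, command, seed, config hash and fixture registry. On failure,
#' partially written outputs are removed before the error propagates.
#'
#' @param config a [run_config()] (or path to a JSON config readable by
#'   [read_run_config()]).
#' @return invisibly, a character vector of written file paths.
#' @examples
#' cfg <- run_config("report", output_dir = tempdir(),
#'                   options = list(horizon = "short"))
#' run_pipeline(cfg)
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  out <- function(name) {
    p <- file.path(config$output_dir, name)
    written <<- c(written, p)
    p
  }
  opts <- config$options
  tryCatch({
    switch(config$command,
      report = {
        horizon <- opts$horizon %||% "short"
        scenario <- opts$scenario
        col <- if (!is.null(scenario)) {
          if (!identical(scenario, "low_cost_low_risk")) {
            stop("unknown scenario '", scenario, "'", call. = FALSE)
          }
          "cea_long_sensitivity"
        } else if (horizon == "short") "cea_short" else "cea_long"
        t4 <- load_fixture_table("table4")
        costs <- load_fixture_table("intervention_costs")
        g <- function(q) t4[[col]][t4$quantity == q]
        res <- incremental_analysis(
          cost_HIT = g("intervention_cost_hit"),
          cost_LIT = g("intervention_cost_lit"),
          avoided = g("societal_costs_avoided"),
          qalys = g("incremental_qalys"),
          delta_intervention_cost = g("intervention_cost_diff"))
        df <- table4_column(list(cost_hit = g("intervention_cost_hit"),
                                 cost_lit = g("intervention_cost_lit"),
                                 result = res))
        write_output_csv(df, out("report.csv"), config,
                         extra = sprintf("# column: %s", col))
      },
      cea = {
        horizon <- opts$horizon %||% "short"
        counts <- load_fixture_table("table3_counts")
        pp <- load_fixture_table("table3_per_person", refined = TRUE)
        d <- if (horizon == "short") {
          data.frame(sex = counts$sex, age_group = counts$age_group,
                     n_hit = counts$n_hit_short, n_lit = counts$n_lit_short)
        } else {
          data.frame(sex = counts$sex, age_group = counts$age_group,
                     n_hit = counts$n_hit_long, n_lit = counts$n_lit_long)
        }
        agg <- aggregate_benefits(d, pp)
        costs <- load_fixture_table("intervention_costs")
        ch <- costs$total_specific_cost[costs$programme == "HIT"]
        cl <- costs$total_specific_cost[costs$programme == "LIT"]
        t4 <- load_fixture_table("table4")
        res <- incremental_analysis(
          ch, cl, agg$costs_avoided, agg$qalys_gained,
          delta_intervention_cost =
            t4$cea_short[t4$quantity == "intervention_cost_diff"])
        df <- table4_column(list(cost_hit = ch, cost_lit = cl, result = res))
        write_output_csv(df, out("cea.csv"), config,
                         extra = sprintf("# horizon: %s", horizon))
      },
      per_person = {
        gender <- opts$gender %||% "men"
        res <- per_person_cea(gender = gender,
                              age = opts$age %||% 48.6)
        df <- table4_column(list(cost_hit = 801, cost_lit = 189, result = res))
        write_output_csv(df, out(sprintf("per_person_%s.csv", gender)), config,
                         extra = sprintf("# gender: %s", gender))
      },
      psa = {
        cfg <- psa_config(
          n_runs = opts$n_runs %||% 10000L, seed = config$seed,
          lit_quit_rate = opts$lit_quit_rate %||% 0.07,
          hit_ci = unlist(opts$hit_ci %||% c(0.09, 0.22)),
          wtp_grid = unlist(opts$wtp_grid %||% seq(0, 20000, by = 500)))
        draws <- run_psa(cfg)
        curve <- ceac(draws)
        write_output_csv(as.data.frame(draws), out("psa_draws.csv"), config)
        write_output_csv(curve, out("ceac.csv"), config)
        plot_ceac(curve, file = out("ceac.png"))
      },
      synth = {
        what <- opts$what %||% c("parameters", "trial")
        if ("parameters" %in% what) {
          p <- generate_synthetic_parameters(
            seed = config$seed,
            config = list(discount_rate = config$discount_rate))
          pdir <- file.path(config$output_dir, "parameters")
          write_parameters(p, pdir)
          written <- c(written, file.path(pdir, c("rates.csv", "decay.csv",
                                                  "values.csv")))
        }
        if ("trial" %in% what) {
          rec <- simulate_trial(opts$n_per_arm %||% 150L, seed = config$seed)
          write_records(rec, out("trial_records.csv"))
        }
      },
      simulate = {
        p <- generate_synthetic_parameters(
          seed = config$seed,
          config = list(discount_rate = config$discount_rate))
        res <- simulate_cohort(opts$sex %||% "female", opts$age %||% 40,
                               opts$status %||% "quitter", p)
        write_output_csv(res$trace, out("trace.csv"), config)
        write_output_csv(
          data.frame(quantity = c("discounted_cost", "discounted_qalys"),
                     value = c(res$discounted_cost, res$discounted_qalys)),
          out("summary.csv"), config)
      },
      quit_benefit = {
        p <- generate_synthetic_parameters(
          seed = config$seed,
          config = list(discount_rate = config$discount_rate))
        write_output_csv(quit_benefit_table(p), out("quit_benefits.csv"),
                         config)
      }
    )
    invisible(written)
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
}
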