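.fixture_files <- c(
  table3                  = "table3.csv",
  table3_per_person       = "table3.csv",
  table3_counts           = "table3.csv",
  intervention_costs      = "intervention_costs.csv",
  table1_counts           = "table1_counts.csv",
  table2_logistic         = "table2_logistic.csv",
  table4                  = "table4.csv",
  random_person_estimates = "random_person_estimates.csv"
)

#' Packaged transcriptions of the trial's published summary tables
#'
#' The package ships, as plain CSV under `inst/extdata/`, the published
#' per-person model estimates and abstinent counts by sex and 5-year age
#' band (`"table3"`, with views `"table3_per_person"` and
#' `"table3_counts"`), the programme-specific intervention costs
#' (`"intervention_costs"`), participant and outcome counts
#' (`"table1_counts"`), the logistic abstinence coefficients with odds
#' ratios (`"table2_logistic"`), the incremental cost-effectiveness
#' summary (`"table4"`; the men's per-person ICER is `NA` because the
#' published cell is the dominance marker "<0"), and the random-person
#' model estimates (`"random_person_estimates"`).
#'
#' **De-rounding** (`refined = TRUE`, for `"table3_per_person"`): the
#' published per-person euro/QALY values are rounded, but the published
#' group-difference cells equal count-difference times the *unrounded*
#' per-person value. Where a count difference exceeds 1 in absolute value,
#' dividing the group cell by it recovers an extra decimal (e.g. 42 658 / 5
#' = 8531.6 for women 40-44). The refined view prefers the short-term cell,
#' then the long-term cell, then the printed per-person value; with it the
#' short-term aggregation reproduces the published totals exactly.
#'
#' @param name one of the registry names above.
#' @param refined logical; only used for `"table3_per_person"`.
#' @return a data.frame.
#' @examples
#' load_fixture_table("table3_per_person")[4, ]  # women 40-44: 8532, 0.71
#' @export
load_fixture_table <- function(name, refined = FALSE) {
  if (length(name) != 1L || !name %in% names(.fixture_files)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(.fixture_files), collapse = ", "), call. = FALSE)
  }
  path <- system.file("extdata", .fixture_files[[name]], package = "quitcea")
  tab <- read.csv(path, stringsAsFactors = FALSE)
  switch(name,
    table3_per_person = {
      pp <- tab[, c("sex", "age_group", "costs_avoided", "qalys_gained")]
      if (refined) {
        ds <- tab$n_hit_short - tab$n_lit_short
        dl <- tab$n_hit_long - tab$n_lit_long
        for (i in seq_len(nrow(tab))) {
          if (abs(ds[i]) > 1) {
            pp$costs_avoided[i] <- tab$costs_short[i] / ds[i]
            pp$qalys_gained[i] <- tab$qalys_short[i] / ds[i]
          } else if (abs(dl[i]) > 1) {
            pp$costs_avoided[i] <- tab$costs_long[i] / dl[i]
            pp$qalys_gained[i] <- tab$qalys_long[i] / dl[i]
          }
        }
      }
      pp
    },
    table3_counts = tab[, c("sex", "age_group", "n_hit_short", "n_lit_short",
                            "n_hit_long", "n_lit_long")],
    tab
  )
}

#' @rdname load_fixture_table
#' @export
fixture_names <- function() names(.fixture_files)
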