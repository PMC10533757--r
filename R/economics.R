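#' Cost-and-time ledger for a built-in scenario
#'
#' Deterministic semester-by-semester accounting of each calibration
#' scenario: generation-advance trials (always at the surrogate location
#' PAL, 0.4 of a PAL phenotyping unit), phenotype-evaluation trials (1
#' unit of their location's currency for the full population, scaled by
#' the evaluated fraction as printed), and the GP calibration milestone.
#' Costs are held as integer hundredths of a unit so totals are exact
#' decimals; PAL and SRO units are never added together.
#'
#' @param name one of `"Uni1"`, `"Uni2"`, `"Uni3"`, `"Multi1"`,
#'   `"Multi2"`.
#' @return Object of class `cost_ledger`: `entries` (data.frame),
#'   `totals` (named `c(PAL =, SRO =)` in units), `elapsed_semesters`,
#'   `years_to_calibration`.
#' @export
scenario_ledger <- function(name = c("Uni1", "Uni2", "Uni3", "Multi1",
                                     "Multi2")) {
  name <- match.arg(name)
  e <- function(sem, trans, frac, act, loc, cost)
    data.frame(semester = sem, transition = trans, fraction = frac,
               activity = act, location = loc,
               cost_centi = as.integer(round(cost * 100)),
               stringsAsFactors = FALSE)
  adv <- function(sem, trans, frac = 1)
    e(sem, trans, frac, "generation_advance", "PAL", 0.4)
  entries <- switch(name,
    Uni1 = rbind(adv("Yr1-A", "S0:1->S0:2"),
                 adv("Yr1-B", "S0:2->S0:3"),
                 adv("Yr2-A", "S0:3->S0:4"),
                 e("Yr3-A", "S0:4->S0:5", 1, "phenotype_eval", "SRO", 1.0),
                 e("Yr3-A", "", 1, "gp_calibration", "SRO", 0)),
    Uni2 = rbind(adv("Yr1-A", "S0:1->S0:2"),
                 adv("Yr1-B", "S0:2->S0:3"),
                 e("Yr2-A", "S0:2->S0:3", 1, "phenotype_eval", "SRO", 1.0),
                 e("Yr2-A", "", 1, "gp_calibration", "SRO", 0),
                 e("Yr2-B", "S0:3->S0:4", NA, "generation_advance", "PAL",
                   0.05)),
    Uni3 = rbind(adv("Yr1-A", "S0:1->S0:2"),
                 adv("Yr1-B", "S0:2->S0:3"),
                 e("Yr2-A", "S0:3->S0:4", 1, "phenotype_eval", "SRO", 1.0),
                 e("Yr2-A", "", 1, "gp_calibration", "SRO", 0)),
    Multi1 = rbind(adv("Yr1-A", "S0:1->S0:2"),
                   adv("Yr1-B", "S0:2->S0:3"),
                   adv("Yr2-A", "S0:3->S0:4"),
                   e("Yr2-B", "S0:4->S0:5", 1, "phenotype_eval", "PAL", 1.0),
                   e("Yr3-A", "S0:4->S0:5", 1, "phenotype_eval", "SRO", 1.0),
                   e("Yr3-A", "", 1, "gp_calibration", "SRO", 0)),
    Multi2 = rbind(adv("Yr1-A", "S0:1->S0:2"),
                   e("Yr1-B", "S0:2->S0:3", 1, "phenotype_eval", "PAL", 1.0),
                   e("Yr2-A", "S0:3->S0:4", 0.5, "phenotype_eval", "SRO",
                     0.6),
                   e("Yr2-A", "", 1, "gp_calibration", "SRO", 0)))
  yrs <- c(Uni1 = 2.5, Uni2 = 1.5, Uni3 = 1.5, Multi1 = 2.5, Multi2 = 1.5)
  structure(list(scenario = name, entries = entries,
                 totals = ledger_totals(entries),
                 elapsed_semesters = length(unique(entries$semester)),
                 years_to_calibration = unname(yrs[name])),
            class = "cost_ledger")
}

ledger_totals <- function(entries) {
  if (nrow(entries) == 0) return(c(PAL = 0, SRO = 0))
  if (any(entries$cost_centi < 0)) stop("negative cost entry")
  tot <- c(PAL = 0L, SRO = 0L)
  agg <- tapply(entries$cost_centi, entries$location, sum)
  tot[names(agg)] <- agg
  tot / 100
}

#' Totals for a user-supplied ledger
#'
#' @param entries data.frame with at least `location` (`"PAL"`/`"SRO"`)
#'   and either `cost` (units) or `cost_centi` (integer hundredths).
#' @return Named `c(PAL =, SRO =)` totals in units; exact summation per
#'   currency.
#' @export
custom_ledger <- function(entries) {
  if (nrow(entries) == 0) return(c(PAL = 0, SRO = 0))
  if (!"cost_centi" %in% names(entries)) {
    if (!"cost" %in% names(entries)) stop("need a cost or cost_centi column")
    entries$cost_centi <- as.integer(round(entries$cost * 100))
  }
  ledger_totals(entries)
}

#' @export
#' @method print cost_ledger
print.cost_ledger <- function(x, ...) {
  cat("cost_ledger", x$scenario, "-", x$elapsed_semesters, "semesters,",
      x$years_to_calibration, "years to calibration\n")
  print(x$entries[, c("semester", "transition", "activity", "location",
                      "cost_centi")])
  cat(sprintf("totals: %.2f X$_PAL + %.2f X$_SRO\n",
              x$totals["PAL"], x$totals["SRO"]))
  invisible(x)
}
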