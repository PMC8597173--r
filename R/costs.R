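#' Construct a treatment strategy
#'
#' A strategy bundles the per-dose drug and administration unit costs,
#' the re-dosing interval (= Markov cycle length), and the
#' adverse-event profile. Doses per year are `12 / cycle_length_months`:
#' 2.4 for the dexamethasone implant (5-month cycle), 3 for
#' triamcinolone (4-month cycle).
#'
#' @param id character identifier, e.g. `"dexamethasone"`.
#' @param drug_unit_cost EUR per dose per eye.
#' @param administration_unit_cost EUR per administration visit per eye.
#' @param cycle_length_months positive re-dosing interval.
#' @param adverse_events data frame with columns `name`, `unit_cost`
#'   (EUR), `incidence_per_cycle` (probability), `once_only` (logical).
#' @return A `treatment_strategy` object.
#' @export
treatment_strategy <- function(id, drug_unit_cost, administration_unit_cost,
                               cycle_length_months,
                               adverse_events = empty_adverse_events()) {
  if (!is.numeric(cycle_length_months) || cycle_length_months <= 0) {
    stop("'cycle_length_months' must be positive", call. = FALSE)
  }
  if (drug_unit_cost < 0 || administration_unit_cost < 0) {
    stop("unit costs must be non-negative", call. = FALSE)
  }
  ae <- as.data.frame(adverse_events, stringsAsFactors = FALSE)
  needed <- c("name", "unit_cost", "incidence_per_cycle", "once_only")
  if (!all(needed %in% names(ae))) {
    stop("'adverse_events' must have columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  if (any(ae$incidence_per_cycle < 0) || any(ae$incidence_per_cycle > 1)) {
    stop("adverse-event incidences must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      id = as.character(id),
      drug_unit_cost = as.numeric(drug_unit_cost),
      administration_unit_cost = as.numeric(administration_unit_cost),
      cycle_length_months = as.numeric(cycle_length_months),
      adverse_events = ae
    ),
    class = "treatment_strategy"
  )
}

empty_adverse_events <- function() {
  data.frame(name = character(), unit_cost = numeric(),
             incidence_per_cycle = numeric(), once_only = logical(),
             stringsAsFactors = FALSE)
}

#' Default adverse-event profile for a strategy
#'
#' Corticosteroid adverse events at 2019 Kuopio University Hospital
#' unit prices, with per-cycle incidences specific to each drug.
#' Cataract surgery, laser, and vitrectomy (both for IOP elevation) are
#' treated at most once per patient over the whole follow-up
#' (`once_only = TRUE`); IOP medication, endophthalmitis, and retinal
#' detachment can recur every cycle. IOP medication cost is drug plus
#' medical visit (12.55 + 65.00 EUR).
#'
#' @param strategy `"dexamethasone"` or `"triamcinolone"`.
#' @return Data frame with columns `name`, `unit_cost`,
#'   `incidence_per_cycle`, `once_only`.
#' @export
default_adverse_events <- function(strategy = c("dexamethasone", "triamcinolone")) {
  strategy <- match.arg(strategy)
  inc <- switch(strategy,
    dexamethasone = c(iop_medication = 0.0890, laser = 0.0049,
                      vitrectomy = 0.0047, cataract = 0.0577,
                      endophthalmitis = 0.0025, retinal_detachment = 0.0004),
    triamcinolone = c(iop_medication = 0.1228, laser = 0.0065,
                      vitrectomy = 0.0129, cataract = 0.1264,
                      endophthalmitis = 0.0020, retinal_detachment = 0.0003)
  )
  data.frame(
    name = c("IOP medication", "Laser", "Vitrectomy", "Cataract",
             "Endophthalmitis", "Retinal detachment"),
    unit_cost = c(12.55 + 65.00, 82.00, 1195.00, 1373.00, 3101.00, 2706.00),
    incidence_per_cycle = unname(inc),
    once_only = c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Default treatment strategies
#'
#' The base-case comparators: the dexamethasone 0.7 mg implant (1075
#' EUR per implant, 90 EUR medical visit for administration, 5-month
#' cycle) and the triamcinolone 40 mg/ml injection (207 EUR per
#' injection, 76 EUR nurse visit, 4-month cycle), each with its default
#' adverse-event profile.
#'
#' @return Named list of two [treatment_strategy()] objects.
#' @export
default_strategies <- function() {
  list(
    dexamethasone = treatment_strategy(
      "dexamethasone", drug_unit_cost = 1075, administration_unit_cost = 90,
      cycle_length_months = 5,
      adverse_events = default_adverse_events("dexamethasone")
    ),
    triamcinolone = treatment_strategy(
      "triamcinolone", drug_unit_cost = 207, administration_unit_cost = 76,
      cycle_length_months = 4,
      adverse_events = default_adverse_events("triamcinolone")
    )
  )
}

#' @export
print.treatment_strategy <- function(x, ...) {
  cat("Treatment strategy:", x$id, "\n")
  cat("  drug", x$drug_unit_cost, "EUR/dose; administration",
      x$administration_unit_cost, "EUR/dose;",
      x$cycle_length_months, "month cycle (",
      round(12 / x$cycle_length_months, 2), "doses/year )\n")
  cat("  adverse events:", nrow(x$adverse_events), "\n")
  invisible(x)
}

#' Default follow-up schedule
#'
#' Monitoring every patient under treatment receives, with per-year
#' utilizations: OCT plus medical visit (50 + 65 EUR, 6x/year),
#' intraocular-pressure measurement (76 EUR, 13x/year), and fluorescein
#' angiography (77 EUR, 1x/year) — 1755 EUR per person-year in total.
#' Accrued for persons in states 1-4 by default (a blind patient is no
#' longer monitored; configurable via `followup_in_state5`).
#'
#' @return A `followup_schedule`: data frame with columns `name`,
#'   `unit_cost`, `utilization_per_year`.
#' @export
default_followup <- function() {
  structure(
    data.frame(
      name = c("OCT + medical visit", "IOP measurement", "FAG"),
      unit_cost = c(50 + 65, 76, 77),
      utilization_per_year = c(6, 13, 1),
      stringsAsFactors = FALSE
    ),
    class = c("followup_schedule", "data.frame")
  )
}

#' Default rehabilitation schedule
#'
#' Annual rehabilitation costs for visual impairment (occupational
#' 2496, discretionary 2176, medical 2648 EUR/year; 7320 EUR/year in
#' total), applied to persons in states 4 and 5.
#'
#' @return A `rehab_schedule`: list with `components` (data frame of
#'   `name`, `annual_cost`) and `applies_to_states`.
#' @export
default_rehab <- function() {
  structure(
    list(
      components = data.frame(
        name = c("Occupational rehabilitation", "Discretionary rehabilitation",
                 "Medical rehabilitation"),
        annual_cost = c(2496, 2176, 2648),
        stringsAsFactors = FALSE
      ),
      applies_to_states = c(4L, 5L)
    ),
    class = "rehab_schedule"
  )
}

#' Annual cost breakdown for a strategy
#'
#' Per-year costs implied by the unit costs and utilizations: drug cost
#' per year is `drug_unit_cost * 12 / cycle_length_months` (one treated
#' eye), administration likewise, and each follow-up item is
#' `unit_cost * utilization_per_year`.
#'
#' @param strategy a [treatment_strategy()].
#' @param followup a follow-up schedule (default [default_followup()]).
#' @return Data frame with columns `item`, `unit_cost`,
#'   `utilization_per_year`, `cost_per_year`.
#' @examples
#' annual_cost_summary(default_strategies()$dexamethasone)
#' @export
annual_cost_summary <- function(strategy, followup = default_followup()) {
  stopifnot(inherits(strategy, "treatment_strategy"))
  doses <- 12 / strategy$cycle_length_months
  df <- data.frame(
    item = c("Medication", "Administration", followup$name),
    unit_cost = c(strategy$drug_unit_cost, strategy$administration_unit_cost,
                  followup$unit_cost),
    utilization_per_year = c(doses, doses, followup$utilization_per_year),
    stringsAsFactors = FALSE
  )
  df$cost_per_year <- df$unit_cost * df$utilization_per_year
  df
}
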